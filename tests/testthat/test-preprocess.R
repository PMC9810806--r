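test_that("consumer-read removal drops matching OTUs and tallies reads", {
  tax <- tiny_taxonomy()
  tab <- make_counts(rbind(c(90, 7, 3), c(50, 0, 10)),
                     samples = c("g1", "g2"),
                     otus = c("otu5", "otu1", "otu2"))
  out <- remove_consumer_reads(tab, tax, "Polyarthra", "genus")
  expect_identical(colnames(out), c("otu1", "otu2"))
  expect_identical(unname(out["g1", ]), c(7L, 3L))
  expect_identical(unname(attr(out, "removed_reads")), c(90, 50))
  expect_identical(attr(out, "empty_samples"), character())

  # no matching OTU: the table is untouched
  no_hit <- tab[, c("otu1", "otu2")]
  same <- remove_consumer_reads(no_hit, tax)
  expect_identical(same[, ], no_hit[, ])
  expect_identical(unname(attr(same, "removed_reads")), c(0L, 0L))
})

test_that("a sample made of consumer reads only is flagged empty, not dropped", {
  tax <- tiny_taxonomy()
  tab <- make_counts(rbind(c(90, 0, 0), c(10, 5, 5)),
                     samples = c("g1", "g2"),
                     otus = c("otu5", "otu1", "otu2"))
  expect_warning(out <- remove_consumer_reads(tab, tax), "g1")
  expect_identical(attr(out, "empty_samples"), "g1")
  expect_identical(nrow(out), 2L)
})

test_that("rank aggregation sums counts and pools unassigned into buckets", {
  tax <- tiny_taxonomy()
  tab <- make_counts(rbind(c(3, 4, 5, 2), c(1, 0, 2, 7)),
                     otus = c("otu1", "otu2", "otu3", "otu4"))
  agg <- aggregate_by_rank(tab, tax, "class")
  expect_identical(agg[1, "Chlorophyceae"], 7L)  # otu1 + otu2 share a class
  expect_identical(agg[1, "unclassified Chlorophyta"], 5L)
  expect_identical(agg[1, "unclassified Eukaryota"], 2L)
})

test_that("aggregation conserves reads and commutes with consumer removal", {
  tax <- tiny_taxonomy()
  for (seed in 1:5) {
    tab <- random_counts(4L, 5L, seed = seed)
    colnames(tab) <- tax$otu_id
    agg <- aggregate_by_rank(tab, tax, "class")
    expect_identical(rowSums(agg), rowSums(tab))

    removed_first <- aggregate_by_rank(
      remove_consumer_reads(tab, tax), tax, "class")
    agg_first <- agg[, colnames(agg) != "Eurotatoria", drop = FALSE]
    expect_identical(removed_first[, sort(colnames(removed_first))],
                     agg_first[, sort(colnames(agg_first))])
  }
})

test_that("relative abundance normalises rows and flags empty samples", {
  tab <- make_counts(rbind(c(2, 1, 1), c(0, 0, 0)))
  rel <- relative_abundance(tab)
  expect_equal(unname(rel[1, ]), c(0.5, 0.25, 0.25))
  expect_identical(attr(rel, "empty_samples"), "s2")
  expect_equal(unname(rel[2, ]), c(0, 0, 0))

  # permuting OTU columns permutes the output identically
  tab2 <- random_counts(3L, 6L, seed = 4)
  perm <- sample(ncol(tab2))
  expect_equal(relative_abundance(tab2)[, perm],
               relative_abundance(tab2[, perm])[, ],
               ignore_attr = TRUE)
})

test_that("rarefaction endpoints are exact", {
  counts <- c(a = 5L, b = 3L, c = 1L, d = 0L)
  full <- rarefaction_curve(counts, sum(counts))
  expect_equal(full$expected_richness, 3)  # every present OTU must appear
  one <- rarefaction_curve(counts, 1L)
  expect_equal(one$expected_richness, 1)   # one read hits exactly one OTU
  expect_error(rarefaction_curve(counts, 10L), "depths")
})

test_that("rarefaction matches the hand-enumerated 2-vs-1 case", {
  # counts {A:2, B:1}, n = 2: of the C(3,2) = 3 subsets, two contain both
  # OTUs and one only A, so E[S] = (2 + 2 + 1)/3 = 5/3
  out <- rarefaction_curve(c(A = 2L, B = 1L), 2L)
  expect_equal(out$expected_richness, 5 / 3)
})

test_that("rarefaction curves are non-decreasing and end at observed richness", {
  tab <- random_counts(3L, 12L, lambda = 6, seed = 7)
  cur <- rarefaction_curves(tab, n_points = 10L)
  for (s in rownames(tab)) {
    er <- cur$expected_richness[cur$sample_id == s]
    expect_true(all(diff(er) >= -1e-10))
    expect_equal(er[length(er)], sum(tab[s, ] > 0))
  }
})

test_that("rarefaction agrees with a Monte-Carlo subsampling oracle", {
  set.seed(31)
  for (i in 1:2) {
    counts <- rpois(8, 12) + 1L
    depth <- floor(sum(counts) / 2)
    exact <- rarefaction_curve(counts, depth)$expected_richness
    mc <- mc_rarefy(counts, depth, n_rep = 4000L)
    expect_lt(abs(exact - mc$mean), 3 * mc$se + 1e-4)
  }
})

test_that("shared/unique OTU sets partition the observed OTUs", {
  a <- make_counts(rbind(c(2, 1, 0)), samples = "s1", otus = c("a", "b", "d"))
  b <- make_counts(rbind(c(3, 2, 0)), samples = "s2", otus = c("b", "c", "d"))
  v <- shared_unique(a, b)
  expect_identical(v$shared, "b")
  expect_identical(v$unique_a, "a")
  expect_identical(v$unique_b, "c")  # d undetected in both groups

  ident <- shared_unique(a, a)
  expect_identical(ident$shared, c("a", "b"))
  expect_identical(ident$n_unique_a + ident$n_unique_b, 0L)
})

test_that("the detection threshold excludes group-level singletons", {
  a <- make_counts(rbind(c(1, 5), c(0, 5)), otus = c("rare", "common"))
  b <- make_counts(rbind(c(1, 5), c(1, 5)), otus = c("rare", "common"))
  v <- shared_unique(a, b, detection_min = 2L)
  expect_identical(v$shared, "common")
  expect_identical(v$unique_a, character())
  expect_identical(v$unique_b, "rare")  # 2 summed reads in b, 1 in a
})
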