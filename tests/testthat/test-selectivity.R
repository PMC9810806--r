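test_that("electivity obeys its algebraic identities", {
  expect_equal(electivity(0.3, 0.3), 0)
  expect_equal(electivity(0.2, 0), 1)
  expect_equal(electivity(0, 0.4), -1)
  expect_equal(electivity(0, 0), 0)
  expect_true(is.nan(electivity(0, 0, zero_zero = NaN)))
  set.seed(1)
  a <- runif(100); b <- runif(100)
  expect_equal(electivity(a, b), -electivity(b, a))
  expect_true(all(abs(electivity(a, b)) <= 1))
  # monotone increasing in the diet share for fixed ambient share
  r <- sort(runif(50))
  expect_true(all(diff(electivity(r, 0.2)) > 0))
  expect_error(electivity(-0.1, 0.5), "non-negative")
  expect_error(electivity(1.2, 0.5), "exceed 1")
})

test_that("classification uses strict thresholds at +/-0.25", {
  expect_identical(classify_electivity(0.72), "preference")
  expect_identical(classify_electivity(-0.47), "discrimination")
  expect_identical(classify_electivity(0.06), "non-selective")
  # boundary values are not selective
  expect_identical(classify_electivity(c(0.25, -0.25)),
                   rep("non-selective", 2L))
  expect_identical(classify_electivity(0.26), "preference")
  expect_error(classify_electivity(1.2), "outside")
  expect_identical(classify_electivity(NA_real_), NA_character_)
  expect_identical(classify_electivity(0.4, threshold = 0.5),
                   "non-selective")
})

test_that("seasonal electivity pools reads across sites per compartment", {
  meta <- data.frame(
    sample_id = c("g1", "g2", "w1", "w2"),
    site = c("S1", "S2", "S1", "S2"), season = "Jun",
    compartment = c("gut", "gut", "water", "water"))
  gut <- make_counts(rbind(c(50, 20), c(25, 5)),
                     samples = c("g1", "g2"), otus = c("A", "B"))
  water <- make_counts(rbind(c(30, 30), c(20, 20)),
                       samples = c("w1", "w2"), otus = c("A", "B"))
  # pooled gut (75, 25) vs pooled water (50, 50)
  et <- electivity_table(gut, water, meta)
  jun <- et[et$season == "Jun", ]
  expect_equal(jun$E[jun$taxon == "A"], 0.2)
  expect_equal(jun$E[jun$taxon == "B"], -1 / 3)

  # equal pooled shares give E = 0 for every taxon
  et0 <- electivity_table(water, water, transform(meta, compartment =
    c("gut", "gut", "water", "water")))
  expect_true(all(et0$E[et0$season == "Jun"] == 0))

  # taxon in the water pool but absent from every gut sample
  gut2 <- gut; gut2[, "B"] <- 0L
  et2 <- electivity_table(gut2, water, meta)
  expect_equal(et2$E[et2$season == "Jun" & et2$taxon == "B"], -1)
  expect_identical(
    et2$classification[et2$season == "Jun" & et2$taxon == "B"],
    "discrimination")
})

test_that("per-site pooling averages site-level electivities", {
  meta <- data.frame(
    sample_id = c("g1", "g2", "w1", "w2"),
    site = c("S1", "S2", "S1", "S2"), season = "Dec",
    compartment = c("gut", "gut", "water", "water"))
  gut <- make_counts(rbind(c(75, 25), c(50, 50)),
                     samples = c("g1", "g2"), otus = c("A", "B"))
  water <- make_counts(rbind(c(50, 50), c(50, 50)),
                       samples = c("w1", "w2"), otus = c("A", "B"))
  et <- electivity_table(gut, water, meta, pooling = "site_mean")
  # site S1 gives E_A = 0.2, site S2 gives 0; the mean is 0.1
  expect_equal(et$E[et$season == "Dec" & et$taxon == "A"], 0.1)
})

test_that("seasons with empty gut pools yield missing records, not values", {
  meta <- data.frame(
    sample_id = c("g1", "w1", "w2"), site = "S1", season = "Mar",
    compartment = c("gut", "water", "water"))
  gut <- make_counts(rbind(c(0, 0)), samples = "g1", otus = c("A", "B"))
  water <- make_counts(rbind(c(5, 5), c(5, 5)),
                       samples = c("w1", "w2"), otus = c("A", "B"))
  et <- electivity_table(gut, water, meta)
  expect_true(all(is.na(et$E[et$season == "Mar"])))
})

test_that("dominance is read share times occupancy", {
  # taxon A in every sample: Y equals its overall share
  tab <- make_counts(rbind(c(40, 8, 2), c(40, 0, 10)),
                     otus = c("A", "B", "C"))
  y <- dominance_index(tab)
  expect_equal(y$Y[y$taxon == "A"], 80 / 100)
  # taxon B: share 8/100, occupancy 1/2
  expect_equal(y$Y[y$taxon == "B"], 0.08 * 0.5)
  # share 0.4 present in half the samples gives 0.2
  tab2 <- make_counts(rbind(c(8, 2), c(0, 10)), otus = c("X", "Z"))
  y2 <- dominance_index(tab2)
  expect_equal(y2$Y[y2$taxon == "X"], 0.4 * 0.5)
  # absent taxon scores zero
  tab3 <- make_counts(cbind(tab, none = c(0L, 0L)))
  expect_equal(dominance_index(tab3)$Y[4], 0)
  # output is sorted by decreasing dominance
  expect_true(all(diff(y$Y) <= 0))
})

test_that("enrichment reproduces the exact rank-sum p on a clean split", {
  gut <- cbind(t1 = c(0.9, 0.8, 0.85, 0.95))
  water <- cbind(t1 = c(0.1, 0.2, 0.15, 0.05))
  gut <- cbind(gut, t2 = 1 - gut[, 1])
  water <- cbind(water, t2 = 1 - water[, 1])
  rownames(gut) <- paste0("g", 1:4); rownames(water) <- paste0("w", 1:4)
  enr <- differential_enrichment(gut, water)
  # complete separation: 2 of the C(8,4) = 70 assignments are as extreme
  expect_equal(enr$p_raw[enr$taxon == "t1"], 2 / 70)
  expect_equal(enr$p_raw[enr$taxon == "t1"],
               wilcox_enum_p(gut[, "t1"], water[, "t1"]))
})

test_that("enrichment handles identical and all-absent taxa by convention", {
  gut <- cbind(same = rep(0.5, 3), zero = 0, var = c(0.5, 0.4, 0.6))
  water <- cbind(same = rep(0.5, 3), zero = 0, var = c(0.1, 0.2, 0.3))
  rownames(gut) <- paste0("g", 1:3); rownames(water) <- paste0("w", 1:3)
  enr <- differential_enrichment(gut, water)
  expect_equal(enr$p_raw[enr$taxon == "same"], 1)
  expect_equal(enr$p_raw[enr$taxon == "zero"], 1)
  expect_lt(enr$p_raw[enr$taxon == "var"], 0.2)
  # FDR-adjusted values never fall below the raw p
  expect_true(all(enr$q_fdr >= enr$p_raw - 1e-12))
})

test_that("empty samples flagged upstream are excluded from testing", {
  gut <- rbind(g1 = c(a = 0.7, b = 0.3), g2 = c(0.6, 0.4),
               g3 = c(0.8, 0.2), g_empty = c(0, 0))
  attr(gut, "empty_samples") <- "g_empty"
  water <- rbind(w1 = c(a = 0.2, b = 0.8), w2 = c(0.3, 0.7),
                 w3 = c(0.1, 0.9))
  enr <- differential_enrichment(gut, water)
  expect_equal(enr$p_raw[enr$taxon == "a"],
               wilcox_enum_p(c(0.7, 0.6, 0.8), c(0.2, 0.3, 0.1)))
})

test_that("rank-sum type-I error is controlled on null data", {
  set.seed(202)
  n_rep <- 400L
  hits <- 0L
  for (i in seq_len(n_rep)) {
    x <- rlnorm(6); y <- rlnorm(6)
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    g <- cbind(t = x / 10); w <- cbind(t = y / 10)
    rownames(g) <- paste0("g", 1:6); rownames(w) <- paste0("w", 1:6)
    enr <- differential_enrichment(g, w)
    expect_equal(enr$p_raw[1], p)
    if (enr$p_raw[1] <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.02)
  expect_lte(hits / n_rep, 0.08)
})

test_that("estimated electivity recovers the simulated truth as depth grows", {
  depths <- c(600L, 6000L, 60000L)
  err <- vapply(depths, function(d) {
    cfg <- sim_config(selectivity_weights = c(OTU003 = 5),
                      season_tilt_sd = 0, depth_water = d,
                      depth_gut = max(20L, d %/% 10), consumer_fraction = 0.5,
                      seed = 77)
    sim <- simulate_study(cfg)
    gut <- remove_consumer_reads(sim$gut, sim$taxonomy)
    et <- electivity_table(gut, sim$water, sim$meta)
    e_hat <- et$E[et$taxon == "OTU003"]
    e_true <- vapply(unique(et$season), function(s)
      truth_electivity(sim$truth, "OTU003", s), numeric(1))
    mean(abs(e_hat - e_true))
  }, numeric(1L))
  expect_true(err[3] < err[1])
  expect_lt(err[3], 0.05)
})
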