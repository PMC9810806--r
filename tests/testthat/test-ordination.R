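test_that("correspondence analysis matches the dense eigen oracle", {
  for (seed in 1:4) {
    Y <- random_counts(6L, 5L, seed = seed)
    ca <- correspondence_analysis(Y)
    expect_equal(ca$eigenvalues, ca_eigen_oracle(Y), tolerance = 1e-10)
    expect_equal(sum(ca$eigenvalues), ca$total_inertia, tolerance = 1e-10)
  }
})

test_that("CA of an independence-model table has zero inertia", {
  Y <- outer(c(1L, 2L, 3L), c(2L, 1L, 1L, 4L))
  dimnames(Y) <- list(paste0("s", 1:3), paste0("t", 1:4))
  expect_equal(correspondence_analysis(Y)$total_inertia, 0,
               tolerance = 1e-12)
  expect_length(correspondence_analysis(Y)$eigenvalues, 0)
})

test_that("a two-block diagonal table yields a unit first eigenvalue", {
  Y <- make_counts(rbind(c(2, 1, 0, 0), c(1, 3, 0, 0),
                         c(0, 0, 4, 1), c(0, 0, 2, 2)))
  expect_equal(correspondence_analysis(Y)$eigenvalues[1], 1,
               tolerance = 1e-10)
})

test_that("CA agrees with vegan on random tables", {
  Y <- random_counts(7L, 6L, seed = 12)
  mine <- correspondence_analysis(Y)$eigenvalues
  ref <- vegan::cca(Y)$CA$eig
  expect_equal(unname(mine), unname(ref[seq_along(mine)]),
               tolerance = 1e-10)
})

test_that("RDA matches vegan and its projection identities", {
  set.seed(21)
  Y <- random_counts(8L, 6L, seed = 21)
  X <- matrix(rnorm(24), 8, 3,
              dimnames = list(rownames(Y), c("a", "b", "c")))
  mine <- rda(Y, X)
  ref <- vegan::rda(Y ~ ., data = as.data.frame(X))
  expect_equal(unname(mine$eigenvalues),
               unname(ref$CCA$eig[seq_along(mine$eigenvalues)]),
               tolerance = 1e-10)
  expect_equal(mine$total_inertia, unname(ref$tot.chi), tolerance = 1e-10)
  expect_lte(mine$constrained_inertia, mine$total_inertia + 1e-10)
  expect_true(all(diff(mine$eigenvalues) <= 1e-12))
  expect_gte(mine$cum_explained_2axes, 0)
  expect_lte(mine$cum_explained_2axes, 1)
})

test_that("full-rank free constraints make RDA constrained inertia total", {
  Y <- random_counts(6L, 5L, seed = 2)
  D <- diag(6)[, 1:5]
  dimnames(D) <- list(rownames(Y), paste0("d", 1:5))
  out <- rda(Y, D)
  expect_equal(out$constrained_inertia, out$total_inertia,
               tolerance = 1e-10)
})

test_that("RDA with group dummies equals PCA of group-mean-fitted data", {
  set.seed(3)
  Y <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:4)))
  g <- rep(c("A", "B", "C"), each = 2)
  X <- stats::model.matrix(~ g)[, -1, drop = FALSE]
  rownames(X) <- rownames(Y)
  out <- rda(Y, X)
  # oracle: replace each row by its group mean, then plain PCA
  Yc <- scale(Y, scale = FALSE)
  fitted <- apply(Yc, 2L, function(col) stats::ave(col, g))
  oracle <- eigen(crossprod(fitted) / (nrow(Y) - 1), symmetric = TRUE)$values
  oracle <- oracle[oracle > 1e-12]
  expect_equal(unname(out$eigenvalues), oracle, tolerance = 1e-10)
})

test_that("RDA is invariant to rescaling environmental columns", {
  Y <- random_counts(8L, 5L, seed = 6)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(rownames(Y), c("a", "b")))
  X2 <- X; X2[, 1] <- X2[, 1] * 1000
  a <- rda(Y, X)
  b <- rda(Y, X2)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-8)
  expect_equal(a$site_scores_lc, b$site_scores_lc, tolerance = 1e-8)
})

test_that("collinear constraints are dropped with a warning", {
  Y <- random_counts(7L, 5L, seed = 8)
  X <- matrix(rnorm(14), 7, 2, dimnames = list(rownames(Y), c("a", "b")))
  X <- cbind(X, dup = X[, "a"] * 2)
  expect_warning(out <- rda(Y, X), "dup")
  expect_identical(out$aliased, "dup")
})

test_that("CCA matches vegan and reproduces CA under free constraints", {
  Y <- random_counts(8L, 6L, seed = 13)
  set.seed(13)
  X <- matrix(rnorm(24), 8, 3,
              dimnames = list(rownames(Y), c("a", "b", "c")))
  mine <- cca(Y, X)
  ref <- vegan::cca(Y ~ ., data = as.data.frame(X))
  expect_equal(unname(mine$eigenvalues),
               unname(ref$CCA$eig[seq_along(mine$eigenvalues)]),
               tolerance = 1e-10)
  expect_equal(mine$total_inertia, unname(ref$tot.chi), tolerance = 1e-10)
  expect_lte(mine$constrained_inertia, mine$total_inertia + 1e-10)

  D <- diag(8)[, 1:7]
  dimnames(D) <- list(rownames(Y), paste0("d", 1:7))
  free <- cca(Y, D)
  plain <- correspondence_analysis(Y)
  expect_equal(unname(free$eigenvalues), unname(plain$eigenvalues),
               tolerance = 1e-10)
})

test_that("a constant constraint contributes nothing to CCA", {
  Y <- random_counts(6L, 5L, seed = 4)
  X <- matrix(1, 6, 1, dimnames = list(rownames(Y), "const"))
  out <- suppressWarnings(cca(Y, X))
  expect_equal(out$constrained_inertia, 0, tolerance = 1e-12)
  expect_length(out$eigenvalues, 0)
})

test_that("the gradient-length decision rule reproduces the printed cases", {
  expect_identical(choose_ordination_method(4.4), "CCA")
  expect_identical(choose_ordination_method(1.6), "RDA")
  expect_identical(choose_ordination_method(3.5), "CCA")  # ambiguous band
  expect_identical(choose_ordination_method(3.5, midband = "RDA"), "RDA")
})

test_that("DCA length is zero for gradient-free data and grows with turnover", {
  flat <- make_counts(matrix(rep(c(3L, 3L, 3L), 4), 4, 3, byrow = TRUE))
  out <- dca_gradient_length(flat)
  expect_equal(out$length, 0)

  short <- dca_gradient_length(simulate_coenocline(2, seed = 1))
  long <- dca_gradient_length(simulate_coenocline(12, seed = 1))
  expect_lt(short$length, long$length)
  expect_identical(long$chosen_method, "CCA")
})

test_that("forward selection finds a true driver and ignores duplicates", {
  set.seed(101)
  n <- 20L
  x1 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = rnorm(n), dup = x1)
  Y <- sapply(1:6, function(j) 0.4 * j * x1 + rnorm(n, sd = 0.5))
  colnames(Y) <- paste0("t", 1:6)
  rownames(Y) <- rownames(X) <- paste0("s", 1:n)
  hits <- 0L
  for (seed in 1:5) {
    fs <- forward_select(Y, X, method = "rda", n_perm = 199, seed = seed)
    if (fs$selected[1] == "x1") hits <- hits + 1L
    expect_false("dup" %in% fs$selected)  # adds zero inertia after x1
    expect_true(all(fs$trace$added_inertia >= 0))
  }
  expect_gte(hits, 5L)
})

test_that("forward selection on pure noise stops with a documented reason", {
  set.seed(5)
  Y <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("s", 1:12),
                                                paste0("t", 1:5)))
  X <- matrix(rnorm(36), 12, 3, dimnames = list(rownames(Y),
                                                c("a", "b", "c")))
  fs <- forward_select(Y, X, method = "rda", alpha = 0.001, n_perm = 199,
                       seed = 1)
  expect_length(fs$selected, 0)
  expect_match(fs$stopping, "not significant")
})

test_that("forward selection is reproducible under a fixed seed", {
  Y <- random_counts(12L, 8L, seed = 30)
  set.seed(30)
  X <- matrix(rnorm(48), 12, 4, dimnames = list(rownames(Y),
                                                paste0("v", 1:4)))
  a <- forward_select(Y, X, method = "cca", n_perm = 99, seed = 7)
  b <- forward_select(Y, X, method = "cca", n_perm = 99, seed = 7)
  expect_identical(a, b)
})
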