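# fixtures are always built in code so tests are self-contained

make_counts <- function(x, samples = NULL, otus = NULL) {
  m <- as.matrix(x)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(otus)) otus <- sprintf("otu%d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  storage.mode(m) <- "integer"
  m
}

random_counts <- function(n = 5L, k = 8L, lambda = 10, seed = 1L) {
  set.seed(seed)
  make_counts(matrix(rpois(n * k, lambda), n, k))
}

tiny_taxonomy <- function() {
  taxonomy_map(
    c("otu1", "otu2", "otu3", "otu4", "otu5"),
    c("Eukaryota;Chlorophyta;Chlorophyceae;Chlamydomonadales",
      "Eukaryota;Chlorophyta;Chlorophyceae",
      "Eukaryota;Chlorophyta",
      "Eukaryota",
      "Eukaryota;Rotifera;Eurotatoria;Ploima;Synchaetidae;Polyarthra"))
}

# independent Wilcoxon oracle: full enumeration of rank assignments,
# two-sided p as twice the smaller tail (capped at 1)
wilcox_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  w_all <- apply(idx, 2L, function(i) sum(rk[i])) - n1 * (n1 + 1) / 2
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Monte-Carlo rarefaction oracle: subsample reads without replacement
mc_rarefy <- function(counts, depth, n_rep = 10000L) {
  pool <- rep(seq_along(counts), counts)
  s <- vapply(seq_len(n_rep), function(i)
    length(unique(sample(pool, depth))), integer(1L))
  list(mean = mean(s), se = stats::sd(s) / sqrt(n_rep))
}

# every E value printed in the seasonal class-level selectivity table,
# with the entries typeset as selective (bold) flagged
printed_E_table <- local({
  rows <- list(
    Chlorophyceae        = list(E = c(0.00, 0.03, 0.06, -0.47), bold = c(F, F, F, F)),
    Cryptophyceae        = list(E = c(-0.48, -0.09, -1.00, -0.69), bold = c(F, F, F, F)),
    Trebouxiophyceae     = list(E = c(-0.04, -0.68, -0.89, 0.19), bold = c(F, F, F, F)),
    Maxillopoda          = list(E = c(-0.87, 0.32, -0.25, -0.99), bold = c(F, T, F, F)),
    Dinophyceae          = list(E = c(-0.09, -0.70, 0.17, 0.27), bold = c(F, F, F, T)),
    uncl_Bacillariophyta = list(E = c(-0.85, -1.00, -1.00, -0.74), bold = c(F, F, F, F)),
    Spirotrichea         = list(E = c(0.26, -0.40, -1.00, 0.10), bold = c(T, F, F, F)),
    uncl_Chlorophyta     = list(E = c(-0.41, -0.41, -1.00, -1.00), bold = c(F, F, F, F)),
    Coscinodiscophyceae  = list(E = c(-0.82, -0.12, -1.00, -0.35), bold = c(F, F, F, F)),
    uncl_Chytridiomycota = list(E = c(0.43, 0.61, -1.00, -1.00), bold = c(T, T, F, F)),
    uncl_Metazoa         = list(E = c(-0.91, 0, 0.94, -1.00), bold = c(F, F, T, F)),
    Raphidophyceae       = list(E = c(-0.72, -1.00, -1.00, -1.00), bold = c(F, F, F, F)),
    Chrysophyceae        = list(E = c(0.72, 0.08, 0.90, 0.96), bold = c(T, F, T, T)),
    uncl_Fungi           = list(E = c(-0.17, -0.47, -0.44, -0.13), bold = c(F, F, F, F)),
    uncl_Eukaryota       = list(E = c(0.39, -0.81, 0.64, 0.68), bold = c(T, F, T, T)),
    Synurophyceae        = list(E = c(0.53, 0.71, 0.98, 0.92), bold = c(T, T, T, T)),
    Chytridiomycetes     = list(E = c(-1.00, -0.55, -1.00, 0), bold = c(F, F, F, F)),
    Oomycetes            = list(E = c(-1.00, 0.99, -1.00, -1.00), bold = c(F, T, F, F)),
    Oligohymenophorea    = list(E = c(0.97, -0.03, -1.00, -1.00), bold = c(T, F, F, F)),
    Labyrinthulomycetes  = list(E = c(0, 0, -1.00, -1.00), bold = c(F, F, F, F)))
  data.frame(taxon = rep(names(rows), each = 4L),
             season = rep(c("Dec", "Mar", "Jun", "Sep"), length(rows)),
             E = unlist(lapply(rows, `[[`, "E"), use.names = FALSE),
             bold = unlist(lapply(rows, `[[`, "bold"), use.names = FALSE),
             stringsAsFactors = FALSE)
})

# independent dense eigen-decomposition oracle for the chi-square
# standardized residual matrix, built without the svd path used internally
ca_eigen_oracle <- function(Y) {
  P <- Y / sum(Y)
  r <- rowSums(P); c <- colSums(P)
  Q <- (P - outer(r, c)) / sqrt(outer(r, c))
  ev <- eigen(crossprod(Q), symmetric = TRUE)$values
  ev[ev > 1e-12]
}

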