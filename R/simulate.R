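#' Configuration for the synthetic paired gut/water study
#'
#' Describes a sampling campaign in which, at each of `n_sites` sites and in
#' each of four seasons, one ambient-water library and one consumer
#' gut-content library are sequenced. Ambient composition follows a
#' season-specific Dirichlet baseline; gut (diet) composition is "ingestion
#' proportional to availability times preference",
#' \eqn{q_k \propto w_k p_k}, with per-taxon selectivity weights `w`; gut
#' libraries additionally carry a dominant consumer self-read fraction.
#' Environmental covariates follow seasonal means plus noise, with total
#' nitrogen, total phosphorus and chlorophyll-a driven by a shared trophic
#' latent factor and transparency (SD) anti-correlated with it.
#'
#' @param n_sites number of sites (default 3).
#' @param n_taxa number of diet taxa K (default 40), assigned to plankton
#'   classes/phyla; a few are left unassigned at class to exercise the
#'   unclassified-bucket aggregation.
#' @param dirichlet_concentration total Dirichlet concentration governing
#'   site-to-site compositional variation within a season (default 200:
#'   moderate patchiness).
#' @param season_tilt_sd lognormal SD of the per-season multiplicative tilt
#'   on taxon baselines (default 0.4: mild seasonal succession). Zero gives
#'   a flat baseline with every taxon near 1/K.
#' @param selectivity_weights positive per-taxon preference weights, length
#'   `n_taxa` or a named subset over default 1 (default: all 1, i.e.
#'   non-selective feeding).
#' @param consumer_fraction expected fraction of gut reads that are the
#'   consumer's own sequences, in [0, 1) (default 0.9).
#' @param depth_water reads per water library (default 60000).
#' @param depth_gut total reads per gut library including consumer reads
#'   (default 5500, leaving ~550 diet reads at the default
#'   `consumer_fraction`).
#' @param seed integer RNG seed; the same seed reproduces the study
#'   bit-identically.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 3L, n_taxa = 40L,
                       dirichlet_concentration = 200,
                       season_tilt_sd = 0.4,
                       selectivity_weights = NULL,
                       consumer_fraction = 0.9,
                       depth_water = 60000L, depth_gut = 5500L,
                       seed = 1L) {
  stopifnot(n_sites >= 1L, n_taxa >= 2L, dirichlet_concentration > 0,
            season_tilt_sd >= 0, depth_water >= 1L, depth_gut >= 1L)
  if (consumer_fraction < 0 || consumer_fraction >= 1)
    stop("consumer_fraction must lie in [0, 1): at 1 no diet reads remain",
         call. = FALSE)
  w <- rep(1, n_taxa)
  names(w) <- sprintf("OTU%03d", seq_len(n_taxa))
  if (!is.null(selectivity_weights)) {
    if (any(selectivity_weights <= 0))
      stop("selectivity weights must be positive", call. = FALSE)
    if (is.null(names(selectivity_weights))) {
      stopifnot(length(selectivity_weights) == n_taxa)
      w[] <- selectivity_weights
    } else {
      bad <- setdiff(names(selectivity_weights), names(w))
      if (length(bad)) stop("unknown taxa in selectivity_weights: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      w[names(selectivity_weights)] <- selectivity_weights
    }
  }
  structure(list(n_sites = as.integer(n_sites), n_taxa = as.integer(n_taxa),
                 dirichlet_concentration = dirichlet_concentration,
                 season_tilt_sd = season_tilt_sd,
                 selectivity_weights = w,
                 consumer_fraction = consumer_fraction,
                 depth_water = as.integer(depth_water),
                 depth_gut = as.integer(depth_gut),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run code under a private RNG stream, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# plankton classes used for the simulated taxonomy; a realistic mix of the
# algal, ciliate and metazoan classes seen in lake 18S surveys
SIM_CLASSES <- data.frame(
  class  = c("Chlorophyceae", "Trebouxiophyceae", "Cryptophyceae",
             "Chrysophyceae", "Synurophyceae", "Dinophyceae",
             "Bacillariophyceae", "Coscinodiscophyceae", "Raphidophyceae",
             "Spirotrichea", "Oligohymenophorea", "Maxillopoda"),
  phylum = c("Chlorophyta", "Chlorophyta", "Cryptophyta",
             "Ochrophyta", "Ochrophyta", "Dinoflagellata",
             "Bacillariophyta", "Bacillariophyta", "Ochrophyta",
             "Ciliophora", "Ciliophora", "Arthropoda"),
  stringsAsFactors = FALSE)

sim_taxonomy <- function(n_taxa) {
  idx <- rep(seq_len(nrow(SIM_CLASSES)), length.out = n_taxa)
  cls <- SIM_CLASSES$class[idx]
  phy <- SIM_CLASSES$phylum[idx]
  # leave every 13th taxon unassigned at class (assigned phylum only) and
  # one taxon unassigned below kingdom, to exercise unclassified pooling
  drop_class <- seq_len(n_taxa) %% 13L == 0L
  cls[drop_class] <- ""
  lin <- paste("Eukaryota", phy, cls, sep = ";")
  if (n_taxa >= 5L) lin[[5L]] <- "Eukaryota"
  ids <- sprintf("OTU%03d", seq_len(n_taxa))
  tax <- taxonomy_map(c(ids, "OTU_consumer"),
                      c(lin, paste("Eukaryota", "Rotifera", "Eurotatoria",
                                   "Ploima", "Synchaetidae", "Polyarthra",
                                   sep = ";")))
  tax
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# seasonal environmental model: means by season plus noise; TN, TP and
# Chl-a load on one trophic latent factor, transparency loads negatively
sim_env <- function(site, season, latent) {
  noise <- function(sd) stats::rnorm(1L, 0, sd)
  temp_mu <- c(Dec = 12, Mar = 18, Jun = 28, Sep = 25)
  do_mu   <- c(Dec = 9.5, Mar = 8.5, Jun = 6.5, Sep = 7.2)
  c(Temp = temp_mu[[season]] + noise(1.2),
    DO = max(0.5, do_mu[[season]] + noise(0.6)),
    pH = 8.1 + 0.1 * latent + noise(0.15),
    Salinity = max(0.01, 0.3 + noise(0.05)),
    Dep = max(0.5, 2.5 + noise(0.4)),
    SD = max(0.1, 0.9 - 0.35 * latent + noise(0.1)),
    Chla = exp(log(15) + 0.6 * latent + noise(0.2)),
    CODMn = max(0.5, 5 + 0.8 * latent + noise(0.5)),
    TP = exp(log(0.08) + 0.5 * latent + noise(0.15)),
    NH4N = max(0.01, 0.3 + 0.05 * latent + noise(0.08)),
    TN = exp(log(1.5) + 0.4 * latent + noise(0.15)))
}

#' Simulate a paired gut/water metabarcoding study
#'
#' Draws, for every site x season, a true ambient composition `p` from the
#' season's Dirichlet baseline, derives the true diet composition
#' \eqn{q_k = w_k p_k / \sum_j w_j p_j}, then samples reads: water counts
#' are Multinomial(`depth_water`, p); gut libraries first draw the
#' consumer's self-reads as Binomial(`depth_gut`, `consumer_fraction`) on a
#' dedicated OTU with genus `Polyarthra`, and the remaining reads as
#' Multinomial over `q`. Environmental covariates are generated for water
#' samples only.
#'
#' @param config a [sim_config].
#' @return list with elements `gut` and `water` (OTU tables), `taxonomy`,
#'   `meta` (sample frame; env variables on water rows), and `truth` (per
#'   site x season true `p`, `q`, `E_true` and the trophic latent factor).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$n_taxa
    taxa <- names(config$selectivity_weights)
    tax <- sim_taxonomy(K)
    # per-season baseline tilt (lognormal, season-specific succession)
    tilt <- sapply(SEASONS, function(s)
      exp(stats::rnorm(K, 0, config$season_tilt_sd)))
    base <- tilt / rep(colSums(tilt), each = K)  # mean composition per season
    alpha <- base * config$dirichlet_concentration
    dimnames(alpha) <- list(taxa, SEASONS)

    sites <- sprintf("S%d", seq_len(config$n_sites))
    grid <- expand.grid(site = sites, season = SEASONS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    season_mu <- c(Dec = -0.5, Mar = 0, Jun = 0.8, Sep = 0.5)

    n_lib <- nrow(grid)
    water <- matrix(0L, n_lib, K,
                    dimnames = list(paste0("W_", grid$site, "_", grid$season),
                                    taxa))
    gut <- matrix(0L, n_lib, K + 1L,
                  dimnames = list(paste0("G_", grid$site, "_", grid$season),
                                  c(taxa, "OTU_consumer")))
    p_true <- q_true <- matrix(0, n_lib, K, dimnames = list(NULL, taxa))
    latent <- numeric(n_lib)
    env <- matrix(NA_real_, n_lib, length(ENV_VARS),
                  dimnames = list(NULL, ENV_VARS))
    w <- config$selectivity_weights
    for (i in seq_len(n_lib)) {
      s <- grid$season[[i]]
      p <- rdirichlet1(alpha[, s])
      q <- w * p
      q <- q / sum(q)
      p_true[i, ] <- p
      q_true[i, ] <- q
      water[i, ] <- stats::rmultinom(1L, config$depth_water, p)[, 1L]
      n_cons <- stats::rbinom(1L, config$depth_gut, config$consumer_fraction)
      diet <- stats::rmultinom(1L, config$depth_gut - n_cons, q)[, 1L]
      gut[i, ] <- c(diet, n_cons)
      latent[[i]] <- season_mu[[s]] + stats::rnorm(1L, 0, 0.5)
      env[i, ] <- sim_env(grid$site[[i]], s, latent[[i]])
    }

    meta <- rbind(
      data.frame(sample_id = rownames(water), site = grid$site,
                 season = grid$season, compartment = "water",
                 as.data.frame(env), stringsAsFactors = FALSE),
      data.frame(sample_id = rownames(gut), site = grid$site,
                 season = grid$season, compartment = "gut",
                 as.data.frame(env * NA_real_), stringsAsFactors = FALSE))
    rownames(meta) <- NULL

    truth <- list(site = grid$site, season = grid$season,
                  p = p_true, q = q_true,
                  E_true = (q_true - p_true) / (q_true + p_true),
                  latent = latent)
    list(gut = validate_otu_table(gut), water = validate_otu_table(water),
         taxonomy = tax, meta = validate_sample_frame(meta), truth = truth)
  })
}

#' Ground-truth electivity for a taxon in a season
#'
#' Pools the true compositions over the season's sites (equal weight per
#' site) and evaluates \eqn{E = (r_i - p_i) / (r_i + p_i)} on the pooled
#' true diet (`q`) and ambient (`p`) proportions.
#'
#' @param truth the `truth` element of [simulate_study] output.
#' @param taxon taxon (OTU) id.
#' @param season one of `Dec`, `Mar`, `Jun`, `Sep`.
#' @return electivity in [-1, 1].
#' @export
truth_electivity <- function(truth, taxon, season) {
  if (!taxon %in% colnames(truth$p))
    stop("unknown taxon: ", taxon, call. = FALSE)
  season <- match.arg(season, SEASONS)
  rows <- truth$season == season
  if (!any(rows)) stop("unknown season: ", season, call. = FALSE)
  p <- mean(truth$p[rows, taxon])
  r <- mean(truth$q[rows, taxon])
  electivity(r, p)
}

#' Simulate a Gaussian coenocline community
#'
#' Sites are placed evenly along a single latent gradient and species are
#' given Gaussian (unimodal) responses with unit tolerance, so the
#' gradient's length in species-turnover SD units is set directly by
#' `sd_length`. Reads are drawn multinomially per site. Used to calibrate
#' gradient-length estimators: the estimated DCA axis-1 length should grow
#' with `sd_length`.
#'
#' @param sd_length gradient extent in SD (tolerance) units.
#' @param n_sites number of sites along the gradient.
#' @param n_species number of species with optima uniform on the (slightly
#'   extended) gradient.
#' @param depth reads per site.
#' @param seed RNG seed.
#' @return count matrix (sites x species).
#' @export
simulate_coenocline <- function(sd_length, n_sites = 30L, n_species = 25L,
                                depth = 400L, seed = 1L) {
  stopifnot(sd_length >= 0, n_sites >= 3L, n_species >= 2L, depth >= 1L)
  with_seed(seed, {
    g <- seq(0, sd_length, length.out = n_sites)
    u <- stats::runif(n_species, -1, sd_length + 1)
    lambda <- exp(-outer(g, u, "-")^2 / 2)
    counts <- t(vapply(seq_len(n_sites), function(i)
      stats::rmultinom(1L, depth, lambda[i, ] / sum(lambda[i, ]))[, 1L],
      integer(n_species)))
    dimnames(counts) <- list(sprintf("site%02d", seq_len(n_sites)),
                             sprintf("sp%02d", seq_len(n_species)))
    counts
  })
}

#' Write all simulated study tables to a directory
#'
#' Emits `gut_otu.tsv`, `water_otu.tsv`, `taxonomy.tsv`, `metadata.tsv` and
#' `truth_electivity.tsv` (season-pooled true E per taxon).
#'
#' @param sim output of [simulate_study].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$gut, file.path(dir, "gut_otu.tsv"))
  write_otu_table(sim$water, file.path(dir, "water_otu.tsv"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_frame(sim$meta, file.path(dir, "metadata.tsv"))
  taxa <- colnames(sim$truth$p)
  e_true <- sapply(SEASONS, function(s)
    vapply(taxa, truth_electivity, numeric(1L), truth = sim$truth, season = s))
  utils::write.table(data.frame(taxon = taxa, e_true, check.names = FALSE),
                     file.path(dir, "truth_electivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
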