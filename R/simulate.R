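#' Configure the diallel simulator
#'
#' Describes a synthetic full diallel flower-diameter study with known
#' genetic architecture. Defaults emulate the study design this package is
#' built around: 12 parents, all 144 ordered genotypes, two biological
#' replicates per genotype per temperature (17 / 23 degC), six flowers per
#' replicate, baseline flower diameter 3.6 mm at 17 degC, and parental fold
#' changes equally spaced across 0.79-1.10.
#'
#' Genetic effects act on the FC scale (optionally on log FC via
#' `log_scale`). Under `inheritance_mode = "griffing"` every cell mean FC is
#' `mu + g_i + g_j + s_ij + r_ij` with effects drawn from the configured
#' SDs and projected onto the Method I constraints; under the
#' `additive` / `dominant` / `overdominant` modes hybrids sit at
#' `MPV + d * (FC_dom - MPV)` with `d = 0` (additive), `d = 1` (full
#' dominance) or `d > 1` (overdominance) and `FC_dom` the FC of the dominant
#' parent chosen by `dominant_parent_rule`. Measurement noise has two
#' layers, mirroring replicates grown as separate trials: biological
#' replicate means are drawn around the genotype-temperature mean with
#' `sigma_rep` (mm) and individual flowers around the replicate mean with
#' `sigma_flower` (mm).
#'
#' @param n_parents Number of parents (default 12).
#' @param temperatures (T_low, T_high) pair in degC.
#' @param b_replicates Biological replicates per genotype per temperature.
#' @param flowers_per_replicate Flowers measured per replicate.
#' @param seed Integer seed; same seed, same table bit-for-bit.
#' @param mu_fd_low Baseline flower diameter at T_low (mm).
#' @param parental_fc_range Interval the parental target FCs span.
#' @param sigma_g,sigma_s,sigma_r SDs of GCA / SCA / reciprocal effects on
#'   the FC scale (used by mode `griffing`).
#' @param sigma_flower Within-replicate flower SD (mm).
#' @param sigma_rep Between-biological-replicate SD (mm).
#' @param inheritance_mode One of `additive`, `dominant`, `overdominant`,
#'   `griffing`.
#' @param dominance_degree `d`; required for modes `dominant` (typically 1)
#'   and `overdominant` (> 1).
#' @param dominant_parent_rule `maternal`, `paternal`, or `random`.
#' @param log_scale Apply the genetic model on log FC instead of FC.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_parents = 12L,
                              temperatures = c(17, 23),
                              b_replicates = 2L,
                              flowers_per_replicate = 6L,
                              seed = 1L,
                              mu_fd_low = 3.6,
                              parental_fc_range = c(0.79, 1.10),
                              sigma_g = 0.03,
                              sigma_s = 0.01,
                              sigma_r = 0.005,
                              sigma_flower = 0.2,
                              sigma_rep = 0.06,
                              inheritance_mode = c("additive", "dominant",
                                                   "overdominant",
                                                   "griffing"),
                              dominance_degree = NULL,
                              dominant_parent_rule = c("maternal",
                                                       "paternal", "random"),
                              log_scale = FALSE) {
  inheritance_mode <- match.arg(inheritance_mode)
  dominant_parent_rule <- match.arg(dominant_parent_rule)
  if (any(c(sigma_g, sigma_s, sigma_r, sigma_flower, sigma_rep) < 0))
    stop("config error: noise SDs must be >= 0")
  if (length(parental_fc_range) != 2L || any(parental_fc_range <= 0) ||
      parental_fc_range[1] > parental_fc_range[2])
    stop("config error: parental_fc_range must be a positive interval")
  if (inheritance_mode %in% c("dominant", "overdominant")) {
    if (is.null(dominance_degree))
      dominance_degree <- if (inheritance_mode == "dominant") 1 else 1.5
  } else if (!is.null(dominance_degree)) {
    stop("config error: dominance_degree only applies to modes ",
         "dominant/overdominant")
  }
  if (n_parents < 2L) stop("config error: need at least 2 parents")
  structure(
    list(n_parents = as.integer(n_parents),
         temperatures = as.numeric(temperatures),
         b_replicates = as.integer(b_replicates),
         flowers_per_replicate = as.integer(flowers_per_replicate),
         seed = as.integer(seed),
         mu_fd_low = mu_fd_low,
         parental_fc_range = as.numeric(parental_fc_range),
         sigma_g = sigma_g, sigma_s = sigma_s, sigma_r = sigma_r,
         sigma_flower = sigma_flower, sigma_rep = sigma_rep,
         inheritance_mode = inheritance_mode,
         dominance_degree = dominance_degree,
         dominant_parent_rule = dominant_parent_rule,
         log_scale = log_scale),
    class = "simulation_config")
}

#' The design implied by a simulation config
#' @param config A [simulation_config()].
#' @return A [diallel_design()].
#' @export
design_from_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  diallel_design(sprintf("P%02d", seq_len(config$n_parents)),
                 temperatures = config$temperatures,
                 b_replicates = config$b_replicates,
                 min_flowers = config$flowers_per_replicate)
}

#' Simulate a full diallel flower-diameter table with known truth
#'
#' Generates per-flower diameter records for every ordered genotype at both
#' temperatures, plus a truth sidecar recording every generating parameter
#' and the true inheritance class of every cross. All genotypes share the
#' baseline diameter `mu_fd_low` at T_low; a genotype's diameter at T_high
#' is `mu_fd_low * FC` with its cell FC set by the configured genetic model,
#' so in a noiseless run every pipeline estimate reproduces the sidecar
#' exactly.
#'
#' @param config A [simulation_config()].
#' @return List of class `diallel_simulation` with `table` (flower records),
#'   `design` (the [diallel_design()]) and `truth` (parental FCs, cell FC
#'   matrix, per-cross true classes, drawn effects for mode `griffing`, RNG
#'   metadata, and the config).
#' @export
simulate_diallel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  design <- design_from_config(config)
  parents <- design$parents
  n <- config$n_parents
  link <- if (config$log_scale) log else identity
  unlink <- if (config$log_scale) exp else identity

  parental_fc <- if (n == 1L) mean(config$parental_fc_range) else
    seq(config$parental_fc_range[1], config$parental_fc_range[2],
        length.out = n)
  names(parental_fc) <- parents

  effects <- NULL
  fc <- matrix(NA_real_, n, n, dimnames = list(mother = parents,
                                               father = parents))
  classes <- matrix("additive", n, n, dimnames = dimnames(fc))
  if (config$inheritance_mode == "griffing") {
    mu_fc <- link(mean(config$parental_fc_range))
    g <- stats::rnorm(n, 0, config$sigma_g); g <- g - mean(g)
    s0 <- matrix(0, n, n)
    s0[upper.tri(s0, diag = TRUE)] <-
      stats::rnorm(n * (n + 1) / 2, 0, config$sigma_s)
    s0 <- s0 + t(s0) - diag(diag(s0))
    rm_ <- rowMeans(s0)
    s <- s0 - outer(rm_, rm_, "+") + mean(s0)   # symmetric, row sums 0
    r <- matrix(0, n, n)
    r[upper.tri(r)] <- stats::rnorm(n * (n - 1) / 2, 0, config$sigma_r)
    r <- r - t(r)
    fc <- unlink(mu_fc + outer(g, g, "+") + s + r)
    classes[] <- NA_character_   # no categorical truth under this mode
    effects <- list(mu_fc = mu_fc, g = stats::setNames(g, parents),
                    s = s, r = r)
    parental_fc <- diag(fc)
  } else {
    d <- switch(config$inheritance_mode,
                additive = 0,
                dominant = config$dominance_degree,
                overdominant = config$dominance_degree)
    lp <- link(parental_fc)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { fc[i, j] <- parental_fc[i]; next }
      mpv <- (lp[i] + lp[j]) / 2
      dom_is_mother <- switch(config$dominant_parent_rule,
                              maternal = TRUE, paternal = FALSE,
                              random = stats::runif(1) < 0.5)
      fc_dom <- if (dom_is_mother) lp[i] else lp[j]
      fc[i, j] <- unlink(mpv + d * (fc_dom - mpv))
      classes[i, j] <- switch(config$inheritance_mode,
                              additive = "additive",
                              dominant = if (dom_is_mother)
                                "dominant_maternal" else "dominant_paternal",
                              overdominant = "overdominant")
    }
  }
  if (any(fc <= 0))
    stop("config error: genetic model produced non-positive fold changes")

  t_low <- config$temperatures[1]; t_high <- config$temperatures[2]
  cells <- expand.grid(bio_replicate = seq_len(config$b_replicates),
                       temperature_C = c(t_low, t_high),
                       father = parents, mother = parents,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("mother", "father", "temperature_C", "bio_replicate")]
  geno_mean <- ifelse(cells$temperature_C == t_high,
                      config$mu_fd_low *
                        fc[cbind(match(cells$mother, parents),
                                 match(cells$father, parents))],
                      config$mu_fd_low)
  rep_mean <- geno_mean + stats::rnorm(nrow(cells), 0, config$sigma_rep)
  f <- config$flowers_per_replicate
  tab <- cells[rep(seq_len(nrow(cells)), each = f), ]
  tab$flower_id <- rep(seq_len(f), nrow(cells))
  tab$diameter_mm <- rep(rep_mean, each = f) +
    stats::rnorm(nrow(tab), 0, config$sigma_flower)
  rownames(tab) <- NULL
  if (any(tab$diameter_mm <= 0))
    stop("config error: noise SDs produced non-positive flower diameters")

  cross_classes <- data.frame(
    mother = rep(parents, each = n), father = rep(parents, n),
    true_class = as.vector(t(classes)), stringsAsFactors = FALSE)
  cross_classes <- cross_classes[cross_classes$mother !=
                                   cross_classes$father, ]
  rownames(cross_classes) <- NULL

  structure(list(
    table = tab,
    design = design,
    truth = list(config = config,
                 parents = parents,
                 parental_fc = parental_fc,
                 fc_matrix = fc,
                 classes = cross_classes,
                 effects = effects,
                 rng = list(kind = RNGkind()[1],
                            normal_kind = RNGkind()[2],
                            seed = config$seed))),
    class = "diallel_simulation")
}

# Delta-method SD of one FC replicate at FC ~ 1 given the mm-scale noise
# layers: replicate-mean SD sigma_m = sqrt(sigma_rep^2 + sigma_flower^2/f),
# and FC = m_high/m_low with independent numerator/denominator.
fc_replicate_sd <- function(config) {
  sigma_m <- sqrt(config$sigma_rep^2 +
                    config$sigma_flower^2 / config$flowers_per_replicate)
  sigma_m * sqrt(2) / config$mu_fd_low
}

#' Dominant-mode config with a prescribed effect/noise ratio
#'
#' Convenience constructor for power batteries: full maternal dominance
#' (`d = 1`) with the flower-level noise chosen (via the delta method, with
#' `sigma_rep = 0`) so that the smallest hybrid deviation from its MPV in
#' the design - half the spacing of the equally spaced parental FCs -
#' equals `ratio` times the SD of a single FC replicate.
#'
#' @param ratio Desired (smallest effect) / (FC replicate SD).
#' @param ... Passed on to [simulation_config()].
#' @return A [simulation_config()].
#' @export
dominant_config_for_ratio <- function(ratio, ...) {
  cfg <- simulation_config(inheritance_mode = "dominant",
                           dominance_degree = 1, sigma_rep = 0, ...)
  spacing <- diff(cfg$parental_fc_range) / (cfg$n_parents - 1)
  target_sd <- (spacing / 2) / ratio
  sigma_m <- target_sd * cfg$mu_fd_low / sqrt(2)
  cfg$sigma_flower <- sigma_m * sqrt(cfg$flowers_per_replicate)
  cfg
}

#' Purely additive config with a prescribed narrow-sense heritability
#'
#' Convenience constructor for heritability-recovery batteries: Griffing
#' mode with `sigma_s = sigma_r = 0` (purely additive architecture) and
#' `sigma_g` chosen so that the true narrow-sense heritability of a
#' parental phenotype - `VA / (VA + VE)` with `VA = 4 sigma_g^2` and `VE`
#' the delta-method variance of a genotype mean FC - equals `h2`.
#'
#' @param h2 Target narrow-sense heritability in (0, 1).
#' @param ... Passed on to [simulation_config()].
#' @return A [simulation_config()].
#' @export
additive_config_for_h2 <- function(h2, ...) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  cfg <- simulation_config(inheritance_mode = "griffing", sigma_s = 0,
                           sigma_r = 0, ...)
  sigma_m2 <- cfg$sigma_rep^2 +
    cfg$sigma_flower^2 / cfg$flowers_per_replicate
  ve_fc <- 2 * sigma_m2 / (cfg$b_replicates * cfg$mu_fd_low^2)
  cfg$sigma_g <- sqrt(h2 * ve_fc / (4 * (1 - h2)))
  cfg
}

#' False-discovery calibration battery on fully additive diallels
#'
#' Simulates `n_sims` independent diallels under a fully additive
#' architecture (every hybrid FC at its MPV plus measurement noise), runs
#' the inheritance classifier on each, and reports the observed fraction of
#' non-additive calls with its Monte-Carlo standard error. Under BH control
#' at FDR `q` this fraction should not exceed `q` by more than sampling
#' noise.
#'
#' @param config A [simulation_config()] with `inheritance_mode` additive
#'   (or `griffing` with `sigma_s = sigma_r = 0`).
#' @param n_sims Number of simulated diallels (>= 10).
#' @param q FDR level passed to the classifier.
#' @return List with `rate`, `mc_se`, `n_sims`, `n_crosses`, `per_sim`.
#' @export
simulate_null_additive_battery <- function(config, n_sims, q = 0.1) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_sims < 10L) stop("refusing n_sims < 10: unstable estimate")
  additive_truth <- config$inheritance_mode == "additive" ||
    (config$inheritance_mode == "griffing" &&
       config$sigma_s == 0 && config$sigma_r == 0)
  if (!additive_truth)
    stop("battery requires a fully additive generating mode")
  per_sim <- vapply(seq_len(n_sims), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    sim <- simulate_diallel(cfg)
    ptab <- plasticity_table(sim$table, sim$design)
    calls <- classify_inheritance(ptab, sim$design, q = q)
    mean(calls$class != "additive")
  }, numeric(1))
  list(rate = mean(per_sim),
       mc_se = stats::sd(per_sim) / sqrt(n_sims),
       n_sims = n_sims,
       n_crosses = config$n_parents * (config$n_parents - 1),
       per_sim = per_sim)
}

#' Classifier power battery against the simulator's truth
#'
#' Simulates `n_sims` diallels under the configured (non-additive) mode,
#' classifies every cross, and reports the fraction of crosses whose call
#' matches the generator's true class, together with the confusion table.
#'
#' @param config A [simulation_config()] with categorical truth (modes
#'   `additive`, `dominant`, `overdominant`).
#' @param n_sims Number of simulated diallels (>= 10).
#' @param q FDR level passed to the classifier.
#' @return List with `accuracy`, `mc_se`, `confusion` (true x called
#'   counts), `per_sim`.
#' @export
inheritance_battery <- function(config, n_sims, q = 0.1) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_sims < 10L) stop("refusing n_sims < 10: unstable estimate")
  if (config$inheritance_mode == "griffing")
    stop("battery needs a mode with categorical truth")
  conf <- NULL
  per_sim <- vapply(seq_len(n_sims), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    sim <- simulate_diallel(cfg)
    ptab <- plasticity_table(sim$table, sim$design)
    calls <- classify_inheritance(ptab, sim$design, q = q)
    key <- genotype_id(calls$mother, calls$father)
    truth <- sim$truth$classes
    tr <- truth$true_class[match(key, genotype_id(truth$mother,
                                                  truth$father))]
    tab <- table(true = tr, called = calls$class)
    conf <<- if (is.null(conf)) tab else {
      u <- union(colnames(conf), colnames(tab))
      pad <- function(m) {
        out <- matrix(0L, nrow(m), length(u),
                      dimnames = list(rownames(m), u))
        out[, colnames(m)] <- m
        out
      }
      pad(conf) + pad(tab)
    }
    mean(calls$class == tr)
  }, numeric(1))
  list(accuracy = mean(per_sim),
       mc_se = stats::sd(per_sim) / sqrt(n_sims),
       confusion = conf,
       per_sim = per_sim)
}
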