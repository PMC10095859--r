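#' Per-replicate mean flower diameters
#'
#' Averages the per-flower diameters within each
#' (genotype, temperature, biological replicate) cell. These replicate means
#' are the building blocks of the fold-change plasticity score.
#'
#' @param records Validated flower records (one or more genotypes).
#' @return Data frame with columns `mother`, `father`, `temperature_C`,
#'   `bio_replicate`, `mean_fd_mm`, `n_flowers`.
#' @export
replicate_means <- function(records) {
  if (nrow(records) == 0L) stop("missing data: no flower records")
  f <- interaction(records$mother, records$father, records$temperature_C,
                   records$bio_replicate, drop = TRUE, lex.order = TRUE)
  idx <- !duplicated(f)
  out <- records[idx, c("mother", "father", "temperature_C",
                        "bio_replicate")]
  out <- out[order(f[idx]), , drop = FALSE]
  out$mean_fd_mm <- as.numeric(tapply(records$diameter_mm, f, mean))
  out$n_flowers <- as.integer(tapply(records$diameter_mm, f, length))
  rownames(out) <- NULL
  out
}

#' Fold-change plasticity replicates for one genotype
#'
#' Plasticity is scored as the fold change (FC) of flower diameter between
#' the warm and the cool temperature. With `b` biological replicates at each
#' temperature, every ordered pairing of a warm replicate mean with a cool
#' replicate mean yields one FC, giving `b^2` FC replicates per genotype
#' (four when b = 2). FC = 1 means no plasticity; FC < 1 means smaller
#' flowers when warm.
#'
#' @param rep_means Replicate means for a single genotype, as one
#'   genotype's rows of [replicate_means()].
#' @param design A [diallel_design()] giving the (T_low, T_high) pair.
#' @return List with `fc_replicates` (numeric, length `b_low * b_high`),
#'   `mean_fc`, `sd_fc` (sample SD, n-1 denominator; NA for a single FC),
#'   `mean_fd_low`, `mean_fd_high` (genotype-level means in mm).
#' @export
compute_fold_changes <- function(rep_means, design) {
  stopifnot(inherits(design, "diallel_design"))
  t_low <- design$temperatures[1]; t_high <- design$temperatures[2]
  m_low <- rep_means$mean_fd_mm[rep_means$temperature_C == t_low]
  m_high <- rep_means$mean_fd_mm[rep_means$temperature_C == t_high]
  if (length(m_low) == 0L || length(m_high) == 0L)
    stop("missing data: genotype lacks replicate means at one temperature")
  if (any(m_low <= 0) || any(m_high <= 0))
    stop("domain error: non-positive replicate mean diameter")
  fc <- as.vector(outer(m_high, m_low, "/"))
  list(fc_replicates = fc,
       mean_fc = mean(fc),
       sd_fc = if (length(fc) > 1L) stats::sd(fc) else NA_real_,
       mean_fd_low = mean(m_low),
       mean_fd_high = mean(m_high))
}

#' Build the per-genotype plasticity table
#'
#' Runs [replicate_means()] and [compute_fold_changes()] over every genotype
#' present in the records.
#'
#' @param records Validated flower records.
#' @param design A [diallel_design()].
#' @return Data frame of class `plasticity_table` with one row per genotype:
#'   `mother`, `father`, `is_self`, `mean_fd_low`, `mean_fd_high`,
#'   `mean_fc`, `sd_fc`, `n_fc`, and list-column `fc_reps` holding the FC
#'   replicates.
#' @export
plasticity_table <- function(records, design) {
  rm_all <- replicate_means(records)
  gid <- genotype_id(rm_all$mother, rm_all$father)
  ord <- order(match(rm_all$mother, design$parents),
               match(rm_all$father, design$parents))
  rm_all <- rm_all[ord, ]; gid <- gid[ord]
  first <- !duplicated(gid)
  out <- rm_all[first, c("mother", "father")]
  rows <- split(seq_len(nrow(rm_all)), factor(gid, levels = unique(gid)))
  fcs <- lapply(rows, function(i) compute_fold_changes(rm_all[i, ], design))
  out$is_self <- out$mother == out$father
  out$mean_fd_low <- vapply(fcs, `[[`, numeric(1), "mean_fd_low")
  out$mean_fd_high <- vapply(fcs, `[[`, numeric(1), "mean_fd_high")
  out$mean_fc <- vapply(fcs, `[[`, numeric(1), "mean_fc")
  out$sd_fc <- vapply(fcs, `[[`, numeric(1), "sd_fc")
  out$n_fc <- vapply(fcs, function(x) length(x$fc_replicates), integer(1))
  out$fc_reps <- I(unname(lapply(fcs, `[[`, "fc_replicates")))
  rownames(out) <- NULL
  class(out) <- c("plasticity_table", class(out))
  out
}

#' Parental within-genotype temperature tests
#'
#' For each parental accession (self genotype), compares flower-level
#' diameters between the two temperatures with a two-sample two-tailed
#' t-test; the pooled-variance form is used unless an F-test of variance
#' equality rejects at `f_test_alpha`, in which case Welch's form is used.
#' P-values are Benjamini-Hochberg adjusted across the n parents and a
#' parent is called plastic in flower size when the adjusted p falls below
#' the FDR level `q`.
#'
#' @param records Validated flower records.
#' @param design A [diallel_design()].
#' @param q FDR level (default 0.10).
#' @param f_test_alpha Alpha of the variance-equality pre-test (default 0.05).
#' @return Data frame with one row per parent: `parent`, `mean_fd_low`,
#'   `mean_fd_high`, `t_statistic`, `df`, `welch`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
parental_temperature_tests <- function(records, design, q = 0.1,
                                       f_test_alpha = 0.05) {
  stopifnot(inherits(design, "diallel_design"))
  t_low <- design$temperatures[1]; t_high <- design$temperatures[2]
  one <- function(p) {
    sub <- records[records$mother == p & records$father == p, ]
    x_hi <- sub$diameter_mm[sub$temperature_C == t_high]
    x_lo <- sub$diameter_mm[sub$temperature_C == t_low]
    if (length(x_hi) < 2L || length(x_lo) < 2L)
      stop("test error: parent ", p,
           " has fewer than 2 flowers in a temperature group")
    tt <- two_sample_t(x_hi, x_lo, f_test_alpha)
    data.frame(parent = p,
               mean_fd_low = mean(x_lo), mean_fd_high = mean(x_hi),
               t_statistic = tt$statistic, df = tt$df, welch = tt$welch,
               p_raw = tt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(design$parents, one))
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < q
  rownames(out) <- NULL
  out
}

# F-test-gated two-sample two-tailed t; degenerate (both variances ~0)
# resolved by the exact-equality convention so noiseless tables test
# deterministically.
two_sample_t <- function(x, y, f_test_alpha = 0.05, tol = 1e-8) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx < tol^2 && vy < tol^2) {
    eq <- abs(mean(x) - mean(y)) <= tol
    return(list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, welch = NA, p = if (eq) 1 else 0))
  }
  welch <- stats::var.test(x, y)$p.value < f_test_alpha
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       welch = welch, p = tt$p.value)
}
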