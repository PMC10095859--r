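#' Mid-parent value
#'
#' Arithmetic mean of the two parental mean fold changes; the hybrid's
#' expected plasticity under purely additive inheritance. Treated as a fixed
#' constant in the downstream one-sample test.
#'
#' @param mother_fc,father_fc Parental mean FC values.
#' @return The mid-parent value.
#' @examples
#' mid_parent_value(0.79, 1.10)  # 0.945
#' @export
mid_parent_value <- function(mother_fc, father_fc) {
  if (any(!is.finite(c(mother_fc, father_fc))))
    stop("missing parental mean FC")
  (mother_fc + father_fc) / 2
}

#' One-sample t-test of a cross's FC replicates against its MPV
#'
#' Two-tailed, df = (number of FC replicates) - 1. A zero-variance set of
#' replicates (as arises in noiseless simulations) is resolved by the
#' exact-equality convention: p = 1 when the replicate mean equals the MPV
#' within tolerance, p = 0 otherwise.
#'
#' @param fc_replicates Numeric FC replicates of the cross.
#' @param mpv Mid-parent value.
#' @param tol Equality tolerance for the degenerate zero-variance case.
#' @return List with `statistic` and `p`.
#' @export
test_vs_mpv <- function(fc_replicates, mpv, tol = 1e-8) {
  if (length(fc_replicates) < 2L)
    stop("need at least 2 FC replicates for the one-sample t-test")
  s <- stats::sd(fc_replicates)
  if (s < tol) {
    eq <- abs(mean(fc_replicates) - mpv) <= tol
    return(list(statistic = if (eq) 0 else
                  sign(mean(fc_replicates) - mpv) * Inf,
                p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(fc_replicates, mu = mpv)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up adjustment: with p-values ranked increasingly,
#' `adj(i) = min_{j >= rank(i)} (m / j) * p_(j)`, capped at 1. The family
#' size `m` defaults to `length(p)` but can be set larger when the intended
#' test family exceeds the p-values at hand.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size (>= `length(p)`).
#' @return Adjusted p-values, in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("domain error: p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Two-sample test of a cross's FC replicates against a parent's
#'
#' An F-test of the variance ratio at `f_test_alpha` selects the pooled
#' (equal variances accepted) versus Welch (rejected) two-sample two-tailed
#' t-test. Degenerate zero-variance-in-both-groups inputs follow the
#' exact-equality convention (p = 1 for equal means, p = 0 otherwise).
#'
#' @param cross_fc,parent_fc FC replicate vectors (>= 2 each).
#' @param f_test_alpha Alpha of the variance pre-test.
#' @return List with `statistic`, `p`, `welch`.
#' @export
compare_to_parent <- function(cross_fc, parent_fc, f_test_alpha = 0.05) {
  if (length(cross_fc) < 2L || length(parent_fc) < 2L)
    stop("need at least 2 FC replicates per group")
  tt <- two_sample_t(cross_fc, parent_fc, f_test_alpha)
  list(statistic = tt$statistic, p = tt$p, welch = tt$welch)
}

#' Classify the mode of inheritance of plasticity for every cross
#'
#' Two-stage procedure. Stage 1: each non-self cross's FC replicates are
#' tested against its mid-parent value (one-sample two-tailed t), with BH
#' adjustment across all tested crosses; crosses not rejected at FDR `q` are
#' called `additive`. Stage 2: rejected crosses are tested against each
#' parent's FC replicates (F-test-gated two-sample t), with BH adjustment
#' across all stage-2 p-values jointly; a cross differing from the father
#' only is `dominant_maternal`, from the mother only `dominant_paternal`,
#' from both - provided its mean FC lies outside the parental range -
#' `overdominant`, and anything else non-additive is
#' `nonadditive_unresolved`. Direction is `negative` when the hybrid mean FC
#' falls below the MPV (greater plasticity here, since parental FCs sit
#' mostly below 1), `positive` otherwise.
#'
#' @param ptab A [plasticity_table()] containing all selfs and crosses.
#' @param design A [diallel_design()].
#' @param q FDR level (default 0.10).
#' @param f_test_alpha Alpha of the variance pre-test (default 0.05).
#' @param bh_family Stage-1 BH family size; `NULL` (default) uses the number
#'   of tested crosses.
#' @return Data frame with one row per non-self cross: `mother`, `father`,
#'   `mpv`, `p_mpv_raw`, `p_mpv_adj`, `p_mother_raw`, `p_mother_adj`,
#'   `p_father_raw`, `p_father_adj` (NA unless stage 1 rejected), `class`,
#'   `direction`.
#' @export
classify_inheritance <- function(ptab, design, q = 0.1,
                                 f_test_alpha = 0.05, bh_family = NULL) {
  stopifnot(inherits(design, "diallel_design"))
  gid <- genotype_id(ptab$mother, ptab$father)
  selfs <- ptab[ptab$is_self, ]
  self_of <- function(p) {
    i <- which(selfs$mother == p)
    if (length(i) != 1L) stop("missing self genotype for parent ", p)
    i
  }
  crosses <- ptab[!ptab$is_self, ]
  if (nrow(crosses) == 0L) stop("no non-self crosses to classify")

  mpv <- mapply(function(m, f)
    mid_parent_value(selfs$mean_fc[self_of(m)], selfs$mean_fc[self_of(f)]),
    crosses$mother, crosses$father)
  stage1 <- lapply(seq_len(nrow(crosses)), function(i)
    test_vs_mpv(crosses$fc_reps[[i]], mpv[i]))
  p1 <- vapply(stage1, `[[`, numeric(1), "p")
  m1 <- if (is.null(bh_family)) length(p1) else as.integer(bh_family)
  p1_adj <- bh_adjust(p1, m = m1)
  rejected <- p1_adj < q

  out <- data.frame(mother = crosses$mother, father = crosses$father,
                    mpv = mpv, p_mpv_raw = p1, p_mpv_adj = p1_adj,
                    p_mother_raw = NA_real_, p_mother_adj = NA_real_,
                    p_father_raw = NA_real_, p_father_adj = NA_real_,
                    class = "additive", direction = NA_character_,
                    stringsAsFactors = FALSE)

  if (any(rejected)) {
    idx <- which(rejected)
    pm <- vapply(idx, function(i)
      compare_to_parent(crosses$fc_reps[[i]],
                        selfs$fc_reps[[self_of(crosses$mother[i])]],
                        f_test_alpha)$p, numeric(1))
    pf <- vapply(idx, function(i)
      compare_to_parent(crosses$fc_reps[[i]],
                        selfs$fc_reps[[self_of(crosses$father[i])]],
                        f_test_alpha)$p, numeric(1))
    adj2 <- bh_adjust(c(pm, pf))
    pm_adj <- adj2[seq_along(idx)]
    pf_adj <- adj2[length(idx) + seq_along(idx)]
    out$p_mother_raw[idx] <- pm;  out$p_mother_adj[idx] <- pm_adj
    out$p_father_raw[idx] <- pf;  out$p_father_adj[idx] <- pf_adj

    for (k in seq_along(idx)) {
      i <- idx[k]
      sig_m <- pm_adj[k] < q
      sig_f <- pf_adj[k] < q
      par_fc <- c(selfs$mean_fc[self_of(crosses$mother[i])],
                  selfs$mean_fc[self_of(crosses$father[i])])
      outside <- crosses$mean_fc[i] < min(par_fc) ||
                 crosses$mean_fc[i] > max(par_fc)
      out$class[i] <-
        if (sig_m && sig_f && outside) "overdominant"
        else if (sig_f && !sig_m) "dominant_maternal"
        else if (sig_m && !sig_f) "dominant_paternal"
        else "nonadditive_unresolved"
      out$direction[i] <- if (crosses$mean_fc[i] < mpv[i]) "negative"
                          else "positive"
    }
  }
  rownames(out) <- NULL
  out
}
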