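#' Fit Griffing's Method I combining-ability model (fixed effects)
#'
#' Decomposes the cell means of a full diallel (all `n^2` ordered genotypes:
#' selfs, crosses and reciprocals) into a grand mean, general combining
#' abilities (GCA, `g_i`), specific combining abilities (SCA, `s_ij`) and
#' reciprocal effects (`r_ij`):
#'
#' \deqn{x_{ij} = \mu + g_i + g_j + s_{ij} + r_{ij}}
#'
#' under the identifiability constraints `sum_i g_i = 0`, `s_ij = s_ji` with
#' `sum_j s_ij = 0` for every `i`, and `r_ij = -r_ji`. On the matrix of cell
#' means `x` with row totals `x_i.` (over fathers), column totals `x._i`
#' (over mothers) and grand total `x..`, the estimates are the closed forms
#'
#' \deqn{\hat\mu = x_{..}/n^2}
#' \deqn{\hat g_i = (x_{i.} + x_{.i})/(2n) - x_{..}/n^2}
#' \deqn{\hat s_{ij} = (x_{ij} + x_{ji})/2 - (x_{i.} + x_{.i} + x_{j.} + x_{.j})/(2n) + x_{..}/n^2}
#' \deqn{\hat r_{ij} = (x_{ij} - x_{ji})/2}
#'
#' which coincide with the constrained least-squares projection (the model is
#' saturated on the `n^2` cell means, so the fitted cell means reproduce the
#' observed ones exactly). All effects are fixed; no inference beyond the
#' parents in the design is intended.
#'
#' @param ptab A [plasticity_table()] covering all `n^2` genotypes of the
#'   design, each with at least one FC replicate.
#' @param design A [diallel_design()].
#' @return Object of class `griffing_fit`: `mu`, `gca` (named vector),
#'   `sca` and `rec` (n x n matrices), `cell_means`, `n_per_cell`,
#'   `balanced`, `resid_ss`, `resid_df`, `parents`.
#' @export
fit_griffing_method1 <- function(ptab, design) {
  stopifnot(inherits(design, "diallel_design"))
  parents <- design$parents
  n <- length(parents)
  X <- matrix(NA_real_, n, n, dimnames = list(mother = parents,
                                              father = parents))
  n_cell <- matrix(0L, n, n, dimnames = dimnames(X))
  resid_ss <- 0; resid_df <- 0L
  for (k in seq_len(nrow(ptab))) {
    i <- match(ptab$mother[k], parents); j <- match(ptab$father[k], parents)
    if (is.na(i) || is.na(j)) next
    fc <- ptab$fc_reps[[k]]
    X[i, j] <- mean(fc)
    n_cell[i, j] <- length(fc)
    resid_ss <- resid_ss + sum((fc - mean(fc))^2)
    resid_df <- resid_df + length(fc) - 1L
  }
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)
    stop(structure(class = c("diallelkit_singularity", "error", "condition"),
                   list(message = paste0(
                     "Method I requires the full n^2 table; missing cell(s): ",
                     paste(genotype_id(parents[miss[, 1]],
                                       parents[miss[, 2]]),
                           collapse = ", "),
                     ". See detect_and_drop_singular_parents()."),
                     call = sys.call(-1))))
  }
  row_tot <- rowSums(X); col_tot <- colSums(X); grand <- sum(X)
  mu <- grand / n^2
  gca <- (row_tot + col_tot) / (2 * n) - grand / n^2
  half_marg <- (row_tot + col_tot) / (2 * n)   # (x_i. + x_.i) / 2n
  sca <- (X + t(X)) / 2 - outer(half_marg, half_marg, "+") + grand / n^2
  rec <- (X - t(X)) / 2
  names(gca) <- parents
  structure(list(mu = mu, gca = gca, sca = sca, rec = rec,
                 cell_means = X, n_per_cell = n_cell,
                 balanced = length(unique(as.vector(n_cell))) == 1L,
                 resid_ss = resid_ss, resid_df = resid_df,
                 parents = parents, n = n),
            class = "griffing_fit")
}

#' @export
print.griffing_fit <- function(x, ...) {
  cat(sprintf("Griffing Method I fit (fixed effects), %d parents\n", x$n))
  cat(sprintf("  grand mean FC: %.4f\n", x$mu))
  cat("  GCA estimates:\n")
  print(round(x$gca, 4))
  cat(sprintf("  residual SS %.4g on %d df%s\n", x$resid_ss, x$resid_df,
              if (x$balanced) "" else " (unbalanced cells)"))
  invisible(x)
}

#' Method I ANOVA of a diallel fit
#'
#' Partitions the among-cell sum of squares into GCA, SCA and reciprocal
#' components. The three effect subspaces are mutually orthogonal under the
#' Method I constraints, so the component sums of squares are the squared
#' norms of the fitted effect patterns over all `n^2` cells, scaled by the
#' per-cell replicate count, and add up exactly to the among-cell SS.
#' F statistics test each effect mean square against the within-cell
#' residual mean square (fixed-effects Model I).
#'
#' @param fit A [fit_griffing_method1()] result.
#' @return Data frame of class `griffing_anova` with rows GCA, SCA,
#'   reciprocal, residual and columns `df`, `ss`, `ms`, `F`, `p`. When cells
#'   carry a single replicate (no residual df) or replication is unbalanced,
#'   F and p are `NA` and the attribute `f_valid` is `FALSE`.
#' @export
anova_method1 <- function(fit) {
  stopifnot(inherits(fit, "griffing_fit"))
  n <- fit$n
  r <- if (fit$balanced) fit$n_per_cell[1, 1] else
    stats::median(as.vector(fit$n_per_cell))
  g <- fit$gca
  ss_gca <- r * 2 * n * sum(g^2)
  ss_sca <- r * sum(fit$sca^2)
  ss_rec <- r * sum(fit$rec^2)
  df <- c(GCA = n - 1, SCA = n * (n - 1) / 2, reciprocal = n * (n - 1) / 2,
          residual = fit$resid_df)
  ss <- c(ss_gca, ss_sca, ss_rec, fit$resid_ss)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  f_valid <- fit$balanced && fit$resid_df > 0L
  Fv <- rep(NA_real_, 4); pv <- rep(NA_real_, 4)
  if (f_valid) {
    Fv[1:3] <- ms[1:3] / ms[4]
    pv[1:3] <- stats::pf(Fv[1:3], df[1:3], df[4], lower.tail = FALSE)
  }
  out <- data.frame(source = names(df), df = unname(df), ss = ss, ms = ms,
                    F = Fv, p = pv, stringsAsFactors = FALSE)
  attr(out, "f_valid") <- f_valid
  attr(out, "replicates_per_cell") <- r
  class(out) <- c("griffing_anova", class(out))
  out
}

#' Baker's predictability ratio
#'
#' `2 * MS_GCA / (2 * MS_GCA + MS_SCA)`, bounded in (0, 1]. The ratio is
#' conventionally read as the share of progeny performance predictable from
#' parental GCA: values near 1 indicate predominance of GCA (additive)
#' variation and values near 0 predominance of SCA. Following the study
#' design this implementation also flags ratios above 0.5 with the
#' report string "non-additive gene action"; the conventional reading is
#' kept alongside in the `note` field (see the methods vignette).
#'
#' @param ms_gca,ms_sca Non-negative GCA and SCA mean squares, not both 0.
#' @return List with `ratio`, `nonadditive_flag` (`ratio > 0.5`) and `note`.
#' @examples
#' bakers_ratio(1, 18)$ratio  # 0.1
#' @export
bakers_ratio <- function(ms_gca, ms_sca) {
  if (ms_gca < 0 || ms_sca < 0) stop("mean squares must be >= 0")
  if (ms_gca == 0 && ms_sca == 0)
    stop("undefined ratio: both mean squares are zero")
  ratio <- 2 * ms_gca / (2 * ms_gca + ms_sca)
  list(ratio = ratio,
       nonadditive_flag = ratio > 0.5,
       note = if (ratio > 0.5)
         "flagged: non-additive gene action (ratio > 0.5); note that the conventional reading of ratios near 1 is GCA/additive predominance"
       else
         "ratio <= 0.5: SCA (non-additive) mean square dominates")
}

#' Variance components and component-based heritability
#'
#' The additive variance is four times the variance in GCA and the dominance
#' variance four times the variance in SCA; "variance in GCA/SCA" is taken
#' as the sample variance (n-1 denominator) of the estimated effects - the
#' `n` GCA estimates and, by default, the `n(n-1)/2` distinct off-diagonal
#' SCA estimates (`include_diagonal_sca = TRUE` adds the self SCAs). The
#' environmental component is the residual mean square divided by the
#' per-cell replicate count (i.e. the variance of a cell mean). Two
#' heritabilities are reported: `h2_narrow = VA / (VA + VD + VE)` and
#' `h2_no_env = VA / (VA + VD)`.
#'
#' @param fit A [fit_griffing_method1()] result.
#' @param anova Optional matching [anova_method1()] table (recomputed if
#'   omitted) supplying the residual MS.
#' @param include_diagonal_sca Include self SCAs in `var_sca`?
#' @return List with `var_gca`, `var_sca`, `VA`, `VD`, `VE`, `h2_narrow`,
#'   `h2_no_env`.
#' @export
variance_components_and_h2 <- function(fit, anova = NULL,
                                       include_diagonal_sca = FALSE) {
  stopifnot(inherits(fit, "griffing_fit"))
  if (fit$n < 3L) stop("variance undefined: need at least 3 parents")
  if (is.null(anova)) anova <- anova_method1(fit)
  var_gca <- stats::var(fit$gca)
  s_off <- fit$sca[upper.tri(fit$sca)]
  s_vals <- if (include_diagonal_sca) c(s_off, diag(fit$sca)) else s_off
  var_sca <- stats::var(s_vals)
  VA <- 4 * var_gca
  VD <- 4 * var_sca
  ms_resid <- anova$ms[anova$source == "residual"]
  r <- attr(anova, "replicates_per_cell")
  VE <- if (is.finite(ms_resid)) ms_resid / r else 0
  ratio0 <- function(num, den) if (den == 0) 0 else num / den
  list(var_gca = var_gca, var_sca = var_sca, VA = VA, VD = VD, VE = VE,
       h2_narrow = ratio0(VA, VA + VD + VE),
       h2_no_env = ratio0(VA, VA + VD))
}

# Design matrix of the Method I model over a set of available cells, in a
# full parameterization [mu | g (n) | s upper-tri incl diag | r upper-tri]
# with the identifiability constraints appended as extra rows. Estimable
# iff rank == ncol.
method1_design_matrix <- function(cells, parents) {
  n <- length(parents)
  s_idx <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    (a - 1) * n - (a - 1) * a / 2 + b   # position in upper-tri-incl-diag
  }
  r_idx <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    (a - 1) * n - a * (a - 1) / 2 + (b - a)
  }
  n_s <- n * (n + 1) / 2; n_r <- n * (n - 1) / 2
  p <- 1 + n + n_s + n_r
  rows <- nrow(cells)
  M <- matrix(0, rows + 1 + n, p)
  for (k in seq_len(rows)) {
    i <- match(cells$mother[k], parents); j <- match(cells$father[k], parents)
    M[k, 1] <- 1
    M[k, 1 + i] <- M[k, 1 + i] + 1
    M[k, 1 + j] <- M[k, 1 + j] + 1
    M[k, 1 + n + s_idx(i, j)] <- 1
    if (i != j)
      M[k, 1 + n + n_s + r_idx(i, j)] <- if (i < j) 1 else -1
  }
  M[rows + 1, 1 + seq_len(n)] <- 1                 # sum g = 0
  for (i in seq_len(n))                             # sum_j s_ij = 0
    for (j in seq_len(n))
      M[rows + 1 + i, 1 + n + s_idx(i, j)] <-
        M[rows + 1 + i, 1 + n + s_idx(i, j)] + 1
  M
}

#' Drop parents whose missing cells make the Method I model inestimable
#'
#' The saturated Method I model needs every ordered (mother, father) cell of
#' the current parent set; missing cells make the constrained design matrix
#' rank-deficient and the fit numerically singular. While the design matrix
#' over the available cells is rank-deficient, the parent with the fewest
#' available cells is dropped (ties broken alphabetically) and the check is
#' repeated on the reduced parent set. Mirrors the common practice of
#' removing an accession that causes singularities rather than abandoning
#' the analysis.
#'
#' @param ptab A [plasticity_table()] (possibly with absent genotypes).
#' @param design A [diallel_design()].
#' @return List with `design` (reduced [diallel_design()]), `dropped`
#'   (character vector, in drop order) and `diagnostics` (data frame per
#'   iteration: parent dropped, available cells, design-matrix rank and
#'   required rank).
#' @export
detect_and_drop_singular_parents <- function(ptab, design) {
  stopifnot(inherits(design, "diallel_design"))
  keep <- design$parents
  have <- unique(genotype_id(ptab$mother[ptab$n_fc > 0],
                             ptab$father[ptab$n_fc > 0]))
  dropped <- character(0)
  diag_rows <- list()
  repeat {
    cells <- expand.grid(father = keep, mother = keep,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells <- cells[genotype_id(cells$mother, cells$father) %in% have, ,
                   drop = FALSE]
    M <- method1_design_matrix(cells, keep)
    rk <- qr(M)$rank
    if (rk == ncol(M)) break
    cnt <- vapply(keep, function(p)
      sum(cells$mother == p | cells$father == p), integer(1))
    victim <- keep[order(cnt, keep)][1]
    diag_rows[[length(diag_rows) + 1]] <-
      data.frame(parent = victim, available_cells = cnt[[victim]],
                 rank = rk, required_rank = ncol(M),
                 stringsAsFactors = FALSE)
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
    if (length(keep) < 3L)
      stop("fatal degeneracy: fewer than 3 estimable parents remain")
  }
  reduced <- if (length(dropped) == 0L) design else
    diallel_design(keep, design$temperatures, design$b_replicates,
                   design$min_flowers)
  list(design = reduced, dropped = dropped,
       diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows)
                     else data.frame(parent = character(0),
                                     available_cells = integer(0),
                                     rank = integer(0),
                                     required_rank = integer(0)))
}
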