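#' Father-offspring regression heritability
#'
#' Ordinary least squares of offspring mean FC on the father's (pollen
#' parent's) own mean FC, one point per non-self cross (reciprocals are
#' separate points with their respective fathers). For a single-parent
#' regression the narrow-sense heritability is twice the regression slope,
#' `h2 = 2b`. Estimates outside `[0, 1]` are reported as-is and flagged.
#'
#' @param ptab A [plasticity_table()] holding selfs and crosses.
#' @param design Optional [diallel_design()]; when given, restricts to its
#'   parents.
#' @return List with `slope`, `intercept`, `h2` (= 2 * slope), `r_squared`,
#'   `n_points`, `out_of_range` flag, and the scatter `points` data frame
#'   (father_fc, offspring_fc, mother, father).
#' @export
father_offspring_regression <- function(ptab, design = NULL) {
  if (!is.null(design)) {
    stopifnot(inherits(design, "diallel_design"))
    ptab <- ptab[ptab$mother %in% design$parents &
                 ptab$father %in% design$parents, ]
  }
  selfs <- ptab[ptab$is_self, ]
  crosses <- ptab[!ptab$is_self, ]
  father_fc <- selfs$mean_fc[match(crosses$father, selfs$father)]
  ok <- !is.na(father_fc)
  crosses <- crosses[ok, ]; father_fc <- father_fc[ok]
  if (nrow(crosses) < 3L) stop("need at least 3 crosses for the regression")
  if (stats::var(father_fc) < .Machine$double.eps)
    stop("undefined slope: no variance in father mean FC")
  fit <- stats::lm(offspring_fc ~ father_fc,
                   data = data.frame(offspring_fc = crosses$mean_fc,
                                     father_fc = father_fc))
  b <- unname(stats::coef(fit)[2])
  h2 <- 2 * b
  list(slope = b,
       intercept = unname(stats::coef(fit)[1]),
       h2 = h2,
       r_squared = summary(fit)$r.squared,
       n_points = nrow(crosses),
       out_of_range = h2 < 0 || h2 > 1,
       points = data.frame(mother = crosses$mother,
                           father = crosses$father,
                           father_fc = father_fc,
                           offspring_fc = crosses$mean_fc,
                           stringsAsFactors = FALSE))
}

#' Parent-versus-hybrid comparison of plasticity distributions
#'
#' Compares the genotype-level mean FCs of the selfed parents against those
#' of all non-self hybrids: a two-sided Wilcoxon rank-sum test for a
#' location shift and a Brown-Forsythe Levene test (one-way ANOVA on the
#' absolute deviations from the group medians) for homogeneity of variances.
#' The rank-sum statistic `W` follows the Mann-Whitney U convention for the
#' hybrid group (first sample), i.e. `W` lies in `[0, n_hybrids *
#' n_parents]`; exact enumeration is used when both groups are at or below
#' `exact_threshold` and there are no ties, the tie-corrected normal
#' approximation otherwise.
#'
#' @param ptab A [plasticity_table()].
#' @param exact_threshold Largest group size for the exact Wilcoxon path.
#' @return List with `wilcoxon_W`, `wilcoxon_p`, `wilcoxon_method`,
#'   `levene_F`, `levene_p`, `n_parents`, `n_hybrids`,
#'   `median_parent_fc`, `median_hybrid_fc`.
#' @export
compare_parent_hybrid_groups <- function(ptab, exact_threshold = 25L) {
  parent_fc <- ptab$mean_fc[ptab$is_self]
  hybrid_fc <- ptab$mean_fc[!ptab$is_self]
  if (length(parent_fc) < 2L || length(hybrid_fc) < 2L)
    stop("each group needs at least 2 genotypes for the variance test")
  ties <- anyDuplicated(c(parent_fc, hybrid_fc)) > 0L
  exact <- !ties && max(length(parent_fc), length(hybrid_fc)) <=
    exact_threshold
  wt <- stats::wilcox.test(hybrid_fc, parent_fc, exact = exact,
                           correct = TRUE)
  lv <- brown_forsythe(list(parents = parent_fc, hybrids = hybrid_fc))
  list(wilcoxon_W = unname(wt$statistic),
       wilcoxon_p = wt$p.value,
       wilcoxon_method = if (exact) "exact enumeration"
                         else "normal approximation with tie correction",
       levene_F = lv$F, levene_p = lv$p,
       n_parents = length(parent_fc), n_hybrids = length(hybrid_fc),
       median_parent_fc = stats::median(parent_fc),
       median_hybrid_fc = stats::median(hybrid_fc))
}

# Brown-Forsythe form of Levene's test: one-way ANOVA of |x - median(group)|.
brown_forsythe <- function(groups) {
  z <- unlist(lapply(groups, function(x) abs(x - stats::median(x))),
              use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1])
}
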