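#' Assemble a pipeline run configuration
#'
#' @param input Path to a phenotype CSV/TSV, or `NULL` to simulate.
#' @param design A [diallel_design()] (required with `input`).
#' @param simulate A [simulation_config()] (used when `input` is `NULL`).
#' @param q FDR level for all BH-controlled test families.
#' @param f_test_alpha Alpha of the variance-equality pre-tests.
#' @param bh_family `"all_crosses"` or an integer stage-1 family size.
#' @param include_diagonal_sca Include self SCAs in the SCA variance?
#' @param out_dir Output directory for the report bundle (`NULL`: no files).
#' @param seed Seed applied to any simulation requested.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, design = NULL, simulate = NULL,
                       q = 0.1, f_test_alpha = 0.05,
                       bh_family = "all_crosses",
                       include_diagonal_sca = FALSE,
                       out_dir = NULL, seed = 1L) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (f_test_alpha <= 0 || f_test_alpha >= 1)
    stop("f_test_alpha must lie in (0, 1)")
  if (is.null(input)) {
    if (is.null(simulate)) simulate <- simulation_config(seed = seed)
    simulate$seed <- as.integer(seed)
  } else if (is.null(design)) {
    stop("a design must accompany a phenotype file")
  }
  structure(list(input = input, design = design, simulate = simulate,
                 q = q, f_test_alpha = f_test_alpha,
                 bh_family = bh_family,
                 include_diagonal_sca = include_diagonal_sca,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate` mapping
#' is passed to [simulation_config()] and a `design` mapping (keys
#' `parents`, `temperatures`, `b_replicates`, `min_flowers`) to
#' [diallel_design()].
#'
#' @param path YAML file.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is needed to read YAML configs")
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(simulation_config,
                                                  y$simulate)
  if (!is.null(y$design)) y$design <- do.call(diallel_design, y$design)
  do.call(run_config, y)
}

#' Run the full plasticity pipeline
#'
#' Sequences the stages end to end: phenotype input (read or simulated) ->
#' per-genotype fold changes and parental temperature tests -> inheritance
#' classification -> singularity check and Griffing Method I combining
#' abilities, ANOVA, Baker's ratio, variance components -> father-offspring
#' regression heritability and parent-vs-hybrid comparisons. When
#' `out_dir` is set, every stage table is written as TSV, the scalar results
#' as a JSON run summary, and a log of all decisions taken (parents
#' dropped, BH family sizes, test-branch choices) as plain text.
#'
#' @param cfg A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return List of class `diallel_report`: `design`, `plasticity`,
#'   `parental_tests`, `inheritance`, `griffing` (fit, anova, bakers,
#'   variance components, dropped parents), `heritability` (regression and
#'   group comparison), `summary` (flat named list), `log`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.null(cfg$input)) {
    sim <- simulate_diallel(cfg$simulate)
    records <- sim$table
    design <- sim$design
    note("simulated %d-parent diallel (mode %s, seed %d): %d flower records",
         cfg$simulate$n_parents, cfg$simulate$inheritance_mode,
         cfg$simulate$seed, nrow(records))
  } else {
    design <- cfg$design
    records <- read_phenotypes(cfg$input, design)
    note("read %d flower records from %s", nrow(records), cfg$input)
  }
  completeness <- check_design_completeness(records, design)
  if (!completeness$complete)
    note("design incomplete: %d absent genotype(s), %d under-replicated cell(s)",
         nrow(completeness$missing_genotypes),
         nrow(completeness$under_replicated))

  ptab <- plasticity_table(records, design)
  selfed <- ptab$mother[ptab$is_self]
  no_self <- setdiff(design$parents, selfed)
  par_design <- design
  if (length(no_self)) {
    note("parent(s) without a phenotyped self genotype: %s",
         paste(no_self, collapse = ", "))
    par_design <- diallel_design(intersect(design$parents, selfed),
                                 design$temperatures, design$b_replicates,
                                 design$min_flowers)
  }
  partests <- parental_temperature_tests(records, par_design, q = cfg$q,
                                         f_test_alpha = cfg$f_test_alpha)
  note("parental temperature tests: %d of %d parents significant at FDR %g",
       sum(partests$significant), nrow(partests), cfg$q)

  bh_m <- if (identical(cfg$bh_family, "all_crosses")) NULL
          else as.integer(cfg$bh_family)
  cls_keep <- ptab$is_self |
    (ptab$mother %in% selfed & ptab$father %in% selfed)
  if (any(!cls_keep))
    note("%d cross(es) excluded from classification for lack of a parental self",
         sum(!cls_keep))
  calls <- classify_inheritance(ptab[cls_keep, ], design, q = cfg$q,
                                f_test_alpha = cfg$f_test_alpha,
                                bh_family = bh_m)
  note("inheritance stage-1 BH family size: %d",
       if (is.null(bh_m)) nrow(calls) else bh_m)
  tab_classes <- table(calls$class)
  note("inheritance calls: %s",
       paste(sprintf("%s=%d", names(tab_classes), tab_classes),
             collapse = ", "))

  dropinfo <- detect_and_drop_singular_parents(ptab, design)
  if (length(dropinfo$dropped))
    note("singularity handling dropped parent(s): %s",
         paste(dropinfo$dropped, collapse = ", "))
  gdesign <- dropinfo$design
  gptab <- ptab[ptab$mother %in% gdesign$parents &
                  ptab$father %in% gdesign$parents, ]
  fit <- fit_griffing_method1(gptab, gdesign)
  av <- anova_method1(fit)
  baker <- bakers_ratio(av$ms[av$source == "GCA"],
                        av$ms[av$source == "SCA"])
  vc <- variance_components_and_h2(fit, av,
                                   include_diagonal_sca =
                                     cfg$include_diagonal_sca)

  reg <- father_offspring_regression(ptab, design)
  grp <- compare_parent_hybrid_groups(ptab)
  note("Wilcoxon convention: Mann-Whitney U of the hybrid group; %s",
       grp$wilcoxon_method)

  summary <- list(
    n_parents = design$n_parents,
    n_genotypes = nrow(ptab),
    parental_fc_min = min(ptab$mean_fc[ptab$is_self]),
    parental_fc_max = max(ptab$mean_fc[ptab$is_self]),
    n_parents_plastic = sum(partests$significant),
    n_crosses_tested = nrow(calls),
    n_nonadditive = sum(calls$class != "additive"),
    n_dominant = sum(calls$class %in% c("dominant_maternal",
                                        "dominant_paternal")),
    n_dominant_maternal = sum(calls$class == "dominant_maternal"),
    n_dominant_paternal = sum(calls$class == "dominant_paternal"),
    n_overdominant = sum(calls$class == "overdominant"),
    n_unresolved = sum(calls$class == "nonadditive_unresolved"),
    griffing_parents_dropped = length(dropinfo$dropped),
    grand_mean_fc = fit$mu,
    bakers_ratio = baker$ratio,
    var_gca = vc$var_gca, var_sca = vc$var_sca,
    VA = vc$VA, VD = vc$VD, VE = vc$VE,
    h2_narrow = vc$h2_narrow, h2_no_env = vc$h2_no_env,
    regression_slope = reg$slope,
    h2_regression = reg$h2,
    h2_regression_out_of_range = reg$out_of_range,
    wilcoxon_W = grp$wilcoxon_W, wilcoxon_p = grp$wilcoxon_p,
    levene_F = grp$levene_F, levene_p = grp$levene_p)

  report <- structure(list(design = design,
                           completeness = completeness,
                           plasticity = ptab,
                           parental_tests = partests,
                           inheritance = calls,
                           griffing = list(fit = fit, anova = av,
                                           bakers = baker,
                                           variance_components = vc,
                                           dropped = dropinfo$dropped,
                                           diagnostics = dropinfo$diagnostics),
                           heritability = list(regression = reg,
                                               groups = grp),
                           summary = summary,
                           log = log),
                      class = "diallel_report")
  if (!is.null(cfg$out_dir)) write_report_bundle(report, cfg$out_dir)
  report
}

#' @export
print.diallel_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Diallel plasticity report: %d parents, %d genotypes\n",
              s$n_parents, s$n_genotypes))
  cat(sprintf("  parental mean FC range: %.3f - %.3f; %d/%d parents plastic\n",
              s$parental_fc_min, s$parental_fc_max, s$n_parents_plastic,
              s$n_parents))
  cat(sprintf("  inheritance: %d/%d non-additive (%d dominant, %d overdominant, %d unresolved)\n",
              s$n_nonadditive, s$n_crosses_tested, s$n_dominant,
              s$n_overdominant, s$n_unresolved))
  cat(sprintf("  Baker's ratio %.3f; VA %.3g, VD %.3g, VE %.3g; h2 %.3f (no-VE %.3f)\n",
              s$bakers_ratio, s$VA, s$VD, s$VE, s$h2_narrow, s$h2_no_env))
  cat(sprintf("  father-offspring h2 = 2b = %.3f%s\n", s$h2_regression,
              if (s$h2_regression_out_of_range) " (out of [0,1])" else ""))
  cat(sprintf("  parents vs hybrids: W = %g (p = %.3g), Levene F = %.3g (p = %.3g)\n",
              s$wilcoxon_W, s$wilcoxon_p, s$levene_F, s$levene_p))
  invisible(x)
}

flatten_plasticity <- function(ptab) {
  k <- max(ptab$n_fc)
  fc <- t(vapply(ptab$fc_reps, function(v) c(v, rep(NA_real_, k - length(v))),
                 numeric(k)))
  colnames(fc) <- paste0("fc_", seq_len(k))
  cbind(ptab[, c("mother", "father", "is_self", "mean_fd_low",
                 "mean_fd_high", "mean_fc", "sd_fc", "n_fc")],
        as.data.frame(fc))
}

write_tsv10 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_float)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a report bundle to disk
#'
#' Emits one TSV per pipeline stage, a JSON run summary
#' (`summary.json`, schema version recorded in the file) and the decision
#' log (`log.txt`).
#'
#' @param report A `diallel_report` from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(report, out_dir) {
  stopifnot(inherits(report, "diallel_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv10(flatten_plasticity(report$plasticity),
              file.path(out_dir, "plasticity.tsv"))
  write_tsv10(report$parental_tests,
              file.path(out_dir, "parental_tests.tsv"))
  write_tsv10(report$inheritance, file.path(out_dir, "inheritance.tsv"))
  av <- report$griffing$anova
  write_tsv10(as.data.frame(av), file.path(out_dir, "griffing_anova.tsv"))
  fit <- report$griffing$fit
  eff <- rbind(
    data.frame(term = "mu", parent_i = NA, parent_j = NA,
               estimate = fit$mu, stringsAsFactors = FALSE),
    data.frame(term = "gca", parent_i = names(fit$gca), parent_j = NA,
               estimate = unname(fit$gca), stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(fit$parents), function(i)
      do.call(rbind, lapply(seq(i, fit$n), function(j)
        data.frame(term = "sca", parent_i = fit$parents[i],
                   parent_j = fit$parents[j],
                   estimate = fit$sca[i, j], stringsAsFactors = FALSE))))),
    do.call(rbind, lapply(seq_len(fit$n - 1), function(i)
      do.call(rbind, lapply(seq(i + 1, fit$n), function(j)
        data.frame(term = "reciprocal", parent_i = fit$parents[i],
                   parent_j = fit$parents[j],
                   estimate = fit$rec[i, j], stringsAsFactors = FALSE))))))
  write_tsv10(eff, file.path(out_dir, "griffing_effects.tsv"))
  write_tsv10(report$heritability$regression$points,
              file.path(out_dir, "regression_points.tsv"))
  jsonlite::write_json(c(list(schema = "diallelkit-report/1"),
                         report$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
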