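fit_from_matrix <- function(X, parents = sprintf("Q%02d", seq_len(nrow(X))),
                            reps = 1, sd = 0) {
  set.seed(1)
  ptab <- toy_ptab(X, parents, reps = reps, sd = sd)  # sd = 0: exact cells
  fit_griffing_method1(ptab, diallel_design(parents))
}

test_that("a constant table fits as grand mean with all effects zero", {
  X <- matrix(0.93, 4, 4)
  fit <- fit_from_matrix(X)
  expect_equal(fit$mu, 0.93)
  expect_equal(unname(fit$gca), rep(0, 4))
  expect_equal(max(abs(fit$sca)), 0)
  expect_equal(max(abs(fit$rec)), 0)
})

test_that("closed forms equal constrained least squares on random tables", {
  set.seed(11)
  for (n in 3:6) {
    for (rep in 1:5) {
      X <- matrix(sample(1:40, n * n, replace = TRUE), n, n)
      fit <- fit_from_matrix(X)
      or <- griffing_ls_oracle(X)
      expect_equal(fit$mu, or$mu, tolerance = 1e-8)
      expect_equal(unname(fit$gca), or$g, tolerance = 1e-8)
      expect_equal(unname(fit$sca), or$s, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(unname(fit$rec), or$r, tolerance = 1e-8,
                   ignore_attr = TRUE)
      # constraints and saturation
      expect_equal(sum(fit$gca), 0, tolerance = 1e-10)
      expect_equal(max(abs(rowSums(fit$sca))), 0, tolerance = 1e-10)
      expect_equal(unname(fit$sca), unname(t(fit$sca)))
      expect_equal(unname(fit$rec), unname(-t(fit$rec)))
      fitted <- fit$mu + outer(fit$gca, fit$gca, "+") + fit$sca + fit$rec
      expect_equal(unname(fitted), unname(X * 1.0), tolerance = 1e-10)
    }
  }
})

test_that("noiseless simulated effects are recovered exactly", {
  cfg <- simulation_config(n_parents = 6, seed = 17,
                           inheritance_mode = "griffing",
                           sigma_flower = 0, sigma_rep = 0)
  sim <- simulate_diallel(cfg)
  ptab <- plasticity_table(sim$table, sim$design)
  fit <- fit_griffing_method1(ptab, sim$design)
  expect_equal(fit$mu, sim$truth$effects$mu_fc, tolerance = 1e-10)
  expect_equal(fit$gca, sim$truth$effects$g, tolerance = 1e-10)
  expect_equal(unname(fit$sca), unname(sim$truth$effects$s),
               tolerance = 1e-10)
  expect_equal(unname(fit$rec), unname(sim$truth$effects$r),
               tolerance = 1e-10)
})

test_that("ANOVA df follow the Method I identities and SS decompose", {
  for (n in c(3, 5, 12, 20)) {
    X <- matrix(rnorm(n * n, 1, 0.1), n, n)
    av <- anova_method1(fit_from_matrix(X, reps = 2, sd = 0))
    expect_equal(av$df[1:3], c(n - 1, n * (n - 1) / 2, n * (n - 1) / 2))
    expect_equal(sum(av$df[1:3]), n^2 - 1)
  }
  # SS(GCA) + SS(SCA) + SS(rec) equals the among-cell SS
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    X <- matrix(rnorm(n * n, 1, 0.2), n, n)
    fit <- fit_from_matrix(X, reps = 3, sd = 0)
    av <- anova_method1(fit)
    among <- 3 * sum((X - mean(X))^2)
    expect_equal(sum(av$ss[1:3]), among, tolerance = 1e-8)
  }
})

test_that("effect estimates are shift- and relabelling-equivariant", {
  set.seed(31)
  n <- 5
  X <- matrix(rnorm(n * n, 1, 0.1), n, n)
  fit <- fit_from_matrix(X)
  fit_shift <- fit_from_matrix(X + 0.37)
  expect_equal(fit_shift$mu, fit$mu + 0.37, tolerance = 1e-10)
  expect_equal(fit_shift$gca, fit$gca, tolerance = 1e-10)
  expect_equal(fit_shift$sca, fit$sca, tolerance = 1e-10)

  perm <- sample(n)
  fit_perm <- fit_from_matrix(X[perm, perm])
  expect_equal(unname(fit_perm$gca), unname(fit$gca[perm]),
               tolerance = 1e-10)
  expect_equal(unname(fit_perm$sca), unname(fit$sca[perm, perm]),
               tolerance = 1e-10)
})

test_that("null F statistics are calibrated and SCA signal is detected", {
  # gca-free tables with strong SCA: GCA F near 1, SCA F large
  set.seed(41)
  n <- 6
  f_gca <- f_sca <- numeric(60)
  for (k in seq_len(60)) {
    s0 <- matrix(rnorm(n * n, 0, 0.2), n, n); s0 <- (s0 + t(s0)) / 2
    rm_ <- rowMeans(s0)
    s <- s0 - outer(rm_, rm_, "+") + mean(s0)
    ptab <- toy_ptab(1 + s, sprintf("Q%02d", 1:n), reps = 3, sd = 0.05)
    av <- anova_method1(fit_griffing_method1(
      ptab, diallel_design(sprintf("Q%02d", 1:n))))
    f_gca[k] <- av$F[1]; f_sca[k] <- av$F[2]
  }
  expect_equal(mean(f_gca), 1, tolerance = 0.35)
  expect_gt(mean(f_sca), 5)
})

test_that("Baker's ratio follows its closed form and monotonicity", {
  expect_equal(bakers_ratio(3, 0)$ratio, 1)
  expect_equal(bakers_ratio(2, 2)$ratio, 2 / 3)
  expect_equal(bakers_ratio(1, 18)$ratio, 0.1)
  expect_error(bakers_ratio(0, 0), "undefined")
  expect_true(bakers_ratio(3, 1)$nonadditive_flag)
  expect_false(bakers_ratio(1, 3)$nonadditive_flag)
  r <- vapply(seq(0, 10, by = 0.5),
              function(s) bakers_ratio(1, s)$ratio, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0 & r <= 1))
})

test_that("variance components follow the 4x rule and bound cases", {
  cfg <- simulation_config(n_parents = 6, seed = 55,
                           inheritance_mode = "griffing")
  sim <- simulate_diallel(cfg)
  ptab <- plasticity_table(sim$table, sim$design)
  fit <- fit_griffing_method1(ptab, sim$design)
  vc <- variance_components_and_h2(fit)
  expect_equal(vc$VA, 4 * var(fit$gca))
  expect_equal(vc$VD, 4 * var(fit$sca[upper.tri(fit$sca)]))
  expect_equal(vc$h2_no_env, vc$VA / (vc$VA + vc$VD))
  expect_gt(vc$h2_narrow, 0); expect_lt(vc$h2_narrow, 1)
  vc_diag <- variance_components_and_h2(fit, include_diagonal_sca = TRUE)
  expect_false(vc_diag$var_sca == vc$var_sca)

  # degenerate bound: no GCA spread -> VA = 0, h2 = 0
  fit0 <- fit_from_matrix(matrix(1, 4, 4), reps = 2)
  vc0 <- variance_components_and_h2(fit0)
  expect_equal(vc0$VA, 0)
  expect_equal(vc0$h2_narrow, 0)
})

test_that("GCA/SCA variances are recovered from their generating SDs", {
  set.seed(61)
  va <- vd <- numeric(40)
  for (k in 1:40) {
    cfg <- simulation_config(n_parents = 12, seed = 6000 + k,
                             inheritance_mode = "griffing",
                             sigma_g = 0.1, sigma_s = 0.05,
                             sigma_flower = 0.02, sigma_rep = 0)
    sim <- simulate_diallel(cfg)
    ptab <- plasticity_table(sim$table, sim$design)
    vc <- variance_components_and_h2(fit_griffing_method1(ptab, sim$design))
    va[k] <- vc$VA; vd[k] <- vc$VD
  }
  expect_equal(mean(va), 4 * 0.1^2, tolerance = 0.25)
  expect_equal(mean(vd), 4 * 0.05^2, tolerance = 0.25)
})

test_that("missing cells are diagnosed and singular parents dropped", {
  cfg <- simulation_config(n_parents = 5, seed = 71)
  sim <- simulate_diallel(cfg)
  ptab <- plasticity_table(sim$table, sim$design)

  # complete table: nothing dropped
  keep <- detect_and_drop_singular_parents(ptab, sim$design)
  expect_length(keep$dropped, 0)
  expect_equal(keep$design$parents, sim$design$parents)

  # all cells of one parent missing: that parent dropped, rest fits
  p3 <- ptab[ptab$mother != "P03" & ptab$father != "P03", ]
  dr <- detect_and_drop_singular_parents(p3, sim$design)
  expect_equal(dr$dropped, "P03")
  fit <- fit_griffing_method1(p3, dr$design)
  expect_equal(fit$n, 4)

  # the unreduced fit refuses with a singularity error
  expect_error(fit_griffing_method1(p3, sim$design),
               class = "diallelkit_singularity")

  # two parents sharing missing cells: deterministic alphabetical order
  p2 <- ptab[!(ptab$mother %in% c("P02", "P04")) &
               !(ptab$father %in% c("P02", "P04")), ]
  dr2 <- detect_and_drop_singular_parents(p2, sim$design)
  expect_equal(dr2$dropped, c("P02", "P04"))
  expect_equal(nrow(dr2$diagnostics), 2)

  # fewer than 3 estimable parents is fatal
  p1 <- ptab[ptab$mother == ptab$father, ]
  expect_error(detect_and_drop_singular_parents(p1, sim$design),
               "fatal degeneracy")
})
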