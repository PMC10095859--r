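test_that("mid-parent value is the parental mean and errors when absent", {
  expect_equal(mid_parent_value(0.79, 1.10), 0.945)
  expect_equal(mid_parent_value(0.9, 0.9), 0.9)
  expect_equal(mid_parent_value(1.0, 0.8), 0.9)
  expect_error(mid_parent_value(NA, 1), "missing")
})

test_that("one-sample test against the MPV matches the closed form", {
  r <- test_vs_mpv(c(0.9, 1.1, 0.9, 1.1), 1.0)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  x <- c(0.80, 0.82, 0.78, 0.80)
  r2 <- test_vs_mpv(x, 1.0)
  t_manual <- (mean(x) - 1.0) / (sd(x) / 2)
  expect_equal(r2$statistic, t_manual)       # ~ -24.5
  expect_equal(r2$statistic, -24.49, tolerance = 1e-3)
  expect_lt(r2$p, 0.001)
  expect_equal(r2$p, 2 * pt(t_manual, df = 3), tolerance = 1e-12)

  # zero-variance convention
  expect_equal(test_vs_mpv(c(1, 1, 1, 1), 1)$p, 1)
  expect_equal(test_vs_mpv(c(1, 1, 1, 1), 0.9)$p, 0)
})

test_that("null p-values of the MPV test are uniform", {
  set.seed(123)
  p <- replicate(4000, test_vs_mpv(rnorm(4, 0.9, 0.05), 0.9)$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.01)
})

test_that("BH adjustment reproduces the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "domain error")

  set.seed(7)
  for (k in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    # independent cross-check against the reference implementation
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
    adj <- bh_adjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw p
  }
  # enlarged family scales the adjustment up
  p <- c(0.01, 0.04)
  expect_equal(bh_adjust(p, m = 10), bh_bruteforce(p, m = 10))
  expect_true(all(bh_adjust(p, m = 10) >= bh_adjust(p)))
})

test_that("parent comparison gates pooled vs Welch on the F-test", {
  x <- c(0.80, 0.81, 0.79, 0.80)
  expect_equal(compare_to_parent(x, x)$p, 1)

  y <- c(1.00, 1.01, 0.99, 1.00)
  r <- compare_to_parent(x, y)
  expect_lt(r$p, 1e-6)
  expect_false(r$welch)   # equal spreads -> pooled branch

  # variance ratio 100 with n = 4 each: F(3,3) critical ~ 9.28 < 100
  set.seed(5)
  a <- 1 + scale(rnorm(4))[, 1] * 0.10
  b <- 1 + scale(rnorm(4))[, 1] * 0.01
  expect_equal(var(a) / var(b), 100, tolerance = 1e-9)
  expect_true(compare_to_parent(a, b)$welch)

  # degenerate conventions
  expect_equal(compare_to_parent(c(1, 1), c(1, 1))$p, 1)
  expect_equal(compare_to_parent(c(1, 1), c(2, 2))$p, 0)
})

test_that("constructed dominance fixtures classify as built", {
  # hybrid FC replicates copied verbatim from one parent (effect/noise
  # ratio to the other parent >> 10): the copied parent can never test as
  # different, the other parent always does
  dominance_fixture <- function(dominant = c("mother", "father")) {
    dominant <- match.arg(dominant)
    set.seed(202)
    parents <- c("A", "B", "C")
    fc_par <- c(A = 0.8, B = 1.0, C = 1.1)
    ptab <- toy_ptab(diag(fc_par) + 0, parents, sd = 0.002)
    selfs <- which(ptab$is_self)
    for (k in selfs)
      ptab$fc_reps[[k]] <- fc_par[ptab$mother[k]] +
        (ptab$fc_reps[[k]] - mean(ptab$fc_reps[[k]]))
    for (k in setdiff(seq_len(nrow(ptab)), selfs)) {
      src <- if (dominant == "mother") ptab$mother[k] else ptab$father[k]
      ptab$fc_reps[[k]] <-
        ptab$fc_reps[[selfs[match(src, ptab$mother[selfs])]]]
    }
    ptab$mean_fc <- vapply(ptab$fc_reps, mean, numeric(1))
    ptab$sd_fc <- vapply(ptab$fc_reps, sd, numeric(1))
    ptab
  }
  d <- diallel_design(c("A", "B", "C"))
  calls <- classify_inheritance(dominance_fixture("mother"), d)
  expect_true(all(calls$class == "dominant_maternal"))
  expect_true(all(calls$direction %in% c("negative", "positive")))
  calls2 <- classify_inheritance(dominance_fixture("father"), d)
  expect_true(all(calls2$class == "dominant_paternal"))
})

test_that("swapping parental labels swaps maternal and paternal dominance", {
  cfg <- simulation_config(n_parents = 5, seed = 77,
                           inheritance_mode = "dominant",
                           dominance_degree = 1,
                           sigma_flower = 0.02, sigma_rep = 0)
  sim <- simulate_diallel(cfg)
  ptab <- plasticity_table(sim$table, sim$design)
  calls <- classify_inheritance(ptab, sim$design)

  swapped <- sim$table
  swapped[, c("mother", "father")] <- swapped[, c("father", "mother")]
  ptab_sw <- plasticity_table(swapped, sim$design)
  calls_sw <- classify_inheritance(ptab_sw, sim$design)

  key <- paste(calls$mother, calls$father)
  key_sw <- paste(calls_sw$father, calls_sw$mother)
  m <- match(key, key_sw)
  flip <- c(additive = "additive",
            dominant_maternal = "dominant_paternal",
            dominant_paternal = "dominant_maternal",
            overdominant = "overdominant",
            nonadditive_unresolved = "nonadditive_unresolved")
  expect_equal(unname(flip[calls$class]), calls_sw$class[m])
  expect_equal(calls$direction, calls_sw$direction[m])
})

test_that("overdominance needs a hybrid mean outside the parental range", {
  set.seed(303)
  parents <- c("A", "B", "C")
  fc_par <- c(A = 0.85, B = 0.95, C = 1.05)
  # hybrids pushed 1.6x past the mid-parent towards the mother: outside
  fc <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    mpv <- (fc_par[i] + fc_par[j]) / 2
    fc[i, j] <- if (i == j) fc_par[i] else mpv + 1.6 * (fc_par[i] - mpv)
  }
  ptab <- toy_ptab(fc, parents, sd = 0.002)
  calls <- classify_inheritance(ptab, diallel_design(parents))
  expect_true(all(calls$class == "overdominant"))
  low <- calls$mother == "A"  # pushed below the smaller parent
  expect_true(all(calls$direction[low] == "negative"))

  # property: overdominant is never called with the mean strictly inside
  for (s in 1:20) {
    set.seed(s)
    fcr <- matrix(runif(9, 0.8, 1.1), 3, 3)
    pt2 <- toy_ptab(fcr, parents, sd = 0.01)
    cl <- classify_inheritance(pt2, diallel_design(parents))
    selfs <- pt2[pt2$is_self, ]
    hyb_fc <- pt2$mean_fc[!pt2$is_self]
    for (k in seq_len(nrow(cl))) {
      pr <- range(selfs$mean_fc[match(c(cl$mother[k], cl$father[k]),
                                      selfs$mother)])
      if (cl$class[k] == "overdominant")
        expect_false(hyb_fc[k] > pr[1] && hyb_fc[k] < pr[2])
    }
  }
})

test_that("fully symmetric hybrids come out additive", {
  parents <- c("A", "B")
  ptab <- toy_ptab(matrix(c(0.9, 1.0, 1.0, 1.1), 2, 2, byrow = TRUE),
                   parents, sd = 0)
  # replicates symmetric about the MPV
  ptab$fc_reps[[2]] <- c(0.95, 1.05, 0.95, 1.05)
  ptab$fc_reps[[3]] <- c(0.95, 1.05, 0.95, 1.05)
  ptab$mean_fc <- vapply(ptab$fc_reps, mean, numeric(1))
  ptab$fc_reps[[1]] <- ptab$fc_reps[[1]] + c(-0.001, 0.001, -0.001, 0.001)
  ptab$fc_reps[[4]] <- ptab$fc_reps[[4]] + c(-0.001, 0.001, -0.001, 0.001)
  calls <- classify_inheritance(ptab, diallel_design(parents))
  expect_true(all(calls$class == "additive"))
  expect_true(all(is.na(calls$p_mother_raw)))
})
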