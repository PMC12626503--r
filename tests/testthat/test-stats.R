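# Statistical battery: quartiles, Mann-Whitney, t tests, ICC, regression,
# sample size, bilateral summation, directional comparison.

test_that("quartiles follow the weighted-average (n+1)p convention", {
  q <- quartiles(c(1, 2, 3, 4))
  expect_equal(q$q25, 1.25)
  expect_equal(q$median, 2.5)
  expect_equal(q$q75, 3.75)
  q5 <- quartiles(c(5, 5, 5))
  expect_equal(c(q5$q25, q5$median, q5$q75), c(5, 5, 5))
  expect_equal(q5$sd, 0)
  # affine equivariance
  set.seed(3)
  x <- stats::rnorm(17)
  qa <- quartiles(3 * x + 2)
  qb <- quartiles(x)
  expect_equal(qa$median, 3 * qb$median + 2, tolerance = 1e-12)
  expect_equal(qa$q25, 3 * qb$q25 + 2, tolerance = 1e-12)
  expect_error(quartiles(numeric(0)), "empty")
})

test_that("Mann-Whitney exact p comes from full label enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 of 20 assignments as extreme
  # identical samples -> p = 1 (with tie warning)
  expect_warning(r2 <- mann_whitney(c(2, 2), c(2, 2)), "tied")
  expect_equal(r2$p_value, 1)
  r3 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r3$p_value, 1, tolerance = 1e-12)
  # exact agrees with an independent enumeration oracle under ties
  x <- c(1, 2, 2, 5); y <- c(2, 3, 7)
  r4 <- mann_whitney(x, y, mode = "exact")
  rk <- rank(c(x, y))
  combos <- utils::combn(7, 4)
  u_all <- apply(combos, 2, function(id) sum(rk[id]) - 4 * 5 / 2)
  u_obs <- sum(rk[1:4]) - 10
  p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(r4$p_value, p_oracle)
})

test_that("asymptotic Mann-Whitney is close to exact at small n", {
  set.seed(7)
  for (k in 1:8) {
    x <- stats::rnorm(8); y <- stats::rnorm(8, 0.3)
    pe <- mann_whitney(x, y, mode = "exact", exact_limit = 16)$p_value
    pa <- mann_whitney(x, y, mode = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("t test summary and raw paths agree; degenerate inputs pinned", {
  set.seed(13)
  x <- stats::rnorm(23, -0.151, 1.197)
  y <- stats::rnorm(18, -1.068, 1.333)
  raw <- unpaired_t(x, y, "pooled")
  summ <- unpaired_t(list(n = 23, mean = mean(x), sd = stats::sd(x)),
                     list(n = 18, mean = mean(y), sd = stats::sd(y)),
                     "pooled")
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  # cross-check against stats::t.test on the same data
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(raw$p_value, ref$p.value, tolerance = 1e-9)
  refw <- stats::t.test(x, y)
  w <- unpaired_t(x, y, "welch")
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-9)
  deg <- unpaired_t(list(n = 5, mean = 1, sd = 0),
                    list(n = 5, mean = 1, sd = 0))
  expect_equal(deg$p_value, 1)
})

test_that("published-scale asymmetry summaries give the closed-form pooled t", {
  # hand-computed pooled-variance t from the group summaries
  n1 <- 23; m1 <- -0.151; s1 <- 1.197
  n2 <- 18; m2 <- -1.068; s2 <- 1.333
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t_oracle <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  r <- unpaired_t(list(n = n1, mean = m1, sd = s1),
                  list(n = n2, mean = m2, sd = s2), "pooled")
  expect_equal(r$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(r$statistic, 2.316, tolerance = 1e-3)
  # the corresponding two-sided p from these summaries
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_oracle), n1 + n2 - 2),
               tolerance = 1e-12)
})

test_that("type-I error of both tests is 5% under the null", {
  set.seed(202)
  n_rep <- 2000L
  rej_t <- 0L; rej_m <- 0L
  for (k in seq_len(n_rep)) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    if (unpaired_t(x, y)$p_value < 0.05) rej_t <- rej_t + 1L
    if (mann_whitney(x, y, mode = "asymptotic")$p_value < 0.05) {
      rej_m <- rej_m + 1L
    }
  }
  # binomial 3-sigma band around the nominal level at 2000 replicates
  expect_lt(abs(rej_t / n_rep - 0.05), 0.015)
  expect_lt(abs(rej_m / n_rep - 0.05), 0.015)
})

test_that("ICC(A,1) recovers known variance components", {
  # identical raters -> ICC 1
  set.seed(5)
  v <- stats::rnorm(20)
  r <- icc_inter_rater(cbind(v, v))
  expect_equal(r$icc, 1, tolerance = 1e-9)
  # pure noise -> near 0
  set.seed(31)
  iccs <- replicate(50, {
    suppressWarnings(icc_inter_rater(matrix(stats::rnorm(60), 30, 2))$icc)
  })
  expect_lt(abs(mean(iccs)), 0.15)
  expect_true(all(abs(iccs) < 0.5))
  # between-subject sd 4, rater noise sd 1 -> ICC ~ 16/17
  set.seed(77)
  iccs <- replicate(200, {
    subj <- stats::rnorm(30, sd = 4)
    icc_inter_rater(simulate_raters(subj, 1, seed = sample.int(1e6, 1)))$icc
  })
  expect_lt(abs(mean(iccs) - 16 / 17), 0.05)
  # CI brackets the estimate
  subj <- stats::rnorm(30, sd = 4)
  r <- icc_inter_rater(simulate_raters(subj, 1, seed = 99))
  expect_lt(r$ci_low, r$icc)
  expect_gt(r$ci_high, r$icc)
  # zero rater noise via the simulator
  expect_equal(icc_inter_rater(simulate_raters(v, 0, seed = 1))$icc, 1,
               tolerance = 1e-9)
})

test_that("dummy regression recovers exact and noisy effects", {
  set.seed(41)
  n <- 60
  df <- tibble::tibble(
    gender = sample(c("female", "male"), n, TRUE, c(0.9, 0.1)),
    group = rep(c("DD", "DR"), each = n / 2),
    age_band = sample(c("10-18", "19-25"), n, TRUE, c(0.65, 0.35)),
    diagnosis = sample(c("unilateral", "bilateral"), n, TRUE))
  # exact fit: response = 100 * indicator(DR)
  df$volume_change <- 100 * (df$group == "DR")
  fit <- ols_dummy_regression(df)
  b_disc <- fit$b[fit$term == "Disc position (Reposited)"]
  expect_equal(b_disc, 100, tolerance = 1e-9)
  expect_lt(fit$se[fit$term == "Disc position (Reposited)"], 1e-9)
  expect_equal(fit$b[fit$term == "Gender (Female)"], 0, tolerance = 1e-8)
  # row order invariance
  perm <- sample(n)
  fit2 <- ols_dummy_regression(df[perm, ])
  expect_equal(fit2$b, fit$b, tolerance = 1e-9)
  # cross-check SEs and CIs against stats::lm on a noisy response
  df$volume_change <- 50 + 350 * (df$group == "DR") + stats::rnorm(n, 0, 240)
  fit3 <- ols_dummy_regression(df)
  ref <- stats::lm(volume_change ~ I(gender == "female") + I(group == "DR") +
                     I(age_band == "10-18") + I(diagnosis == "unilateral"),
                   data = df)
  expect_equal(fit3$b, unname(stats::coef(ref)), tolerance = 1e-9)
  expect_equal(fit3$se, unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-9)
  ci <- stats::confint(ref)
  expect_equal(fit3$ci_low, unname(ci[, 1]), tolerance = 1e-9)
})

test_that("regression Monte-Carlo: estimates within 10%, CI coverage in band", {
  set.seed(61)
  n <- 60
  b_true <- 350
  est <- numeric(500)
  cover <- logical(500)
  for (k in 1:500) {
    # fixed covariate margins (54/6, 39/21, 30/30) keep the dummy design
    # full rank in every replicate
    df <- tibble::tibble(
      gender = sample(rep(c("female", "male"), c(54, 6))),
      group = rep(c("DD", "DR"), each = n / 2),
      age_band = sample(rep(c("10-18", "19-25"), c(39, 21))),
      diagnosis = sample(rep(c("unilateral", "bilateral"), c(30, 30))))
    df$volume_change <- b_true * (df$group == "DR") + stats::rnorm(n, 0, 240)
    fit <- ols_dummy_regression(df)
    i <- which(fit$term == "Disc position (Reposited)")
    est[k] <- fit$b[i]
    cover[k] <- fit$ci_low[i] <= b_true && b_true <= fit$ci_high[i]
  }
  expect_lt(abs(mean(est) - b_true) / b_true, 0.10)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("sample-size scan matches a noncentral-t oracle and scales as sigma^2", {
  res <- required_sample_size(0.94, 166.50, 153.7, 201.5,
                              alpha = 0.05, power = 0.90, dropout = 0.10)
  # independent brute-force oracle over the same power function
  oracle_n <- NA
  for (n in 2:200) {
    a <- 153.7^2 / n; b <- 201.5^2 / n
    df <- (a + b)^2 / (a^2 / (n - 1) + b^2 / (n - 1))
    ncp <- (166.50 - 0.94) / sqrt(a + b)
    tc <- stats::qt(0.975, df)
    pw <- stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
    if (pw >= 0.90) { oracle_n <- n; break }
  }
  expect_equal(res$n_per_group, oracle_n)
  expect_equal(res$total_enrolled, 2 * ceiling(oracle_n / 0.9))
  # doubling both sds ~ quadruples pre-dropout n (+/- 1)
  res2 <- required_sample_size(0.94, 166.50, 2 * 153.7, 2 * 201.5,
                               alpha = 0.05, power = 0.90, dropout = 0)
  expect_lte(abs(res2$n_per_group - 4 * res$n_per_group), 4)
  # monotonicity in effect and spread
  res_big <- required_sample_size(0.94, 300, 153.7, 201.5)
  expect_lte(res_big$n_per_group, res$n_per_group)
  expect_error(required_sample_size(1, 1, 10, 10), "zero effect")
})

test_that("bilateral summation adds sides and differences timepoints", {
  sp <- cohort_spec(n_per_group = 5, seed = 9)
  tab <- simulate_cohort(sp)
  pb <- sum_bilateral(tab)
  # direct check on one patient
  p1 <- tab[tab$patient_id == "P001", ]
  v0 <- sum(p1$volume[p1$timepoint == "T0"])
  v1 <- sum(p1$volume[p1$timepoint == "T1"])
  row <- pb[pb$patient_id == "P001", ]
  expect_equal(row$volume_t0, v0)
  expect_equal(row$volume_change, v1 - v0, tolerance = 1e-12)
  # ledger bookkeeping: summed draws recovered exactly
  led <- attr(tab, "ledger")
  m <- match(pb$patient_id, led$patient_id)
  expect_equal(pb$volume_t0, led$volume_t0[m], tolerance = 1e-9)
  expect_equal(pb$volume_change, led$volume_change[m], tolerance = 1e-9)
  expect_equal(pb$h_po_change, led$dh_po[m], tolerance = 1e-9)
  # scale example: left 1300 + right 1341.1
  one <- tibble::tibble(patient_id = "X", side = c("left", "right"),
                        timepoint = "T0", volume = c(1300, 1341.1))
  one <- dplyr::bind_rows(one, dplyr::mutate(one, timepoint = "T1",
                                             volume = volume + c(10, 20)))
  sb <- sum_bilateral(one)
  expect_equal(sb$volume_t0, 2641.1)
  expect_equal(sb$volume_change, 30, tolerance = 1e-9)
  # missing side errors with the patient named
  expect_error(sum_bilateral(tab[-1, ]), "P001")
})

test_that("directional comparison summarizes and tests d_io / d_pipo", {
  # identical groups -> t = 0, p = 1
  d <- tibble::tibble(
    timepoint = "T0",
    disc_direction = rep(c("anteromedial", "anterolateral"), each = 4),
    d_io = rep(c(1, 2, 3, 4), 2), d_pipo = rep(c(-1, 0, 1, 2), 2))
  r <- directional_resorption_analysis(d)
  expect_equal(r$tests$d_io$statistic, 0)
  expect_equal(r$tests$d_pipo$p_value, 1)
  # summaries agree with the quartiles module on the same subsets
  q <- quartiles(d$d_io[d$disc_direction == "anteromedial"])
  srow <- r$summary[r$summary$disc_direction == "anteromedial" &
                      r$summary$measure == "d_io", ]
  expect_equal(srow$mean, q$mean)
  expect_equal(srow$sd, q$sd)
  expect_error(directional_resorption_analysis(d[c(1, 5), ]), "n < 2")
})

test_that("a 1 mm deeper posteromedial deficit is detected with high power", {
  # measurement-level joints: anterolateral group has extra posteromedial
  # resorption; per-joint noise sd 0.8, n = 20 + 20, 200 seeds
  set.seed(303)
  rej <- 0L
  n_rep <- 200L
  for (k in seq_len(n_rep)) {
    am <- stats::rnorm(20, -0.15, 0.8)
    al <- stats::rnorm(20, -1.15, 0.8)
    d <- tibble::tibble(
      timepoint = "T0",
      disc_direction = rep(c("anteromedial", "anterolateral"), each = 20),
      d_io = stats::rnorm(40, 2, 1), d_pipo = c(am, al))
    r <- directional_resorption_analysis(d)
    if (r$tests$d_pipo$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.8)
})

test_that("demographic and directional proportions reproduce count arithmetic", {
  p <- directional_displacement_proportion(34, 26, 23, 18)
  expect_equal(p$affected_joints, 86)
  expect_equal(p$directional_joints, 41)
  expect_equal(round(p$percent, 1), 47.7)
  demo <- demographic_percentages(
    tibble::tibble(gender = rep(c("female", "male"), c(54, 6)),
                   age_band = rep(c("10-18", "19-25"), c(39, 21))))
  expect_equal(demo$percent_female, 90)
  expect_equal(demo$percent_age_10_18, 65)
})
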