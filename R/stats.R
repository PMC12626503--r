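# Cohort statistical battery: quartile summaries (weighted-average
# percentile convention), Mann-Whitney U (exact enumeration at small n,
# tie-corrected normal approximation otherwise), pooled/Welch two-sample t,
# two-way random absolute-agreement single-measure ICC, dummy-coded linear
# regression, bilateral summation, and the noncentral-t sample-size
# calculation.  All tests are two-sided; no multiplicity correction is
# applied (per-table marginal tests).

#' Quartile summary of a numeric vector
#'
#' Percentiles use the weighted-average rule at position `h = (n + 1) p`
#' (the default of the major commercial statistics packages), so summaries
#' are comparable with clinical reports produced by that convention.  Mean
#' and SD use the n-1 denominator.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return List with `median`, `q25`, `q75`, `mean`, `sd`, `n`.
#' @export
quartiles <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("quartiles: empty input", call. = FALSE)
  s <- sort(values)
  pct <- function(p) {
    h <- (n + 1) * p
    h <- min(max(h, 1), n)
    lo <- floor(h)
    if (lo == n) s[n] else s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  list(median = pct(0.5), q25 = pct(0.25), q75 = pct(0.75),
       mean = mean(s), sd = if (n > 1) stats::sd(s) else 0, n = n)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by full enumeration of group-label assignments when the combined
#' sample size is at most `exact_limit` (handles ties exactly); otherwise a
#' tie-corrected normal approximation, by default with continuity
#' correction (set `correct = FALSE` for the uncorrected asymptotic value
#' some commercial packages print).
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"` (default), `"exact"`, or `"asymptotic"`.
#' @param exact_limit Combined-n threshold for exact enumeration.
#' @param correct Apply the continuity correction in asymptotic mode.
#' @return List with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         exact_limit = 12L, correct = TRUE) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("mann_whitney: empty sample", call. = FALSE)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(all_v)) == 1L) {
    warning("mann_whitney: all values tied across both groups")
    return(list(statistic = u_x, p_value = 1, method = "mann-whitney (degenerate)"))
  }
  use_exact <- switch(mode,
                      exact = TRUE,
                      asymptotic = FALSE,
                      auto = (n1 + n2) <= exact_limit)
  if (use_exact) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- apply(combos, 2, function(id) {
      sum(r[id]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * n2 / 2
    p_lo <- mean(u_all <= u_x + 1e-9)
    p_hi <- mean(u_all >= u_x - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = u_x, p_value = p, method = "mann-whitney exact")
  } else {
    nn <- n1 + n2
    ties <- table(all_v)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    dev <- u_x - n1 * n2 / 2
    cc <- if (correct) 0.5 * sign(dev) else 0
    z <- (dev - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    list(statistic = u_x, p_value = min(1, p),
         method = "mann-whitney asymptotic (tie-corrected)")
  }
}

#' Two-sample t test from raw data or summary statistics
#'
#' Accepts either raw numeric vectors or summaries `list(n =, mean =, sd =)`;
#' the two paths agree exactly.  `variant = "pooled"` is the classical
#' Student test (equal variances), `"welch"` uses the Satterthwaite df.
#'
#' @param x,y Raw vectors or `list(n, mean, sd)` summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `statistic` (t), `df`, `p_value`, `method`.
#' @export
unpaired_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  summ <- function(v) {
    if (is.list(v)) {
      list(n = v$n, mean = v$mean, sd = v$sd)
    } else {
      list(n = length(v), mean = mean(v), sd = stats::sd(v))
    }
  }
  s1 <- summ(x); s2 <- summ(y)
  if (s1$n < 2 || s2$n < 2) stop("unpaired_t: need n >= 2 per group",
                                 call. = FALSE)
  if (s1$sd == 0 && s2$sd == 0) {
    if (s1$mean == s2$mean) {
      return(list(statistic = 0, df = s1$n + s2$n - 2, p_value = 1,
                  method = paste0("t (", variant, ", degenerate)")))
    }
    return(list(statistic = Inf * sign(s1$mean - s2$mean),
                df = s1$n + s2$n - 2, p_value = 0,
                method = paste0("t (", variant, ", degenerate)")))
  }
  if (variant == "pooled") {
    df <- s1$n + s2$n - 2
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  } else {
    a <- s1$sd^2 / s1$n; b <- s2$sd^2 / s2$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (s1$n - 1) + b^2 / (s2$n - 1))
  }
  t_stat <- (s1$mean - s2$mean) / se
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       method = paste0("t (", variant, ")"))
}

#' Two-way random-effects absolute-agreement single-measure ICC
#'
#' ICC(A,1) in the McGraw-Wong nomenclature, with the F-distribution-based
#' 95% confidence interval, for an n-subject by k-rater complete matrix.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns, no
#'   missing cells, `n >= 5`, `k >= 2`.
#' @param conf_level Confidence level for the interval.
#' @return List with `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc_inter_rater <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("icc_inter_rater: need >= 5 subjects and >= 2 raters",
                           call. = FALSE)
  if (anyNA(ratings)) stop("icc_inter_rater: missing cells", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- (msr - mse) / denom
  if (msr <= mse) {
    warning("icc_inter_rater: no between-subject variance above error; ICC floored at 0")
    icc <- max(0, icc)
  }
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = lower, ci_high = upper, n = n, k = k)
}

#' Power of the two-sample unequal-variance t test
#'
#' Noncentral-t power at equal per-group size `n` for a two-sided test.
#'
#' @param n Per-group sample size.
#' @param mu1,mu2 Group means.
#' @param sd1,sd2 Group standard deviations.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
two_sample_t_power <- function(n, mu1, mu2, sd1, sd2, alpha = 0.05) {
  a <- sd1^2 / n; b <- sd2^2 / n
  se <- sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (n - 1) + b^2 / (n - 1))
  ncp <- abs(mu2 - mu1) / se
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Required sample size for a two-sample t design
#'
#' Scans equal per-group n upward until the two-sided unequal-variance t test
#' attains the target power (noncentral-t computation), then inflates each
#' group by `1 / (1 - dropout)` with ceiling rounding; the total is forced
#' even (1:1 allocation).
#'
#' @param mu1,mu2 Expected group means.
#' @param sd1,sd2 Expected group SDs.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param dropout Anticipated dropout fraction in `[0, 1)`.
#' @param n_max Scan bound.
#' @return List with `n_per_group` (pre-dropout), `n_per_group_enrolled`,
#'   `total_enrolled`, `achieved_power` at the pre-dropout n.
#' @export
required_sample_size <- function(mu1, mu2, sd1, sd2, alpha = 0.05,
                                 power = 0.90, dropout = 0.10,
                                 n_max = 100000L) {
  if (mu1 == mu2) stop("required_sample_size: zero effect; power unattainable",
                       call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("required_sample_size: dropout must be in [0, 1)",
                                        call. = FALSE)
  n <- 2L
  repeat {
    pw <- two_sample_t_power(n, mu1, mu2, sd1, sd2, alpha)
    if (pw >= power) break
    n <- n + 1L
    if (n > n_max) stop("required_sample_size: scan bound exceeded",
                        call. = FALSE)
  }
  n_infl <- ceiling(n / (1 - dropout))
  total <- 2L * as.integer(n_infl)
  list(n_per_group = n, n_per_group_enrolled = as.integer(n_infl),
       total_enrolled = total,
       achieved_power = two_sample_t_power(n, mu1, mu2, sd1, sd2, alpha))
}

#' Dummy-coded multiple linear regression for volume change
#'
#' Fits an ordinary least-squares model of a per-patient response on
#' indicator-coded covariates: female gender, reposited disc (DR group),
#' age band 10-18, and unilateral diagnosis, each coded 1 for the named
#' level.  Returns the coefficient table with 95% confidence intervals.
#'
#' @param table Per-patient data frame with columns `gender` ("female"/
#'   "male"), `group` ("DD"/"DR"), `age_band` ("10-18"/"19-25"),
#'   `diagnosis` ("unilateral"/"bilateral") and the response column.
#' @param response Name of the response column (default
#'   `"volume_change"`).
#' @param conf_level Confidence level.
#' @return A tibble with columns `term`, `b`, `se`, `ci_low`, `ci_high`,
#'   `t`, `p`.
#' @export
ols_dummy_regression <- function(table, response = "volume_change",
                                 conf_level = 0.95) {
  df <- as.data.frame(table)
  y <- df[[response]]
  X <- cbind(`Intercept` = 1,
             `Gender (Female)` = as.numeric(tolower(df$gender) == "female"),
             `Disc position (Reposited)` = as.numeric(df$group == "DR"),
             `Age (10-18y)` = as.numeric(df$age_band == "10-18"),
             `TMJ diagnosis (Unilateral)` =
               as.numeric(tolower(df$diagnosis) == "unilateral"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("ols_dummy_regression: rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  n <- length(y); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  b <- fit$coefficients
  tval <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
  pval <- 2 * stats::pt(-abs(tval), n - p)
  tq <- stats::qt(1 - (1 - conf_level) / 2, n - p)
  tibble::tibble(term = colnames(X), b = unname(b), se = se,
                 ci_low = unname(b) - tq * se, ci_high = unname(b) + tq * se,
                 t = unname(tval), p = unname(pval))
}

#' Sum bilateral condylar measurements per patient
#'
#' The bilateral coupled-joint analysis sums right and left condylar values
#' per patient at each timepoint and forms T1 - T0 changes of the sums.
#' Every patient must have both sides at both timepoints (unilateral patients
#' still have two condyles).
#'
#' @param table Per-condyle measurement table (one row per condyle per
#'   timepoint) with columns `patient_id`, `side`, `timepoint`, `volume`,
#'   and the seven height columns `h_i`, `h_o`, `h_a`, `h_p`, `h_pi`,
#'   `h_po`, `h_up`.
#' @return A per-patient tibble with summed `volume`/heights at T0 and T1
#'   plus `*_change` columns, carrying over patient-level metadata.
#' @export
sum_bilateral <- function(table) {
  df <- tibble::as_tibble(table)
  meas_cols <- intersect(c("volume", "h_i", "h_o", "h_a", "h_p", "h_pi",
                           "h_po", "h_up"), names(df))
  chk <- dplyr::count(df, .data$patient_id, .data$timepoint)
  bad <- chk$patient_id[chk$n != 2L]
  if (length(bad)) {
    stop("sum_bilateral: patients without exactly two sides per timepoint: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  meta_cols <- intersect(c("group", "gender", "age_band", "diagnosis"),
                         names(df))
  summed <- df |>
    dplyr::group_by(.data$patient_id, .data$timepoint) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(meas_cols), sum),
                     dplyr::across(dplyr::all_of(meta_cols), dplyr::first),
                     .groups = "drop")
  t0 <- dplyr::filter(summed, .data$timepoint == "T0")
  t1 <- dplyr::filter(summed, .data$timepoint == "T1")
  joined <- dplyr::inner_join(
    t0, t1[, c("patient_id", meas_cols)],
    by = "patient_id", suffix = c("_t0", "_t1"))
  for (mc in meas_cols) {
    joined[[paste0(mc, "_change")]] <-
      joined[[paste0(mc, "_t1")]] - joined[[paste0(mc, "_t0")]]
  }
  joined$timepoint <- NULL
  joined
}

#' Compare condylar asymmetry measures by disc-displacement direction
#'
#' Per-joint baseline (T0) rows labelled with the disc-displacement direction
#' are split into anteromedial and anterolateral groups; `d_io` and `d_pipo`
#' are summarized (mean, SD, n) per group and compared with a two-tailed
#' unpaired t test.
#'
#' @param table Per-joint table with columns `disc_direction`
#'   (`"anteromedial"` / `"anterolateral"`; other labels ignored), `d_io`,
#'   `d_pipo`, and optionally `timepoint` (filtered to `"T0"`).
#' @param variant t-test variant (default pooled).
#' @return List with `summary` tibble and `tests` (per-measure t results).
#' @export
directional_resorption_analysis <- function(table, variant = "pooled") {
  df <- tibble::as_tibble(table)
  if ("timepoint" %in% names(df)) df <- df[df$timepoint == "T0", ]
  df <- df[df$disc_direction %in% c("anteromedial", "anterolateral"), ]
  groups <- split(df, df$disc_direction)
  for (g in c("anteromedial", "anterolateral")) {
    if (is.null(groups[[g]]) || nrow(groups[[g]]) < 2) {
      stop("directional_resorption_analysis: group '", g, "' has n < 2",
           call. = FALSE)
    }
  }
  summarize_measure <- function(meas) {
    gs <- c("anteromedial", "anterolateral")
    tibble::tibble(
      disc_direction = gs,
      measure = rep(meas, 2),
      n = vapply(gs, function(g) nrow(groups[[g]]), integer(1),
                 USE.NAMES = FALSE),
      mean = vapply(gs, function(g) mean(groups[[g]][[meas]]), numeric(1),
                    USE.NAMES = FALSE),
      sd = vapply(gs, function(g) stats::sd(groups[[g]][[meas]]),
                  numeric(1), USE.NAMES = FALSE))
  }
  tests <- lapply(c(d_io = "d_io", d_pipo = "d_pipo"), function(m) {
    unpaired_t(groups$anteromedial[[m]], groups$anterolateral[[m]],
               variant = variant)
  })
  list(summary = dplyr::bind_rows(summarize_measure("d_io"),
                                  summarize_measure("d_pipo")),
       tests = tests)
}

#' Proportion of affected joints with a medial/lateral displacement component
#'
#' The denominator is the number of affected joints implied by the diagnosis
#' counts (one joint per unilateral patient, two per bilateral patient); the
#' numerator is the count of joints whose anterior displacement has a medial
#' or lateral component.
#'
#' @param n_unilateral,n_bilateral Patient counts by diagnosis.
#' @param n_anteromedial,n_anterolateral Joint counts by displacement
#'   direction.
#' @return List with `affected_joints`, `directional_joints`,
#'   `percent` (0-100 scale).
#' @export
directional_displacement_proportion <- function(n_unilateral, n_bilateral,
                                                n_anteromedial,
                                                n_anterolateral) {
  denom <- n_unilateral + 2L * n_bilateral
  num <- n_anteromedial + n_anterolateral
  list(affected_joints = denom, directional_joints = num,
       percent = 100 * num / denom)
}

#' Demographic percentages from cohort counts
#'
#' @param table Per-patient table with `gender` and `age_band` columns (one
#'   row per patient).
#' @return List with `percent_female` and `percent_age_10_18` (0-100 scale).
#' @export
demographic_percentages <- function(table) {
  df <- tibble::as_tibble(table)
  list(percent_female = 100 * mean(tolower(df$gender) == "female"),
       percent_age_10_18 = 100 * mean(df$age_band == "10-18"))
}
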