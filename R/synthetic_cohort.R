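# Measurement-level and mesh-level cohort simulation.  Defaults are sized to
# the scale of published TMJ disc-displacement cohorts: summed bilateral T0
# volumes ~2100-3400 mm^3, group volume-change medians ~30 (untreated) vs
# ~280 mm^3 (disc repositioned), right-skewed change distributions, and
# direction-dependent baseline asymmetry of the posteromedial/posterolateral
# height difference.

# Skewed sampler parameterized by median and quartiles: a two-piece (split)
# normal whose lower and upper half-scales are matched to (median - q25) and
# (q75 - median).  Median and both quartiles are reproduced exactly, the
# median differs from the mean whenever the IQR is asymmetric, and both
# tails stay Gaussian (finite moments at any asymmetry).
rskewed <- function(n, median, q25, q75) {
  upper <- q75 - median
  lower <- median - q25
  if (upper <= 0 || lower <= 0) {
    return(stats::rnorm(n, median, (q75 - q25) / 1.349))
  }
  z75 <- stats::qnorm(0.75)
  u <- stats::runif(n)
  z <- stats::qnorm(u)
  scale <- ifelse(u >= 0.5, upper / z75, lower / z75)
  median + scale * z
}

#' Specify a simulated two-group cohort
#'
#' Distribution defaults echo the scale of the untreated (DD) versus
#' disc-repositioned (DR) randomized comparison this package analyzes; all
#' are overridable, and a spec with identical group parameters gives a null
#' cohort for calibration.
#'
#' @param n_per_group Patients per group.
#' @param seed Simulation seed.
#' @param volume_t0 List `median`, `q25`, `q75` of summed baseline volume
#'   (mm^3).
#' @param volume_change Per-group lists (`DD`, `DR`) of `median`, `q25`,
#'   `q75` of summed volume change (mm^3).
#' @param height_change_medians Per-group named vectors (points i, o, a, p,
#'   pi, po, up) of summed height-change medians (mm).
#' @param height_change_sd SD of summed height changes (mm).
#' @param height_t0_means Per-side baseline height means (mm), named.
#' @param height_t0_sd Per-side baseline height SD (mm).
#' @param direction_effect Extra posteromedial height deficit of
#'   anterolaterally displaced joints at baseline (mm).
#' @param cephalo_change Per-group lists of `me`, `anb`, `pn` change
#'   medians/IQRs.
#' @param prop_female,prop_age_10_18,prop_unilateral Cohort mix.
#' @param direction_mix Probabilities of `anteromedial`, `anterolateral`,
#'   `pure_anterior` displacement for affected joints.
#' @param rater_noise_sd Measurement noise SD for rater simulation (mm^3 or
#'   mm depending on measure).
#' @return Object of class `condylo_cohort_spec`.
#' @export
cohort_spec <- function(
    n_per_group = 30L,
    seed = 1L,
    volume_t0 = list(median = 2600, q25 = 2150, q75 = 3240),
    volume_change = list(
      DD = list(median = 29.5, q25 = -138.4, q75 = 93.8),
      DR = list(median = 279.6, q25 = 149.5, q75 = 434.1)),
    height_change_medians = list(
      DD = c(i = -0.040, o = -1.000, a = 0.145, p = 0.560, pi = 0.705,
             po = 0.370, up = 0.175),
      DR = c(i = 1.020, o = 0.425, a = 0.870, p = 1.230, pi = 1.595,
             po = 1.330, up = 0.940)),
    height_change_sd = 1.6,
    height_t0_means = c(i = 10, o = 7.8, a = 6, p = 6, pi = 5.8, po = 6,
                        up = 13),
    height_t0_sd = 1.5,
    direction_effect = 0.92,
    cephalo_change = list(
      DD = list(me = c(0.975, 0.328, 1.920), anb = c(0.015, -1.078, 1.005),
                pn = c(3.945, -1.233, 5.580)),
      DR = list(me = c(-0.515, -1.415, 0.108), anb = c(-0.400, -1.883, 0.153),
                pn = c(-0.145, -4.760, 3.300))),
    prop_female = 0.9,
    prop_age_10_18 = 0.65,
    prop_unilateral = 34 / 60,
    direction_mix = c(anteromedial = 23 / 86, anterolateral = 18 / 86,
                      pure_anterior = 45 / 86),
    rater_noise_sd = 0.5) {
  if (n_per_group < 2) stop("cohort_spec: need n >= 2 per group",
                            call. = FALSE)
  structure(as.list(environment()), class = "condylo_cohort_spec")
}

point_names <- c("i", "o", "a", "p", "pi", "po", "up")

#' Simulate a measurement-level or mesh-level cohort
#'
#' In measurement-level mode (default) per-patient summed values and their
#' per-side split are drawn directly from the spec distributions, which is
#' fast enough for repeated calibration runs.  In mesh-level mode a synthetic
#' condyle mesh pair (baseline and follow-up under a group-specific
#' remodeling field) is generated per joint and the real geometry pipeline
#' measures it; this mode emits one condyle per patient and is intended for
#' end-to-end validation at reduced resolution.
#'
#' A ledger of ground-truth draws is attached as `attr(table, "ledger")` for
#' recovery tests.
#'
#' @param spec A `condylo_cohort_spec`.
#' @param mesh_level Run the geometry pipeline on generated meshes.
#' @param subdivision Mesh resolution for mesh-level mode.
#' @param dr_field,dd_field Mean regional apposition amplitudes (mm) for the
#'   two groups in mesh-level mode.
#' @param amplitude_sd Between-patient SD of the regional amplitudes (mm).
#' @param return_meshes Also return the generated meshes (mesh-level mode).
#' @return A tibble of per-condyle, per-timepoint measurement rows with the
#'   ground-truth ledger attached.
#' @export
simulate_cohort <- function(spec, mesh_level = FALSE, subdivision = 3L,
                            dr_field = c(posterolateral = 1.4, lateral = 1.0,
                                         posterior = 0.9, superior = 2.0),
                            dd_field = c(posterolateral = 0.15,
                                         lateral = 0.1, superior = 0.2),
                            amplitude_sd = 0.25,
                            return_meshes = FALSE) {
  stopifnot(inherits(spec, "condylo_cohort_spec"))
  set.seed(spec$seed)
  if (mesh_level) {
    return(simulate_cohort_mesh(spec, subdivision, dr_field, dd_field,
                                amplitude_sd, return_meshes))
  }
  n <- spec$n_per_group
  np <- 2L * n
  group <- rep(c("DD", "DR"), each = n)
  pid <- sprintf("P%03d", seq_len(np))
  gender <- ifelse(stats::runif(np) < spec$prop_female, "female", "male")
  age_band <- ifelse(stats::runif(np) < spec$prop_age_10_18, "10-18",
                     "19-25")
  diagnosis <- ifelse(stats::runif(np) < spec$prop_unilateral, "unilateral",
                      "bilateral")
  affected_side <- sample(c("left", "right"), np, replace = TRUE)

  vt0 <- rskewed(np, spec$volume_t0$median, spec$volume_t0$q25,
                 spec$volume_t0$q75)
  dv <- numeric(np)
  for (g in c("DD", "DR")) {
    vc <- spec$volume_change[[g]]
    idx <- group == g
    dv[idx] <- rskewed(sum(idx), vc$median, vc$q25, vc$q75)
  }
  f_side <- pmin(0.6, pmax(0.4, stats::rnorm(np, 0.5, 0.02)))

  # per-patient summed height changes, 7 columns in point order
  dh <- matrix(0, np, 7, dimnames = list(NULL, point_names))
  for (g in c("DD", "DR")) {
    idx <- which(group == g)
    med <- spec$height_change_medians[[g]][point_names]
    dh[idx, ] <- matrix(stats::rnorm(length(idx) * 7,
                                     rep(med, each = length(idx)),
                                     spec$height_change_sd),
                        length(idx), 7)
  }

  ceph_t0 <- cbind(me = abs(stats::rnorm(np, 2, 1.2)),
                   anb = stats::rnorm(np, 3, 1.8),
                   pn = abs(stats::rnorm(np, 3, 1.8)))
  d_ceph <- matrix(0, np, 3, dimnames = list(NULL, c("me", "anb", "pn")))
  for (g in c("DD", "DR")) {
    idx <- which(group == g)
    cc <- spec$cephalo_change[[g]]
    for (m in c("me", "anb", "pn")) {
      d_ceph[idx, m] <- rskewed(length(idx), cc[[m]][1], cc[[m]][2],
                                cc[[m]][3])
    }
  }

  # expand to one row per (patient, side, timepoint)
  side_of <- rep(c("right", "left"), each = np)
  pi2 <- rep(seq_len(np), 2L)          # patient index per (patient, side)
  frac <- ifelse(side_of == "right", f_side[pi2], 1 - f_side[pi2])
  status <- ifelse(diagnosis[pi2] == "bilateral" |
                     side_of == affected_side[pi2], "affected", "normal")
  direction <- rep("none", 2L * np)
  aff <- which(status == "affected")
  direction[aff] <- sample(names(spec$direction_mix), length(aff),
                           replace = TRUE, prob = spec$direction_mix)
  h_t0 <- matrix(stats::rnorm(2 * np * 7,
                              rep(spec$height_t0_means[point_names],
                                  each = 2 * np),
                              spec$height_t0_sd),
                 2 * np, 7, dimnames = list(NULL, point_names))
  h_t0[direction == "anterolateral", "pi"] <-
    h_t0[direction == "anterolateral", "pi"] - spec$direction_effect
  h_t1 <- h_t0 + dh[pi2, , drop = FALSE] * frac

  one_tp <- function(tp) {
    h <- if (tp == "T0") h_t0 else h_t1
    vol <- if (tp == "T0") vt0[pi2] * frac else (vt0 + dv)[pi2] * frac
    ceph <- if (tp == "T0") ceph_t0[pi2, , drop = FALSE] else
      (ceph_t0 + d_ceph)[pi2, , drop = FALSE]
    tibble::tibble(
      patient_id = pid[pi2], group = group[pi2], gender = gender[pi2],
      age_band = age_band[pi2], diagnosis = diagnosis[pi2], side = side_of,
      joint_status = status, timepoint = tp, volume = vol,
      h_i = h[, "i"], h_o = h[, "o"], h_a = h[, "a"], h_p = h[, "p"],
      h_pi = h[, "pi"], h_po = h[, "po"], h_up = h[, "up"],
      d_io = h[, "i"] - h[, "o"], d_pipo = h[, "pi"] - h[, "po"],
      disc_direction = direction,
      me = ceph[, "me"], anb = ceph[, "anb"], pn = ceph[, "pn"])
  }
  out <- dplyr::bind_rows(one_tp("T0"), one_tp("T1"))
  out <- dplyr::arrange(out, .data$patient_id, .data$side, .data$timepoint)
  ledger <- tibble::tibble(patient_id = pid, group = group,
                           volume_t0 = vt0, volume_change = dv)
  for (pt in point_names) ledger[[paste0("dh_", pt)]] <- dh[, pt]
  attr(out, "ledger") <- ledger
  out
}

simulate_cohort_mesh <- function(spec, subdivision, dr_field, dd_field,
                                 amplitude_sd, return_meshes) {
  n <- spec$n_per_group
  groups <- rep(c("DD", "DR"), each = n)
  rows <- list()
  ledger <- list()
  meshes <- list()
  for (k in seq_along(groups)) {
    g <- groups[k]
    pid <- sprintf("P%03d", k)
    gender <- if (stats::runif(1) < spec$prop_female) "female" else "male"
    age_band <- if (stats::runif(1) < spec$prop_age_10_18) "10-18" else "19-25"
    size <- stats::rnorm(1, 1, 0.04)
    params <- condyle_params(head_ml = 7 * size, head_ap = 5.5 * size,
                             head_si = 6.5 * size, neck_radius = 5.5 * size,
                             neck_length = 5 * size,
                             inflection_height = 6 * size,
                             side = "right", subdivision = subdivision,
                             seed = spec$seed + k)
    gen <- generate_condyle(params)
    base_amp <- if (g == "DR") dr_field else dd_field
    amp <- stats::rnorm(length(base_amp), base_amp, amplitude_sd)
    amp <- pmax(pmin(amp, 5), -5)
    names(amp) <- names(base_amp)
    field <- remodeling_field(as.list(amp), smoothness = 3)

    m0 <- measure_condyle(gen$mesh, gen$landmarks, side = "right")
    mesh_t1 <- apply_remodeling(gen$mesh, field, m0$frame,
                                seed = spec$seed + 10000L + k,
                                growth = Inf)
    m1 <- measure_condyle(mesh_t1, gen$landmarks, side = "right")

    ledger[[k]] <- tibble::tibble(
      patient_id = pid, group = g,
      volume_t0_analytic = gen$ledger$block_volume,
      volume_t0_measured = m0$volume,
      mean_edge = gen$ledger$mean_edge,
      !!!stats::setNames(as.list(amp), paste0("amp_", names(amp))))
    if (return_meshes) {
      meshes[[pid]] <- list(T0 = gen$mesh, T1 = mesh_t1,
                            landmarks = gen$landmarks)
    }
    for (tp in c("T0", "T1")) {
      m <- if (tp == "T0") m0 else m1
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, group = g, gender = gender, age_band = age_band,
        diagnosis = "bilateral", side = "right", joint_status = "affected",
        timepoint = tp, volume = m$volume,
        h_i = m$heights[["i"]], h_o = m$heights[["o"]],
        h_a = m$heights[["a"]], h_p = m$heights[["p"]],
        h_pi = m$heights[["pi"]], h_po = m$heights[["po"]],
        h_up = m$heights[["up"]],
        d_io = m$d_io, d_pipo = m$d_pipo,
        disc_direction = "pure_anterior",
        me = NA_real_, anb = NA_real_, pn = NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ledger") <- dplyr::bind_rows(ledger)
  if (return_meshes) attr(out, "meshes") <- meshes
  out
}

#' Simulate two raters re-measuring a set of true values
#'
#' Each rater's column is the true measurement plus independent Gaussian
#' noise, supporting inter-rater agreement (ICC) calibration.
#'
#' @param values Numeric vector of true measurements.
#' @param noise_sd Rater noise SD.
#' @param seed Seed.
#' @param n_raters Number of raters (default 2).
#' @return Numeric matrix, subjects x raters.
#' @export
simulate_raters <- function(values, noise_sd, seed = 1L, n_raters = 2L) {
  if (noise_sd < 0) stop("simulate_raters: noise_sd must be >= 0",
                         call. = FALSE)
  set.seed(seed)
  values <- as.numeric(values)
  m <- vapply(seq_len(n_raters), function(j) {
    values + stats::rnorm(length(values), sd = noise_sd)
  }, numeric(length(values)))
  colnames(m) <- paste0("rater", seq_len(n_raters))
  m
}
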