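# End-to-end orchestration: per-patient measurement (osteotomy plane, block
# volume, seven heights, cephalometrics) and the cohort analysis battery
# mirroring the result-table layout of a two-group disc-displacement trial.

#' Measure one condyle mesh against a landmark set
#'
#' Builds the Frankfort plane from the porions and orbitale (superior side
#' declared by the crista galli), the osteotomy plane C through the
#' side-specific sigmoid-notch point, the anatomical frame, cuts and caps
#' the condylar block, and assembles the seven landmark heights.
#'
#' @param mesh Watertight `condylo_mesh` of the hemimandible or condyle.
#' @param landmarks Named landmark list (see [read_landmarks()]).
#' @param side `"left"` or `"right"`.
#' @param cap_exclusion,spacing Passed to [assemble_seven()].
#' @return List with `volume`, `heights` (named, mm), `d_io`, `d_pipo`,
#'   `block`, `frame`, `seven`, `plane_c`.
#' @export
measure_condyle <- function(mesh, landmarks, side,
                            cap_exclusion = cap_exclusion_default,
                            spacing = 0.1) {
  side <- match.arg(side, c("left", "right"))
  require_landmarks(landmarks, c("porion_l", "porion_r", "orbitale",
                                 "crista_galli",
                                 paste0("s_", substr(side, 1, 1))))
  sup <- landmarks$crista_galli
  fh <- fit_frankfort_plane(landmarks$porion_l, landmarks$porion_r,
                            landmarks$orbitale, sup)
  s <- landmarks[[paste0("s_", substr(side, 1, 1))]]
  plane_c <- build_cut_plane(fh, s, sup)
  frame <- build_frame(plane_c, landmarks$porion_l, landmarks$porion_r,
                       landmarks$orbitale, side)
  block <- cut_block(mesh, plane_c, frame)
  seven <- assemble_seven(block, cap_exclusion, spacing)
  list(volume = block$volume, heights = seven$heights,
       d_io = seven$d_io, d_pipo = seven$d_pipo,
       block = block, frame = frame, seven = seven, plane_c = plane_c)
}

#' Measure a patient (one or both sides, one timepoint)
#'
#' @param meshes Named list of meshes, names in `c("left", "right")`.
#' @param landmarks Named landmark list for this patient/timepoint.
#' @param timepoint `"T0"` or `"T1"`.
#' @param metadata Named list merged into every output row (e.g.
#'   `patient_id`, `group`, `gender`, `age_band`, `diagnosis`,
#'   `disc_direction` per side as a named list).
#' @param cap_exclusion,spacing Passed through to the landmark search.
#' @return A tibble with one row per condyle, carrying volume, the seven
#'   heights, `d_io`, `d_pipo`, and cephalometric indices when the full
#'   cephalometric landmark set is present.
#' @export
measure_patient <- function(meshes, landmarks, timepoint = "T0",
                            metadata = list(),
                            cap_exclusion = cap_exclusion_default,
                            spacing = 0.1) {
  stopifnot(length(meshes) >= 1, !is.null(names(meshes)))
  ceph <- tryCatch({
    idx <- cephalo_indices(cephalo_from_landmarks(landmarks))
    list(me = idx$me, anb = idx$anb, pn = idx$pn)
  }, error = function(e) list(me = NA_real_, anb = NA_real_, pn = NA_real_))
  rows <- lapply(names(meshes), function(side) {
    m <- tryCatch(
      measure_condyle(meshes[[side]], landmarks, side, cap_exclusion,
                      spacing),
      error = function(e) {
        stop(sprintf("measure_patient [%s/%s/%s]: %s",
                     metadata$patient_id %||% "?", side, timepoint,
                     conditionMessage(e)), call. = FALSE)
      })
    dirs <- metadata$disc_direction
    dir <- if (is.list(dirs) || length(dirs) > 1) {
      dirs[[side]] %||% "none"
    } else {
      dirs %||% "none"
    }
    tibble::tibble(
      patient_id = metadata$patient_id %||% NA_character_,
      group = metadata$group %||% NA_character_,
      gender = metadata$gender %||% NA_character_,
      age_band = metadata$age_band %||% NA_character_,
      diagnosis = metadata$diagnosis %||% NA_character_,
      side = side,
      joint_status = (metadata$joint_status %||% list())[[side]] %||%
        NA_character_,
      timepoint = timepoint,
      volume = m$volume,
      h_i = m$heights[["i"]], h_o = m$heights[["o"]], h_a = m$heights[["a"]],
      h_p = m$heights[["p"]], h_pi = m$heights[["pi"]],
      h_po = m$heights[["po"]], h_up = m$heights[["up"]],
      d_io = m$d_io, d_pipo = m$d_pipo,
      disc_direction = dir,
      me = ceph$me, anb = ceph$anb, pn = ceph$pn)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

group_summary_mwu <- function(per_patient, value_col) {
  by_group <- split(per_patient[[value_col]], per_patient$group)
  summ <- lapply(by_group, quartiles)
  test <- if (length(by_group) == 2) {
    mann_whitney(by_group[[1]], by_group[[2]], mode = "auto")
  } else NULL
  tab <- dplyr::bind_rows(lapply(names(summ), function(g) {
    s <- summ[[g]]
    tibble::tibble(group = g, n = s$n, median = s$median, q25 = s$q25,
                   q75 = s$q75, mean = s$mean, sd = s$sd)
  }))
  list(summary = tab, p_value = if (!is.null(test)) test$p_value else NA_real_,
       test = test)
}

#' Run the full cohort analysis battery
#'
#' From a per-condyle, per-timepoint measurement table this produces the
#' standard result set of a two-group condylar remodeling trial:
#' summed-volume baseline and change comparisons, the unilateral per-joint
#' analysis, a dummy-coded regression of volume change on cohort covariates,
#' cephalometric index changes, per-point height-change comparisons, the
#' baseline asymmetry comparison by disc-displacement direction, and cohort
#' proportions (gender, age band, directional displacement among affected
#' joints).  Between-group tests are two-tailed Mann-Whitney U except the
#' directional comparison, which is an unpaired t test; no multiplicity
#' correction is applied.
#'
#' @param table Measurement table (see [simulate_cohort()] for the schema).
#' @param mwu_mode Mann-Whitney mode (`"auto"`, `"exact"`, `"asymptotic"`).
#' @return Named list of result tables.
#' @export
run_full_analysis <- function(table, mwu_mode = "auto") {
  df <- tibble::as_tibble(table)
  needed <- c("patient_id", "group", "side", "timepoint", "volume")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("run_full_analysis: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bilateral <- nrow(dplyr::count(df, .data$patient_id, .data$timepoint)) ==
    0 || all(dplyr::count(df, .data$patient_id, .data$timepoint)$n == 2L)
  per_patient <- if (bilateral) {
    sum_bilateral(df)
  } else {
    # single-condyle rows: per-joint values stand in for the per-patient sums
    t0 <- df[df$timepoint == "T0", ]
    t1 <- df[df$timepoint == "T1", ]
    j <- dplyr::inner_join(
      t0, t1[, c("patient_id", "side", "volume",
                 paste0("h_", point_names))],
      by = c("patient_id", "side"), suffix = c("_t0", "_t1"))
    for (mc in c("volume", paste0("h_", point_names))) {
      j[[paste0(mc, "_change")]] <- j[[paste0(mc, "_t1")]] -
        j[[paste0(mc, "_t0")]]
    }
    j
  }

  out <- list()
  out$volume_t0 <- group_summary_mwu(per_patient, "volume_t0")
  out$volume_change <- group_summary_mwu(per_patient, "volume_change")

  # unilateral per-joint analysis (normal vs affected condyle per group)
  uni <- df[df$diagnosis == "unilateral" & !is.na(df$diagnosis), ]
  if (nrow(uni) > 0 && "joint_status" %in% names(uni)) {
    t0 <- uni[uni$timepoint == "T0", ]
    t1 <- uni[uni$timepoint == "T1", ]
    jj <- dplyr::inner_join(t0, t1[, c("patient_id", "side", "volume")],
                            by = c("patient_id", "side"),
                            suffix = c("_t0", "_t1"))
    jj$volume_change <- jj$volume_t1 - jj$volume_t0
    out$unilateral <- lapply(split(jj, jj$joint_status), function(sub) {
      if (length(unique(sub$group)) == 2) {
        group_summary_mwu(sub, "volume_change")
      } else NULL
    })
  }

  if (all(c("gender", "age_band", "diagnosis") %in% names(per_patient)) &&
      !anyNA(per_patient$gender)) {
    out$regression <- tryCatch(
      ols_dummy_regression(per_patient, response = "volume_change"),
      error = function(e) NULL)
  }

  if (all(c("me", "anb", "pn") %in% names(df)) && !all(is.na(df$me))) {
    ceph0 <- df[df$timepoint == "T0" & !duplicated(df$patient_id), ]
    ceph1 <- df[df$timepoint == "T1", ]
    ceph1 <- ceph1[!duplicated(ceph1$patient_id), ]
    cj <- dplyr::inner_join(ceph0[, c("patient_id", "group", "me", "anb", "pn")],
                            ceph1[, c("patient_id", "me", "anb", "pn")],
                            by = "patient_id", suffix = c("_t0", "_t1"))
    out$cephalo_change <- lapply(
      stats::setNames(nm = c("me", "anb", "pn")), function(m) {
        cj$chg <- cj[[paste0(m, "_t1")]] - cj[[paste0(m, "_t0")]]
        group_summary_mwu(cj, "chg")
      })
  }

  hcols <- paste0("h_", point_names, "_change")
  if (all(hcols %in% names(per_patient))) {
    out$height_change <- lapply(
      stats::setNames(hcols, point_names), function(hc) {
        group_summary_mwu(per_patient, hc)
      })
  }

  if ("disc_direction" %in% names(df) &&
      sum(df$timepoint == "T0" &
            df$disc_direction %in% c("anteromedial", "anterolateral")) >= 4) {
    out$directional <- tryCatch(
      directional_resorption_analysis(df), error = function(e) NULL)
  }

  pat <- df[df$timepoint == "T0" & !duplicated(df$patient_id), ]
  out$demographics <- demographic_percentages(pat)
  if (all(c("joint_status", "disc_direction") %in% names(df))) {
    t0j <- df[df$timepoint == "T0" & df$joint_status %in% "affected", ]
    if (nrow(t0j) > 0) {
      out$directional_proportion <- list(
        affected_joints = nrow(t0j),
        directional_joints = sum(t0j$disc_direction %in%
                                   c("anteromedial", "anterolateral")),
        percent = 100 * mean(t0j$disc_direction %in%
                               c("anteromedial", "anterolateral")))
    }
  }
  out
}

#' Write analysis results to disk
#'
#' Summary tables go to CSV (full precision); the whole result object to a
#' JSON file.
#'
#' @param results Output of [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_analysis <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- list()
  grab <- function(x, name) {
    if (is.data.frame(x)) {
      return(invisible(NULL))
    } else if (is.list(x) && "summary" %in% names(x)) {
      s <- x$summary
      s$p_value <- x$p_value
      flat[[name]] <<- s
    } else if (is.list(x)) {
      for (nm in names(x)) if (!is.null(x[[nm]])) {
        grab(x[[nm]], paste0(name, "_", nm))
      }
    }
  }
  for (nm in names(results)) grab(results[[nm]], nm)
  for (nm in names(flat)) {
    utils::write.csv(flat[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(results$regression)) {
    utils::write.csv(results$regression, file.path(dir, "regression.csv"),
                     row.names = FALSE)
  }
  strip <- rapply(results, function(x) x, how = "replace")
  jsonlite::write_json(strip, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
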