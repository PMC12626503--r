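# Synthetic condyle and cohort generator.  Condyles are surfaces of
# revolution with elliptical cross-sections: an ellipsoidal head blended C1
# into a cosh-profile neck whose waist (the concave head-neck inflection) is
# placed analytically at a stated height above the cut plane, plus a
# flaring sub-notch stub below the plane.  Remodeling is modelled as smooth
# region-weighted displacement along outward vertex normals.  Cohorts can be
# simulated at the measurement level (fast, distributional) or at the mesh
# level (the full geometry pipeline runs on every synthetic joint).

#' Parameters of a synthetic condyle
#'
#' @param head_ml,head_ap,head_si Head semi-axes along the mediolateral,
#'   anteroposterior and superoinferior axes (mm).
#' @param neck_radius Mediolateral waist semi-width of the neck (mm); must
#'   satisfy `head_ml > neck_radius > 0` and exceed the head profile value
#'   at the inflection height.
#' @param neck_length Distance from the inflection height to the head centre
#'   (mm).  Zero gives a pure (half-)ellipsoid: the head centred at the
#'   inflection height with no neck.
#' @param inflection_height Height of the concave head-neck inflection above
#'   the cut plane (mm); must exceed the cap exclusion band.
#' @param head_tilt Rotation of the condyle about the anteroposterior axis,
#'   degrees (0 = upright).
#' @param side `"left"` or `"right"`.
#' @param subdivision Mesh resolution level; azimuthal vertex count is
#'   `8 * 2^subdivision`.
#' @param stub_depth Depth of the sub-notch stub below the cut plane (mm).
#' @param noise_amp Amplitude of smooth pseudo-random surface perturbation
#'   (mm, default 0 = perfectly symmetric fixture).
#' @param seed Seed for the surface perturbation.
#' @return Object of class `condylo_params`.
#' @export
condyle_params <- function(head_ml = 7, head_ap = 5.5, head_si = 6.5,
                           neck_radius = 5.5, neck_length = 5,
                           inflection_height = 6, head_tilt = 0,
                           side = "right", subdivision = 3L,
                           stub_depth = 4, noise_amp = 0, seed = 1L) {
  side <- match.arg(side, c("left", "right"))
  if (min(head_ml, head_ap, head_si) <= 0) {
    stop("condyle_params: head semi-axes must be positive", call. = FALSE)
  }
  if (neck_length > 0) {
    if (neck_radius <= 0 || neck_radius >= head_ml) {
      stop("condyle_params: need head_ml > neck_radius > 0", call. = FALSE)
    }
    if (inflection_height <= cap_exclusion_default) {
      stop("condyle_params: inflection height must exceed the cap exclusion band",
           call. = FALSE)
    }
  }
  structure(list(head_ml = head_ml, head_ap = head_ap, head_si = head_si,
                 neck_radius = neck_radius, neck_length = neck_length,
                 inflection_height = inflection_height, head_tilt = head_tilt,
                 side = side, subdivision = as.integer(subdivision),
                 stub_depth = stub_depth, noise_amp = noise_amp,
                 seed = as.integer(seed)),
            class = "condylo_params")
}

# Normalized radial profile rho(z) in [0, 1]: ellipse above the C1 join
# height, w * cosh((z - h*) / s) below.  Solves the join height so the waist
# value equals neck_radius / head_ml with continuous value and slope.
condyle_profile <- function(params) {
  c_si <- params$head_si
  h_star <- params$inflection_height
  z0 <- h_star + params$neck_length
  z_top <- z0 + c_si
  if (params$neck_length <= 0) {
    return(list(z0 = z0, z_top = z_top, h_join = -Inf, s = NA, w = NA,
                rho = function(z) {
                  u <- (z - z0) / c_si
                  sqrt(pmax(0, 1 - u^2))
                }))
  }
  w_target <- params$neck_radius / params$head_ml
  ell <- function(z) sqrt(pmax(1e-12, 1 - ((z - z0) / c_si)^2))
  ell_slope <- function(z) (z0 - z) / (c_si^2 * ell(z))
  w_implied <- function(h_j) {
    v <- ell(h_j); vp <- ell_slope(h_j)
    delta <- h_j - h_star
    # solve tanh(delta/s)/s = vp/v for s
    g <- function(s) tanh(delta / s) / s - vp / v
    s <- stats::uniroot(g, c(1e-3, 1e4), tol = 1e-12)$root
    c(w = v / cosh(delta / s), s = s)
  }
  lo <- h_star + 1e-3
  hi <- z0 - 1e-3
  f <- function(h_j) w_implied(h_j)[["w"]] - w_target
  if (f(lo) > 0 || f(hi) < 0) {
    stop("condyle_params: neck_radius incompatible with head/inflection geometry",
         call. = FALSE)
  }
  h_join <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  ws <- w_implied(h_join)
  w <- ws[["w"]]; s <- ws[["s"]]
  # below the waist the neck re-widens toward the ramus with a gentler
  # length-scale (C1 at the waist: value w, slope 0 on both sides), clamped
  # below the head equator so the crest poles stay on the head
  s_low <- 2.5 * s
  rho <- function(z) {
    up <- sqrt(pmax(0, 1 - ((z - z0) / c_si)^2))
    mid <- w * cosh((z - h_star) / s)
    low <- pmin(0.97, w * cosh((z - h_star) / s_low))
    ifelse(z >= h_join, up, ifelse(z >= h_star, mid, low))
  }
  list(z0 = z0, z_top = z_top, h_join = h_join, s = s, w = w, rho = rho)
}

# Analytic block volume above the cut plane: integral of the elliptical
# cross-section area pi * a * b * rho(z)^2 over z in [0, z_top].
profile_block_volume <- function(params, profile = condyle_profile(params)) {
  f <- function(z) pi * params$head_ml * params$head_ap * profile$rho(z)^2
  stats::integrate(f, 0, profile$z_top, rel.tol = 1e-10,
                   subdivisions = 400L)$value
}

#' Generate a synthetic condyle mesh with consistent cranial landmarks
#'
#' Builds the watertight condyle surface in a cranial coordinate system
#' (+x toward the patient's right, +y anterior, +z superior; Frankfort plane
#' at z = 0) and emits a full landmark set: porions, orbitale, per-side
#' sigmoid-notch points `s_l`/`s_r` at the cut-plane height, and a
#' cephalometric set constructed to prescribed ANB/PN/ME values.  Purely
#' deterministic given `params` (the seed only drives the optional surface
#' perturbation).
#'
#' @param params A `condylo_params`.
#' @param cut_height Global z of the cut plane (mm below FH; default -22).
#' @param anb_deg,pn_mm,me_mm Prescribed cephalometric indices for the
#'   emitted landmark set.
#' @return List with `mesh` (`condylo_mesh`), `landmarks` (named list), and
#'   `ledger` (analytic ground truth: block volume above the cut plane, apex
#'   height, inflection height, mean edge length).
#' @export
generate_condyle <- function(params, cut_height = -22, anb_deg = 4,
                             pn_mm = 4, me_mm = 2) {
  prof <- condyle_profile(params)
  n_theta <- 8L * 2L^params$subdivision
  # ring heights: linear in the stub/neck, angle-uniform over the head cap
  target_dz <- 2 * pi * params$head_ml / n_theta
  z_lo <- -params$stub_depth
  z_hi <- min(prof$z_top - 1e-9,
              if (is.finite(prof$h_join)) prof$h_join else prof$z0)
  n_low <- max(4L, ceiling((z_hi - z_lo) / target_dz))
  z_low <- seq(z_lo, z_hi, length.out = n_low + 1L)
  t_lo <- asin(max(-1, min(1, (z_hi - prof$z0) / params$head_si)))
  n_cap <- max(6L, ceiling((pi / 2 - t_lo) * params$head_si / target_dz))
  t_cap <- seq(t_lo, pi / 2, length.out = n_cap + 1L)
  z_cap <- prof$z0 + params$head_si * sin(t_cap)
  z_rings <- c(z_low, z_cap[-1][-n_cap])  # drop duplicate join and apex
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  rho <- prof$rho(z_rings)
  nv_ring <- length(z_rings)
  verts <- matrix(0, nv_ring * n_theta + 2L, 3)
  for (r in seq_len(nv_ring)) {
    idx <- (r - 1L) * n_theta + seq_len(n_theta)
    verts[idx, 1] <- params$head_ml * rho[r] * cos(theta)
    verts[idx, 2] <- params$head_ap * rho[r] * sin(theta)
    verts[idx, 3] <- z_rings[r]
  }
  bottom_c <- nv_ring * n_theta + 1L
  apex <- nv_ring * n_theta + 2L
  verts[bottom_c, ] <- c(0, 0, z_lo)
  verts[apex, ] <- c(0, 0, prof$z_top)

  faces <- matrix(0L, 0, 3)
  band <- function(r) {
    i0 <- (r - 1L) * n_theta
    i1 <- r * n_theta
    a <- i0 + seq_len(n_theta)
    b <- i0 + c(seq_len(n_theta)[-1], 1L)
    c3 <- i1 + seq_len(n_theta)
    d <- i1 + c(seq_len(n_theta)[-1], 1L)
    rbind(cbind(a, b, d), cbind(a, d, c3))
  }
  for (r in seq_len(nv_ring - 1L)) faces <- rbind(faces, band(r))
  top_ring <- (nv_ring - 1L) * n_theta + seq_len(n_theta)
  top_next <- (nv_ring - 1L) * n_theta + c(seq_len(n_theta)[-1], 1L)
  faces <- rbind(faces, cbind(top_ring, top_next, apex))
  bot_ring <- seq_len(n_theta)
  bot_next <- c(seq_len(n_theta)[-1], 1L)
  faces <- rbind(faces, cbind(bot_next, bot_ring, bottom_c))

  # smooth pseudo-random perturbation (low-order spherical harmonics mix)
  if (params$noise_amp > 0) {
    set.seed(params$seed)
    coef <- stats::rnorm(6, sd = params$noise_amp / 2)
    zc <- (verts[, 3] - prof$z0) / max(prof$z_top - z_lo, 1)
    az <- atan2(verts[, 2], verts[, 1])
    bump <- coef[1] * sin(az) + coef[2] * cos(az) +
      coef[3] * sin(2 * az) + coef[4] * cos(2 * az) +
      coef[5] * sin(pi * zc) + coef[6] * cos(pi * zc)
    radial <- sqrt(verts[, 1]^2 + verts[, 2]^2)
    scale <- ifelse(radial > 1e-9, 1 + bump * 0.05, 1)
    verts[, 1] <- verts[, 1] * scale
    verts[, 2] <- verts[, 2] * scale
  }

  if (params$head_tilt != 0) {
    R <- rotation_about(c(0, 1, 0), params$head_tilt * pi / 180)
    verts <- verts %*% t(R)
  }

  # place into cranial coordinates: +x right, +y anterior, +z superior
  mirror <- if (params$side == "right") 1 else -1
  attach_xy <- c(48, -8)
  verts_g <- cbind(mirror * (verts[, 1] + attach_xy[1]),
                   verts[, 2] + attach_xy[2],
                   verts[, 3] + cut_height)
  if (mirror < 0) faces <- faces[, c(1, 3, 2)]
  mesh <- triangle_mesh(verts_g, faces)

  landmarks <- synthetic_landmarks(cut_height = cut_height, anb_deg = anb_deg,
                                   pn_mm = pn_mm, me_mm = me_mm)
  list(mesh = mesh, landmarks = landmarks,
       ledger = list(block_volume = profile_block_volume(params, prof),
                     apex_height = prof$z_top,
                     inflection_height = params$inflection_height,
                     mean_edge = mean_edge_length(mesh)))
}

#' Synthetic cranial/cephalometric landmark set
#'
#' Landmarks in the canonical cranial frame (+x right, +y anterior, +z
#' superior, Frankfort plane z = 0), with the B point constructed so the
#' midsagittal ANB equals `anb_deg`, pogonion placed at `pn_mm` from the
#' nasion vertical, and menton offset `me_mm` from the facial midline.
#'
#' @param cut_height Global z of the per-side sigmoid-notch points (mm).
#' @param anb_deg,pn_mm,me_mm Prescribed index values.
#' @return Named list of landmark points.
#' @export
synthetic_landmarks <- function(cut_height = -22, anb_deg = 4, pn_mm = 4,
                                me_mm = 2) {
  nasion <- c(0, 72, 2)
  a_point <- c(0, 78, -28)
  ra <- a_point - nasion
  # rotate the nasion->A ray about the mediolateral axis; pick the sign that
  # puts B posterior to A (positive ANB convention) for positive anb_deg
  ang <- anb_deg * pi / 180
  dir1 <- drop(rotation_about(c(1, 0, 0), ang) %*% ra)
  dir2 <- drop(rotation_about(c(1, 0, 0), -ang) %*% ra)
  pick <- if (dir1[2] / abs(dir1[3]) < dir2[2] / abs(dir2[3])) dir1 else dir2
  if (anb_deg < 0) pick <- if (identical(pick, dir1)) dir2 else dir1
  # B at the same radius as A from nasion so the angular offset and the
  # anterior/posterior positional sign of ANB always agree
  b_point <- nasion + sqrt(sum(ra^2)) * pick / sqrt(sum(pick^2))
  list(porion_l = c(-60, 0, 0), porion_r = c(60, 0, 0),
       orbitale = c(40, 65, 0),
       s_l = c(-44, 1, cut_height), s_r = c(44, 1, cut_height),
       nasion = nasion, a_point = a_point, b_point = b_point,
       pogonion = c(0, 72 + pn_mm, -70),
       menton = c(me_mm, 70, -78),
       crista_galli = c(0, 45, 15),
       zf_l = c(-48, 38, 8), zf_r = c(48, 38, 8))
}

#' Define a surface remodeling field
#'
#' Regional apposition (+) / resorption (-) amplitudes in mm, applied along
#' outward vertex normals with smooth blending between regions.  Regions are
#' spherical-direction bins around the head centroid at 45-degree
#' boundaries: `superior` (elevation above 45 degrees) and the azimuthal
#' bins `anterior`, `anterolateral`, `lateral`, `posterolateral`,
#' `posterior`, `posteromedial`, `medial`, `anteromedial`.
#'
#' @param ... Named region amplitudes (mm); unnamed regions default to 0.
#' @param smoothness Blending length-scale (mm).
#' @param noise_sd Per-vertex displacement noise SD (mm, default 0).
#' @return Object of class `condylo_field`.
#' @export
remodeling_field <- function(..., smoothness = 3, noise_sd = 0) {
  amp <- c(superior = 0, anterior = 0, anterolateral = 0, lateral = 0,
           posterolateral = 0, posterior = 0, posteromedial = 0,
           medial = 0, anteromedial = 0)
  given <- list(...)
  if (length(given) == 1L && is.null(names(given)) && is.list(given[[1]])) {
    given <- given[[1]]
  }
  for (nm in names(given)) {
    if (!nm %in% names(amp)) {
      stop("remodeling_field: unknown region '", nm, "'", call. = FALSE)
    }
    amp[nm] <- as.numeric(given[[nm]])
  }
  if (any(abs(amp) > 5)) {
    stop("remodeling_field: |amplitude| must be <= 5 mm", call. = FALSE)
  }
  if (smoothness <= 0) stop("remodeling_field: smoothness must be positive",
                            call. = FALSE)
  structure(list(amplitudes = amp, smoothness = smoothness,
                 noise_sd = noise_sd),
            class = "condylo_field")
}

# Area-weighted outward vertex normals of a watertight mesh.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (col in 1:3) {
    for (j in 1:3) {
      acc <- tapply(fn[, col], f[, j], sum)
      vn[as.integer(names(acc)), col] <- vn[as.integer(names(acc)), col] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-12] <- 1
  vn / len
}

#' Apply a remodeling field to a condyle mesh
#'
#' Each vertex above the cut plane is assigned the amplitude of its
#' spherical-direction bin (relative to the head centroid, axes from
#' `frame`), the per-vertex amplitude field is smoothed over the mesh graph
#' at the field's length-scale, tapered to zero at the cut plane (so the
#' below-plane stub and the osteotomy geometry are unchanged), and vertices
#' are displaced along outward normals.  To first order the volume change
#' equals the surface integral of the displacement.
#'
#' @param mesh Watertight `condylo_mesh` of the condyle.
#' @param field A `condylo_field`.
#' @param frame A `condylo_frame` giving the anatomical axes and plane C.
#' @param seed Seed for the optional per-vertex noise.
#' @param taper_height Height band above plane C over which the displacement
#'   ramps from 0 to full (mm).
#' @param growth Superior bias of the displacement direction: 0 (default)
#'   displaces along pure outward normals (a surface offset); positive
#'   values blend the direction toward the superior axis,
#'   `dir = normalize(normal + growth * u_si)`; `Inf` displaces purely
#'   along `u_si`.  A pure offset provably leaves the height of the
#'   head-neck inflection unchanged, so superiorly biased apposition
#'   (emulating growth at the superior condylar cartilage) is what drives
#'   landmark-height dynamics.
#' @return The displaced `condylo_mesh`.
#' @export
apply_remodeling <- function(mesh, field, frame, seed = 1L,
                             taper_height = 1.5, growth = 0) {
  stopifnot(inherits(field, "condylo_field"))
  v <- mesh$vertices
  h <- signed_distance(v, frame$plane_c)
  above <- h > 0
  if (!any(above)) stop("apply_remodeling: no vertices above plane C",
                        call. = FALSE)
  head_c <- colMeans(v[above, , drop = FALSE])
  rel <- sweep(v, 2, head_c)
  si <- drop(rel %*% frame$u_si)
  ml <- drop(rel %*% frame$u_ml)
  ap <- drop(rel %*% frame$u_ap)
  r <- sqrt(si^2 + ml^2 + ap^2)
  r[r < 1e-9] <- 1e-9
  elev <- asin(pmax(-1, pmin(1, si / r)))
  az <- atan2(ml, ap)  # 0 = anterior, +pi/2 = lateral

  # analytic smooth field: periodic linear interpolation between the eight
  # azimuth bin centres, blended with the superior amplitude over elevation
  # 30-60 degrees, and confined to the head (fading out down the neck so the
  # anatomical head-neck waist and the osteotomy region stay intact)
  bins <- c("anterior", "anterolateral", "lateral", "posterolateral",
            "posterior", "posteromedial", "medial", "anteromedial")
  bin_amp <- field$amplitudes[bins]
  pos <- (az %% (2 * pi)) / (pi / 4)      # 0..8, bin centres at integers
  i0 <- floor(pos) %% 8
  frac <- pos - floor(pos)
  az_amp <- bin_amp[i0 + 1] * (1 - frac) + bin_amp[(i0 + 1) %% 8 + 1] * frac
  smoothstep <- function(x) { x <- pmax(0, pmin(1, x)); x * x * (3 - 2 * x) }
  w_sup <- smoothstep((elev - pi / 6) / (pi / 12))         # 30 -> 60 deg
  amp <- az_amp * (1 - w_sup) + field$amplitudes[["superior"]] * w_sup

  if (field$noise_sd > 0) {
    set.seed(seed)
    amp <- amp + stats::rnorm(length(amp), sd = field$noise_sd)
  }
  taper <- pmax(0, pmin(1, h / taper_height))
  disp <- amp * taper
  vn <- vertex_normals(mesh)
  if (is.infinite(growth)) {
    vn <- matrix(frame$u_si, nrow(vn), 3, byrow = TRUE)
  } else if (growth > 0) {
    vg <- vn + matrix(frame$u_si, nrow(vn), 3, byrow = TRUE) * growth
    len <- sqrt(rowSums(vg^2))
    ok <- len > 1e-6
    vn[ok, ] <- vg[ok, ] / len[ok]
  }
  triangle_mesh(v + vn * disp, mesh$faces, validate = FALSE)
}
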