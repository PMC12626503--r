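# Cephalometric deformity/asymmetry indices computed from 3D landmark
# coordinates: ANB (sagittal jaw relationship), PN (pogonion deviation from
# the nasion vertical), ME (menton deviation from the facial midline).  ANB
# is evaluated in midsagittal projection, reproducing the lateral-radiograph
# convention for 3D input.

#' Bundle cephalometric landmarks
#'
#' @param nasion,a_point,b_point,pogonion,menton,crista_galli,zf_left,zf_right
#'   Landmark coordinates (mm).  `zf_*` are the intersections of the
#'   zygomatico-frontal suture with the lateral orbital margin.
#' @param fh Frankfort plane (`condylo_plane`, normal superior).
#' @return Object of class `condylo_cephalo_lm`.
#' @export
cephalo_landmarks <- function(nasion, a_point, b_point, pogonion, menton,
                              crista_galli, zf_left, zf_right, fh) {
  stopifnot(is_plane(fh))
  lm <- list(nasion = point3(nasion), a_point = point3(a_point),
             b_point = point3(b_point), pogonion = point3(pogonion),
             menton = point3(menton), crista_galli = point3(crista_galli),
             zf_left = point3(zf_left), zf_right = point3(zf_right),
             fh = fh)
  if (sqrt(sum((lm$zf_left - lm$zf_right)^2)) < 1e-9) {
    stop("cephalo_landmarks: zf_left and zf_right coincide", call. = FALSE)
  }
  structure(lm, class = "condylo_cephalo_lm")
}

#' Facial midline plane
#'
#' The midsagittal plane through the crista galli whose normal is the
#' in-Frankfort-plane component of the left-to-right zygomatico-frontal
#' vector (the midline extended vertically).
#'
#' @param lm A `condylo_cephalo_lm`.
#' @return A `condylo_plane`.
#' @export
facial_midline <- function(lm) {
  n_fh <- lm$fh$normal
  zf <- lm$zf_right - lm$zf_left
  zf_in <- zf - sum(zf * n_fh) * n_fh
  if (sqrt(sum(zf_in^2)) < 1e-9) {
    stop("facial_midline: zf vector parallel to the Frankfort normal",
         call. = FALSE)
  }
  plane3(lm$crista_galli, zf_in)
}

#' ME: distance from menton to the facial midline
#'
#' @param lm A `condylo_cephalo_lm`.
#' @param signed Return the signed distance (positive toward the right zf
#'   side) instead of the absolute deviation.
#' @return Distance in mm.
#' @export
compute_me <- function(lm, signed = FALSE) {
  d <- signed_distance(lm$menton, facial_midline(lm))
  if (signed) d else abs(d)
}

#' PN: distance from pogonion to the nasion vertical
#'
#' Distance from pogonion to the line through nasion perpendicular to the
#' Frankfort plane, i.e. the norm of the component of (pogonion - nasion)
#' orthogonal to the Frankfort normal.
#'
#' @param lm A `condylo_cephalo_lm`.
#' @return Distance in mm (non-negative).
#' @export
compute_pn <- function(lm) {
  v <- lm$pogonion - lm$nasion
  v_perp <- v - sum(v * lm$fh$normal) * lm$fh$normal
  sqrt(sum(v_perp^2))
}

#' ANB: subspinale-nasion-supramentale angle
#'
#' Nasion, A point and B point are projected onto the midsagittal plane; the
#' angle at nasion between the rays to A and B is returned in degrees, signed
#' positive when the A point lies anterior to the B point (the skeletal
#' Class II direction).
#'
#' @param lm A `condylo_cephalo_lm`.
#' @return Angle in degrees (signed).
#' @export
compute_anb <- function(lm) {
  mid <- facial_midline(lm)
  n_p <- project_to_plane(lm$nasion, mid)
  a_p <- project_to_plane(lm$a_point, mid)
  b_p <- project_to_plane(lm$b_point, mid)
  ra <- a_p - n_p; rb <- b_p - n_p
  la <- sqrt(sum(ra^2)); lb <- sqrt(sum(rb^2))
  if (la < 1e-9 || lb < 1e-9) {
    stop("compute_anb: degenerate ray after midsagittal projection",
         call. = FALSE)
  }
  cosang <- max(-1, min(1, sum(ra * rb) / (la * lb)))
  ang <- acos(cosang) * 180 / pi
  # anterior direction within the midsagittal plane: A point relative to
  # crista galli, orthogonalized against the superior axis
  u_si <- lm$fh$normal
  ap_ref <- lm$a_point - lm$crista_galli
  ap_ref <- ap_ref - sum(ap_ref * mid$normal) * mid$normal
  ap_ref <- ap_ref - sum(ap_ref * u_si) * u_si
  if (sqrt(sum(ap_ref^2)) < 1e-9) return(ang)
  u_ap <- unit3(ap_ref)
  s <- sign(sum((a_p - b_p) * u_ap))
  if (s == 0) s <- 1
  s * ang
}

#' Compute all three cephalometric indices
#'
#' @param lm A `condylo_cephalo_lm`.
#' @param signed_me Report ME signed rather than absolute.
#' @return List with `anb` (degrees), `pn` (mm), `me` (mm).
#' @export
cephalo_indices <- function(lm, signed_me = FALSE) {
  list(anb = compute_anb(lm), pn = compute_pn(lm),
       me = compute_me(lm, signed = signed_me))
}

#' Build a cephalometric landmark bundle from a named landmark list
#'
#' Fits the Frankfort plane from the porions and orbitale (superior side
#' declared by the crista galli unless `superior_ref` is given) and bundles
#' the cephalometric points from a landmark list as returned by
#' [read_landmarks()].
#'
#' @param landmarks Named list of length-3 points.
#' @param superior_ref Optional superior reference point for the Frankfort
#'   normal orientation.
#' @return A `condylo_cephalo_lm`.
#' @export
cephalo_from_landmarks <- function(landmarks, superior_ref = NULL) {
  require_landmarks(landmarks,
                    c("porion_l", "porion_r", "orbitale", "nasion", "a_point",
                      "b_point", "pogonion", "menton", "crista_galli",
                      "zf_l", "zf_r"))
  if (is.null(superior_ref)) superior_ref <- landmarks$crista_galli
  fh <- fit_frankfort_plane(landmarks$porion_l, landmarks$porion_r,
                            landmarks$orbitale, superior_ref)
  cephalo_landmarks(landmarks$nasion, landmarks$a_point, landmarks$b_point,
                    landmarks$pogonion, landmarks$menton,
                    landmarks$crista_galli, landmarks$zf_l, landmarks$zf_r,
                    fh)
}
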