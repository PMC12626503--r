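# Construction of the seven condylar surface landmarks and their heights
# above the osteotomy plane C:
#   i  - innermost (medial) point of the condylar crest
#   o  - outermost (lateral) point
#   up - highest point of the condylar upper edge on plane M
#   a  - lowest edge of the anterior slope on plane N
#   p  - lowest edge of the posterior slope on plane N
#   pi - posterior-slope point on plane N1/N2 closer to i (posteromedial)
#   po - posterior-slope point closer to o (posterolateral)
# "Lowest edge of the slope" is operationalized as the head-neck concave
# curvature inflection on the section contour (first local maximum of
# concavity walking down from the contour apex); a literal lowest point would
# sit on the cut plane at height zero.  Fallback: lowest non-cap point.

#' Default exclusion band above plane C for slope searches (mm)
#'
#' Contour points closer than this to the cut plane are treated as cut
#' boundary artifacts and excluded from slope-point searches.
#' @export
cap_exclusion_default <- 0.5

#' Find the medial and lateral crest extreme points i and o
#'
#' Scans block vertices (cap excluded, i.e. vertices above plane C) for the
#' extremes along the medial-to-lateral axis `u_ml`.  Ties are broken by
#' greater height above C, then by vertex index.
#'
#' @param block A `condylo_block`.
#' @return List with points `i` and `o` (length-3 each).
#' @export
find_extreme_points <- function(block) {
  v <- block$mesh$vertices
  h <- signed_distance(v, block$frame$plane_c)
  cand <- which(h > 1e-9)
  if (length(cand) == 0) {
    stop("find_extreme_points: block has no vertices above plane C",
         call. = FALSE)
  }
  ml <- drop(v[cand, , drop = FALSE] %*% block$frame$u_ml)
  pick <- function(val) {
    sel <- cand[abs(val - max(val)) < 1e-12]
    if (length(sel) > 1) {
      sel <- sel[order(-h[sel], sel)]
    }
    sel[1]
  }
  i_idx <- pick(-ml)
  o_idx <- pick(ml)
  list(i = v[i_idx, ], o = v[o_idx, ])
}

#' Build the section planes M, N, N1, N2
#'
#' M is perpendicular to plane C through i and o.  IO is the projection of
#' segment i-o onto C; N is perpendicular to both IO and C through IO's
#' midpoint; N1 and N2 are perpendicular to C at +45 and -45 degrees to N
#' through the same midpoint.
#'
#' @param i,o Crest extreme points.
#' @param plane_c Osteotomy plane.
#' @return List of planes `M`, `N`, `N1`, `N2` and the midpoint `io_mid`.
#' @export
build_section_planes <- function(i, o, plane_c) {
  ip <- project_to_plane(point3(i), plane_c)
  op <- project_to_plane(point3(o), plane_c)
  w <- op - ip
  if (sqrt(sum(w^2)) < 1e-9) {
    stop("build_section_planes: i and o project to the same point on C",
         call. = FALSE)
  }
  w <- unit3(w)
  n <- plane_c$normal
  mid <- (ip + op) / 2
  M <- plane3(mid, cross3(w, n))       # contains w and n directions
  N <- plane3(mid, w)                  # perpendicular to IO and to C
  R45 <- rotation_about(n, pi / 4)
  N1 <- plane3(mid, drop(R45 %*% w))
  N2 <- plane3(mid, drop(t(R45) %*% w))
  list(M = M, N = N, N1 = N1, N2 = N2, io_mid = mid)
}

# Largest closed cross-section contour of the block on a section plane,
# resampled at uniform arc-length spacing (default 0.1 mm).
section_contour <- function(block, section, spacing = 0.1) {
  cs <- cross_section(block$mesh, section)
  cs <- Filter(function(ct) isTRUE(ct$closed), cs)
  if (length(cs) == 0) {
    stop("section plane does not intersect the block", call. = FALSE)
  }
  areas <- vapply(cs, function(ct) {
    abs(polygon_area2(to_plane_coords(ct$points, section)))
  }, numeric(1))
  pts <- cs[[which.max(areas)]]$points
  resample_closed(pts, spacing)
}

# Uniform arc-length resampling of a closed polyline (k x 3 matrix).
resample_closed <- function(pts, spacing) {
  # drop zero-length segments (shared cut vertices)
  dup <- c(FALSE, rowSums(abs(diff(pts))) < 1e-12)
  pts <- pts[!dup, , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  seg[seg < 1e-12] <- 1e-12
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_out <- max(16L, ceiling(total / spacing))
  s_out <- seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
  out <- cbind(approx(cum, closed[, 1], xout = s_out)$y,
               approx(cum, closed[, 2], xout = s_out)$y,
               approx(cum, closed[, 3], xout = s_out)$y)
  list(points = out, spacing = total / n_out)
}

#' Find the highest point up on plane M
#'
#' The point of the plane-M cross-section contour with maximal height above
#' plane C; ties go to the most lateral point.
#'
#' @param block A `condylo_block`.
#' @param M Section plane through i and o, perpendicular to C.
#' @param spacing Contour resampling interval, mm.
#' @return Length-3 point.
#' @export
find_up <- function(block, M, spacing = 0.1) {
  rc <- section_contour(block, M, spacing)
  h <- signed_distance(rc$points, block$frame$plane_c)
  top <- which(h > max(h) - 1e-9)
  if (length(top) > 1) {
    ml <- drop(rc$points[top, , drop = FALSE] %*% block$frame$u_ml)
    top <- top[which.max(ml)]
  }
  rc$points[top[1], ]
}

# Signed curvature along a uniformly resampled closed contour, smoothed over
# an arc-length window.  Positive = convex for a CCW contour.
contour_curvature <- function(points, spacing, window_mm) {
  n <- nrow(points)
  nxt <- c(2:n, 1)
  t_seg <- points[nxt, ] - points
  theta <- numeric(n)
  # angles in the contour plane: build a 2D basis from the first two tangents
  e1 <- unit3(t_seg[1, ])
  nrm <- NULL
  for (k in 2:n) {
    cp <- cross3(t_seg[1, ], t_seg[k, ])
    if (sqrt(sum(cp^2)) > 1e-9) { nrm <- unit3(cp); break }
  }
  if (is.null(nrm)) return(rep(0, n))
  e2 <- cross3(nrm, e1)
  tx <- drop(t_seg %*% e1); ty <- drop(t_seg %*% e2)
  theta <- atan2(ty, tx)
  dtheta <- diff(c(theta, theta[1]))
  dtheta <- (dtheta + pi) %% (2 * pi) - pi
  kappa <- dtheta / spacing
  # circular moving average over the arc-length window
  w <- max(1L, round(window_mm / spacing))
  if (w > 1L) {
    kern <- rep(1 / (2 * w + 1), 2 * w + 1)
    kappa <- stats::filter(c(kappa[(n - w + 1):n], kappa, kappa[1:w]),
                           kern, sides = 2)[(w + 1):(w + n)]
  }
  # the curvature plane normal may be flipped relative to the CCW convention;
  # normalize sign so the total turning is +2*pi
  if (sum(dtheta) < 0) kappa <- -kappa
  as.numeric(kappa)
}

#' Find the lowest-edge point of the anterior or posterior slope
#'
#' On the section contour the apex (maximum height) splits the curve into two
#' branches; the branch lying posterior of the apex (negative `u_ap` side) is
#' the posterior slope.  Walking from the apex downward, the returned point
#' is the first local maximum of concave curvature (the head-neck
#' inflection), estimated over an arc-length window of three mean mesh edge
#' lengths; contour points within `cap_exclusion` of plane C are excluded.
#' If no concave inflection is detectable the lowest non-excluded point is
#' returned with a warning.
#'
#' @param block A `condylo_block`.
#' @param section One of the planes N, N1, N2.
#' @param slope `"anterior"` or `"posterior"`.
#' @param cap_exclusion Exclusion band above C, mm.
#' @param spacing Contour resampling interval, mm.
#' @param min_concavity Minimum smoothed concave curvature (1/mm) to accept
#'   an inflection.
#' @param height_ceiling Only contour points below this height (mm above C)
#'   are eligible: the slope's lowest edge lies below the condylar crest, so
#'   the default is the lower of the two crest-pole heights.
#' @return Length-3 point on the contour.
#' @export
find_slope_point <- function(block, section, slope = c("posterior", "anterior"),
                             cap_exclusion = cap_exclusion_default,
                             spacing = 0.1, min_concavity = 0.01,
                             height_ceiling = NULL) {
  slope <- match.arg(slope)
  frame <- block$frame
  if (is.null(height_ceiling)) {
    ext <- find_extreme_points(block)
    height_ceiling <- min(signed_distance(ext$i, frame$plane_c),
                          signed_distance(ext$o, frame$plane_c))
  }
  rc <- section_contour(block, section, spacing)
  pts <- rc$points
  n <- nrow(pts)
  h <- signed_distance(pts, frame$plane_c)
  apex <- which.max(h)
  ap <- drop(pts %*% frame$u_ap)

  walk_branch <- function(step) {
    idx <- integer(0)
    k <- apex
    for (r in seq_len(n - 1)) {
      k <- ((k - 1 + step) %% n) + 1
      if (h[k] < cap_exclusion) break
      idx <- c(idx, k)
    }
    idx
  }
  fwd <- walk_branch(1L)
  bwd <- walk_branch(-1L)
  if (length(fwd) == 0 && length(bwd) == 0) {
    stop("find_slope_point: contour does not extend below the apex",
         call. = FALSE)
  }
  mean_ap <- function(idx) if (length(idx)) mean(ap[idx] - ap[apex]) else NA_real_
  post_first <- isTRUE(mean_ap(fwd) <= mean_ap(bwd)) ||
    (length(bwd) == 0)
  branch <- if (slope == "posterior") {
    if (post_first) fwd else bwd
  } else {
    if (post_first) bwd else fwd
  }
  if (length(branch) == 0) {
    stop("find_slope_point: requested slope branch is empty", call. = FALSE)
  }

  window_mm <- 3 * mean_edge_length(block$mesh)
  kappa <- contour_curvature(pts, rc$spacing, window_mm)
  conc <- -kappa  # concavity: positive where the surface curves inward
  w_loc <- max(2L, round(window_mm / rc$spacing / 2))
  m <- length(branch)
  eligible <- h[branch] < height_ceiling - 1e-9
  pick <- NA_integer_
  for (t in seq_len(m)) {
    k <- branch[t]
    if (!eligible[t] || conc[k] < min_concavity) next
    lo <- max(1L, t - w_loc); hi <- min(m, t + w_loc)
    if (conc[k] >= max(conc[branch[lo:hi]]) - 1e-12) {
      pick <- k
      break
    }
  }
  if (is.na(pick)) {
    warning("find_slope_point: no concave inflection found; ",
            "falling back to the lowest non-cap contour point")
    cand <- if (any(eligible)) branch[eligible] else branch
    pick <- cand[which.min(h[cand])]
  }
  pts[pick, ]
}

#' Assemble the seven-point landmark set of a condylar block
#'
#' Runs the full construction: crest extremes i/o, section planes M/N/N1/N2,
#' apex point up, anterior/posterior slope points a/p on N, and the two
#' posterior-slope points on N1/N2, of which the one closer to i is pi and
#' the one closer to o is po.  Heights are signed distances to plane C.
#'
#' @param block A `condylo_block`.
#' @param cap_exclusion Exclusion band above C for slope searches, mm.
#' @param spacing Contour resampling interval, mm.
#' @return Object of class `condylo_seven`: list with `points` (named list of
#'   7 points), `heights` (named numeric), `d_io` (= height i - height o) and
#'   `d_pipo` (= height pi - height po), and the section `planes`.
#' @export
assemble_seven <- function(block, cap_exclusion = cap_exclusion_default,
                           spacing = 0.1) {
  ext <- find_extreme_points(block)
  planes <- build_section_planes(ext$i, ext$o, block$frame$plane_c)
  up <- find_up(block, planes$M, spacing)
  ceil_h <- min(signed_distance(ext$i, block$frame$plane_c),
                signed_distance(ext$o, block$frame$plane_c))
  a <- find_slope_point(block, planes$N, "anterior", cap_exclusion, spacing,
                        height_ceiling = ceil_h)
  p <- find_slope_point(block, planes$N, "posterior", cap_exclusion, spacing,
                        height_ceiling = ceil_h)
  q1 <- find_slope_point(block, planes$N1, "posterior", cap_exclusion,
                         spacing, height_ceiling = ceil_h)
  q2 <- find_slope_point(block, planes$N2, "posterior", cap_exclusion,
                         spacing, height_ceiling = ceil_h)
  d_q1_i <- sum((q1 - ext$i)^2); d_q2_i <- sum((q2 - ext$i)^2)
  if (d_q1_i <= d_q2_i) {
    p_i <- q1; p_o <- q2
  } else {
    p_i <- q2; p_o <- q1
  }
  points <- list(i = ext$i, o = ext$o, a = a, p = p, pi = p_i, po = p_o,
                 up = up)
  heights <- vapply(points, signed_distance, numeric(1),
                    plane = block$frame$plane_c)
  structure(list(points = points, heights = heights,
                 d_io = heights[["i"]] - heights[["o"]],
                 d_pipo = heights[["pi"]] - heights[["po"]],
                 planes = planes),
            class = "condylo_seven")
}

#' @export
print.condylo_seven <- function(x, ...) {
  cat("<seven-point set> heights above plane C (mm):\n")
  print(round(x$heights, 3))
  cat(sprintf("  d_io = %.3f, d_pipo = %.3f\n", x$d_io, x$d_pipo))
  invisible(x)
}
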