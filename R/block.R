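# Osteotomy-plane construction and condylar block separation.  The block is
# the part of the mandible above plane C (parallel to the Frankfort plane
# through the sigmoid-notch point s), re-capped at C so its volume is defined.

#' Build the osteotomy plane C
#'
#' Plane C is parallel to the Frankfort plane and passes through the lowest
#' point of the mandibular sigmoid notch, `s`.  The normal is oriented so the
#' declared superior reference point has positive signed distance.
#'
#' @param fh Frankfort plane (`condylo_plane`).
#' @param s Sigmoid-notch point (mm).
#' @param superior_ref A point on the superior side (e.g. a condylar-head
#'   vertex or crista galli).
#' @return A `condylo_plane` through `s` parallel to `fh`.
#' @export
build_cut_plane <- function(fh, s, superior_ref) {
  stopifnot(is_plane(fh))
  pln <- plane3(point3(s), fh$normal)
  d <- signed_distance(point3(superior_ref), pln)
  if (abs(d) < .tol_exact) {
    stop("build_cut_plane: superior reference lies on the plane; orientation ambiguous",
         call. = FALSE)
  }
  if (d < 0) pln$normal <- -pln$normal
  pln
}

#' Build the anatomical condylar frame
#'
#' An orthonormal frame anchoring every directional rule: `u_si` is the plane
#' C normal (superior); `u_ml` is the in-plane projection of the inter-porion
#' vector signed to point medial-to-lateral for the declared side; `u_ap` is
#' the in-plane projection of (orbitale - porion midpoint), i.e.
#' posterior-to-anterior, re-orthogonalized against `u_ml`.
#'
#' @param plane_c Osteotomy plane.
#' @param porion_left,porion_right,orbitale Cranial landmarks (mm).
#' @param side `"left"` or `"right"`.
#' @return Object of class `condylo_frame` with `plane_c`, `u_si`, `u_ml`,
#'   `u_ap`, `side`.
#' @export
build_frame <- function(plane_c, porion_left, porion_right, orbitale, side) {
  side <- match.arg(side, c("left", "right"))
  pl <- point3(porion_left); pr <- point3(porion_right)
  n <- plane_c$normal
  ip <- pr - pl
  ip_in <- ip - sum(ip * n) * n
  if (sqrt(sum(ip_in^2)) < 1e-6) {
    stop("build_frame: inter-porion vector degenerate or parallel to plane normal",
         call. = FALSE)
  }
  # right-to-left is lateral on the left side; left-to-right on the right
  u_ml <- if (side == "right") unit3(ip_in) else unit3(-ip_in)
  ap <- point3(orbitale) - (pl + pr) / 2
  ap_in <- ap - sum(ap * n) * n
  ap_in <- ap_in - sum(ap_in * u_ml) * u_ml
  if (sqrt(sum(ap_in^2)) < 1e-6) {
    stop("build_frame: anteroposterior direction degenerate", call. = FALSE)
  }
  structure(list(plane_c = plane_c, u_si = n, u_ml = u_ml,
                 u_ap = unit3(ap_in), side = side),
            class = "condylo_frame")
}

#' @export
print.condylo_frame <- function(x, ...) {
  cat(sprintf("<condylar frame> side %s\n", x$side))
  cat(sprintf("  u_si (%.4f, %.4f, %.4f)\n", x$u_si[1], x$u_si[2], x$u_si[3]))
  cat(sprintf("  u_ml (%.4f, %.4f, %.4f)\n", x$u_ml[1], x$u_ml[2], x$u_ml[3]))
  cat(sprintf("  u_ap (%.4f, %.4f, %.4f)\n", x$u_ap[1], x$u_ap[2], x$u_ap[3]))
  invisible(x)
}

# ---- half-space clipping ---------------------------------------------------

# Clip a watertight mesh to the half-space signed_distance >= 0 and cap the
# cut with triangulated planar polygons.  Vertices within snap_tol of the
# plane are snapped onto it first to avoid sliver triangles.  Returns the
# clipped mesh plus indices of cap faces and cap-interior vertices.
clip_mesh_halfspace <- function(mesh, plane, snap_tol = .tol_mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- signed_distance(v, plane)
  snap <- abs(d) < snap_tol
  if (any(snap)) {
    v[snap, ] <- project_to_plane(v[snap, , drop = FALSE], plane)
    d[snap] <- 0
  }

  keep_all <- d[f[, 1]] >= 0 & d[f[, 2]] >= 0 & d[f[, 3]] >= 0
  drop_all <- d[f[, 1]] <= 0 & d[f[, 2]] <= 0 & d[f[, 3]] <= 0
  # fully on-plane triangles count as dropped (they would duplicate the cap)
  mixed <- which(!keep_all & !drop_all)
  keep_faces <- f[keep_all & !drop_all, , drop = FALSE]

  new_v <- list()
  new_key <- character(0)
  edge_idx <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  get_cut_vertex <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- edge_idx[[key]]
    if (is.null(id)) {
      t <- d[i] / (d[i] - d[j])
      p <- v[i, ] + t * (v[j, ] - v[i, ])
      new_v[[length(new_v) + 1L]] <<- p
      id <- nv0 + length(new_v)
      edge_idx[[key]] <<- id
    }
    id
  }

  clipped <- list()
  for (r in mixed) {
    tri <- f[r, ]
    poly <- integer(0)
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
      if (d[i] >= 0) poly <- c(poly, i)
      if ((d[i] > 0 && d[j] < 0) || (d[i] < 0 && d[j] > 0)) {
        poly <- c(poly, get_cut_vertex(i, j))
      }
    }
    poly <- poly[c(TRUE, poly[-1] != poly[-length(poly)])]
    if (length(poly) > 1 && poly[1] == poly[length(poly)]) {
      poly <- poly[-length(poly)]
    }
    if (length(poly) >= 3) {
      for (k in 2:(length(poly) - 1)) {
        clipped[[length(clipped) + 1L]] <- poly[c(1, k, k + 1)]
      }
    }
  }

  all_v <- rbind(v, do.call(rbind, c(new_v, list(matrix(0, 0, 3)))))
  all_f <- rbind(keep_faces,
                 if (length(clipped)) do.call(rbind, clipped) else
                   matrix(0L, 0, 3))
  if (nrow(all_f) == 0) {
    stop("clip_mesh_halfspace: no geometry above the plane", call. = FALSE)
  }

  # cap: boundary edges (used once) chained into loops on the plane
  ek <- edge_keys(all_f)
  tab <- table(ek)
  boundary_keys <- names(tab)[tab == 1L]
  cap_faces <- matrix(0L, 0, 3)
  cap_vertex_start <- nrow(all_v) + 1L
  if (length(boundary_keys)) {
    e <- rbind(all_f[, c(1, 2), drop = FALSE],
               all_f[, c(2, 3), drop = FALSE],
               all_f[, c(3, 1), drop = FALSE])
    bidx <- which(ek %in% boundary_keys)
    be <- e[bidx, , drop = FALSE]  # directed boundary edges
    # The surface is oriented, so boundary edges chain head-to-tail.
    nxt <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(be))) nxt[[as.character(be[k, 1])]] <- be[k, 2]
    visited <- new.env(parent = emptyenv())
    basis <- plane_basis(plane)
    for (k in seq_len(nrow(be))) {
      start <- be[k, 1]
      if (!is.null(visited[[as.character(start)]])) next
      loop <- integer(0)
      cur <- start
      repeat {
        if (!is.null(visited[[as.character(cur)]])) break
        visited[[as.character(cur)]] <- TRUE
        loop <- c(loop, cur)
        nx <- nxt[[as.character(cur)]]
        if (is.null(nx)) break
        cur <- nx
        if (cur == start) break
      }
      if (length(loop) < 3) next
      uv <- to_plane_coords(all_v[loop, , drop = FALSE], plane, basis)
      # ear-clip in CCW convention, then reverse each cap triangle so its
      # directed edges oppose the rim edges of the kept surface (cap normal
      # points along -plane normal, i.e. outward for a block above the plane)
      if (polygon_area2(uv) < 0) {
        loop <- rev(loop)
        uv <- uv[rev(seq_len(nrow(uv))), , drop = FALSE]
      }
      tris <- ear_clip(uv)
      if (nrow(tris)) {
        cap <- cbind(loop[tris[, 1]], loop[tris[, 3]], loop[tris[, 2]])
        cap_faces <- rbind(cap_faces, cap)
      }
    }
  }
  all_f <- rbind(all_f, cap_faces)

  out <- triangle_mesh(all_v, all_f, validate = FALSE)
  # drop unreferenced vertices
  used <- sort(unique(as.vector(all_f)))
  remap <- integer(nrow(all_v))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(all_v[used, , drop = FALSE],
                       matrix(remap[all_f], ncol = 3), validate = FALSE)
  cap_face_idx <- if (nrow(cap_faces)) {
    (nrow(all_f) - nrow(cap_faces) + 1L):nrow(all_f)
  } else integer(0)
  list(mesh = out, cap_faces = cap_face_idx)
}

# Ear-clipping triangulation of a simple CCW polygon given as k x 2 coords.
# Returns index triples into the polygon (CCW).  Falls back to fanning if no
# ear is found (degenerate collinear runs).
ear_clip <- function(uv) {
  n <- nrow(uv)
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  in_tri <- function(p, a, b, c3) {
    d1 <- cross2(a, b, p); d2 <- cross2(b, c3, p); d3 <- cross2(c3, a, p)
    (d1 >= -1e-12 && d2 >= -1e-12 && d3 >= -1e-12)
  }
  guard <- 0L
  while (length(idx) > 3 && guard < 10000L) {
    guard <- guard + 1L
    m <- length(idx)
    found <- FALSE
    for (k in seq_len(m)) {
      ia <- idx[if (k == 1) m else k - 1]
      ib <- idx[k]
      ic <- idx[if (k == m) 1 else k + 1]
      a <- uv[ia, ]; b <- uv[ib, ]; c3 <- uv[ic, ]
      if (cross2(a, b, c3) <= 1e-12) next  # reflex or collinear
      ok <- TRUE
      for (j in idx) {
        if (j %in% c(ia, ib, ic)) next
        if (in_tri(uv[j, ], a, b, c3)) { ok <- FALSE; break }
      }
      if (ok) {
        tris <- rbind(tris, c(ia, ib, ic))
        idx <- idx[-k]
        found <- TRUE
        break
      }
    }
    if (!found) {
      # degenerate remainder (collinear runs): fan it
      for (k in 2:(length(idx) - 1)) {
        tris <- rbind(tris, idx[c(1, k, k + 1)])
      }
      return(tris)
    }
  }
  rbind(tris, idx[1:3])
}

#' Cut the condylar block off the mandible at plane C
#'
#' Clips the watertight mandible mesh to the half-space above plane C, caps
#' the cut, and — when several components lie above the plane (e.g. the
#' coronoid process) — keeps the component whose centroid is most posterior
#' along `u_ap`: plane C through the sigmoid notch separates the condyle
#' (posterior) from the coronoid (anterior).
#'
#' @param mandible Watertight `condylo_mesh` of a hemimandible or condyle.
#' @param plane_c Osteotomy plane (normal pointing superior).
#' @param frame A `condylo_frame`; used for component selection and kept for
#'   downstream landmark searches.
#' @return Object of class `condylo_block`: `mesh`, `frame`, `volume` (mm^3),
#'   `cap_area` (mm^2), `n_components` found above the plane.
#' @export
cut_block <- function(mandible, plane_c, frame) {
  check_watertight(mandible)
  d <- signed_distance(mandible$vertices, plane_c)
  if (all(d <= .tol_mesh)) {
    stop("cut_block: no geometry above the plane (empty block)",
         call. = FALSE)
  }
  if (all(d >= -.tol_mesh)) {
    # plane below the whole mesh: the block is the full mesh
    mesh <- mandible
    if (mesh_volume(mesh) < 0) {
      mesh <- triangle_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)],
                            validate = FALSE)
    }
    return(structure(list(mesh = mesh, frame = frame,
                          volume = mesh_volume(mesh), cap_area = 0,
                          n_components = 1L),
                     class = "condylo_block"))
  }
  clip <- clip_mesh_halfspace(mandible, plane_c)
  comp <- mesh_components(clip$mesh)
  ncomp <- max(comp$face)
  mesh <- clip$mesh
  if (ncomp > 1L) {
    cent_ap <- vapply(seq_len(ncomp), function(ci) {
      vv <- mesh$vertices[comp$vertex == ci, , drop = FALSE]
      mean(vv %*% frame$u_ap)
    }, numeric(1))
    mesh <- submesh(mesh, which(comp$face == which.min(cent_ap)))
  }
  vol <- mesh_volume(mesh)
  if (vol < 0) {
    message("cut_block: flipping inward-oriented block")
    mesh <- triangle_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)],
                          validate = FALSE)
    vol <- -vol
  }
  check_watertight(mesh)
  # cap area: faces whose three vertices are on plane C
  dd <- abs(signed_distance(mesh$vertices, plane_c)) < 10 * .tol_mesh
  on_cap <- dd[mesh$faces[, 1]] & dd[mesh$faces[, 2]] & dd[mesh$faces[, 3]]
  cap_area <- if (any(on_cap)) {
    fsub <- mesh$faces[on_cap, , drop = FALSE]
    a <- mesh$vertices[fsub[, 1], , drop = FALSE]
    b <- mesh$vertices[fsub[, 2], , drop = FALSE]
    c3 <- mesh$vertices[fsub[, 3], , drop = FALSE]
    nx <- (b[, 2] - a[, 2]) * (c3[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c3[, 2] - a[, 2])
    ny <- (b[, 3] - a[, 3]) * (c3[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c3[, 3] - a[, 3])
    nz <- (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1])
    sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
  } else 0
  structure(list(mesh = mesh, frame = frame, volume = vol,
                 cap_area = cap_area, n_components = ncomp),
            class = "condylo_block")
}

#' @export
print.condylo_block <- function(x, ...) {
  cat(sprintf("<condylar block> side %s, volume %.1f mm^3, cap area %.1f mm^2\n",
              x$frame$side, x$volume, x$cap_area))
  invisible(x)
}

#' Volume of a condylar block
#'
#' Divergence-theorem signed volume of the capped block mesh.  A negative
#' signed volume indicates inward orientation and is auto-fixed with a
#' message.
#'
#' @param block A `condylo_block`.
#' @return Volume in mm^3 (positive).
#' @export
block_volume <- function(block) {
  v <- mesh_volume(block$mesh)
  if (v < 0) {
    message("block_volume: mesh was inward-oriented; sign corrected")
    v <- -v
  }
  v
}
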