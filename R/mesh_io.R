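# Mesh file I/O.  Units are millimetres by contract; no unit metadata in the
# file is trusted.  STL stores a triangle soup, so vertices are merged on
# read by exact coordinate match (CT-derived meshes are exported with shared
# vertices, so exact matching is lossless).

#' Read a surface mesh from STL (binary or ASCII) or PLY (ASCII)
#'
#' @param path File path; format chosen by extension (.stl / .ply).
#' @return A `condylo_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("read_mesh: unsupported extension '", ext, "'", call. = FALSE))
}

#' Write a surface mesh to STL (binary or ASCII) or PLY (ASCII)
#'
#' @param mesh A `condylo_mesh`.
#' @param path Output path; format chosen by extension.
#' @param ascii Write text STL instead of binary (ignored for PLY, always
#'   text).
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (ascii) write_stl_ascii(mesh, path) else
           write_stl_binary(mesh, path),
         ply = write_ply(mesh, path),
         stop("write_mesh: unsupported extension '", ext, "'", call. = FALSE))
  invisible(path)
}

soup_to_mesh <- function(tri_coords) {
  # tri_coords: (3*m) x 3, triangles in consecutive row triples
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3], sep = "|")
  idx <- match(key, unique(key))
  verts <- tri_coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80)
  close(con)
  txt_head <- rawToChar(header[header != as.raw(0)][1:min(5, sum(header != 0))])
  size <- file.info(path)$size
  if (grepl("^solid", txt_head)) {
    # could still be binary with a "solid" header: check size consistency
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && size == 84 + 50 * n) {
      close(con); on.exit()
      return(read_stl_binary(path))
    }
    close(con); on.exit()
    return(read_stl_ascii(path))
  }
  read_stl_binary(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", n * 50)
  m <- matrix(rec, nrow = 50)
  tri <- array(0, dim = c(3L * n, 3L))
  for (v in 0:2) {
    for (coord in 0:2) {
      off <- 12 + v * 12 + coord * 4
      vals <- readBin(as.vector(m[(off + 1):(off + 4), ]), "numeric",
                      n, size = 4, endian = "little")
      tri[seq(v + 1, by = 3, length.out = n), coord + 1] <- vals
    }
  }
  soup_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  parts <- strsplit(trimws(vl), "\\s+")
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(tri) %% 3 != 0) stop("read_stl_ascii: vertex count not a multiple of 3",
                                call. = FALSE)
  soup_to_mesh(tri)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  nfaces <- nrow(mesh$faces)
  writeBin(as.integer(nfaces), con, size = 4, endian = "little")
  v <- mesh$vertices; f <- mesh$faces
  for (k in seq_len(nfaces)) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c3 <- v[f[k, 3], ]
    n <- cross3(b - a, c3 - a)
    ln <- sqrt(sum(n^2))
    n <- if (ln > 0) n / ln else c(0, 0, 0)
    writeBin(as.numeric(c(n, a, b, c3)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  out <- character(2 + 7 * nrow(f))
  out[1] <- "solid condylomorph"
  pos <- 2L
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c3 <- v[f[k, 3], ]
    n <- cross3(b - a, c3 - a)
    ln <- sqrt(sum(n^2))
    n <- if (ln > 0) n / ln else c(0, 0, 0)
    out[pos:(pos + 6)] <- c(
      sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "  outer loop",
      sprintf("    vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("    vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("    vertex %.9g %.9g %.9g", c3[1], c3[2], c3[3]),
      "  endloop",
      "endfacet")
    pos <- pos + 7L
  }
  out[pos] <- "endsolid condylomorph"
  writeLines(out, path)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("read_ply: no end_header", call. = FALSE)
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format ascii", hdr))) {
    stop("read_ply: only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(end_hdr + 1):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) stop("read_ply: non-triangular face",
                                     call. = FALSE)
    as.integer(p[2:4]) + 1L  # PLY is 0-based
  }, integer(3)))
  triangle_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vtxt <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  ftxt <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, vtxt, ftxt), path)
  invisible(path)
}

# ---- landmark file ---------------------------------------------------------

.landmark_names <- c("porion_l", "porion_r", "orbitale", "s_l", "s_r",
                     "nasion", "a_point", "b_point", "pogonion", "menton",
                     "crista_galli", "zf_l", "zf_r")

#' Read a named 3D landmark file (JSON)
#'
#' The file maps landmark name to an `[x, y, z]` triple in mm.  Recognized
#' names: `porion_l`, `porion_r`, `orbitale` (alias `orbitale_l`), `s_l`,
#' `s_r`, `nasion`, `a_point`, `b_point`, `pogonion`, `menton`,
#' `crista_galli`, `zf_l`, `zf_r`.  A single orbitale point defines the
#' Frankfort plane (the left one by convention when both are digitized).
#'
#' @param path JSON file path.
#' @return Named list of length-3 numeric points.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lm$orbitale_l) && is.null(lm$orbitale)) {
    lm$orbitale <- lm$orbitale_l
  }
  lapply(lm, function(p) point3(as.numeric(p)))
}

#' Write a named 3D landmark file (JSON)
#'
#' @param landmarks Named list of length-3 points.
#' @param path Output path.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA)
  invisible(path)
}

require_landmarks <- function(landmarks, needed) {
  missing <- setdiff(needed, names(landmarks))
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
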