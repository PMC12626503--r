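# Programmatic mesh fixtures: UV-sphere, ellipsoid, axis-aligned cube.
# All watertight with outward orientation.

make_uv_sphere <- function(radius = 1, n_theta = 48L, n_phi = 24L,
                           center = c(0, 0, 0), scale = c(1, 1, 1)) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ph <- seq(0, pi, length.out = n_phi + 1L)
  v <- matrix(0, 0, 3)
  for (p in ph[-c(1, n_phi + 1L)]) {
    v <- rbind(v, cbind(radius * sin(p) * cos(th),
                        radius * sin(p) * sin(th),
                        radius * cos(p)))
  }
  v <- rbind(c(0, 0, radius), v, c(0, 0, -radius))
  v <- sweep(sweep(v, 2, scale, "*"), 2, center, "+")
  nr <- n_phi - 1L
  ring <- function(r) 1L + (r - 1L) * n_theta + seq_len(n_theta)
  top <- 1L
  bot <- nrow(v)
  faces <- matrix(0L, 0, 3)
  r1 <- ring(1)
  faces <- rbind(faces, cbind(top, r1, c(r1[-1], r1[1])))
  for (r in seq_len(nr - 1L)) {
    a <- ring(r); b <- ring(r + 1L)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    faces <- rbind(faces, cbind(a, b, bn), cbind(a, bn, an))
  }
  rl <- ring(nr)
  faces <- rbind(faces, cbind(bot, c(rl[-1], rl[1]), rl))
  triangle_mesh(v, faces)
}

make_ellipsoid <- function(a, b, c3, n_theta = 48L, n_phi = 24L,
                           center = c(0, 0, 0)) {
  make_uv_sphere(1, n_theta, n_phi, center = center, scale = c(a, b, c3))
}

make_cube <- function(side = 1, center = c(0.5, 0.5, 0.5)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  # 12 outward-oriented triangles
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7),   # z = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 7, 8), c(3, 8, 4),   # y = +h
    c(1, 5, 7), c(1, 7, 3),   # x = -h
    c(2, 4, 8), c(2, 8, 6))   # x = +h
  triangle_mesh(v, f)
}

canonical_frame <- function(plane_c = plane3(c(0, 0, 0), c(0, 0, 1)),
                            side = "right") {
  build_frame(plane_c, c(-60, 0, 0), c(60, 0, 0), c(40, 65, 0), side)
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- unit3(stats::rnorm(3))
  rigid_transform(rotation_about(ax, stats::runif(1, 0, 2 * pi)),
                  stats::rnorm(3, sd = 20))
}
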