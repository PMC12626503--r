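# Seven-point construction: crest extremes, section planes, apex, slope
# inflections, assembly invariants.

make_block <- function(params = condyle_params(), ...) {
  g <- generate_condyle(params, ...)
  fh <- plane3(c(0, 0, 0), c(0, 0, 1))
  pc <- build_cut_plane(fh, g$landmarks[[paste0("s_", substr(params$side, 1, 1))]],
                        g$landmarks$crista_galli)
  fr <- build_frame(pc, g$landmarks$porion_l, g$landmarks$porion_r,
                    g$landmarks$orbitale, params$side)
  list(block = cut_block(g$mesh, pc, fr), gen = g)
}

test_that("crest extremes match a brute-force vertex scan", {
  mb <- make_block(condyle_params(subdivision = 2, noise_amp = 0.8, seed = 4))
  blk <- mb$block
  ext <- find_extreme_points(blk)
  v <- blk$mesh$vertices
  h <- signed_distance(v, blk$frame$plane_c)
  cand <- v[h > 1e-9, , drop = FALSE]
  ml <- drop(cand %*% blk$frame$u_ml)
  expect_equal(drop(ext$i %*% blk$frame$u_ml), min(ml), tolerance = 1e-12)
  expect_equal(drop(ext$o %*% blk$frame$u_ml), max(ml), tolerance = 1e-12)
  expect_lte(nrow(v), 5000)
})

test_that("extreme points sit at the equator of an ellipsoid block", {
  pc <- plane3(c(0, 0, 0), c(0, 0, 1))
  ell <- make_ellipsoid(10, 8, 6, 64, 33, center = c(0, 0, 5))
  blk <- cut_block(ell, pc, canonical_frame(pc))
  ext <- find_extreme_points(blk)
  expect_equal(ext$i[1], -10, tolerance = 0.05)
  expect_equal(ext$o[1], 10, tolerance = 0.05)
  expect_equal(ext$i[3], 5, tolerance = 0.3)
})

test_that("section planes have the prescribed orthogonality and 45-degree angles", {
  pc <- plane3(c(0, 0, 0), c(0, 0, 1))
  # axis-aligned construction
  pl <- build_section_planes(c(-10, 0, 5), c(10, 0, 5), pc)
  expect_equal(pl$io_mid, c(0, 0, 0))
  expect_equal(abs(pl$M$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(abs(pl$N$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(sum(pl$N1$normal * pl$N$normal)), cos(pi / 4),
               tolerance = 1e-12)
  expect_equal(abs(sum(pl$N2$normal * pl$N$normal)), cos(pi / 4),
               tolerance = 1e-12)
  # generic inputs: orthogonality and containment
  set.seed(9)
  for (k in 1:5) {
    i <- stats::rnorm(3, sd = 10); o <- stats::rnorm(3, sd = 10)
    pcg <- plane3(stats::rnorm(3), stats::rnorm(3))
    if (sqrt(sum((project_to_plane(i, pcg) - project_to_plane(o, pcg))^2)) < 1) next
    pl <- build_section_planes(i, o, pcg)
    for (nm in c("M", "N", "N1", "N2")) {
      expect_lt(abs(sum(pl[[nm]]$normal * pcg$normal)), 1e-9)  # perp to C
    }
    expect_lt(abs(signed_distance(i, pl$M)), 1e-9)
    expect_lt(abs(signed_distance(o, pl$M)), 1e-9)
    for (nm in c("N", "N1", "N2")) {
      expect_lt(abs(signed_distance(pl$io_mid, pl[[nm]])), 1e-9)
    }
    expect_equal(abs(sum(pl$N1$normal * pl$N$normal)), cos(pi / 4),
                 tolerance = 1e-9)
  }
  expect_error(build_section_planes(c(0, 0, 1), c(0, 0, 5), pc),
               "same point")
})

test_that("up is the contour apex and translates with the block", {
  mb <- make_block(condyle_params(subdivision = 3))
  blk <- mb$block
  seven <- assemble_seven(blk)
  # apex height from the generator's profile, within chord error
  expect_equal(seven$heights[["up"]], mb$gen$ledger$apex_height,
               tolerance = 0.05)
  # up has the maximal height among all seven points
  expect_true(all(seven$heights[["up"]] >= seven$heights - 1e-9))
  # dense-resampling brute force on the same contour
  pl <- build_section_planes(seven$points$i, seven$points$o,
                             blk$frame$plane_c)
  rc <- condylomorph:::section_contour(blk, pl$M, 0.02)
  h <- signed_distance(rc$points, blk$frame$plane_c)
  expect_equal(seven$heights[["up"]], max(h), tolerance = 0.02)
  # raising the block by +2 mm raises up by exactly 2 mm
  up_shift <- rigid_transform(diag(3), 2 * blk$frame$u_si)
  blk2 <- blk
  blk2$mesh <- apply_rigid(blk$mesh, up_shift)
  expect_equal(find_up(blk2, pl$M)[3] - find_up(blk, pl$M)[3], 2,
               tolerance = 0.02)
})

test_that("slope points find the generator-placed neck inflection", {
  for (hstar in c(5, 6, 7)) {
    mb <- make_block(condyle_params(inflection_height = hstar,
                                    subdivision = 3))
    seven <- assemble_seven(mb$block)
    edge <- mb$gen$ledger$mean_edge
    for (pt in c("a", "p", "pi", "po")) {
      expect_lt(abs(seven$heights[[pt]] - hstar), edge)
    }
  }
})

test_that("symmetric fixtures give d_io = 0 and d_pipo = 0", {
  mb <- make_block(condyle_params(subdivision = 3))
  seven <- assemble_seven(mb$block)
  expect_equal(seven$d_io, 0, tolerance = 1e-9)
  expect_lt(abs(seven$d_pipo), 0.2)  # discretization-level asymmetry only
})

test_that("mirrored blocks swap (i, pi) with (o, po) heights", {
  mbr <- make_block(condyle_params(side = "right", subdivision = 3,
                                   noise_amp = 0.5, seed = 8))
  mbl <- make_block(condyle_params(side = "left", subdivision = 3,
                                   noise_amp = 0.5, seed = 8))
  sr <- assemble_seven(mbr$block)
  sl <- assemble_seven(mbl$block)
  edge <- mbr$gen$ledger$mean_edge
  expect_equal(sl$heights[["i"]], sr$heights[["i"]], tolerance = 1e-6)
  expect_equal(sl$heights[["o"]], sr$heights[["o"]], tolerance = 1e-6)
  expect_lt(abs(sl$heights[["up"]] - sr$heights[["up"]]), 0.05)
  expect_lt(abs(sl$heights[["pi"]] - sr$heights[["pi"]]), edge)
  expect_lt(abs(sl$heights[["po"]] - sr$heights[["po"]]), edge)
  expect_equal(sl$d_io, sr$d_io, tolerance = 1e-6)
})

test_that("all seven heights are non-negative and rigid-invariant", {
  mb <- make_block(condyle_params(subdivision = 2, noise_amp = 0.6,
                                  seed = 12))
  s0 <- assemble_seven(mb$block)
  expect_true(all(s0$heights >= 0))
  tr <- random_rigid(23)
  blk2 <- mb$block
  blk2$mesh <- apply_rigid(mb$block$mesh, tr)
  blk2$frame <- local({
    fr <- mb$block$frame
    fr$plane_c <- apply_rigid(fr$plane_c, tr)
    fr$u_si <- drop(tr$R %*% fr$u_si)
    fr$u_ml <- drop(tr$R %*% fr$u_ml)
    fr$u_ap <- drop(tr$R %*% fr$u_ap)
    fr
  })
  s1 <- assemble_seven(blk2)
  expect_equal(unname(s1$heights), unname(s0$heights), tolerance = 1e-6)
})

test_that("a localized posterolateral field raises po and leaves a fixed", {
  mb <- make_block(condyle_params(subdivision = 3))
  m0h <- assemble_seven(mb$block)$heights
  fld <- remodeling_field(posterolateral = 1.5)
  mesh1 <- apply_remodeling(mb$gen$mesh, fld, mb$block$frame, growth = Inf)
  blk1 <- cut_block(mesh1, mb$block$frame$plane_c, mb$block$frame)
  m1h <- assemble_seven(blk1)$heights
  expect_gte(m1h[["po"]] - m0h[["po"]], 1.0)
  expect_lte(m1h[["po"]] - m0h[["po"]], 1.5 + 0.3)
  expect_lt(abs(m1h[["a"]] - m0h[["a"]]), 0.2)
})
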