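# Generator determinism, analytic limits, remodeling fields, cohort
# distributions.

test_that("generation is deterministic and validates parameters", {
  p <- condyle_params(noise_amp = 0.5, seed = 42)
  g1 <- generate_condyle(p)
  g2 <- generate_condyle(p)
  expect_identical(g1$mesh$vertices, g2$mesh$vertices)
  expect_identical(g1$mesh$faces, g2$mesh$faces)
  g3 <- generate_condyle(condyle_params(noise_amp = 0.5, seed = 43))
  expect_false(identical(g1$mesh$vertices, g3$mesh$vertices))
  expect_error(condyle_params(neck_radius = 10), "neck_radius")
  expect_error(condyle_params(inflection_height = 0.2), "inflection")
})

test_that("the head-only limit reproduces the half-ellipsoid volume", {
  p <- condyle_params(head_ml = 8, head_ap = 6, head_si = 7,
                      neck_length = 0, inflection_height = 0,
                      stub_depth = 5, subdivision = 4)
  g <- generate_condyle(p)
  pc <- plane3(g$landmarks$s_r, c(0, 0, 1))
  blk <- cut_block(g$mesh, pc, canonical_frame(pc))
  half <- 2 / 3 * pi * 8 * 6 * 7
  expect_lt(abs(blk$volume - half) / half, 0.015)
  expect_equal(g$ledger$block_volume, half, tolerance = 1e-6)
})

test_that("generated meshes are watertight across parameter ranges", {
  for (p in list(condyle_params(subdivision = 1),
                 condyle_params(head_tilt = 10, subdivision = 2),
                 condyle_params(side = "left", subdivision = 2),
                 condyle_params(neck_length = 3, inflection_height = 4,
                                neck_radius = 6.4, subdivision = 2))) {
    g <- generate_condyle(p)
    expect_true(is_watertight(g$mesh))
    expect_gt(mesh_volume(g$mesh), 0)
  }
})

test_that("zero remodeling is the identity; uniform field obeys the shell formula", {
  g <- generate_condyle(condyle_params(subdivision = 2))
  fr <- canonical_frame(plane3(g$landmarks$s_r, c(0, 0, 1)))
  m0 <- apply_remodeling(g$mesh, remodeling_field(), fr)
  expect_identical(m0$vertices, g$mesh$vertices)
  # uniform +0.1 mm along normals on a sphere: dV ~ 4 pi r^2 delta
  sph <- make_uv_sphere(radius = 8, n_theta = 48, n_phi = 24,
                        center = c(0, 0, 20))
  pc <- plane3(c(0, 0, 0), c(0, 0, 1))  # sphere entirely above C: no taper
  fr2 <- canonical_frame(pc)
  fld <- remodeling_field(superior = 0.1, anterior = 0.1,
                          anterolateral = 0.1, lateral = 0.1,
                          posterolateral = 0.1, posterior = 0.1,
                          posteromedial = 0.1, medial = 0.1,
                          anteromedial = 0.1)
  sph1 <- apply_remodeling(sph, fld, fr2, growth = 0)
  dv <- mesh_volume(sph1) - mesh_volume(sph)
  expect_lt(abs(dv - 4 * pi * 64 * 0.1) / (4 * pi * 64 * 0.1), 0.05)
  expect_error(remodeling_field(lateral = 7), "5 mm")
})

test_that("measurement-level cohorts track their spec distributions", {
  sp <- cohort_spec(n_per_group = 200, seed = 17)
  tab <- simulate_cohort(sp)
  pb <- sum_bilateral(tab)
  med_dd <- stats::median(pb$volume_change[pb$group == "DD"])
  med_dr <- stats::median(pb$volume_change[pb$group == "DR"])
  expect_lt(abs(med_dd - 29.5), 40)
  expect_lt(abs(med_dr - 279.6), 50)
  q <- quartiles(pb$volume_t0)
  expect_gt(q$q25, 1800); expect_lt(q$q75, 3800)
  # ledger medians equal table medians
  led <- attr(tab, "ledger")
  expect_equal(stats::median(led$volume_change[led$group == "DR"]), med_dr,
               tolerance = 1e-9)
  # d_pipo direction structure at T0
  t0 <- tab[tab$timepoint == "T0", ]
  dpp_am <- mean(t0$d_pipo[t0$disc_direction == "anteromedial"])
  dpp_al <- mean(t0$d_pipo[t0$disc_direction == "anterolateral"])
  expect_lt(dpp_al, dpp_am)  # anterolateral joints sit lower posteromedially
})

test_that("null cohorts reject at the nominal rate; shifted cohorts have power", {
  null_change <- list(DD = list(median = 0, q25 = -160, q75 = 160),
                      DR = list(median = 0, q25 = -160, q75 = 160))
  set.seed(404)
  n_rep <- 400L
  rej <- 0L
  for (k in seq_len(n_rep)) {
    sp <- cohort_spec(n_per_group = 30, seed = sample.int(1e6, 1),
                      volume_change = null_change)
    pb <- sum_bilateral(simulate_cohort(sp))
    p <- mann_whitney(pb$volume_change[pb$group == "DD"],
                      pb$volume_change[pb$group == "DR"],
                      mode = "asymptotic")$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.025)
  # location shift 250, scale ~240: rejection rate > 0.9
  shift_change <- list(DD = list(median = 0, q25 = -180, q75 = 180),
                       DR = list(median = 250, q25 = 70, q75 = 430))
  rej <- 0L
  for (k in 1:100) {
    sp <- cohort_spec(n_per_group = 30, seed = sample.int(1e6, 1),
                      volume_change = shift_change)
    pb <- sum_bilateral(simulate_cohort(sp))
    p <- mann_whitney(pb$volume_change[pb$group == "DD"],
                      pb$volume_change[pb$group == "DR"],
                      mode = "asymptotic")$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 100, 0.9)
})

test_that("rater simulation is seeded and degenerates correctly", {
  v <- stats::rnorm(12)
  m1 <- simulate_raters(v, 0.5, seed = 2)
  m2 <- simulate_raters(v, 0.5, seed = 2)
  expect_identical(m1, m2)
  m0 <- simulate_raters(v, 0, seed = 2)
  expect_equal(m0[, 1], v)
  expect_equal(m0[, 2], v)
})

test_that("skewed sampler reproduces the requested median and IQR", {
  set.seed(29)
  x <- condylomorph:::rskewed(40000, 279.6, 149.5, 434.1)
  expect_lt(abs(stats::median(x) - 279.6), 6)
  expect_lt(abs(stats::quantile(x, 0.25) - 149.5), 8)
  expect_lt(abs(stats::quantile(x, 0.75) - 434.1), 8)
  # right-skewed quartile spec: mean pulled above the median
  expect_gt(mean(x), stats::median(x))
  # left-skewed case mirrors, with tails still well-behaved
  y <- condylomorph:::rskewed(40000, 29.5, -138.4, 93.8)
  expect_lt(abs(stats::median(y) - 29.5), 4)
  expect_lt(abs(stats::quantile(y, 0.25) - (-138.4)), 8)
  expect_lt(mean(y), stats::median(y))
  expect_lt(max(abs(y - 29.5)), 8 * (93.8 + 138.4))
})
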