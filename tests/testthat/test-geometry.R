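test_that("reference mesh reproduces shell volume, areas and conformity", {
  mesh <- coarse_mesh(1.0)
  vols <- nucleomech:::tet_volumes(mesh$verts, mesh$tets)
  expect_gt(min(vols), 0)
  shell_vol <- sum(vols[mesh$region == 1])
  expect_lt(abs(shell_vol - pi / 3 * (4.1^3 - 3.9^3)) /
              (pi / 3 * (4.1^3 - 3.9^3)), 0.05)
  # curved quadratic facets improve on the flat-triangle areas
  fo <- facet_measures_cpp(mesh$Xp2, mesh$outer_facets$nodes6,
                           numeric(3 * mesh$n_p2))
  expect_lt(abs(sum(fo$area_ref) - pi * 4.1^2) / (pi * 4.1^2), 0.005)
  # conformity: every interior face is shared by exactly two tets
  faces <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
                 mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  fk <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  expect_true(all(table(fk) <= 2))
  # inner facet centroids sit on the inner sphere
  cent <- (mesh$verts[mesh$inner_tri[, 1], ] +
           mesh$verts[mesh$inner_tri[, 2], ] +
           mesh$verts[mesh$inner_tri[, 3], ]) / 3
  r <- sqrt(rowSums(sweep(cent, 2, mesh$center)^2))
  expect_true(all(abs(r - 3.9) < mesh$shell$hedge / 4))
})

test_that("mesh measures converge to the closed forms at second order", {
  err <- sapply(c(1.2, 0.6), function(h) {
    mesh <- build_reference_mesh(shell_geometry(hedge = h))
    vols <- nucleomech:::tet_volumes(mesh$verts, mesh$tets)
    abs(sum(vols[mesh$region == 1]) - pi / 3 * (4.1^3 - 3.9^3))
  })
  # halving the edge length should reduce the error by about 4x
  expect_gt(err[1] / err[2], 3)
})

test_that("degenerate shell specifications are rejected", {
  expect_error(shell_geometry(R0 = 4.1, DT = 4.2))
  expect_error(nanopillar_array(r_np = 0.5, h_np = 1, p_np = 0.7))
})

test_that("reference normals and tangent frames form orthonormal triads", {
  sh <- shell_geometry()
  expect_equal(as.numeric(reference_normal(c(0, 0, sh$znuc + 2 * 4.1), sh)),
               c(0, 0, 1))
  expect_equal(as.numeric(reference_normal(c(0, 0, sh$znuc), sh)),
               c(0, 0, -1))
  expect_equal(as.numeric(reference_normal(c(4.1, 0, sh$znuc + 4.1), sh)),
               c(1, 0, 0))
  expect_error(reference_normal(sh$center, sh))
  # example frame at the equator point
  fr <- tangent_frame(c(4.1, 0, sh$znuc + 4.1), sh)
  expect_equal(as.numeric(fr$e_theta), c(0, 1, 0))
  expect_equal(as.numeric(fr$e_phi), c(0, 0, -1))
  set.seed(7)
  th <- runif(1000, 0.05, pi - 0.05); ph <- runif(1000, 0.05, pi / 2 - 0.05)
  X <- cbind(4 * sin(th) * cos(ph), 4 * sin(th) * sin(ph),
             sh$znuc + 4.1 + 4 * cos(th))
  N <- reference_normal(X, sh)
  fr <- tangent_frame(X, sh)
  expect_equal(rowSums(fr$e_theta^2), rep(1, 1000), tolerance = 1e-12)
  expect_equal(rowSums(fr$e_phi^2), rep(1, 1000), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(fr$e_theta * N))), 1e-12)
  expect_lt(max(abs(rowSums(fr$e_theta * fr$e_phi))), 1e-12)
})

test_that("sharp pillar indicator follows the lattice geometry", {
  sp <- nanopillar_array(r_np = 0.2, h_np = 1.5, p_np = 2, r_max = 7.5)
  expect_identical(pillar_indicator(0, 0, sp), 1L)
  expect_identical(pillar_indicator(1, 1, sp), 0L)
  expect_identical(pillar_indicator(2.1, 0, sp), 1L)
  expect_identical(pillar_indicator(0, 0, flat_substrate()), 0L)
})

test_that("smooth indicator approximates the sharp one", {
  sp <- nanopillar_array(r_np = 0.2, h_np = 1.5, p_np = 5, r_max = 7.5)
  expect_equal(pillar_indicator_smooth(0, 0, sp), 1, tolerance = 1e-6)
  # at the super-Gaussian width the value is exp(-1/2)
  expect_equal(pillar_indicator_smooth(0.25, 0, sp), exp(-0.5),
               tolerance = 1e-6)
  expect_lt(pillar_indicator_smooth(2.5, 0, sp), 1e-6)
  # never more than ~0.4 below the sharp indicator on a grid of specs
  for (p in c(2, 3, 5)) {
    spp <- nanopillar_array(0.2, 1.5, p, 7.5)
    xs <- seq(-3, 3, by = 0.05)
    sharp <- pillar_indicator(xs, rep(0, length(xs)), spp)
    smooth <- pillar_indicator_smooth(xs, rep(0, length(xs)), spp)
    expect_true(all(smooth >= sharp - 0.4))
  }
})

test_that("PM distance, curvature and the F-actin field follow the cylinder model", {
  sp <- nanopillar_array(r_np = 0.2, h_np = 1.5, p_np = 5, r_max = 7.5)
  pm <- pm_distance_and_curvature(c(0, 0, 1.0), sp, d_steric = 0.2)
  expect_equal(pm$d_top, 1.2)
  pm2 <- pm_distance_and_curvature(c(1.2, 0, -0.5), sp, d_steric = 0.2)
  expect_equal(pm2$d_side, 1.0)
  expect_equal(pm2$H_pm, 1 / (2 * 0.25))
  kin <- kinetic_params()
  # flat substrate at the floor: F0 + F1
  expect_equal(
    factin_concentration(c(1, 1, -0.2), flat_substrate(), kin), 160)
  # far from the substrate the baseline is recovered
  expect_equal(
    factin_concentration(c(0, 0, 8), flat_substrate(), kin), kin$F0_flat,
    tolerance = 1e-4)
  # pillar side at contact: side term carries the curvature boost
  fside <- factin_concentration(c(0.25, 0, -0.7), sp, kin)
  expect_equal(fside, 100 + 20 * exp(1 / (2 * 0.25) / 2), tolerance = 0.01)
  # continuity across the pillar shoulder (max construction)
  path <- cbind(seq(0, 1.2, by = 0.002), 0,
                0.3 - seq(0, 1.2, by = 0.002) * 0.5)
  fv <- factin_concentration(path, sp, kin)
  expect_lt(max(abs(diff(fv))), 1.0)
  expect_true(all(fv >= 100))
})
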