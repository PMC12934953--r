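test_that("reference transport maps reproduce geometric measures", {
  mesh <- coarse_mesh(1.0)
  geom <- transport_geometry(mesh)
  maps <- transport_maps(geom, mesh$verts)
  expect_equal(maps$vol_tot, pi / 3 * 4.1^3, tolerance = 0.05)
  expect_equal(maps$area_out, pi * 4.1^2, tolerance = 0.02)
  expect_equal(maps$area_inner, pi * 3.9^2, tolerance = 0.02)
  # concentric map at rest: inner stretch equals the squared radius ratio
  im <- inner_surface_maps(mesh)
  expect_equal(mean(im$alpha_inner), (3.9 / 4.1)^2, tolerance = 1e-6)
  expect_equal(mean(im$alpha_inner_rel), 1, tolerance = 1e-9)
  # inner normals at rest are radial
  cent <- (mesh$verts[mesh$inner_tri[, 1], ] + mesh$verts[mesh$inner_tri[, 2], ] +
           mesh$verts[mesh$inner_tri[, 3], ]) / 3
  Nref <- sweep(cent, 2, mesh$center)
  Nref <- Nref / sqrt(rowSums(Nref^2))
  expect_lt(max(abs(rowSums(Nref * im$n_inner) - 1)), 1e-3)
})

test_that("inner map composes with homogeneous dilation", {
  mesh <- coarse_mesh(1.0)
  # prescribed dilation applied as a displacement of the shell P2 nodes
  lam <- 1.15
  u <- as.vector(t((lam - 1) * sweep(mesh$Xp2, 2, mesh$center)))
  st <- list(u = u)
  im <- inner_surface_maps(mesh, st)
  expect_equal(mean(im$alpha_inner), lam^2 * (3.9 / 4.1)^2, tolerance = 1e-6)
})

test_that("dilution conserves totals exactly under prescribed deformation", {
  mesh <- coarse_mesh(1.2)
  geom <- transport_geometry(mesh)
  maps0 <- transport_maps(geom, mesh$verts)
  for (kind in c("dilation", "squash")) {
    x1 <- prescribed_deformation(mesh, kind, s = if (kind == "dilation") 1.26 else 0.7)
    maps1 <- transport_maps(geom, x1)
    set.seed(3)
    u <- runif(geom$nv, 0.5, 2)
    v <- runif(geom$n_ang, 0.5, 2)
    u1 <- step_volume_species(u, 0, 10, maps0, maps1, geom)
    expect_equal(sum(u1 * maps1$w_vol), sum(u * maps0$w_vol),
                 tolerance = 1e-12)
    v1 <- step_surface_species(v, 0, 10, maps0, maps1, geom)
    expect_equal(sum(v1 * maps1$w_out), sum(v * maps0$w_out),
                 tolerance = 1e-12)
    l1 <- step_lamin(v, 0, 10, maps0, maps1, geom)
    expect_equal(sum(l1 * maps1$w_inner), sum(v * maps0$w_inner),
                 tolerance = 1e-12)
    # uniform dilation of a uniform field scales by exactly 1/J (1/alpha)
    if (kind == "dilation") {
      w1 <- step_volume_species(rep(2, geom$nv), 0, 10, maps0, maps1, geom)
      expect_equal(w1, rep(2 / 1.26^3, geom$nv), tolerance = 1e-9)
      s1 <- step_surface_species(rep(2, geom$n_ang), 0, 10, maps0, maps1, geom)
      expect_equal(s1, rep(2 / 1.26^2, geom$n_ang), tolerance = 1e-9)
    }
  }
})

test_that("static domain, no reactions: fields unchanged; decay matches exp", {
  mesh <- coarse_mesh(1.2)
  geom <- transport_geometry(mesh)
  maps <- transport_maps(geom, mesh$verts)
  u <- rep(1.5, geom$nv)
  u1 <- step_volume_species(u, 4.0, 25, maps, maps, geom)
  expect_equal(u1, u, tolerance = 1e-12)
  # implicit Euler decay error is O(dt^2) against the closed form
  k <- 0.01
  for (dt in c(5, 2.5)) {
    nsteps <- round(100 / dt)
    v <- rep(1, geom$n_ang)
    for (i in seq_len(nsteps))
      v <- step_surface_species(v, 0.001, dt, maps, maps, geom, impl = k)
    err <- abs(v[1] - exp(-k * 100))
    expect_lt(err, 1.1 * k^2 * dt * 100 / 2 * exp(-k * 100) + 1e-12)
  }
})

test_that("splitting error decreases linearly with dt on a moving domain", {
  mesh <- coarse_mesh(1.2)
  geom <- transport_geometry(mesh)
  # sinusoidal dilation path s(t); compare dt against dt/2 against dt/4
  s_of_t <- function(t) 1 + 0.2 * sin(pi * t / 100)
  run <- function(dt) {
    u <- rep(1, geom$nv) + 0.3 * sin(mesh$verts[, 3])
    maps_old <- transport_maps(geom, prescribed_deformation(mesh, "dilation", s_of_t(0)))
    t <- 0
    while (t < 100 - 1e-9) {
      t <- t + dt
      maps_new <- transport_maps(geom, prescribed_deformation(mesh, "dilation", s_of_t(t)))
      u <- step_volume_species(u, 1.0, dt, maps_old, maps_new, geom)
      maps_old <- maps_new
    }
    u
  }
  u1 <- run(25); u2 <- run(12.5); u4 <- run(6.25)
  e1 <- sqrt(sum((u1 - u4)^2)); e2 <- sqrt(sum((u2 - u4)^2))
  expect_gt(e1 / e2, 1.6)  # first-order splitting: error ~ dt
})

test_that("NPC pair exchange conserves the pointwise sum and totals", {
  mesh <- coarse_mesh(1.2)
  geom <- transport_geometry(mesh)
  maps <- transport_maps(geom, mesh$verts)
  set.seed(11)
  npc <- runif(geom$n_ang, 3, 5)
  npca <- runif(geom$n_ang, 0, 1)
  kf <- runif(geom$n_ang, 0.01, 0.2)
  tot0 <- npc + npca
  out <- step_npc_pair(npc, npca, kf, 8.7, 0, 1.0, maps, maps, geom)
  # zero diffusion: activation/deactivation moves mass pointwise only
  expect_equal(out$npc + out$npca, tot0, tolerance = 1e-10)
  # with diffusion the total over the surface is still conserved
  out2 <- step_npc_pair(npc, npca, kf, 8.7, 0.001, 50, maps, maps, geom)
  expect_equal(sum((out2$npc + out2$npca) * maps$w_out),
               sum(tot0 * maps$w_out), tolerance = 1e-9)
})

test_that("positivity is preserved by the implicit steps", {
  mesh <- coarse_mesh(1.2)
  geom <- transport_geometry(mesh)
  maps0 <- transport_maps(geom, mesh$verts)
  maps1 <- transport_maps(geom, prescribed_deformation(mesh, "squash", 0.8))
  set.seed(5)
  u <- runif(geom$nv)
  u[sample(geom$nv, 50)] <- 0
  for (i in 1:10) u <- step_volume_species(u, 4, 10, maps0, maps1, geom,
                                           impl = 0.01)
  expect_gt(min(u), -1e-10)
})
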