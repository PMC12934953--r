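test_that("pointwise kinematics match closed forms", {
  k0 <- kinematics_point(diag(3), N = c(1, 0, 0))
  expect_equal(k0$I1, 3); expect_equal(k0$I2, 3); expect_equal(k0$J, 1)
  expect_equal(k0$alpha, 1)
  expect_equal(as.numeric(k0$n), c(1, 0, 0))
  # homogeneous dilation
  kd <- kinematics_point(1.2 * diag(3), N = c(0, 0, 1))
  expect_equal(kd$J, 1.2^3)
  expect_equal(kd$alpha, 1.2^2)
  # uniaxial stretch along the normal leaves the transverse area unchanged
  ku <- kinematics_point(diag(c(1.4, 1, 1)), N = c(1, 0, 0))
  expect_equal(ku$alpha, 1)
})

test_that("stress evaluation matches the incompressible uniaxial closed form", {
  pars <- material_params()
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  # choose p to cancel the lateral Cauchy stress
  s0 <- evaluate_stress(F, 0, pars)
  p <- s0$sigma[2, 2]
  s <- evaluate_stress(F, p, pars)
  expect_equal(s$sigma[2, 2], 0, tolerance = 1e-9)
  sigma_axial <- 2 * (pars$E1 + pars$E2 / lam) * (lam^2 - 1 / lam)
  expect_equal(s$sigma[1, 1], sigma_axial, tolerance = 1e-6 * sigma_axial)
  # stress-free reference
  sref <- evaluate_stress(diag(3), 0, pars)
  expect_equal(sref$W, 0)
  expect_equal(max(abs(sref$sigma)), 0)
})

test_that("analytic stress agrees with numerical differentiation of W", {
  pars <- material_params()
  Wof <- function(F, p) evaluate_stress(F, p, pars)$W
  for (F in random_def_grads(6)) {
    p <- runif(1, -500, 500)
    tk <- evaluate_stress(F, p, pars)$t_pk
    num <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fm <- F
      Fp[i, j] <- Fp[i, j] + h; Fm[i, j] <- Fm[i, j] - h
      num[i, j] <- (Wof(Fp, p) - Wof(Fm, p)) / (2 * h)
    }
    expect_equal(unname(tk), unname(num), tolerance = 1e-4)
    # Cauchy stress symmetry
    sig <- evaluate_stress(F, p, pars)$sigma
    expect_equal(sig, t(sig), tolerance = 1e-8 * max(abs(sig)))
  }
})

test_that("cap schedule, cap profile, contact law and pressure update follow their formulas", {
  sh <- shell_geometry()
  expect_equal(cap_stress_schedule(0, 800, 1000), 0)
  expect_equal(cap_stress_schedule(1000, 800, 1000), 800 * (1 - exp(-1)))
  expect_equal(cap_stress_schedule(1e9, 800, 1000), 800)
  ztop <- sh$znuc + 2 * sh$R0
  expect_equal(cap_stress_profile(ztop, 500, 2.05, sh), 500)
  expect_equal(cap_stress_profile(ztop - 2.05, 500, 2.05, sh), 500 * exp(-1))
  pars <- material_params()
  expect_equal(contact_repulsion(pars$d_steric, pars), pars$sigma_contact0)
  expect_equal(contact_repulsion(2 * pars$d_steric, pars),
               pars$sigma_contact0 * exp(-1))
  expect_equal(update_pressure(500, 10, 10, 100), 500)
  expect_equal(update_pressure(500, 9, 10, 100), 500 + 100 * (1 / 9))
  # compression always raises the pressure
  expect_gt(update_pressure(500, 8, 10, 100), 500)
})

test_that("free-shell inflation matches the thick-sphere oracle", {
  mesh <- coarse_mesh(1.0)
  pars <- material_params()
  st <- inflated_state(300, 1.0)
  expect_true(st$converged)
  orc <- balloon_oracle(300, mesh$shell, pars)
  ov <- mesh$outer_vl
  xd <- mesh$Xp2[ov, ] + matrix(st$u[as.vector(t(outer(3 * (ov - 1), 1:3, `+`)))],
                                ncol = 3, byrow = TRUE)
  r <- sqrt(rowSums(sweep(xd, 2, mesh$center)^2))
  expect_lt(abs(mean(r) - orc$r_outer) / orc$r_outer, 0.02)
  # incompressibility of the accepted solution
  expect_lt(shell_volume_check(mesh, st)$dev, 2e-4)
  # reference equilibrium: no loads -> no displacement
  st0 <- solve_equilibrium(mesh, list(sigma_cap = 0, dP = 0), pars,
                           z_symmetry = TRUE)
  expect_lt(max(abs(st0$u)), 1e-10)
})

test_that("membrane tension of the inflated sphere matches the Laplace scaling", {
  mesh <- coarse_mesh(1.0)
  pars <- material_params()
  st <- inflated_state(300, 1.0)
  orc <- balloon_oracle(300, mesh$shell, pars)
  mt <- membrane_tension(mesh, st, pars)
  # bilayer tension = (dz_hat / deformed thickness) x Laplace wall tension
  h_def <- orc$thickness
  gamma_exp <- 1e-3 * pars$dz_hat / h_def * 300 * orc$r_outer / 2
  gm <- mean(mt$gamma_mN_m)
  expect_lt(abs(gm - gamma_exp) / gamma_exp, 0.15)
  # near-uniform over the sphere
  expect_lt(max(mt$gamma_mN_m) / gm, 1.15)
  # stress-free state has zero tension
  st0 <- solve_equilibrium(mesh, list(sigma_cap = 0, dP = 0), pars,
                           z_symmetry = TRUE)
  mt0 <- membrane_tension(mesh, st0, pars)
  expect_lt(max(abs(mt0$gamma_mN_m)), 1e-10)
})

test_that("nucleoplasm extension honors its boundary data and rigid motions", {
  mesh <- coarse_mesh(1.0)
  pars <- material_params()
  # zero boundary displacement -> zero extension
  st0 <- list(u = numeric(3 * mesh$n_p2))
  ext0 <- extend_displacement_to_nucleoplasm(mesh, st0, pars)
  expect_true(ext0$converged)
  expect_lt(max(abs(ext0$u_nuc)), 1e-10)
  # rigid translation along z maps through exactly
  stz <- list(u = rep(c(0, 0, 0.3), mesh$n_p2))
  extz <- extend_displacement_to_nucleoplasm(mesh, stz, pars)
  nuc_ids <- unique(as.vector(mesh$tets[mesh$region == 2, ]))
  uz <- matrix(extz$u_nuc, ncol = 3, byrow = TRUE)[nuc_ids, ]
  expect_equal(max(abs(uz[, 1:2])), 0, tolerance = 1e-8)
  expect_equal(range(uz[, 3]), c(0.3, 0.3), tolerance = 1e-6)
})

test_that("inflation under a substrate engages floor contact without penetration", {
  mesh <- coarse_mesh(1.0)
  pars <- material_params()
  st <- inflate_shell(mesh, pars, 820, pillars = flat_substrate(),
                      n_steps = 8)
  expect_true(st$converged)
  expect_gt(length(st$active), 0)
  zdef <- mesh$Xp2[, 3] + st$u[seq(3, 3 * mesh$n_p2, by = 3)]
  expect_gt(min(zdef), -1e-6)
  fixture_env$flat_inflated <- st
})

test_that("swapping the x and y axes leaves the inflated solution invariant", {
  mesh <- coarse_mesh(1.0)
  st <- inflated_state(300, 1.0)
  # mirror map on the angular grid: vertex at (x, y, z) <-> vertex at (y, x, z)
  X <- mesh$Xp2[seq_len(mesh$n_sv), ]
  key <- function(M) paste(round(M[, 1], 7), round(M[, 2], 7), round(M[, 3], 7))
  mir <- match(key(cbind(X[, 2], X[, 1], X[, 3])), key(X))
  expect_false(any(is.na(mir)))
  # the subdivision diagonals of the triangulation break exact mirror
  # symmetry, so fields agree to discretization (not solver) tolerance
  U <- matrix(st$u[seq_len(3 * mesh$n_sv)], ncol = 3, byrow = TRUE)
  expect_equal(U[mir, c(2, 1, 3)], U, tolerance = 0.01)
  # scalar outputs are unchanged under the axis swap to much tighter
  # tolerance
  r_mir <- sqrt(rowSums(sweep(mesh$Xp2[seq_len(mesh$n_sv), ] + U, 2,
                              mesh$center)^2))
  expect_equal(mean(r_mir[mir]), mean(r_mir), tolerance = 1e-12)
})
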