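test_that("lamin cycling rates follow the Hill-modulated mass action laws", {
  kin <- kinetic_params()
  expect_equal(lamin_dephos_rate(0, kin), 0)
  r <- lamin_cycling_rates(L = 1000, Lphos = 0, Fconc = 160, kin)
  expect_equal(r$phos, kin$krl * 1000)
  expect_equal(r$dephos, 0)
  # arithmetic check of the Hill factor at [F] = 160 uM
  h <- kin$pcyto * 160^2.6
  expect_equal(lamin_dephos_rate(160, kin), kin$kfl * h / (kin$CL + h))
})

test_that("NPC activation has mass-action structure and conserves the pair", {
  kin <- kinetic_params()
  r0 <- npc_activation_rates(0, 1, 140, 2980, kin)
  expect_equal(r0$forward, 0)
  r <- npc_activation_rates(5, 1, 140, 2980, kin)
  # steady-state active fraction
  kf <- kin$kfNPC * 140 * 2980 * kin$MA
  frac <- kf / (kf + kin$krNPC)
  tot <- 5
  npca_ss <- tot * frac
  rss <- npc_activation_rates(tot - npca_ss, npca_ss, 140, 2980, kin)
  expect_equal(rss$forward, rss$reverse, tolerance = 1e-12)
})

test_that("stretch-gated import rate matches its closed form and is monotone", {
  kin <- kinetic_params()
  expect_equal(yap_import_rate(1.2, 1.2, 0, kin), kin$phi_scale * kin$kin_b)
  expect_equal(yap_import_rate(1.2 + kin$alpha0, 1.2, 0, kin),
               exp(1) * kin$phi_scale * kin$kin_b)
  set.seed(9)
  for (i in 1:50) {
    a <- runif(2, 0.8, 2); a <- sort(a)
    n <- sort(runif(2, 0, 1))
    expect_lte(yap_import_rate(a[1], 1, n[1], kin),
               yap_import_rate(a[2], 1, n[1], kin))
    expect_lte(yap_import_rate(a[1], 1, n[1], kin),
               yap_import_rate(a[1], 1, n[2], kin))
    # NPC forward rate monotone in each modifier
    expect_lte(npc_activation_rates(1, 0, 100, 2000, kin)$forward,
               npc_activation_rates(1, 0, 100 + 50 * runif(1), 2000, kin)$forward)
  }
})

test_that("cytosolic pools follow global conservation and the free fraction", {
  kin <- kinetic_params()
  # all YAP nuclear -> empty cytosol
  cyt <- cytosolic_yap(kin$NY, 152, 140, kin)
  expect_equal(cyt$Ycyto, 0)
  # no nuclear YAP
  cyt0 <- cytosolic_yap(0, 152, 140, kin)
  expect_equal(cyt0$Ycyto, kin$NY / (kin$Nconv * (kin$voltot - 152)))
  # free fraction reduces to kCN/(kNC + kCN) without actomyosin
  kin2 <- kinetic_params(kCY = 0)
  cf <- cytosolic_yap(1e5, 152, 140, kin2)
  expect_equal(cf$free_fraction, 0.56 / (0.14 + 0.56))
  expect_error(cytosolic_yap(0, kin$voltot + 1, 140, kin))
})

test_that("steady-state initialization reproduces the tabulated values", {
  # literal (bare-rate) expressions reproduce the printed reference density
  kin_lit <- kinetic_params(ss_hill = FALSE)
  ss <- initial_steady_state(table_measures(), kin_lit, Fconc = 140)
  expect_equal(ss$L, 2980, tolerance = 0.01)
  # NPC partition sums to the total surface density
  expect_equal(ss$npc + ss$npca, 594.7 / 118.4, tolerance = 1e-9)
  # low-lamin preset scales the density by the total (linearity)
  kin_lo <- kinetic_params(ss_hill = FALSE, NL = 1.601e5)
  ss_lo <- initial_steady_state(table_measures(), kin_lo, Fconc = 140)
  expect_equal(ss_lo$L / ss$L, 1.601e5 / 3.202e5, tolerance = 1e-3)
  # the default (Hill-consistent) state is a fixed point of the cycling ODE
  kin_h <- kinetic_params(ss_hill = TRUE)
  ssh <- initial_steady_state(table_measures(), kin_h, Fconc = 140)
  r <- lamin_cycling_rates(ssh$L, ssh$Lphos, 140, kin_h)
  expect_equal(r$phos, r$dephos, tolerance = 1e-9 * r$phos)
  # N/C at initialization equals the closed-form balance ratio
  fr <- ssh$cytosol$free_fraction
  k1 <- fr * kin_h$phi_scale * (kin_h$kin_b + kin_h$kin * ssh$npca)
  expect_equal(ssh$nc_ratio, k1 / kin_h$kout, tolerance = 0.005)
  # YAP boundary flux balances at initialization
  kt <- yap_import_rate(1.3, 1.3, ssh$npca, kin_h)
  expect_equal(yap_boundary_flux(ssh$Ynuc, ssh$cytosol$Yfree, kt, kin_h), 0,
               tolerance = 1e-12)
})

test_that("stiffness scale is 1 at the reference density and keeps the membrane floor", {
  kin <- kinetic_params(L_ref = 2980)
  expect_equal(stiffness_scale(2980, kin), 1)
  expect_equal(stiffness_scale(0, kin), 0.5)
  kin0 <- kinetic_params(phi_L = 0, L_ref = 2980)
  expect_equal(stiffness_scale(c(0, 500, 9000), kin0), rep(1, 3))
})

test_that("force per lamin converts units and guards low densities", {
  expect_equal(as.numeric(force_per_lamin(1000, 2980)), 1000 / 2980)
  expect_equal(as.numeric(force_per_lamin(0, 2980)), 0)
  expect_equal(as.numeric(force_per_lamin(100, 500)),
               2 * as.numeric(force_per_lamin(100, 1000)))
  fl <- force_per_lamin(100, 0.1)
  expect_true(attr(fl, "flagged"))
  expect_equal(as.numeric(fl), 100)
})
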