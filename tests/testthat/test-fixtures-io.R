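test_that("balloon oracle is exact at zero load and conserves wall volume", {
  orc0 <- balloon_oracle(0)
  expect_equal(orc0$r_outer, 4.1)
  expect_equal(orc0$thickness, 0.2)
  orc <- balloon_oracle(500)
  ro <- orc$r_outer; ri <- ro - orc$thickness
  expect_equal(ro^3 - ri^3, 4.1^3 - 3.9^3, tolerance = 1e-6)
  # pressure-radius relation is monotone over the working range
  expect_gt(orc$P_of_r(5.5), orc$P_of_r(4.5))
})

test_that("prescribed deformations keep positive volumes", {
  mesh <- coarse_mesh(1.2)
  for (kind in c("dilation", "squash", "inflation")) {
    x <- prescribed_deformation(mesh, kind, 0.8)
    expect_gt(min(nucleomech:::tet_volumes(x, mesh$tets)), 0)
  }
})

test_that("configuration round-trips through YAML", {
  cfg <- sim_config(shell = shell_geometry(hedge = 0.7),
                    pillars = nanopillar_array(0.2, 1.5, 4.0),
                    kinetics = kinetic_params(NL = 1.601e5, MA = 2),
                    schedule = sim_schedule(sigma_max = 400, t_end = 2000),
                    seed = 7L)
  path <- tempfile(fileext = ".yml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$shell$R0, cfg$shell$R0)
  expect_equal(cfg2$pillars$p_np, 4.0)
  expect_equal(cfg2$kinetics$NL, 1.601e5)
  expect_equal(cfg2$kinetics$MA, 2)
  expect_equal(cfg2$schedule$sigma_max, 400)
  expect_equal(cfg2$seed, 7L)
  # second round trip is the identity
  path2 <- tempfile(fileext = ".yml")
  write_config(cfg2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("scalar log appends and guards its column set", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 50), vol_nuc = c(152, 150))
  append_scalar_log(df, path)
  append_scalar_log(data.frame(t = 100, vol_nuc = 148), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$vol_nuc[3], 148)
  expect_error(append_scalar_log(data.frame(bad = 1), path))
})

test_that("mesh export writes a well-formed MSH file", {
  mesh <- coarse_mesh(1.2)
  path <- tempfile(fileext = ".msh")
  write_msh(mesh, path)
  lines <- readLines(path)
  expect_equal(lines[1], "$MeshFormat")
  nv <- as.integer(lines[which(lines == "$Nodes") + 1])
  expect_equal(nv, nrow(mesh$verts))
  ne <- as.integer(lines[which(lines == "$Elements") + 1])
  expect_equal(ne, nrow(mesh$tets) + nrow(mesh$outer_tri) + nrow(mesh$inner_tri))
})

test_that("coarse fixtures build consistent mesh/config pairs", {
  fx <- make_coarse_fixture("pillar200_coarse", hedge = 1.2)
  expect_s3_class(fx$mesh, "ne_mesh")
  expect_equal(fx$config$pillars$r_np, 0.2)
  expect_equal(fx$config$pillars$h_np, 1.5)
  expect_equal(fx$config$pillars$p_np, 5.0)
  expect_false(fx$z_symmetry)
  fx2 <- make_coarse_fixture("sphere_free", hedge = 1.2)
  expect_true(fx2$z_symmetry)
  expect_error(make_coarse_fixture("nope"))
})
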