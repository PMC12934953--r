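# Test fixtures, the independent inflation oracle, prescribed-deformation
# harnesses and configuration / log I/O.

#' Coarse simulation fixtures
#'
#' Ready-made mesh + configuration pairs at test-scale resolution:
#' `"flat_coarse"` (flat substrate), `"pillar200_coarse"` (0.2 um pillars,
#' 1.5 um tall, 5 um pitch) and `"sphere_free"` (no substrate, pure
#' inflation with z-mirror symmetry).
#'
#' @param preset Fixture name.
#' @param hedge Mesh edge length (um); the coarse default keeps the mesh
#'   small enough for interactive tests.
#' @param t_end Shortened schedule end time (s).
#' @return List with `mesh`, `config`, and `z_symmetry` flag.
#' @export
make_coarse_fixture <- function(preset = c("flat_coarse", "pillar200_coarse",
                                           "sphere_free"),
                                hedge = 0.8, t_end = 500) {
  preset <- match.arg(preset)
  shell <- shell_geometry(hedge = hedge)
  pillars <- switch(preset,
                    flat_coarse = flat_substrate(),
                    pillar200_coarse = nanopillar_array(0.2, 1.5, 5.0),
                    sphere_free = flat_substrate())
  cfg <- sim_config(shell = shell, pillars = pillars,
                    schedule = sim_schedule(t_end = t_end))
  mesh <- build_reference_mesh(shell)
  list(mesh = mesh, config = cfg, z_symmetry = preset == "sphere_free")
}

#' Closed-form thick-sphere inflation oracle
#'
#' Independent 1-D solution of the incompressible Mooney-Rivlin
#' thick-sphere inflation: for a radial incompressible deformation the
#' stored energy is a single quadrature over the wall, and the pressure is
#' its derivative with respect to the enclosed volume. Solved for the
#' deformed outer radius by root finding; completely independent of the
#' finite-element code path.
#'
#' @param dP Transmembrane pressure (Pa).
#' @param shell A [shell_geometry()].
#' @param params A [material_params()] (uses `E1`, `E2`).
#' @return List `r_outer`, `thickness` (um), and the pressure function
#'   `P_of_r`.
#' @export
balloon_oracle <- function(dP, shell = shell_geometry(),
                           params = material_params()) {
  R0 <- shell$R0; Ri <- R0 - shell$DT
  E1 <- params$E1; E2 <- params$E2
  Wfun <- function(lam) {
    I1 <- 2 * lam^2 + lam^-4
    I2 <- lam^4 + 2 * lam^-2
    E1 * (I1 - 3) + E2 * (I2 - 3)
  }
  shell_const <- R0^3 - Ri^3
  E_total <- function(ro) {
    f <- function(R) {
      r <- (ro^3 - (R0^3 - R^3))^(1 / 3)
      Wfun(r / R) * 4 * pi * R^2
    }
    stats::integrate(f, Ri, R0, rel.tol = 1e-10)$value
  }
  P_of_r <- function(ro) {
    h <- 1e-5
    (E_total(ro + h) - E_total(ro - h)) / (2 * h) / (4 * pi * ro^2)
  }
  if (dP == 0) {
    return(list(r_outer = R0, thickness = shell$DT, P_of_r = P_of_r))
  }
  ro <- stats::uniroot(function(r) P_of_r(r) - dP, c(R0 * 1.0001, R0 * 3),
                       tol = 1e-8)$root
  ri <- (ro^3 - shell_const)^(1 / 3)
  list(r_outer = ro, thickness = ro - ri, P_of_r = P_of_r)
}

#' Prescribed closed-form deformations for transport tests
#'
#' Families of analytic deformations of the reference vertices, used to
#' exercise the transport splitting without the mechanics solver:
#' uniform dilation about the shell center, uniaxial squash along z, and
#' radial inflation of the whole domain.
#'
#' @param mesh Mesh.
#' @param kind One of `"dilation"`, `"squash"`, `"inflation"`.
#' @param s Deformation parameter: linear scale for dilation/inflation,
#'   z-compression factor for squash.
#' @return nv x 3 matrix of deformed vertex coordinates (J > 0 for
#'   s in (0, +inf)).
#' @export
prescribed_deformation <- function(mesh, kind = c("dilation", "squash",
                                                  "inflation"), s = 1.1) {
  kind <- match.arg(kind)
  stopifnot(s > 0)
  ctr <- mesh$center
  D <- sweep(mesh$verts, 2, ctr)
  x <- switch(kind,
              dilation = sweep(D * s, 2, ctr, `+`),
              squash = sweep(cbind(D[, 1] / sqrt(s), D[, 2] / sqrt(s),
                                   D[, 3] * s), 2, ctr, `+`),
              inflation = sweep(D * s, 2, ctr, `+`))
  x
}

#' Write / read a simulation configuration (YAML)
#'
#' Round-trippable serialization of a [sim_config()] with field names
#' mirroring the parameter tables (`sigma_max`, `t0_cap`, `r_np`, `p_np`,
#' `h_np`, `phi_L`, ...).
#' @param config A [sim_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, logical(1))]
  }
  obj <- list(shell = strip(config$shell)[c("R0", "DT", "znuc", "hedge", "Droof")],
              pillars = strip(config$pillars)[c("r_np", "h_np", "p_np", "r_max")],
              material = strip(config$material),
              kinetics = strip(config$kinetics),
              schedule = strip(config$schedule),
              seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  null_ok <- function(v) if (is.null(v)) NULL else v
  sim_config(
    shell = do.call(shell_geometry, obj$shell),
    pillars = do.call(nanopillar_array, obj$pillars),
    material = do.call(material_params, obj$material),
    kinetics = do.call(kinetic_params,
                       c(obj$kinetics[setdiff(names(obj$kinetics), "L_ref")],
                         list(L_ref = null_ok(obj$kinetics$L_ref)))),
    schedule = do.call(sim_schedule, obj$schedule),
    seed = obj$seed)
}

#' Append scalar rows to a CSV log
#'
#' Writes with a fixed column set; creates the file with a header on first
#' use, appends (and checks columns) afterwards.
#' @param df Data frame of rows.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
append_scalar_log <- function(df, path) {
  if (!file.exists(path)) {
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, qmethod = "double")
  } else {
    hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
    if (!identical(hdr, names(df)))
      stop("column mismatch appending to ", path)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE, qmethod = "double")
  }
  invisible(path)
}

#' Write a run manifest (JSON)
#'
#' Records the configuration, package version and session seeds alongside
#' the outputs, so a scalar log can be traced to its exact inputs.
#' @param config [sim_config()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  obj <- c(list(package = "nucleomech",
                version = as.character(utils::packageVersion("nucleomech")),
                r_version = R.version.string,
                seed = config$seed,
                config = yaml::read_yaml(tmp)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Writes vertices and tetrahedra (physical tag 1 = NE shell,
#' 2 = nucleoplasm) plus the tagged outer (11) and inner (12) surface
#' triangles, for inspection in external mesh viewers.
#' @param mesh Mesh.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$verts)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nv)), con)
  writeLines(sprintf("%d %.12g %.12g %.12g", seq_len(nv), mesh$verts[, 1],
                     mesh$verts[, 2], mesh$verts[, 3]), con)
  writeLines("$EndNodes", con)
  nt <- nrow(mesh$tets); no <- nrow(mesh$outer_tri); ni <- nrow(mesh$inner_tri)
  writeLines(c("$Elements", as.character(nt + no + ni)), con)
  k <- 0
  lines <- character(0)
  for (tag_tri in list(list(tri = mesh$outer_tri, tag = 11),
                       list(tri = mesh$inner_tri, tag = 12))) {
    tri <- tag_tri$tri
    lines <- c(lines, sprintf("%d 2 2 %d %d %d %d %d", k + seq_len(nrow(tri)),
                              tag_tri$tag, tag_tri$tag, tri[, 1], tri[, 2],
                              tri[, 3]))
    k <- k + nrow(tri)
  }
  lines <- c(lines, sprintf("%d 4 2 %d %d %d %d %d %d",
                            k + seq_len(nt), mesh$region, mesh$region,
                            mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                            mesh$tets[, 4]))
  writeLines(lines, con)
  writeLines("$EndElements", con)
  invisible(path)
}
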