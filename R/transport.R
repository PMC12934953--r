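# Reaction-transport on the deforming geometry.
#
# All species are P1 vertex fields. Advection enters exclusively through the
# multiplicative dilution correction of the splitting scheme: each step first
# solves implicit-Euler diffusion-reaction on the domain frozen at the new
# time, then multiplies concentrations by the ratio of old to new local
# measure (lumped vertex volumes/areas), which conserves lumped totals
# exactly under pure advection. Assembling mass/stiffness matrices on the
# deformed vertex coordinates is algebraically identical to the Lagrangian
# pullback formulation (J- and alpha-weighted inner products and pulled-back
# gradients) for piecewise-linear isoparametric elements.

#' Static index structures for transport
#'
#' @param mesh A [build_reference_mesh()] result.
#' @return List with the volume tetrahedra, nucleoplasm subset, outer and
#'   inner surface triangulations in global vertex numbering, and the
#'   angular-column maps between outer-surface vertices and global ids.
#' @export
transport_geometry <- function(mesh) {
  list(tets = mesh$tets, nuc_tets = mesh$tets[mesh$region == 2L, , drop = FALSE],
       outer_tri = mesh$outer_tri, inner_tri = mesh$inner_tri,
       outer_vg = mesh$outer_vg, inner_vg = mesh$inner_vg,
       n_ang = mesh$n_ang, nv = nrow(mesh$verts))
}

#' Deformed vertex coordinates of a coupled state
#'
#' Shell vertices move with the mechanical displacement; nucleoplasm
#' vertices with its neo-Hookean extension.
#' @param mesh Mesh.
#' @param state `mech_state`.
#' @param ext Result of [extend_displacement_to_nucleoplasm()] (or `NULL`
#'   for shell-only geometry with the nucleoplasm frozen).
#' @return nv x 3 matrix of deformed coordinates.
#' @export
deformed_vertices <- function(mesh, state, ext = NULL) {
  x <- mesh$verts
  if (!is.null(ext)) x <- x + matrix(ext$u_nuc, ncol = 3, byrow = TRUE)
  sv <- mesh$shell_verts
  us <- matrix(state$u[seq_len(3 * mesh$n_sv)], ncol = 3, byrow = TRUE)
  x[sv, ] <- mesh$verts[sv, ] + us
  x
}

# vectorized P1 mass/stiffness triplets on tets (deformed coordinates)
p1_vol_matrices <- function(x, tets, nv) {
  a <- x[tets[, 2], ] - x[tets[, 1], ]
  b <- x[tets[, 3], ] - x[tets[, 1], ]
  c_ <- x[tets[, 4], ] - x[tets[, 1], ]
  cr <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                             p[, 3] * q[, 1] - p[, 1] * q[, 3],
                             p[, 1] * q[, 2] - p[, 2] * q[, 1])
  bxc <- cr(b, c_); cxa <- cr(c_, a); axb <- cr(a, b)
  det6 <- rowSums(a * bxc)
  V <- det6 / 6
  if (any(V <= 0)) stop("inverted tetrahedra in transport geometry")
  g2 <- bxc / det6; g3 <- cxa / det6; g4 <- axb / det6
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)
  ii <- jj <- integer(0); mm <- kk <- numeric(0)
  for (i_ in 1:4) for (j_ in 1:4) {
    ii <- c(ii, tets[, i_]); jj <- c(jj, tets[, j_])
    kk <- c(kk, V * rowSums(G[[i_]] * G[[j_]]))
    mm <- c(mm, V / 20 * (1 + (i_ == j_)))
  }
  list(M = Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(nv, nv)),
       K = Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(nv, nv)),
       V = V)
}

# vectorized P1 mass/stiffness triplets on a 3D surface triangulation
p1_surf_matrices <- function(x, tris, nv) {
  e1 <- x[tris[, 3], ] - x[tris[, 2], ]
  e2 <- x[tris[, 1], ] - x[tris[, 3], ]
  e3 <- x[tris[, 2], ] - x[tris[, 1], ]
  cx <- cbind(e3[, 2] * (-e2[, 3]) - e3[, 3] * (-e2[, 2]),
              e3[, 3] * (-e2[, 1]) - e3[, 1] * (-e2[, 3]),
              e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  A <- sqrt(rowSums(cx^2)) / 2
  if (any(A <= 0)) stop("degenerate surface triangles")
  E <- list(e1, e2, e3)
  ii <- jj <- integer(0); mm <- kk <- numeric(0)
  for (i_ in 1:3) for (j_ in 1:3) {
    ii <- c(ii, tris[, i_]); jj <- c(jj, tris[, j_])
    kk <- c(kk, rowSums(E[[i_]] * E[[j_]]) / (4 * A))
    mm <- c(mm, A / 12 * (1 + (i_ == j_)))
  }
  list(M = Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(nv, nv)),
       K = Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(nv, nv)),
       A = A)
}

#' Lagrangian transport operators and measures for one geometry
#'
#' Builds all finite-element operators (mass and Laplace-Beltrami /
#' Laplacian stiffness) and lumped vertex measures on the deformed
#' configuration: the whole-nucleus volume, the nucleoplasm subset, the
#' outer NE surface, and the concentric inner NE surface (whose vertices
#' are the radial projections of the outer ones).
#'
#' @param geom [transport_geometry()].
#' @param x Deformed vertex coordinates (nv x 3).
#' @return List of class `transport_maps`: operators, lumped weights
#'   (`w_vol`, `w_nuc`, `w_out`, `w_inner`), totals and areas.
#' @export
transport_maps <- function(geom, x) {
  nv <- geom$nv; na <- geom$n_ang
  vol <- p1_vol_matrices(x, geom$tets, nv)
  # surface systems live on the n_ang angular nodes
  o_l <- match(seq_len(nv), geom$outer_vg)  # global -> angular (NA elsewhere)
  otri <- matrix(match(geom$outer_tri, geom$outer_vg), ncol = 3)
  itri <- matrix(match(geom$inner_tri, geom$inner_vg), ncol = 3)
  surf_o <- p1_surf_matrices(x[geom$outer_vg, , drop = FALSE], otri, na)
  surf_i <- p1_surf_matrices(x[geom$inner_vg, , drop = FALSE], itri, na)
  w_vol <- as.numeric(vol$M %*% rep(1, nv))
  w_out <- as.numeric(surf_o$M %*% rep(1, na))
  w_inner <- as.numeric(surf_i$M %*% rep(1, na))
  nuc_ids <- sort(unique(as.vector(geom$nuc_tets)))
  # lumped mass matrices: both splitting sub-steps then conserve the same
  # (lumped) species totals exactly
  structure(list(x = x, Mvol = Matrix::Diagonal(x = w_vol), Kvol = vol$K,
                 Mout = Matrix::Diagonal(x = w_out), Kout = surf_o$K,
                 Minn = Matrix::Diagonal(x = w_inner), Kinn = surf_i$K,
                 w_vol = w_vol, w_out = w_out, w_inner = w_inner,
                 vol_tot = sum(vol$V), area_out = sum(surf_o$A),
                 area_inner = sum(surf_i$A),
                 otri = otri, nuc_ids = nuc_ids),
            class = "transport_maps")
}

#' Inner-surface deformation maps (concentric projection)
#'
#' The inner NE reference surface is the radial projection of the outer
#' one; on the structured mesh the projected points are exactly the
#' inner-level vertices, so the inner areal stretch relative to the outer
#' reference measure is the ratio of deformed inner facet areas to
#' reference outer facet areas. Deformed inner normals are facet normals.
#'
#' @param mesh Mesh.
#' @param state `mech_state` (or `NULL` for the reference).
#' @return List with per-facet `alpha_inner` (deformed inner area over
#'   reference outer area), `alpha_inner_rel` (over reference inner area),
#'   facet normals `n_inner`, and per-vertex lumped equivalents.
#' @export
inner_surface_maps <- function(mesh, state = NULL) {
  u <- if (is.null(state)) numeric(3 * mesh$n_p2) else state$u
  fi <- facet_measures_cpp(mesh$Xp2, mesh$inner_facets$nodes6, u)
  fo <- facet_measures_cpp(mesh$Xp2, mesh$outer_facets$nodes6, u)
  fs <- facet_stress_cpp(mesh$Xp2, mesh$cells10, mesh$inner_facets$nodes6,
                         mesh$inner_facets$parent, u,
                         numeric(mesh$n_sv), rep(1, mesh$n_sv), 0, 0,
                         0, mesh$center, 0)
  list(alpha_inner = fi$area_def / fo$area_ref,
       alpha_inner_rel = fi$area_def / fi$area_ref,
       n_inner = fs$normal, F_inner = fs$F,
       area_def = fi$area_def, area_ref_outer = fo$area_ref)
}

# implicit-Euler diffusion(-decay) solve on a frozen domain:
# (M/dt + D K + M*diag(impl)) u = M (u_old/dt + src)
implicit_step <- function(M, K, D, dt, u_old, src = 0, impl = 0,
                          extra_diag = NULL) {
  A <- M / dt + D * K
  if (any(impl != 0)) A <- A + M %*% Matrix::Diagonal(x = impl)
  if (!is.null(extra_diag)) A <- A + extra_diag
  rhs <- M %*% (u_old / dt + src)
  as.numeric(Matrix::solve(A, rhs))
}

#' Advance a volume species one step
#'
#' Implicit-Euler diffusion-reaction on the frozen new-time domain followed
#' by the multiplicative Jacobian-ratio dilution. Reactions are supplied as
#' an explicit source plus an implicit linear decay coefficient per vertex;
#' boundary (outer NE) fluxes enter through `surf_src`/`surf_impl`, scaled
#' by the lumped outer-surface areas.
#'
#' @param field Vertex concentrations (uM) at the previous time.
#' @param D Diffusion coefficient (um^2/s).
#' @param dt Time step (s).
#' @param maps_old,maps_new [transport_maps()] at the old and new time.
#' @param geom [transport_geometry()].
#' @param src Explicit volumetric source (uM/s), scalar or per-vertex.
#' @param impl Implicit volumetric decay rate (1/s).
#' @param surf_src Explicit boundary influx density (uM um/s) on the outer
#'   surface angular nodes.
#' @param surf_impl Implicit boundary loss coefficient (um/s) on the outer
#'   surface angular nodes.
#' @return Updated vertex concentrations.
#' @export
step_volume_species <- function(field, D, dt, maps_old, maps_new, geom,
                                src = 0, impl = 0, surf_src = NULL,
                                surf_impl = NULL) {
  stopifnot(dt > 0, D >= 0)
  nv <- geom$nv
  src_v <- rep(0, nv) + src
  impl_v <- rep(0, nv) + impl
  extra <- NULL
  if (!is.null(surf_src)) {
    # lumped surface load: uM um/s times area -> divide by vertex volume via M
    sv <- rep(0, nv)
    sv[geom$outer_vg] <- surf_src * maps_new$w_out
    src_v <- src_v + sv / pmax(maps_new$w_vol, 1e-300)
  }
  if (!is.null(surf_impl)) {
    dd <- rep(0, nv)
    dd[geom$outer_vg] <- surf_impl * maps_new$w_out
    extra <- Matrix::Diagonal(x = dd)
  }
  uD <- implicit_step(maps_new$Mvol, maps_new$Kvol, D, dt, field,
                      src = src_v, impl = impl_v, extra_diag = extra)
  uD * maps_old$w_vol / maps_new$w_vol
}

#' Advance a surface species one step (outer NE measures)
#'
#' @inheritParams step_volume_species
#' @param field Concentrations on the outer-surface angular nodes (um^-2).
#' @param src,impl Explicit source (um^-2 s^-1) and implicit decay (1/s).
#' @return Updated surface concentrations.
#' @export
step_surface_species <- function(field, D, dt, maps_old, maps_new, geom,
                                 src = 0, impl = 0) {
  stopifnot(dt > 0, D >= 0)
  uD <- implicit_step(maps_new$Mout, maps_new$Kout, D, dt, field,
                      src = rep(0, geom$n_ang) + src,
                      impl = rep(0, geom$n_ang) + impl)
  uD * maps_old$w_out / maps_new$w_out
}

#' Advance the NE-bound lamin pool one step (inner-surface measures)
#'
#' Identical splitting to [step_surface_species()] but with the
#' concentric inner-surface operators and area weights, as the lamin field
#' is tracked on the outer surface while advecting with the inner one.
#'
#' @inheritParams step_surface_species
#' @export
step_lamin <- function(field, D, dt, maps_old, maps_new, geom,
                       src = 0, impl = 0) {
  stopifnot(dt > 0, D >= 0)
  uD <- implicit_step(maps_new$Minn, maps_new$Kinn, D, dt, field,
                      src = rep(0, geom$n_ang) + src,
                      impl = rep(0, geom$n_ang) + impl)
  uD * maps_old$w_inner / maps_new$w_inner
}

#' Advance activated and deactivated NPC densities jointly
#'
#' Both pools diffuse on the outer NE and exchange by the activation /
#' deactivation reaction; the pair is solved as one implicit block system
#' so the pointwise sum is conserved exactly under the reaction.
#'
#' @param npc,npca Inactive/active NPC densities (um^-2) on the outer
#'   surface nodes.
#' @param kf_field Per-vertex activation rate coefficient (1/s).
#' @param kr Deactivation rate (1/s).
#' @param D Diffusion coefficient.
#' @param dt Step (s).
#' @param maps_old,maps_new,geom As in [step_surface_species()].
#' @return List `npc`, `npca`.
#' @export
step_npc_pair <- function(npc, npca, kf_field, kr, D, dt,
                          maps_old, maps_new, geom) {
  na <- geom$n_ang
  M <- maps_new$Mout; K <- maps_new$Kout
  A11 <- M / dt + D * K + M %*% Matrix::Diagonal(x = kf_field)
  A12 <- -kr * M
  A21 <- -M %*% Matrix::Diagonal(x = kf_field)
  A22 <- M / dt + D * K + kr * M
  A <- rbind(cbind(A11, A12), cbind(A21, A22))
  rhs <- c(as.numeric(M %*% (npc / dt)), as.numeric(M %*% (npca / dt)))
  sol <- as.numeric(Matrix::solve(A, rhs))
  ratio <- maps_old$w_out / maps_new$w_out
  list(npc = sol[seq_len(na)] * ratio, npca = sol[na + seq_len(na)] * ratio)
}
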