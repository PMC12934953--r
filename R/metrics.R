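# Derived outputs: lower-NE stretch, critical pitch, tension extrema,
# YAP/TAZ N/C, lamin statistics and the force-per-lamin rupture proxy.

#' Average stretch of the lower inner NE
#'
#' Area-weighted mean of the inner-surface areal stretch restricted to the
#' region with deformed z below `zcenter + offset`, where `zcenter` is the
#' deformed height of the inner NE point directly above the central
#' nanopillar (the lowest inner point on a flat substrate).
#'
#' @param mesh Mesh.
#' @param state `mech_state`.
#' @param pillars Substrate (only used to define the central reference
#'   point; the lowest point is used either way since the nucleus is
#'   centered above a pillar).
#' @param offset Selection band above `zcenter` (um), default 0.05.
#' @return Scalar mean stretch; `NA` with a warning if the selection is
#'   empty.
#' @export
mean_lower_stretch <- function(mesh, state, pillars = flat_substrate(),
                               offset = 0.05) {
  fi <- facet_measures_cpp(mesh$Xp2, mesh$inner_facets$nodes6, state$u)
  stretch <- fi$area_def / fi$area_ref
  # deformed centroid of each inner facet
  n6 <- mesh$inner_facets$nodes6
  zc <- facet_def_centroids(mesh, state, n6)[, 3]
  iv <- mesh$inner_vl
  zv <- mesh$Xp2[iv, 3] + state$u[3 * (iv - 1) + 3]
  zcenter <- if (pillars$h_np > 0) {
    # inner NE point directly above the central pillar: the bottom pole
    zv[which.min(mesh$Xp2[iv, 3])]
  } else {
    # flat substrate: the lowest point of the deformed inner NE
    min(zv)
  }
  sel <- zc < zcenter + offset
  if (!any(sel)) sel <- zc <= min(zc) + 1e-9  # degenerate: keep the lowest facet
  sum(stretch[sel] * fi$area_def[sel]) / sum(fi$area_def[sel])
}

facet_def_centroids <- function(mesh, state, n6) {
  x <- mesh$Xp2 + matrix(state$u, ncol = 3, byrow = TRUE)
  (x[n6[, 1], ] + x[n6[, 2], ] + x[n6[, 3], ]) / 3
}

#' Maximum NE membrane tension
#'
#' Maximum of the bilayer tension over the outer NE, in mN/m.
#' @param mesh Mesh.
#' @param state `mech_state`.
#' @param params [material_params()].
#' @return Scalar (mN/m).
#' @export
max_tension <- function(mesh, state, params) {
  mt <- membrane_tension(mesh, state, params)
  max(mt$gamma_mN_m)
}

#' YAP/TAZ nuclear-to-cytosolic ratio
#'
#' Volume-averaged nuclear concentration over the cytosolic concentration.
#' @param Ynuc Nuclear YAP/TAZ vertex field (uM).
#' @param w_vol Lumped deformed vertex volumes.
#' @param cytosol `cytosol_state`.
#' @return Scalar ratio (`Inf` if the cytosolic pool is empty).
#' @export
yap_nc_ratio <- function(Ynuc, w_vol, cytosol) {
  ybar <- sum(Ynuc * w_vol) / sum(w_vol)
  if (cytosol$Ycyto <= 0) return(Inf)
  ybar / cytosol$Ycyto
}

#' Critical pitch of a sweep
#'
#' Pitch maximizing the mean lower-NE stretch; ties break to the smaller
#' pitch. A maximum on the sweep boundary is flagged.
#' @param sweep Data frame from [run_pitch_sweep()] (one sigma_max).
#' @param metric Column to maximize.
#' @return Scalar pitch with attributes `boundary` (logical) and
#'   `resolution` (the sweep grid spacing).
#' @export
critical_pitch <- function(sweep, metric = "mean_lower_stretch") {
  sweep <- sweep[is.finite(sweep[[metric]]) & sweep$pitch > 0, , drop = FALSE]
  if (nrow(sweep) < 3) stop("need at least 3 pitches spanning a maximum")
  sweep <- sweep[order(sweep$pitch), , drop = FALSE]
  v <- sweep[[metric]]
  imax <- which(v >= max(v) - 1e-12)[1]   # tie -> smaller pitch
  out <- sweep$pitch[imax]
  attr(out, "boundary") <- imax == 1 || imax == nrow(sweep)
  attr(out, "resolution") <- if (nrow(sweep) > 1) min(diff(sweep$pitch)) else NA
  out
}

#' Trapezoidal area under the maximum force-per-lamin curve
#'
#' @param t Time points (s).
#' @param FL_max Maximum force per lamin at each time (pN).
#' @return Integrated force (pN s).
#' @export
integrated_force <- function(t, FL_max) {
  stopifnot(length(t) == length(FL_max))
  if (length(t) < 2) return(0)
  o <- order(t)
  t <- t[o]; f <- FL_max[o]
  sum(diff(t) * (head(f, -1) + tail(f, -1)) / 2)
}

#' Mean lamin density over the lower NE region
#'
#' Average over outer-surface nodes whose undeformed coordinates satisfy
#' X < 1.5, Y < 1.5, Z < znuc + 1.
#' @param mesh Mesh.
#' @param L Lamin field on the outer-surface nodes.
#' @param w Lumped node areas (deformed).
#' @return Scalar mean density (um^-2).
#' @export
lamin_lower_mean <- function(mesh, L, w) {
  X <- mesh$verts[mesh$outer_vg, , drop = FALSE]
  sel <- X[, 1] < 1.5 & X[, 2] < 1.5 & X[, 3] < mesh$shell$znuc + 1
  sum(L[sel] * w[sel]) / sum(w[sel])
}

# one metrics row of a coupled run
metrics_row <- function(mesh, state, species, maps, maps_ref, geom,
                        pars, kin, t, alpha_init, L_ref,
                        pillars = flat_substrate()) {
  sa <- surface_areas(mesh, state)
  vol <- nucleoplasm_volume(mesh, state)
  fs <- facet_stress_cpp(mesh$Xp2, mesh$cells10, mesh$inner_facets$nodes6,
                         mesh$inner_facets$parent, state$u, state$p,
                         state$Escale, pars$E1, pars$E2, 0.1, mesh$center,
                         pars$dz_hat)
  # lamin density per inner facet (mean of its angular nodes)
  itri <- maps$otri
  Lfac <- rowMeans(matrix(species$L[itri], ncol = 3))
  FL <- force_per_lamin(fs$traction_mag, Lfac)
  data.frame(
    t = t,
    sigma_cap_Pa = state$load$sigma_cap,
    dP_Pa = state$load$dP,
    vol_nuc = vol,
    area_outer = sa$outer_def,
    area_inner = sa$inner_def,
    mean_lower_stretch = mean_lower_stretch(mesh, state, pillars),
    max_tension = max_tension(mesh, state, pars),
    npcA_mean = sum(species$npca * maps$w_out) / sum(maps$w_out),
    yap_nc = yap_nc_ratio(species$Ynuc, maps$w_vol, species$cytosol),
    Y_free_uM = species$cytosol$Yfree,
    Y_cyto_uM = species$cytosol$Ycyto,
    lamin_lower_mean = lamin_lower_mean(mesh, species$L, maps$w_out),
    lamin_mean = sum(species$L * maps$w_inner) / sum(maps$w_inner),
    FL_max = max(FL),
    L_total = sum(species$L * maps$w_inner),
    Lphos_total = kin$Nconv * sum(species$Lphos * maps$w_vol),
    NPC_total = sum(species$npc * maps$w_out),
    NPCA_total = sum(species$npca * maps$w_out),
    Ynuc_total = kin$Nconv * sum(species$Ynuc * maps$w_vol))
}
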