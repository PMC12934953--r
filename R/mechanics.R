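# Quasi-static mechanics of the NE shell: mixed displacement/pressure
# Newton solver with follower loads (osmotic pressure, actin cap, pillar
# repulsion), floor-contact active set, roof stabilization and the
# osmotic-pressure feedback loop.

#' Cap stress time schedule
#'
#' Saturating ramp `sigma_cap(t) = sigma_max (1 - exp(-t / t0_cap))`.
#' @param t Time (s).
#' @param sigma_max Plateau cap stress (Pa).
#' @param t0_cap Assembly time scale (s).
#' @return Cap stress (Pa).
#' @export
cap_stress_schedule <- function(t, sigma_max, t0_cap) {
  stopifnot(all(t >= 0))
  sigma_max * (1 - exp(-t / t0_cap))
}

#' Cap stress spatial profile
#'
#' Exponential decay from the apex of the reference shell:
#' `sigma_cap * exp((Z - (znuc + 2 R0)) / Z0)`.
#' @param Z Material height coordinate (um).
#' @param sigma_cap Cap stress amplitude (Pa).
#' @param Z0 Decay length (um).
#' @param shell A [shell_geometry()].
#' @return Stress magnitude (Pa), directed along -z on the outer NE.
#' @export
cap_stress_profile <- function(Z, sigma_cap, Z0, shell) {
  sigma_cap * exp((Z - (shell$znuc + 2 * shell$R0)) / Z0)
}

#' Pillar contact repulsion magnitude
#'
#' `sigma_contact0 * exp(-(z - d_steric)/d_steric)` with z = Z + uz the
#' deformed height above the pillar-top plane.
#' @param z Deformed height (um).
#' @param params A [material_params()].
#' @return Repulsive stress (Pa).
#' @export
contact_repulsion <- function(z, params) {
  params$sigma_contact0 * exp(-(z - params$d_steric) / params$d_steric)
}

#' Osmotic pressure update
#'
#' Penalizes nucleoplasm volume change:
#' `dP = dP_prev - phi_inner (vol - vol_prev) / vol`.
#' @param dP_prev Previous pressure difference (Pa).
#' @param vol,vol_prev Current and previous nucleoplasm volumes (um^3).
#' @param phi_inner Nucleoplasm bulk modulus (Pa).
#' @return Updated pressure (Pa).
#' @export
update_pressure <- function(dP_prev, vol, vol_prev, phi_inner) {
  stopifnot(vol > 0)
  dP_prev - phi_inner * (vol - vol_prev) / vol
}

# ---- constraint bookkeeping ------------------------------------------------

# fixed symmetry constraints for the quarter domain (and optional z-mirror
# used for the free floating sphere); returns integer dof ids and values
sym_constraints <- function(mesh, z_symmetry = FALSE) {
  X <- mesh$Xp2
  tol <- 1e-8
  dofs <- c(3 * (which(abs(X[, 1]) < tol) - 1) + 1,
            3 * (which(abs(X[, 2]) < tol) - 1) + 2)
  if (z_symmetry) {
    eq <- which(abs(X[, 3] - mesh$center[3]) < 1e-6)
    dofs <- c(dofs, 3 * (eq - 1) + 3)
  }
  list(dofs = dofs, vals = numeric(length(dofs)))
}

roof_nodes <- function(mesh) {
  unique(as.vector(mesh$outer_facets$nodes6[mesh$roof1, , drop = FALSE]))
}

# alpha-weighted average of uz over the roof annulus (Gamma_upper,2)
roof_target <- function(mesh, u_prev) {
  f2 <- mesh$roof2
  fm <- facet_measures_cpp(mesh$Xp2, mesh$outer_facets$nodes6[f2, , drop = FALSE],
                           u_prev)
  # facet-mean uz of the previous displacement
  uz <- matrix(u_prev[3 * (as.vector(mesh$outer_facets$nodes6[f2, , drop = FALSE]) - 1) + 3],
               nrow = length(f2))
  uzm <- rowMeans(uz)
  sum(uzm * fm$area_def) / sum(fm$area_def)
}

#' Solve the quasi-static mechanical equilibrium
#'
#' Newton solution of the mixed displacement/pressure system for the NE
#' shell under the current osmotic pressure, cap stress and substrate
#' interactions. Floor contact is an active-set Dirichlet condition
#' (nodes with deformed z below the floor are pinned to it and released
#' when their reaction becomes adhesive); the roof patch is pinned to the
#' stretch-weighted average height of the surrounding annulus at the
#' previous step.
#'
#' @param mesh A [build_reference_mesh()] result.
#' @param load List with `sigma_cap` and `dP` (Pa).
#' @param params A [material_params()].
#' @param pillars A [nanopillar_array()].
#' @param prev Previous state (list with `u`, `p`, `Escale`, `active`) or
#'   `NULL` to start from the reference configuration.
#' @param z_symmetry Pin the equator plane in z (free-sphere runs only).
#' @param use_roof Apply the roof Dirichlet stabilization (default: on
#'   unless `z_symmetry`).
#' @param newton_tol,newton_max Convergence controls.
#' @param quiet Suppress iteration output.
#' @return List of class `mech_state`: displacement `u`, pressure `p`,
#'   `Escale`, converged flag, residual norm, floor active set, load echo.
#' @export
solve_equilibrium <- function(mesh, load, params, pillars = flat_substrate(),
                              prev = NULL, z_symmetry = FALSE,
                              use_roof = !z_symmetry,
                              newton_tol = 1e-8, newton_max = 50,
                              quiet = TRUE) {
  np2 <- mesh$n_p2; nsv <- mesh$n_sv
  ndof <- 3 * np2 + nsv
  u <- if (!is.null(prev)) prev$u else numeric(3 * np2)
  p <- if (!is.null(prev)) prev$p else numeric(nsv)
  Escale <- if (!is.null(prev) && !is.null(prev$Escale)) prev$Escale else rep(1, nsv)
  active <- if (!is.null(prev)) prev$active else integer(0)

  sym <- sym_constraints(mesh, z_symmetry)
  # roof multi-point constraint: uz on the apex patch equals the
  # area-weighted mean uz over the surrounding annulus
  Pmpc <- NULL; slave_dofs <- integer(0)
  if (use_roof) {
    u_ref <- if (!is.null(prev)) prev$u else numeric(3 * np2)
    rn1 <- roof_nodes(mesh)
    ann_f <- mesh$roof2
    fm <- facet_measures_cpp(mesh$Xp2,
                             mesh$outer_facets$nodes6[ann_f, , drop = FALSE],
                             u_ref)
    n6 <- mesh$outer_facets$nodes6[ann_f, , drop = FALSE]
    wts <- numeric(np2)
    for (k in seq_len(nrow(n6))) wts[n6[k, ]] <- wts[n6[k, ]] + fm$area_def[k] / 6
    ann_nodes <- setdiff(which(wts > 0), rn1)
    wts <- wts[ann_nodes] / sum(wts[ann_nodes])
    slave_dofs <- 3 * (rn1 - 1) + 3
    master_dofs <- 3 * (ann_nodes - 1) + 3
    Pmpc <- Matrix::sparseMatrix(
      i = c(setdiff(seq_len(ndof), slave_dofs),
            rep(slave_dofs, each = length(master_dofs))),
      j = c(setdiff(seq_len(ndof), slave_dofs),
            rep(master_dofs, times = length(slave_dofs))),
      x = c(rep(1, ndof - length(slave_dofs)),
            rep(wts, times = length(slave_dofs))),
      dims = c(ndof, ndof))
  }
  h_np <- pillars$h_np
  floor_z <- -h_np
  Xz <- mesh$Xp2[, 3]
  anchor_dofs <- 3 * (roof_nodes(mesh) - 1L) + 3L
  anchor_k <- 2  # Pa um^2 / um per node

  pars_cap <- c(load$sigma_cap, mesh$shell$znuc + 2 * mesh$shell$R0, params$Z0)
  w4 <- 2 * (pillars$r_np + 0.05)^4
  pars_con <- c(params$sigma_contact0, params$d_steric, pillars$p_np,
                pillars$n_np, w4, as.numeric(params$contact_ez))
  has_pillars <- pillars$h_np > 0 && load$sigma_cap >= 0

  assemble <- function(u, p, want_K) {
    a <- mech_assemble_cpp(mesh$Xp2, mesh$cells10, u, p, Escale,
                           params$E1, params$E2, params$phi0, want_K)
    Ru <- a$Ru; Rp <- a$Rp
    tri <- if (want_K) list(i = a$Ki, j = a$Kj, x = a$Kx) else NULL
    addload <- function(type, pars, facets) {
      fl <- facet_loads_cpp(mesh$Xp2, mesh$cells10, facets$nodes6,
                            facets$parent, u, type, pars, want_K)
      Ru <<- Ru + fl$Ru
      if (want_K) tri <<- list(i = c(tri$i, fl$Ki), j = c(tri$j, fl$Kj),
                               x = c(tri$x, fl$Kx))
    }
    if (load$dP != 0) addload(1, c(load$dP), mesh$inner_facets)
    if (load$sigma_cap > 0) addload(2, pars_cap, mesh$outer_facets)
    if (has_pillars) addload(3, pars_con, mesh$outer_facets)
    if (use_roof) {
      Ru[anchor_dofs] <- Ru[anchor_dofs] + anchor_k * u[anchor_dofs]
      if (want_K) tri <- list(i = c(tri$i, anchor_dofs - 1L),
                              j = c(tri$j, anchor_dofs - 1L),
                              x = c(tri$x, rep(anchor_k, length(anchor_dofs))))
    }
    # scale the pressure-projection equation to O(1)
    Rp <- Rp / params$phi0
    list(R = c(Ru, Rp), tri = tri, minJ = a$minJ)
  }

  # assemble the Jacobian with Dirichlet rows/cols eliminated in triplet form
  build_K <- function(tri, fixed_mask) {
    sc <- rep(1, length(tri$x))
    sc[tri$i >= 3 * np2] <- 1 / params$phi0
    keep <- !(fixed_mask[tri$i + 1L] | fixed_mask[tri$j + 1L])
    fix <- which(fixed_mask)
    Matrix::sparseMatrix(i = c(tri$i[keep] + 1L, fix),
                         j = c(tri$j[keep] + 1L, fix),
                         x = c(tri$x[keep] * sc[keep], rep(1, length(fix))),
                         dims = c(ndof, ndof))
  }

  conv <- FALSE; res <- NA; it_tot <- 0
  for (as_iter in 1:6) {
    fixed_dofs <- c(sym$dofs, 3 * (active - 1) + 3)
    fixed_vals <- c(sym$vals, floor_z - Xz[active])
    fixed_mask <- logical(ndof)
    fixed_mask[fixed_dofs] <- TRUE
    free <- which(!fixed_mask)
    # impose Dirichlet changes in sub-steps so large constraint jumps
    # (e.g. the roof pin moving between load steps) cannot invert elements
    delta0 <- fixed_vals - u[fixed_dofs]
    nsub <- max(1L, min(8L, ceiling(max(abs(delta0), 0) / 0.05)))
    for (sub in seq_len(nsub)) {
    u[fixed_dofs] <- fixed_vals - delta0 * (1 - sub / nsub)
    if (!is.null(Pmpc)) u[slave_dofs] <- as.numeric(Pmpc %*% c(u, p))[slave_dofs]
    R0n <- NULL
    conv <- FALSE
    # chord Newton: the Jacobian factorization is reused while convergence
    # stays fast, and refreshed when the contraction rate degrades
    Lfac <- NULL
    rn_prev <- Inf
    refactor <- TRUE
    forced <- 0L
    for (it in 1:newton_max) {
      it_tot <- it_tot + 1
      # activate floor contact for nodes penetrating at the current iterate
      zdef_it <- Xz + u[seq(3, 3 * np2, by = 3)]
      pen_it <- which(zdef_it < floor_z - 1e-9)
      newly_it <- setdiff(pen_it, active)
      if (length(newly_it) > 0) {
        active <- sort(c(active, newly_it))
        fixed_dofs <- c(sym$dofs, 3 * (active - 1) + 3)
        fixed_vals <- c(sym$vals, floor_z - Xz[active])
        fixed_mask <- logical(ndof); fixed_mask[fixed_dofs] <- TRUE
        u[fixed_dofs] <- fixed_vals
        refactor <- TRUE; R0n <- NULL
      }
      sys <- assemble(u, p, refactor)
      Rv <- sys$R
      Rv[fixed_dofs] <- 0
      rn <- if (!is.null(Pmpc)) {
        rr <- as.numeric(Matrix::crossprod(Pmpc, Rv))
        rr[fixed_dofs] <- 0; rr[slave_dofs] <- 0
        sqrt(sum(rr^2))
      } else sqrt(sum(Rv^2))
      if (!is.finite(rn)) break
      if (is.null(R0n)) R0n <- max(rn, 1e-4)
      if (!quiet) cat(sprintf("  newton %2d |R| = %.3e (minJ %.3f%s)\n", it, rn,
                              sys$minJ, if (refactor) ", factor" else ""))
      if (rn <= max(newton_tol * R0n, 1e-8)) { conv <- TRUE; res <- rn; break }
      if (refactor) {
        K <- build_K(sys$tri, fixed_mask)
        if (!is.null(Pmpc)) {
          K <- Matrix::crossprod(Pmpc, K %*% Pmpc) +
            Matrix::sparseMatrix(i = slave_dofs, j = slave_dofs,
                                 x = rep(1, length(slave_dofs)),
                                 dims = c(ndof, ndof))
        }
        Lfac <- tryCatch(Matrix::lu(K, order = 2L), error = function(e) NULL)
        if (is.null(Lfac)) break
      }
      Rhs <- if (!is.null(Pmpc)) {
        rr <- as.numeric(Matrix::crossprod(Pmpc, Rv)); rr[slave_dofs] <- 0
        rr[fixed_dofs] <- 0; rr
      } else Rv
      du <- tryCatch(as.numeric(Matrix::solve(Lfac, -Rhs)),
                     error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      if (!is.null(Pmpc)) du <- as.numeric(Pmpc %*% du)
      step <- 1; ok <- FALSE
      repeat {
        u2 <- u + step * du[seq_len(3 * np2)]
        p2 <- p + step * du[3 * np2 + seq_len(nsv)]
        s2 <- assemble(u2, p2, FALSE)
        R2 <- s2$R; R2[fixed_dofs] <- 0
        rn2 <- if (!is.null(Pmpc)) {
          rr <- as.numeric(Matrix::crossprod(Pmpc, R2))
          rr[fixed_dofs] <- 0; rr[slave_dofs] <- 0
          sqrt(sum(rr^2))
        } else sqrt(sum(R2^2))
        ok <- is.finite(rn2) && s2$minJ > 0.02 && rn2 < (1 - 1e-4 * step) * rn
        if (ok || step < 1 / 64) break
        step <- step / 2
      }
      if (!ok) {
        if (!refactor) { refactor <- TRUE; next }
        # line search exhausted. Near contact snap-through the iteration can
        # stagnate at a small residual for any increment size; accept the
        # state once the residual has dropped well below the step scale.
        if (rn < 1e-4 || rn < 1e-2 * R0n) { conv <- TRUE; res <- rn; break }
        # otherwise take a bounded non-monotone step: near a fold the
        # residual must rise before the iteration can reach the post-snap
        # branch; the element-inversion guard still applies
        if (forced < 8L) {
          forced <- forced + 1L
          stepf <- 1 / 8
          repeat {
            u2 <- u + stepf * du[seq_len(3 * np2)]
            p2 <- p + stepf * du[3 * np2 + seq_len(nsv)]
            s2 <- assemble(u2, p2, FALSE)
            if ((is.finite(sqrt(sum(s2$R^2))) && s2$minJ > 0.02) ||
                stepf < 1 / 256) break
            stepf <- stepf / 2
          }
          if (s2$minJ > 0.02) {
            u <- u2; p <- p2
            refactor <- TRUE
            next
          }
        }
        break
      }
      u <- u2; p <- p2
      forced <- 0L
      # refresh the factorization if contraction is poor or damping was used
      refactor <- (step < 1) || (rn2 > 0.2 * rn)
      rn_prev <- rn
    }
    if (!conv) break
    }
    # update floor active set from the converged (or last) iterate
    zdef <- Xz + u[seq(3, 3 * np2, by = 3)]
    pen <- which(zdef < floor_z - 1e-9)
    newly <- setdiff(pen, active)
    release <- integer(0)
    if (length(active) && conv) {
      # adhesive reactions (pulling down) release the node
      sysr <- assemble(u, p, FALSE)
      rz <- sysr$R[3 * (active - 1) + 3]
      release <- active[rz < -1e-8]
    }
    if (length(newly) == 0 && length(release) == 0) break
    active <- sort(setdiff(union(active, newly), release))
  }
  structure(list(u = u, p = p, Escale = Escale, converged = conv,
                 residual = res, iterations = it_tot, active = active,
                 load = load, z_symmetry = z_symmetry, use_roof = use_roof),
            class = "mech_state")
}

#' @export
print.mech_state <- function(x, ...) {
  cat(sprintf("mech_state: sigma_cap = %g Pa, dP = %g Pa, converged = %s (%d Newton its, %d floor nodes)\n",
              x$load$sigma_cap, x$load$dP, x$converged, x$iterations,
              length(x$active)))
  invisible(x)
}

#' Shell volume measures of a state
#'
#' Reference and deformed shell volume by quadrature of the displacement
#' Jacobian, plus the minimum J (element-inversion guard).
#' @param mesh Mesh.
#' @param state A `mech_state` (or displacement vector).
#' @return List `vol_ref`, `vol_def`, `minJ`, `dev` (relative deviation).
#' @export
shell_volume_check <- function(mesh, state) {
  u <- if (is.list(state)) state$u else state
  m <- shell_measures_cpp(mesh$Xp2, mesh$cells10, u)
  m$dev <- abs(m$vol_def - m$vol_ref) / m$vol_ref
  m
}

#' Nucleoplasm volume enclosed by the deformed inner NE
#'
#' Divergence-theorem volume of the deformed nucleoplasm from the inner
#' surface alone (the symmetry-plane cuts contribute nothing).
#' @param mesh Mesh.
#' @param state A `mech_state` (or displacement vector).
#' @return Volume (um^3).
#' @export
nucleoplasm_volume <- function(mesh, state) {
  u <- if (is.list(state)) state$u else state
  fm <- facet_measures_cpp(mesh$Xp2, mesh$inner_facets$nodes6, u)
  sum(fm$vflux) / 3
}

#' Surface areas of a state
#' @param mesh Mesh.
#' @param state `mech_state` or displacement vector.
#' @return List with deformed and reference outer/inner areas (um^2).
#' @export
surface_areas <- function(mesh, state) {
  u <- if (is.list(state)) state$u else state
  fo <- facet_measures_cpp(mesh$Xp2, mesh$outer_facets$nodes6, u)
  fi <- facet_measures_cpp(mesh$Xp2, mesh$inner_facets$nodes6, u)
  list(outer_def = sum(fo$area_def), outer_ref = sum(fo$area_ref),
       inner_def = sum(fi$area_def), inner_ref = sum(fi$area_ref))
}

#' Inflate the shell to a target osmotic pressure
#'
#' Ramps the transmembrane pressure in increments with Newton continuation
#' (halving the increment on failure) up to `dP_target`.
#'
#' @param mesh Mesh.
#' @param params A [material_params()].
#' @param dP_target Target pressure (Pa); defaults to `params$Pmax`.
#' @param pillars Substrate (affects floor contact during inflation).
#' @param n_steps Pressure increments.
#' @param z_symmetry Use the z-mirror trick (free sphere only).
#' @param prev Optional starting state.
#' @param Escale Optional stiffness-scale field.
#' @param quiet Suppress progress output.
#' @return Converged `mech_state` at `dP_target`.
#' @export
inflate_shell <- function(mesh, params, dP_target = params$Pmax,
                          pillars = flat_substrate(), n_steps = 8,
                          z_symmetry = FALSE, prev = NULL, Escale = NULL,
                          quiet = TRUE) {
  state <- prev
  if (!is.null(Escale) && !is.null(state)) state$Escale <- Escale
  dP0 <- if (!is.null(prev)) prev$load$dP else 0
  targets <- seq(dP0, dP_target, length.out = n_steps + 1)[-1]
  i <- 1
  while (i <= length(targets)) {
    dP <- targets[i]
    if (!is.null(Escale) && is.null(state)) {
      state0 <- list(u = numeric(3 * mesh$n_p2), p = numeric(mesh$n_sv),
                     Escale = Escale, active = integer(0))
    } else state0 <- state
    st <- solve_equilibrium(mesh, list(sigma_cap = 0, dP = dP), params,
                            pillars, prev = state0, z_symmetry = z_symmetry,
                            quiet = quiet)
    if (!st$converged) {
      # halve the increment and retry
      lo <- if (i == 1) dP0 else targets[i - 1]
      if (abs(dP - lo) < 1e-3 * abs(dP_target - dP0 + 1e-12))
        stop("inflation failed to converge at dP = ", dP)
      targets <- append(targets, (lo + dP) / 2, after = i - 1)
      next
    }
    state <- st
    i <- i + 1
  }
  state
}

#' Equilibrate the osmotic pressure at fixed cap stress
#'
#' Fixed-point loop alternating the mechanical solve and the pressure
#' update until the pressure changes by less than `tol` (relative).
#'
#' @param mesh Mesh.
#' @param load List with `sigma_cap` and starting `dP`.
#' @param params,pillars As in [solve_equilibrium()].
#' @param prev Previous converged state (Newton initial guess; also supplies
#'   the reference nucleoplasm volume `vol_prev` unless given).
#' @param vol_prev Nucleoplasm volume against which changes are penalized;
#'   defaults to the volume of `prev`.
#' @param tol Relative pressure tolerance (default 1%).
#' @param max_iter Iteration cap.
#' @param quiet Progress output.
#' @return `mech_state` with converged `load$dP`, plus `vol_nuc`.
#' @export
equilibrate_pressure <- function(mesh, load, params, pillars = flat_substrate(),
                                 prev = NULL, vol_prev = NULL, tol = 0.01,
                                 max_iter = 30, quiet = TRUE) {
  if (is.null(vol_prev)) {
    stopifnot(!is.null(prev))
    vol_prev <- nucleoplasm_volume(mesh, prev)
  }
  dP <- load$dP
  state <- prev
  trace <- numeric(0)
  for (k in seq_len(max_iter)) {
    st <- solve_equilibrium(mesh, list(sigma_cap = load$sigma_cap, dP = dP),
                            params, pillars, prev = state, quiet = quiet)
    if (!st$converged) {
      if (!is.null(state)) state$converged <- FALSE
      if (is.null(state)) state <- st
      return(state)
    }
    vol <- nucleoplasm_volume(mesh, st)
    dP_new <- update_pressure(dP, vol, vol_prev, params$phi_inner)
    trace <- c(trace, dP_new)
    rel <- abs(dP_new - dP) / max(abs(dP_new), 1e-9)
    state <- st
    vol_prev <- vol
    dP <- dP_new
    if (!quiet) cat(sprintf("  p-loop %d: vol = %.2f dP -> %.2f (rel %.2e)\n",
                            k, vol, dP, rel))
    if (rel < tol) break
    if (k == max_iter) warning("pressure loop did not converge; trace: ",
                               paste(round(trace, 1), collapse = " "))
  }
  state$load$dP <- dP
  state$vol_nuc <- vol_prev
  state
}

#' Ramp the cap stress with pressure equilibration
#'
#' Increases the cap stress to `sigma_target` in increments bounded by
#' `min(2 kPa, sigma_target / 10)`, equilibrating the osmotic pressure after
#' each increment; increments are halved on Newton failure.
#'
#' @param mesh Mesh.
#' @param sigma_target Target cap stress (Pa).
#' @param params,pillars As in [solve_equilibrium()].
#' @param state Converged starting state (post-inflation).
#' @param p_loop_tol,p_loop_max Pressure-loop controls.
#' @param quiet Progress output.
#' @return Converged `mech_state` at `sigma_target`.
#' @export
ramp_cap <- function(mesh, sigma_target, params, pillars, state,
                     p_loop_tol = 0.01, p_loop_max = 30, quiet = TRUE) {
  if (sigma_target <= 0) return(state)
  dsig_max <- min(2000, sigma_target / 10)
  dsig <- dsig_max
  sig <- state$load$sigma_cap
  while (sig < sigma_target - 1e-9) {
    sig_try <- min(sig + dsig, sigma_target)
    st <- equilibrate_pressure(mesh, list(sigma_cap = sig_try,
                                          dP = state$load$dP),
                               params, pillars, prev = state,
                               tol = p_loop_tol, max_iter = p_loop_max,
                               quiet = quiet)
    if (!isTRUE(st$converged)) {
      dsig <- dsig / 2
      if (dsig < sigma_target / 1280)
        stop("cap ramp failed to converge at sigma_cap = ", sig_try)
      next
    }
    state <- st
    sig <- sig_try
    dsig <- min(dsig * 1.5, dsig_max)
    if (!quiet) cat(sprintf("cap %.0f Pa: dP = %.1f, vol = %.1f
",
                            sig, state$load$dP, state$vol_nuc))
  }
  state
}

#' Extend the NE displacement into the nucleoplasm
#'
#' Minimizes a compressible neo-Hookean energy over the nucleoplasm with
#' the shell displacement as Dirichlet data on the inner NE, yielding the
#' displacement extension used to advect volume species.
#'
#' @param mesh Mesh.
#' @param state `mech_state` (supplies u on the inner NE).
#' @param params [material_params()] (`E1_nuc`, `phi_nuc`).
#' @param prev Optional previous extension (Newton start).
#' @param quiet Progress output.
#' @return List `u_nuc` (3 x nucleoplasm vertex displacements, full global
#'   vertex indexing), `converged`.
#' @export
extend_displacement_to_nucleoplasm <- function(mesh, state, params,
                                               prev = NULL, quiet = TRUE) {
  nuc_cells <- mesh$tets[mesh$region == 2L, , drop = FALSE]
  nv <- nrow(mesh$verts)
  u <- if (!is.null(prev)) prev else numeric(3 * nv)
  # Dirichlet: all vertices on Gamma_inner (shared with the shell)
  bnd <- unique(as.vector(mesh$inner_tri))
  ub <- state$u[as.vector(t(outer(3 * (mesh$shell_g2l[bnd] - 1), 1:3, `+`)))]
  bdofs <- as.vector(t(outer(3 * (bnd - 1), 1:3, `+`)))
  vset <- unique(as.vector(nuc_cells))
  adofs <- as.vector(t(outer(3 * (vset - 1), 1:3, `+`)))
  # mirror symmetry on the quarter-domain cut planes
  symx <- vset[abs(mesh$verts[vset, 1]) < 1e-9]
  symy <- vset[abs(mesh$verts[vset, 2]) < 1e-9]
  sdofs <- c(3 * (symx - 1) + 1, 3 * (symy - 1) + 2)
  u[setdiff(sdofs, bdofs)] <- 0
  free <- setdiff(adofs, c(bdofs, sdofs))
  # ramp the boundary data from the warm start so large squashes cannot
  # invert the interior in a single Dirichlet jump
  db <- ub - u[bdofs]
  nsub <- max(1L, min(24L, ceiling(max(abs(db)) / 0.3)))
  conv <- FALSE
  for (sub in seq_len(nsub)) {
  u[bdofs] <- ub - db * (1 - sub / nsub)
  conv <- FALSE
  R0n <- NULL
  for (it in 1:50) {
    a <- nuc_assemble_cpp(mesh$verts, nuc_cells, u, params$E1_nuc,
                          params$phi_nuc, TRUE)
    Rf <- a$Ru[free]
    rn <- sqrt(sum(Rf^2))
    if (is.null(R0n)) R0n <- max(rn, 1e-6)
    if (!quiet) cat(sprintf("  nuc newton %d |R| = %.3e minJ %.3f\n", it, rn, a$minJ))
    if (rn < max(1e-8 * R0n, 1e-9)) { conv <- TRUE; break }
    K <- Matrix::sparseMatrix(i = a$Ki + 1, j = a$Kj + 1, x = a$Kx,
                              dims = c(3 * nv, 3 * nv))
    du <- tryCatch(
      as.numeric(Matrix::solve(Matrix::lu(K[free, free, drop = FALSE]), -Rf)),
      error = function(e) NULL)
    if (is.null(du)) break
    step <- 1
    repeat {
      u2 <- u; u2[free] <- u[free] + step * du
      a2 <- nuc_assemble_cpp(mesh$verts, nuc_cells, u2, params$E1_nuc,
                             params$phi_nuc, FALSE)
      if ((a2$minJ > 0.02 && sqrt(sum(a2$Ru[free]^2)) < rn) || step < 1 / 64) break
      step <- step / 2
    }
    u <- u2
  }
  if (!conv) break
  }
  list(u_nuc = u, converged = conv)
}

# ---- pointwise constitutive helpers (used by tests and metrics) ----------

#' Kinematic quantities from a deformation gradient
#'
#' @param F 3x3 deformation gradient (standard convention F = dx/dX).
#' @param N Optional reference unit normal; if given, the surface stretch
#'   `alpha` and deformed normal `n` are returned via Nanson's formula.
#' @return List with `C`, `I1`, `I2`, `J` and optionally `alpha`, `n`.
#' @export
kinematics_point <- function(F, N = NULL) {
  C <- t(F) %*% F
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * t(C)))
  J <- det(F)
  out <- list(C = C, I1 = I1, I2 = I2, J = J)
  if (!is.null(N)) {
    an <- J * solve(t(F), N)
    out$alpha <- sqrt(sum(an^2))
    out$n <- an / out$alpha
  }
  out
}

#' Stress from the mixed Mooney-Rivlin energy at a point
#'
#' Evaluates the strain energy, first Piola-Kirchhoff stress and Cauchy
#' stress of `W = Es (E1 (I1bar - 3) + E2 (I2bar - 3)) - p (J - 1)` at a
#' single deformation gradient.
#'
#' @param F 3x3 deformation gradient.
#' @param p Pressure multiplier (Pa).
#' @param params [material_params()].
#' @param Escale Stiffness scale (default 1).
#' @return List `W`, `t_pk` (first PK), `sigma` (Cauchy).
#' @export
evaluate_stress <- function(F, p = 0, params = material_params(), Escale = 1) {
  kin <- kinematics_point(F)
  J <- kin$J; C <- kin$C; I1 <- kin$I1; I2 <- kin$I2
  a1 <- J^(-2 / 3); a2 <- a1^2
  Ci <- solve(C)
  W <- Escale * (params$E1 * (a1 * I1 - 3) + params$E2 * (a2 * I2 - 3)) -
    p * (J - 1)
  D1 <- a1 * (diag(3) - (I1 / 3) * Ci)
  D2 <- a2 * (I1 * diag(3) - C - (2 * I2 / 3) * Ci)
  S <- 2 * Escale * (params$E1 * D1 + params$E2 * D2) - p * J * Ci
  t_pk <- F %*% S
  sigma <- t_pk %*% t(F) / J
  list(W = W, t_pk = t_pk, sigma = sigma, S = S)
}

#' Membrane tension field on the outer NE
#'
#' Tension of the double bilayer, evaluated just inside the outer surface
#' (25 nm, the bilayer midplane): `gamma = dz_hat/2 (sigma_t1 + sigma_t2)`
#' with the frame tractions converted to true stresses by the in-plane
#' stretches.
#'
#' @param mesh Mesh.
#' @param state `mech_state`.
#' @param params [material_params()].
#' @return Data frame per outer facet: `gamma_mN_m`, `alpha`, deformed
#'   centroid coordinates, reference height.
#' @export
membrane_tension <- function(mesh, state, params) {
  nr <- sum(mesh$lev_r > mesh$shell$R0 - mesh$shell$DT + 1e-12)
  h_rad <- mesh$shell$DT / max(nr, 1)
  offset <- min(0.45, 0.025 / h_rad)
  fs <- facet_stress_cpp(mesh$Xp2, mesh$cells10, mesh$outer_facets$nodes6,
                         mesh$outer_facets$parent, state$u, state$p,
                         state$Escale, params$E1, params$E2,
                         offset, mesh$center, params$dz_hat)
  data.frame(gamma_mN_m = fs$gamma * 1e-3, alpha = fs$alpha,
             x = fs$x_def[, 1], y = fs$x_def[, 2], z = fs$x_def[, 3],
             Z_ref = fs$Z_ref)
}
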