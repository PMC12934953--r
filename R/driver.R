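# Orchestration of the coupled mechanochemical simulation:
# inflation -> steady-state initialization -> lamin-stiffness re-solve ->
# time loop (cap ramp, pressure equilibration, reaction-transport with
# dilution, stiffness and cytosol updates).

# map a shell-local vertex id to its angular column (outer-surface node)
shell_vert_ang <- function(mesh) {
  g <- mesh$shell_verts
  idx <- g - 1L
  l <- ceiling(idx / mesh$n_ang)
  as.integer(idx - (l - 1L) * mesh$n_ang)
}

# per-vertex outer-surface areal stretch (lumped deformed / reference area)
outer_vertex_stretch <- function(maps_ref, maps_now) {
  maps_now$w_out / maps_ref$w_out
}

# Re-solve the mechanics after a stiffness-scale change. For a uniform
# rescaling the equilibrium is invariant under jointly scaling the moduli
# and the load: the osmotic pressure is the multiplier holding the inflated
# volume, so it is rescaled with the stiffness and the geometry is kept.
# (At fixed pressure a >5% softening has no stable equilibrium at all: the
# tabulated inflation pressure sits just below the shell's limit-pressure
# plateau, and the softened balloon would run away.) Non-uniform changes
# are ramped in sub-steps.
resolve_with_escale <- function(mesh, state, Escale_new, params, pillars,
                                quiet = TRUE) {
  Es0 <- state$Escale
  ratio <- Escale_new / pmax(Es0, 1e-12)
  if (diff(range(ratio)) < 1e-8) {
    f <- ratio[1]
    state$Escale <- Escale_new
    state$load$dP <- state$load$dP * f
    state$p <- state$p * f
    st <- solve_equilibrium(mesh, state$load, params, pillars, prev = state,
                            quiet = quiet)
    if (!st$converged)
      stop("stiffness-scale re-solve failed after pressure rescaling")
    return(st)
  }
  rel <- max(abs(Escale_new - Es0) / pmax(Es0, 1e-9))
  nsub <- max(1L, min(8L, ceiling(rel / 0.05)))
  for (k in seq_len(nsub)) {
    state$Escale <- Es0 + (Escale_new - Es0) * k / nsub
    st <- solve_equilibrium(mesh, state$load, params, pillars, prev = state,
                            quiet = quiet)
    if (!st$converged)
      stop("stiffness-scale re-solve failed at sub-step ", k, " of ", nsub)
    state <- st
  }
  state
}

#' Run the coupled mechanochemical simulation
#'
#' Executes the full pipeline: (1) osmotic inflation of the shell, (2)
#' well-mixed steady-state initialization of all species from the
#' post-inflation measures, (3) re-solve with lamin-scaled stiffness,
#' (4) evaluation of F-actin, the initial stretch and free cytosolic
#' YAP/TAZ, then the time loop (5-11): cap-stress increment, osmotic
#' pressure equilibration, geometry update, implicit reaction-diffusion
#' with multiplicative dilution, cytosol and stiffness updates.
#'
#' @param config A [sim_config()].
#' @param mesh Optional prebuilt [build_reference_mesh()] mesh.
#' @param progress Print per-step progress.
#' @return Object of class `nucleomech_run`: `metrics` (per-output-time
#'   data frame), final `state`, `species`, `mesh`, `config`, and the
#'   initialization record.
#' @export
run_simulation <- function(config, mesh = NULL, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  shell <- config$shell; pillars <- config$pillars
  pars <- config$material; kin <- config$kinetics; sched <- config$schedule
  if (is.null(mesh)) mesh <- build_reference_mesh(shell)
  geom <- transport_geometry(mesh)
  maps_ref <- transport_maps(geom, mesh$verts)

  # (1) inflation
  state <- inflate_shell(mesh, pars, pars$Pmax, pillars = pillars,
                         n_steps = sched$n_inflate, quiet = !progress)
  for (k in 1:2)
    state <- solve_equilibrium(mesh, state$load, pars, pillars, prev = state,
                               quiet = TRUE)

  # (2) steady-state initialization from the post-inflation measures
  sa <- surface_areas(mesh, state)
  vol0 <- nucleoplasm_volume(mesh, state)
  ext <- extend_displacement_to_nucleoplasm(mesh, state, pars)
  xdef <- deformed_vertices(mesh, state, ext)
  maps <- transport_maps(geom, xdef)
  Ffield <- factin_concentration(xdef[geom$outer_vg, , drop = FALSE],
                                 pillars, kin, pars$d_steric)
  F0g <- factin_baseline(pillars, kin)
  Fmean <- sum(Ffield * maps$w_out) / sum(maps$w_out)
  init <- initial_steady_state(
    list(area_inner = sa$inner_def, area_outer = sa$outer_def,
         vol_nuc = vol0), kin, Fconc = Fmean, F0_global = F0g)
  # lamin stiffness reference: wild-type density at these measures
  L_ref <- kin$L_ref
  if (is.null(L_ref)) {
    kin_wt <- kin; kin_wt$NL <- 3.202e5
    L_ref <- initial_steady_state(
      list(area_inner = sa$inner_def, area_outer = sa$outer_def,
           vol_nuc = vol0), kin_wt, Fconc = Fmean, F0_global = F0g)$L
  }

  na <- geom$n_ang
  species <- list(L = rep(init$L, na), npc = rep(init$npc, na),
                  npca = rep(init$npca, na),
                  Lphos = rep(init$Lphos, geom$nv),
                  Ynuc = rep(init$Ynuc, geom$nv),
                  cytosol = init$cytosol)

  # (3) re-solve with lamin-scaled stiffness (ramped if the change is large)
  sva <- shell_vert_ang(mesh)
  Escale <- stiffness_scale(species$L[sva], kin, L_ref)
  state <- resolve_with_escale(mesh, state, Escale, pars, pillars)
  state$vol_nuc <- nucleoplasm_volume(mesh, state)

  # (4) initial stretch, F-actin and free YAP/TAZ over deformed coordinates
  ext <- extend_displacement_to_nucleoplasm(mesh, state, pars, prev = ext$u_nuc)
  xdef <- deformed_vertices(mesh, state, ext)
  maps <- transport_maps(geom, xdef)
  alpha_v <- outer_vertex_stretch(maps_ref, maps)
  alpha_init <- sum(alpha_v * maps$w_out) / sum(maps$w_out)
  Ffield <- factin_concentration(xdef[geom$outer_vg, , drop = FALSE],
                                 pillars, kin, pars$d_steric)

  t <- 0
  rows <- list()
  rows[[1]] <- metrics_row(mesh, state, species, maps, maps_ref, geom,
                           pars, kin, t = 0, alpha_init = alpha_init,
                           L_ref = L_ref, pillars = pillars)
  t_out_next <- sched$out_every
  dsig_max <- min(2000, max(sched$sigma_max, 1e-9) / 10)
  dt_next <- sched$dt_max

  while (t < sched$t_end - 1e-9) {
    # (5) time step bounded by the cap-stress increment rule
    dt <- min(dt_next, sched$t_end - t)
    repeat {
      dsig <- cap_stress_schedule(t + dt, sched$sigma_max, sched$t0_cap) -
        cap_stress_schedule(t, sched$sigma_max, sched$t0_cap)
      if (dsig <= dsig_max || dt <= sched$dt_min) break
      dt <- max(dt / 2, sched$dt_min)
    }
    sig <- cap_stress_schedule(t + dt, sched$sigma_max, sched$t0_cap)
    maps_old <- maps

    # (5-6) mechanics at the new cap stress, pressure equilibration
    st_try <- equilibrate_pressure(mesh, list(sigma_cap = sig,
                                              dP = state$load$dP),
                                   pars, pillars, prev = state,
                                   tol = sched$p_loop_tol,
                                   max_iter = sched$p_loop_max, quiet = TRUE)
    if (!isTRUE(st_try$converged)) {
      if (dt / 2 >= sched$dt_min) { dt_next <- dt / 2; next }
      stop("mechanics failed to converge at t = ", t + dt)
    }
    state <- st_try
    t <- t + dt
    # grow the step back gently after a successful solve
    dt_next <- min(sched$dt_max, dt * 2)

    # (7) geometry-dependent fields
    ext <- extend_displacement_to_nucleoplasm(mesh, state, pars,
                                              prev = ext$u_nuc)
    xdef <- deformed_vertices(mesh, state, ext)
    maps <- transport_maps(geom, xdef)
    alpha_v <- outer_vertex_stretch(maps_ref, maps)
    Ffield <- factin_concentration(xdef[geom$outer_vg, , drop = FALSE],
                                   pillars, kin, pars$d_steric)

    # (8-9) reaction-diffusion with dilution
    species <- transport_step(species, dt, maps_old, maps, geom, mesh,
                              kin, Ffield, alpha_v, alpha_init, F0g)

    # (10) stiffness update from the new lamin field
    Escale <- stiffness_scale(species$L[sva], kin, L_ref)
    state$Escale <- Escale

    if (progress)
      cat(sprintf("t=%6.0f s sigma=%5.1f dP=%6.1f vol=%6.1f N/C=%.3f\n",
                  t, sig, state$load$dP, state$vol_nuc,
                  tail(rows, 1)[[1]]$yap_nc))
    if (t >= t_out_next - 1e-9 || t >= sched$t_end - 1e-9) {
      rows[[length(rows) + 1]] <- metrics_row(mesh, state, species, maps,
                                              maps_ref, geom, pars, kin,
                                              t = t,
                                              alpha_init = alpha_init,
                                              L_ref = L_ref,
                                              pillars = pillars)
      t_out_next <- t_out_next + sched$out_every
    }
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics, state = state, species = species,
                 mesh = mesh, config = config, init = init,
                 alpha_init = alpha_init, L_ref = L_ref, ext = ext),
            class = "nucleomech_run")
}

# one reaction-transport step for all species (implicit diffusion +
# semi-implicit reactions + dilution); exchange fluxes between paired pools
# are explicit so they cancel exactly in the totals
transport_step <- function(species, dt, maps_old, maps_new, geom, mesh,
                           kin, Ffield, alpha_v, alpha_init, F0g) {
  na <- geom$n_ang
  keff <- lamin_dephos_rate(Ffield, kin)
  Lphos_surf <- species$Lphos[geom$outer_vg]

  # lamin cycling: both exchange fluxes are evaluated explicitly on the
  # outer-surface measure, so the pair conserves total lamin exactly (the
  # NE-bound pool advects with the inner surface but reacts at the outer
  # interface); the steady state is unchanged by the measure matching
  flux <- keff * Lphos_surf - kin$krl * species$L   # per outer area, um^-2/s
  w_ratio <- maps_new$w_out / maps_new$w_inner
  L_new <- step_lamin(species$L, kin$DL, dt, maps_old, maps_new, geom,
                      src = flux * w_ratio)

  # phospho-lamin: matching boundary flux with the 1/Nconv conversion
  Lphos_new <- step_volume_species(species$Lphos, kin$DL_vol, dt,
                                   maps_old, maps_new, geom,
                                   surf_src = -flux / kin$Nconv)

  # NPC pair: joint implicit exchange
  kf_field <- kin$kfNPC * Ffield * species$L * kin$MA
  npc_new <- step_npc_pair(species$npc, species$npca, kf_field, kin$krNPC,
                           kin$DNPC, dt, maps_old, maps_new, geom)

  # nuclear YAP/TAZ: stretch-gated import (explicit in Yfree), implicit
  # efflux
  kin_tot <- yap_import_rate(if (kin$alpha_local) alpha_v
                             else rep(sum(alpha_v * maps_new$w_out) /
                                        sum(maps_new$w_out), na),
                             alpha_init, npc_new$npca, kin)
  Ynuc_new <- step_volume_species(species$Ynuc, kin$DY, dt,
                                  maps_old, maps_new, geom,
                                  surf_src = kin_tot * species$cytosol$Yfree /
                                    kin$Nconv,
                                  surf_impl = rep(kin$kout / kin$Nconv, na))

  # clip tiny negatives (implicit Euler keeps these at round-off level)
  clip <- function(x) { x[x > -1e-10 & x < 0] <- 0; x }
  L_new <- clip(L_new); Lphos_new <- clip(Lphos_new)
  npc_new$npc <- clip(npc_new$npc); npc_new$npca <- clip(npc_new$npca)
  Ynuc_new <- clip(Ynuc_new)

  # cytosolic pools from global conservation over the deformed nucleus
  Ynuc_mol <- kin$Nconv * sum(Ynuc_new * maps_new$w_vol)
  cyt <- cytosolic_yap(Ynuc_mol, maps_new$vol_tot, F0g, kin)

  list(L = L_new, npc = npc_new$npc, npca = npc_new$npca,
       Lphos = Lphos_new, Ynuc = Ynuc_new, cytosol = cyt)
}

#' @export
print.nucleomech_run <- function(x, ...) {
  n <- nrow(x$metrics)
  cat(sprintf("nucleomech run: %d output times, t_end = %g s\n", n,
              x$metrics$t[n]))
  cat(sprintf("  final: vol = %.1f um^3, N/C = %.3f, max tension = %.3g mN/m\n",
              x$metrics$vol_nuc[n], x$metrics$yap_nc[n],
              x$metrics$max_tension[n]))
  invisible(x)
}

#' Sweep nanopillar pitch (and cap stress)
#'
#' Runs one simulation per (pitch, sigma_max) combination with identical
#' solver settings and summarizes the stretch / tension / force-per-lamin
#' metrics per row. `mode = "mechanics"` steps the cap stress along its
#' time schedule with the species frozen at their initialized values
#' (the stretch and tension outputs are purely mechanical); `"coupled"`
#' runs the full mechanochemical loop.
#'
#' @param config Template [sim_config()] (its `pillars` supply radius,
#'   height and cutoff).
#' @param pitches Pitch values (um).
#' @param sigma_max Cap stress plateau values (Pa).
#' @param mode `"mechanics"` or `"coupled"`.
#' @param t_end Override of the schedule end time.
#' @param progress Print per-run progress.
#' @return Data frame with one row per (pitch, sigma_max): mean lower-NE
#'   stretch, max tension (mN/m), integrated force per lamin (pN s),
#'   plus status flags. Failed runs are recorded and skipped.
#' @export
run_pitch_sweep <- function(config, pitches, sigma_max = config$schedule$sigma_max,
                            mode = c("mechanics", "coupled"), t_end = NULL,
                            progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(pitches) >= 1)
  out <- list()
  for (sm in sigma_max) for (p in pitches) {
    cfg <- config
    cfg$schedule$sigma_max <- sm
    if (!is.null(t_end)) cfg$schedule$t_end <- t_end
    cfg$pillars <- if (is.finite(p) && p > 0)
      nanopillar_array(config$pillars$r_np, config$pillars$h_np, p,
                       config$pillars$r_max)
    else flat_substrate()
    res <- tryCatch({
      if (mode == "coupled") {
        run <- run_simulation(cfg, progress = FALSE)
        mr <- run$metrics
        nfin <- nrow(mr)
        data.frame(pitch = p, sigma_max = sm,
                   mean_lower_stretch = mr$mean_lower_stretch[nfin],
                   max_tension = max(mr$max_tension),
                   integrated_force = integrated_force(mr$t, mr$FL_max),
                   yap_nc = mr$yap_nc[nfin], vol_nuc = mr$vol_nuc[nfin],
                   ok = TRUE)
      } else {
        sweep_mechanics_run(cfg)
      }
    }, error = function(e) {
      warning("sweep cell (pitch = ", p, ", sigma = ", sm, ") failed: ",
              conditionMessage(e))
      data.frame(pitch = p, sigma_max = sm, mean_lower_stretch = NA,
                 max_tension = NA, integrated_force = NA, yap_nc = NA,
                 vol_nuc = NA, ok = FALSE)
    })
    if (progress)
      cat(sprintf("pitch %.1f sigma %.0f: stretch %.3f tension %.3g\n",
                  p, sm, res$mean_lower_stretch, res$max_tension))
    out[[length(out) + 1]] <- res
  }
  do.call(rbind, out)
}

# mechanics-only sweep cell: inflate, ramp the cap along its schedule,
# record stretch/tension/force-per-lamin at output times
sweep_mechanics_run <- function(cfg) {
  mesh <- build_reference_mesh(cfg$shell)
  pars <- cfg$material; kin <- cfg$kinetics; sched <- cfg$schedule
  pillars <- cfg$pillars
  geom <- transport_geometry(mesh)
  maps_ref <- transport_maps(geom, mesh$verts)
  state <- inflate_shell(mesh, pars, pars$Pmax, pillars = pillars,
                         n_steps = sched$n_inflate, quiet = TRUE)
  for (k in 1:2)
    state <- solve_equilibrium(mesh, state$load, pars, pillars, prev = state,
                               quiet = TRUE)
  sa <- surface_areas(mesh, state)
  vol0 <- nucleoplasm_volume(mesh, state)
  init <- initial_steady_state(list(area_inner = sa$inner_def,
                                    area_outer = sa$outer_def,
                                    vol_nuc = vol0), kin,
                               Fconc = factin_baseline(pillars, kin))
  L_ref <- kin$L_ref
  if (is.null(L_ref)) {
    kin_wt <- kin; kin_wt$NL <- 3.202e5
    L_ref <- initial_steady_state(list(area_inner = sa$inner_def,
                                       area_outer = sa$outer_def,
                                       vol_nuc = vol0), kin_wt,
                                  Fconc = factin_baseline(pillars, kin))$L
  }
  state <- resolve_with_escale(mesh, state,
                               rep(stiffness_scale(init$L, kin, L_ref),
                                   mesh$n_sv),
                               pars, pillars)
  state$vol_nuc <- nucleoplasm_volume(mesh, state)
  # time stepping of the cap schedule (mechanics only)
  tgrid <- seq(0, sched$t_end, by = sched$out_every)
  FLmax <- numeric(length(tgrid))
  for (i in seq_along(tgrid)[-1]) {
    sig <- cap_stress_schedule(tgrid[i], sched$sigma_max, sched$t0_cap)
    st <- equilibrate_pressure(mesh, list(sigma_cap = sig, dP = state$load$dP),
                               pars, pillars, prev = state, quiet = TRUE)
    if (!isTRUE(st$converged)) {
      st <- ramp_cap(mesh, sig, pars, pillars, state, quiet = TRUE)
    }
    state <- st
    fs <- facet_stress_cpp(mesh$Xp2, mesh$cells10, mesh$inner_facets$nodes6,
                           mesh$inner_facets$parent, state$u, state$p,
                           state$Escale, pars$E1, pars$E2, 0.1, mesh$center,
                           pars$dz_hat)
    FLmax[i] <- max(force_per_lamin(fs$traction_mag, init$L))
  }
  mls <- mean_lower_stretch(mesh, state, pillars)
  mt <- max_tension(mesh, state, pars)
  data.frame(pitch = pillars$p_np, sigma_max = sched$sigma_max,
             mean_lower_stretch = mls, max_tension = mt,
             integrated_force = integrated_force(tgrid, FLmax),
             yap_nc = NA, vol_nuc = state$vol_nuc, ok = TRUE)
}
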