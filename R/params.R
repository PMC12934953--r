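#' Mechanical material parameters
#'
#' Constants of the hyperelastic NE model and its numerical treatment.
#' Defaults are the tabulated values for U2OS nuclei: Mooney-Rivlin
#' constants `E1`, `E2`; incompressibility penalty (bulk modulus) `phi0`;
#' nucleoplasm bulk modulus `phi_inner` driving the osmotic-pressure update;
#' inflation pressure `Pmax`; pillar contact-repulsion strength
#' `sigma_contact0` and steric decay length `d_steric`; cap-stress decay
#' length `Z0`; nucleoplasm-extension moduli `E1_nuc`, `phi_nuc`; and the
#' double-bilayer thickness `dz_hat` used by the membrane-tension output.
#'
#' @param E1,E2 Mooney-Rivlin elastic constants (Pa).
#' @param phi0 Incompressibility penalty / bulk modulus of the shell (Pa).
#' @param phi_inner Nucleoplasm bulk modulus for the pressure update (Pa).
#' @param Pmax Target transmembrane (osmotic) pressure (Pa).
#' @param sigma_contact0 Contact repulsion strength (Pa).
#' @param d_steric Steric decay length (um).
#' @param Z0 Cap-stress decay length (um).
#' @param E1_nuc,phi_nuc Nucleoplasm-extension moduli (Pa).
#' @param dz_hat Double bilayer plus perinuclear space thickness (um).
#' @param contact_ez If `TRUE`, apply the pillar repulsion along +ez instead
#'   of the deformed normal (weak-form variant switch).
#' @return Object of class `material_params`.
#' @export
material_params <- function(E1 = 5000, E2 = 1000, phi0 = 1e8,
                            phi_inner = 100, Pmax = 820,
                            sigma_contact0 = 1000, d_steric = 0.2,
                            Z0 = 2.05, E1_nuc = 5000, phi_nuc = 1e5,
                            dz_hat = 0.05, contact_ez = FALSE) {
  stopifnot(E1 > 0, E2 >= 0, phi0 > 0, phi_inner > 0, d_steric > 0, Z0 > 0)
  structure(as.list(environment()), class = "material_params")
}

#' Reaction-transport and signaling parameters
#'
#' Kinetic constants for lamin A/C cycling, NPC activation, YAP/TAZ
#' transport and the cytosolic pools, plus molecule totals for the quarter
#' cell. Defaults are the tabulated wild-type values.
#'
#' Two constants appear in the governing equations but are not tabulated in
#' the source model: the fixed active-myosin concentration `MA` and the
#' YAP/TAZ nuclear efflux rate `kout`. Their defaults (1.5 uM, 1.0 s^-1) are
#' taken from the prior whole-cell model lineage this model builds on and
#' are exposed as ordinary configuration parameters; quantitative outputs
#' that depend on their magnitude should be interpreted accordingly.
#'
#' @param DL NE lamin surface diffusion (um^2/s).
#' @param DL_vol Nucleoplasmic phospho-lamin diffusion (um^2/s).
#' @param DNPC NPC surface diffusion (um^2/s).
#' @param DY Nuclear YAP/TAZ diffusion (um^2/s).
#' @param krl Lamin phosphorylation rate (1/s).
#' @param kfl Maximum lamin dephosphorylation rate (um^-2 uM^-1 s^-1).
#' @param pcyto Cytoplasmic stiffness coefficient (kPa uM^-2.6).
#' @param CL Cytoplasmic stiffness sensitivity (kPa).
#' @param kfNPC NPC activation rate (um^2 s^-1 uM^-1).
#' @param krNPC NPC deactivation rate (1/s).
#' @param kin_b Baseline YAP/TAZ import rate (um^-2 s^-1 uM^-1).
#' @param kin NPC-dependent YAP/TAZ import rate (per um^-2 of active NPC).
#' @param alpha0 NPC stretch sensitivity (dimensionless stretch scale).
#' @param kCN,kCY,kNC Cytosolic YAP/TAZ de-sequestration / sequestration rates.
#' @param MA Fixed active myosin concentration (uM).
#' @param kout YAP/TAZ nuclear efflux rate (1/s).
#' @param phi_scale Flux scaling factor for YAP/TAZ influx.
#' @param phi_L Relative contribution of lamin A/C to NE stiffness (0..1).
#' @param L_ref Lamin stiffness normalization density (um^-2); `NULL` means
#'   "use the wild-type initial density of the run" so the initial stiffness
#'   scale is exactly 1.
#' @param NL,NNPC,NY Total molecule numbers in the quarter cell (wild type).
#' @param voltot Total quarter-cell volume (um^3).
#' @param Nconv Concentration conversion factor (molecules um^-3 uM^-1).
#' @param F0_flat,F0_r02,F0_r05 Baseline F-actin (uM) on flat / 0.2 um /
#'   0.5 um pillar substrates.
#' @param F1 Curvature-dependent F-actin amplitude (uM).
#' @param dF F-actin decay length (um).
#' @param H0 Curvature sensitivity of actin polymerization (um^-1 scale).
#' @param ss_hill If `TRUE` (default) the steady-state initialization uses
#'   the effective dephosphorylation rate (kfl times the Hill factor in
#'   F-actin) so the initial state is a fixed point of the lamin cycling
#'   dynamics; `FALSE` reproduces the literal tabulated expressions with
#'   bare `kfl`.
#' @param alpha_local If `TRUE` (default) the stretch entering the import
#'   rate is the local outer-surface stretch field; `FALSE` uses its
#'   surface average.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(DL = 0.001, DL_vol = 4.0, DNPC = 0.001, DY = 4.0,
                           krl = 0.001, kfl = 415.5, pcyto = 9e-6, CL = 100,
                           kfNPC = 2.8e-7, krNPC = 8.7,
                           kin_b = 1.0, kin = 10.0, alpha0 = 5.0,
                           kCN = 0.56, kCY = 7.6e-4, kNC = 0.14,
                           MA = 1.5, kout = 1.0,
                           phi_scale = 0.2, phi_L = 0.5, L_ref = NULL,
                           NL = 3.202e5, NNPC = 594.7, NY = 5.339e5,
                           voltot = 1024.0, Nconv = 602.2,
                           F0_flat = 140, F0_r02 = 100, F0_r05 = 120,
                           F1 = 20, dF = 0.5, H0 = 2.0,
                           ss_hill = TRUE, alpha_local = TRUE) {
  stopifnot(phi_L >= 0, phi_L <= 1, voltot > 0, Nconv > 0)
  structure(as.list(environment()), class = "kinetic_params")
}

#' Load schedule and solver settings for a coupled run
#'
#' @param sigma_max Maximum perinuclear cap stress (Pa), 0-800 in the study.
#' @param t0_cap Cap assembly time scale (s), 100-1000 in the study.
#' @param t_end End time (s).
#' @param dt_min,dt_max Adaptive time-step bounds (s).
#' @param out_every Output cadence (s of simulated time).
#' @param newton_tol Relative Newton residual tolerance.
#' @param newton_max Maximum Newton iterations.
#' @param p_loop_tol Relative pressure-change tolerance of the osmotic
#'   equilibration loop.
#' @param p_loop_max Maximum pressure-update iterations.
#' @param n_inflate Pressure increments used for the initial inflation.
#' @return Object of class `sim_schedule`.
#' @export
sim_schedule <- function(sigma_max = 400, t0_cap = 1000, t_end = 10000,
                         dt_min = 0.5, dt_max = 50, out_every = 50,
                         newton_tol = 1e-8, newton_max = 50,
                         p_loop_tol = 0.01, p_loop_max = 30,
                         n_inflate = 8) {
  stopifnot(t_end > 0, sigma_max >= 0, t0_cap > 0, dt_min > 0,
            dt_max >= dt_min)
  structure(as.list(environment()), class = "sim_schedule")
}

#' Full simulation configuration
#'
#' Bundles geometry, substrate, material, kinetics and schedule. This is
#' the single object consumed by [run_simulation()] and the configuration
#' file round-trip.
#'
#' @param shell A [shell_geometry()].
#' @param pillars A [nanopillar_array()] or [flat_substrate()].
#' @param material A [material_params()].
#' @param kinetics A [kinetic_params()].
#' @param schedule A [sim_schedule()].
#' @param seed Integer seed recorded in the manifest (the solver itself is
#'   deterministic; the seed governs perturbation-based diagnostics only).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(shell = shell_geometry(), pillars = flat_substrate(),
                       material = material_params(),
                       kinetics = kinetic_params(),
                       schedule = sim_schedule(), seed = 1L) {
  stopifnot(inherits(shell, "shell_geometry"),
            inherits(pillars, "nanopillar_array"),
            inherits(material, "material_params"),
            inherits(kinetics, "kinetic_params"),
            inherits(schedule, "sim_schedule"))
  structure(list(shell = shell, pillars = pillars, material = material,
                 kinetics = kinetics, schedule = schedule,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Coupled NE simulation configuration\n")
  print(x$shell); print(x$pillars)
  cat(sprintf("  sigma_max = %g Pa, t0_cap = %g s, t_end = %g s\n",
              x$schedule$sigma_max, x$schedule$t0_cap, x$schedule$t_end))
  invisible(x)
}
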