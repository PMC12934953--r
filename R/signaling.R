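# Reaction rate laws, cytosolic pools and steady-state initialization.

#' Hill-type effective lamin dephosphorylation rate
#'
#' `kfl * pcyto [F]^2.6 / (CL + pcyto [F]^2.6)`: dephosphorylation is
#' promoted by cytoskeletal (F-actin dependent) stiffness.
#' @param Fconc F-actin concentration (uM), vectorized.
#' @param kin [kinetic_params()].
#' @return Effective rate (same units as `kfl`).
#' @export
lamin_dephos_rate <- function(Fconc, kin) {
  h <- kin$pcyto * Fconc^2.6
  kin$kfl * h / (kin$CL + h)
}

#' Lamin cycling fluxes
#'
#' Phosphorylation `krl [L]` (surface loss) and dephosphorylation
#' `kfl_eff([F]) [L]phos` (surface gain), both per unit NE area; the
#' matching volume-pool flux carries the `1/Nconv` conversion.
#' @param L NE-bound lamin density (um^-2).
#' @param Lphos Phospho-lamin concentration (uM).
#' @param Fconc Local F-actin (uM).
#' @param kin [kinetic_params()].
#' @return List `phos` (um^-2 s^-1), `dephos` (um^-2 s^-1).
#' @export
lamin_cycling_rates <- function(L, Lphos, Fconc, kin) {
  list(phos = kin$krl * L, dephos = lamin_dephos_rate(Fconc, kin) * Lphos)
}

#' NPC activation / deactivation rates
#'
#' Mass-action forward rate with F-actin, lamin and myosin as modifiers,
#' first-order reverse rate.
#' @param npc,npca Inactive/active NPC densities (um^-2).
#' @param Fconc F-actin (uM).
#' @param L Lamin density (um^-2).
#' @param kin [kinetic_params()].
#' @return List `forward`, `reverse` (um^-2 s^-1).
#' @export
npc_activation_rates <- function(npc, npca, Fconc, L, kin) {
  list(forward = kin$kfNPC * Fconc * L * kin$MA * npc,
       reverse = kin$krNPC * npca)
}

#' Stretch-gated YAP/TAZ import rate
#'
#' `kin_tot = phi_scale (kin_b + kin [NPC]A) exp((alpha - alpha_init)/alpha0)`.
#' @param alpha Local outer-NE areal stretch.
#' @param alpha_init Average stretch at initialization.
#' @param npca Active NPC density (um^-2).
#' @param kin [kinetic_params()].
#' @return Import rate (same units as `kin_b`).
#' @export
yap_import_rate <- function(alpha, alpha_init, npca, kin) {
  stopifnot(all(alpha > 0))
  kin$phi_scale * (kin$kin_b + kin$kin * npca) *
    exp((alpha - alpha_init) / kin$alpha0)
}

#' YAP/TAZ boundary flux on the outer NE
#'
#' `D dY/dn = (kin_tot [Y]free - kout [Y]nuc) / Nconv` (influx positive).
#' @param Ynuc Nuclear YAP/TAZ at the surface (uM).
#' @param Yfree Free cytosolic YAP/TAZ (uM).
#' @param kin_tot Import rate (vectorized).
#' @param kin [kinetic_params()].
#' @return Flux density (uM um / s).
#' @export
yap_boundary_flux <- function(Ynuc, Yfree, kin_tot, kin) {
  (kin_tot * Yfree - kin$kout * Ynuc) / kin$Nconv
}

#' Cytosolic YAP/TAZ pools from global conservation
#'
#' Total cytosolic concentration from the conserved molecule number and
#' the current nuclear content; the free fraction follows from the
#' pseudo-steady sequestration balance, with the global actin level
#' used for the cytosol.
#'
#' @param Ynuc_total_molecules Nuclear YAP/TAZ content in molecules
#'   (`Nconv * integral of [Y]nuc over the deformed nucleus`).
#' @param vol_nuc Deformed nuclear volume (um^3).
#' @param F0 Global cytosolic F-actin (uM).
#' @param kin [kinetic_params()].
#' @return List of class `cytosol_state`: `Ycyto`, `Yfree`, `Yseq` (uM),
#'   `free_fraction`.
#' @export
cytosolic_yap <- function(Ynuc_total_molecules, vol_nuc, F0, kin) {
  if (vol_nuc >= kin$voltot)
    stop("deformed nuclear volume exceeds the total cell volume")
  Ycyto <- (kin$NY - Ynuc_total_molecules) / (kin$Nconv * (kin$voltot - vol_nuc))
  fr <- (kin$kCN + kin$kCY * F0 * kin$MA) /
    (kin$kNC + kin$kCN + kin$kCY * F0 * kin$MA)
  structure(list(Ycyto = Ycyto, Yfree = fr * Ycyto,
                 Yseq = (1 - fr) * Ycyto, free_fraction = fr),
            class = "cytosol_state")
}

#' Well-mixed steady-state initialization of all species
#'
#' Sets every species to the uniform steady state of the well-mixed
#' kinetics given the post-inflation measures (inner/outer NE areas and
#' nucleoplasm volume). With `ss_hill = TRUE` (default) the lamin balance
#' uses the effective Hill-modulated dephosphorylation rate evaluated at
#' `Fconc`, so the state is a true fixed point of the cycling dynamics;
#' with `FALSE` the bare maximum rate is used, reproducing the literal
#' tabulated expressions.
#'
#' @param measures List with `area_inner`, `area_outer` (um^2) and
#'   `vol_nuc` (um^3) from the post-inflation solve (the tabulated
#'   reference values may be passed instead).
#' @param kin [kinetic_params()].
#' @param Fconc F-actin concentration used for the balance (uM); typically
#'   the initial surface average.
#' @param F0_global Global cytosolic F-actin (uM) for the sequestration
#'   balance; defaults to `Fconc`.
#' @return List of class `species_init`: `L`, `Lphos`, `npc`, `npca`,
#'   `Ynuc` (uniform values) plus the implied `cytosol` and N/C ratio.
#' @export
initial_steady_state <- function(measures, kin, Fconc = NULL,
                                 F0_global = NULL) {
  SAi <- measures$area_inner; SAo <- measures$area_outer
  vol <- measures$vol_nuc
  stopifnot(SAi > 0, SAo > 0, vol > 0)
  if (is.null(Fconc)) Fconc <- kin$F0_flat
  if (is.null(F0_global)) F0_global <- Fconc
  keff <- if (kin$ss_hill) lamin_dephos_rate(Fconc, kin) else kin$kfl
  # lamin partition: krl L = keff Lphos on the surface; NL conserved
  Lphos <- kin$NL * kin$krl / (keff * SAi + kin$krl * vol * kin$Nconv)
  L <- (kin$NL - Lphos * vol * kin$Nconv) / SAi
  # NPC activation equilibrium
  kf <- kin$kfNPC * Fconc * L * kin$MA
  npc_tot <- kin$NNPC / SAo
  npca <- npc_tot * kf / (kf + kin$krNPC)
  npc <- npc_tot - npca
  # YAP balance: import = efflux with alpha = alpha_init
  fr <- (kin$kCN + kin$kCY * F0_global * kin$MA) /
    (kin$kNC + kin$kCN + kin$kCY * F0_global * kin$MA)
  k1 <- fr * kin$phi_scale * (kin$kin_b + kin$kin * npca)
  Ynuc <- kin$NY * k1 /
    (kin$Nconv * (k1 * vol + kin$kout * (kin$voltot - vol)))
  cyt <- cytosolic_yap(Ynuc * vol * kin$Nconv, vol, F0_global, kin)
  structure(list(L = L, Lphos = Lphos, npc = npc, npca = npca, Ynuc = Ynuc,
                 cytosol = cyt, nc_ratio = Ynuc / cyt$Ycyto,
                 Fconc = Fconc, keff = keff),
            class = "species_init")
}


#' @export
print.species_init <- function(x, ...) {
  cat(sprintf("steady state: [L] = %.0f um^-2, [L]phos = %.4g uM, [NPC]A = %.3g um^-2,\n",
              x$L, x$Lphos, x$npca))
  cat(sprintf("  [Y]nuc = %.3g uM, [Y]cyto = %.3g uM (N/C = %.3g)\n",
              x$Ynuc, x$cytosol$Ycyto, x$nc_ratio))
  invisible(x)
}

#' Lamin-dependent stiffness scale
#'
#' `Escale = (1 - phi_L) + phi_L [L]/[L]ref`: the membrane contribution
#' persists at zero lamin and the scale is exactly 1 at the reference
#' density.
#' @param L Lamin density (um^-2), vectorized.
#' @param kin [kinetic_params()] (`phi_L`, `L_ref`).
#' @param L_ref Optional override of the reference density.
#' @return Stiffness multiplier, same shape as `L`.
#' @export
stiffness_scale <- function(L, kin, L_ref = NULL) {
  ref <- if (!is.null(L_ref)) L_ref else kin$L_ref
  if (is.null(ref)) stop("no lamin reference density available")
  (1 - kin$phi_L) + kin$phi_L * L / ref
}

#' Force per lamin subunit
#'
#' Local NE traction magnitude divided by lamin density, in pN
#' (1 Pa um^2 = 1 pN). Densities below `floor_density` are floored to
#' avoid division blow-up and flagged.
#' @param traction_mag Traction magnitude (Pa).
#' @param L Lamin density (um^-2).
#' @param floor_density Minimum density used in the division.
#' @return Vector of forces (pN); attribute `flagged` marks floored entries.
#' @export
force_per_lamin <- function(traction_mag, L, floor_density = 1) {
  flag <- L < floor_density
  out <- traction_mag / pmax(L, floor_density)
  attr(out, "flagged") <- flag
  out
}
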