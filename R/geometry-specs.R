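#' Shell geometry specification
#'
#' Describes the stress-free reference configuration of the nuclear envelope
#' (NE): a spherical shell of outer radius `R0` and thickness `DT` whose
#' lowest point sits `znuc` above the substrate plane (pillar tops at z = 0).
#'
#' @param R0 Stress-free outer radius (um).
#' @param DT Stress-free shell thickness (um); must satisfy 0 < DT < R0.
#' @param znuc Initial height of the NE bottom above the pillar-top plane (um).
#' @param hedge Target mesh edge length (um).
#' @param Droof Roof-patch diameter cutoff (um); facets of the outer NE with
#'   X^2 + Y^2 <= Droof^2 form the roof patch used by the apex Dirichlet
#'   stabilization. Default `10 * hedge`.
#' @return An object of class `shell_geometry`.
#' @export
shell_geometry <- function(R0 = 4.1, DT = 0.2, znuc = 1.04,
                           hedge = 0.15, Droof = 10 * hedge) {
  stopifnot(R0 > 0, DT > 0, DT < R0, hedge > 0, znuc >= 0, Droof > 0)
  structure(list(R0 = R0, DT = DT, znuc = znuc, hedge = hedge,
                 Droof = Droof, center = c(0, 0, znuc + R0)),
            class = "shell_geometry")
}

#' Nanopillar array specification
#'
#' Square lattice of cylindrical nanopillars with radius `r_np`, height
#' `h_np` and center-to-center pitch `p_np`. Pillar tops lie in the plane
#' z = 0 and the substrate floor at z = -h_np; `h_np = 0` describes a flat
#' substrate (floor at z = 0, no pillars). The lattice is truncated at
#' `r_max`; the half-extent in lattice units is `n_np = round(r_max / p_np)`.
#'
#' @param r_np Pillar radius (um).
#' @param h_np Pillar height (um); 0 means flat substrate.
#' @param p_np Center-to-center pitch (um); must be >= 2 * r_np when
#'   `h_np > 0` so pillars do not overlap.
#' @param r_max Lattice cutoff radius (um). Default 7.5 um, about 1.5x the
#'   inflated nuclear radius, so every pillar the nucleus could touch is
#'   represented.
#' @return An object of class `nanopillar_array`.
#' @export
nanopillar_array <- function(r_np = 0.2, h_np = 1.5, p_np = 5, r_max = 7.5) {
  stopifnot(r_np >= 0, h_np >= 0, p_np >= 0, r_max >= 0)
  if (h_np > 0 && p_np < 2 * r_np)
    stop("pillar pitch must satisfy p_np >= 2 * r_np (non-overlapping pillars)")
  n_np <- if (p_np > 0) round(r_max / p_np) else 0L
  structure(list(r_np = r_np, h_np = h_np, p_np = p_np, r_max = r_max,
                 n_np = as.integer(n_np)),
            class = "nanopillar_array")
}

#' Flat substrate (degenerate nanopillar array)
#' @return A `nanopillar_array` with `h_np = 0`.
#' @export
flat_substrate <- function() nanopillar_array(r_np = 0, h_np = 0, p_np = 0, r_max = 0)

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf(
    "NE shell: R0 = %.3g um, thickness = %.3g um, bottom at z = %.3g um, hedge = %.3g um\n",
    x$R0, x$DT, x$znuc, x$hedge))
  invisible(x)
}

#' @export
print.nanopillar_array <- function(x, ...) {
  if (x$h_np == 0) cat("Flat substrate (floor at z = 0)\n")
  else cat(sprintf(
    "Nanopillar array: r = %.3g um, h = %.3g um, pitch = %.3g um, cutoff %.3g um (half-extent %d)\n",
    x$r_np, x$h_np, x$p_np, x$r_max, x$n_np))
  invisible(x)
}

#' Outward unit normal of the reference shell
#'
#' Radial unit vector about the shell center, valid on any constant-radius
#' slice of the NE.
#'
#' @param X Matrix (n x 3) or length-3 vector of material points.
#' @param shell A [shell_geometry()].
#' @return Matrix (n x 3) of unit outward normals.
#' @export
reference_normal <- function(X, shell) {
  X <- rbind_point(X)
  D <- sweep(X, 2, shell$center)
  r <- sqrt(rowSums(D^2))
  if (any(r < 1e-12)) stop("reference normal undefined at the shell center")
  D / r
}

#' Tangent frame on the reference shell
#'
#' Returns the azimuthal and meridional unit tangents (eTheta, ePhi) with
#' eTheta = (-Y, X, 0)/sqrt(X^2+Y^2) and ePhi = eTheta x N. On the polar
#' axis (X = Y = 0) the frame is singular; a fixed axis-aligned pair
#' (ex rotated into the tangent plane) is substituted there, which is
#' immaterial for isotropic in-plane stress measures.
#'
#' @inheritParams reference_normal
#' @return List with matrices `e_theta`, `e_phi` (n x 3).
#' @export
tangent_frame <- function(X, shell) {
  X <- rbind_point(X)
  N <- reference_normal(X, shell)
  rho <- sqrt(X[, 1]^2 + X[, 2]^2)
  et <- cbind(-X[, 2], X[, 1], 0) / pmax(rho, 1e-300)
  onaxis <- rho < 1e-9
  if (any(onaxis)) {
    # fixed fallback: e_theta = ey, giving e_phi = +-ex at the poles
    et[onaxis, ] <- matrix(rep(c(0, 1, 0), sum(onaxis)), ncol = 3, byrow = TRUE)
  }
  ep <- cbind(et[, 2] * N[, 3] - et[, 3] * N[, 2],
              et[, 3] * N[, 1] - et[, 1] * N[, 3],
              et[, 1] * N[, 2] - et[, 2] * N[, 1])
  list(e_theta = et, e_phi = ep)
}

rbind_point <- function(X) {
  if (is.null(dim(X))) matrix(X, ncol = 3) else as.matrix(X)
}

#' Sharp nanopillar indicator
#'
#' 1 iff the in-plane point (x, y) lies within distance `r_np` of a lattice
#' point of the pillar array, 0 otherwise.
#'
#' @param x,y In-plane coordinates (um), vectors of equal length.
#' @param pillars A [nanopillar_array()].
#' @return Integer vector of 0/1.
#' @export
pillar_indicator <- function(x, y, pillars) {
  if (pillars$h_np == 0 || pillars$p_np <= 0)
    return(integer(length(x)))
  d2 <- nearest_pillar_dist2(x, y, pillars)
  as.integer(d2 <= pillars$r_np^2 + 1e-15)
}

nearest_pillar_dist2 <- function(x, y, pillars) {
  p <- pillars$p_np; n <- pillars$n_np
  # candidate lattice cells around each point (clamped to the lattice extent)
  ix <- pmin(pmax(round(x / p), -n), n)
  iy <- pmin(pmax(round(y / p), -n), n)
  d2 <- rep(Inf, length(x))
  for (dx in -1:1) for (dy in -1:1) {
    jx <- pmin(pmax(ix + dx, -n), n)
    jy <- pmin(pmax(iy + dy, -n), n)
    d2 <- pmin(d2, (x - jx * p)^2 + (y - jy * p)^2)
  }
  d2
}

#' Smooth (super-Gaussian) nanopillar indicator
#'
#' Sum over the pillar lattice of exp(-r^4 / (2 (r_np + 0.05)^4)) where r is
#' the in-plane distance to each pillar center. Approaches the sharp
#' indicator as the super-Gaussian width shrinks, without the sharp cutoff
#' that hampers Newton convergence of the contact term.
#'
#' @inheritParams pillar_indicator
#' @return Numeric vector (nonnegative; about 1 over a pillar).
#' @export
pillar_indicator_smooth <- function(x, y, pillars) {
  if (pillars$h_np == 0 || pillars$p_np <= 0)
    return(numeric(length(x)))
  w4 <- 2 * (pillars$r_np + 0.05)^4
  p <- pillars$p_np; n <- pillars$n_np
  out <- numeric(length(x))
  for (nx in -n:n) for (ny in -n:n) {
    r2 <- (x - nx * p)^2 + (y - ny * p)^2
    out <- out + exp(-r2^2 / w4)
  }
  out
}

#' Distance and curvature of the plasma membrane seen from an NE point
#'
#' The plasma membrane (PM) is modeled as a cylinder hugging each pillar at
#' a steric offset of 0.05 um, plus the flat substrate floor. For a deformed
#' NE point, returns the distance to the PM above the pillar top (`d_top`),
#' to the pillar side (`d_side`), and the PM mean curvature `H_pm` of the
#' nearest PM region (0 on the top, 1/(2 (r_np + 0.05)) on the side).
#'
#' @param x Deformed NE points, matrix (n x 3) with z measured from the
#'   pillar-top plane.
#' @param pillars A [nanopillar_array()].
#' @param d_steric Steric gap between PM and NE (um), default 0.2.
#' @return List with vectors `d_top`, `d_side`, `H_pm`, `r_local`.
#' @export
pm_distance_and_curvature <- function(x, pillars, d_steric = 0.2) {
  x <- rbind_point(x)
  z <- x[, 3]
  rpm <- pillars$r_np + 0.05
  r_local <- sqrt(nearest_pillar_dist2(x[, 1], x[, 2], pillars))
  d_top <- ifelse(r_local <= rpm, z + d_steric,
                  sqrt((r_local - pillars$r_np)^2 + (z + d_steric)^2))
  d_side <- ifelse(z > -d_steric,
                   sqrt((r_local - pillars$r_np)^2 + (z + d_steric)^2),
                   r_local - pillars$r_np)
  H_pm <- ifelse(r_local <= rpm, 0, 1 / (2 * rpm))
  list(d_top = d_top, d_side = d_side, H_pm = H_pm, r_local = r_local)
}

#' Local F-actin concentration at the NE
#'
#' F-actin at the NE-cytosol interface decays with NE-PM distance and is
#' amplified by PM curvature: `[F] = [F]0 + [F]1 exp(-d/dF) exp(H/H0)`.
#' On a flat substrate the distance is the height above the floor plus the
#' steric gap; on pillars the maximum of the top and side contributions is
#' taken, which keeps the field continuous across the pillar shoulder.
#'
#' @param x Deformed NE points (n x 3).
#' @param pillars A [nanopillar_array()].
#' @param kin A [kinetic_params()] (uses `F0` for this pillar radius, `F1`,
#'   `dF`, `H0`).
#' @param d_steric Steric gap (um), default 0.2.
#' @return Numeric vector of concentrations (uM), always >= `F0`.
#' @export
factin_concentration <- function(x, pillars, kin, d_steric = 0.2) {
  x <- rbind_point(x)
  F0 <- factin_baseline(pillars, kin)
  if (pillars$h_np == 0) {
    return(F0 + kin$F1 * exp(-(x[, 3] + d_steric) / kin$dF))
  }
  pm <- pm_distance_and_curvature(x, pillars, d_steric)
  side_curv <- exp(1 / (2 * (pillars$r_np + 0.05)) / kin$H0)
  top <- exp(-pm$d_top / kin$dF)
  side <- exp(-pm$d_side / kin$dF) * side_curv
  F0 + kin$F1 * pmax(top, side)
}

#' Baseline (global cytosolic) F-actin for a substrate
#'
#' The global F-actin level depends on pillar radius: curvature-dependent
#' inhibition of focal adhesions lowers it on nanopillars (140 uM flat,
#' 100 uM for 0.2 um pillars, 120 uM for 0.5 um pillars; linear
#' interpolation in radius between the tabulated values).
#' @inheritParams factin_concentration
#' @return Scalar concentration (uM).
#' @export
factin_baseline <- function(pillars, kin) {
  if (pillars$h_np == 0) return(kin$F0_flat)
  r <- pillars$r_np
  if (r <= 0.2) kin$F0_r02
  else if (r >= 0.5) kin$F0_r05
  else kin$F0_r02 + (kin$F0_r05 - kin$F0_r02) * (r - 0.2) / 0.3
}
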