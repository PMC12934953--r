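# Structured quarter-domain tetrahedral mesh of the NE shell plus nucleoplasm.
#
# The angular discretization is an "octasphere": each of the two octants of
# the quarter sphere (X >= 0, Y >= 0) is a subdivided spherical triangle, and
# the two share the equator arc, giving a conforming triangulation with no
# degenerate pole cells. Radial levels carry copies of this triangulation;
# consecutive levels are connected by prisms split into tetrahedra with the
# minimal-global-vertex diagonal rule, which guarantees a conforming split.
# The radial structure means the concentric inner<->outer surface map sends
# outer vertices exactly onto inner-surface vertices.

octasphere_quarter <- function(n) {
  stopifnot(n >= 2)
  key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9), round(p[, 3], 9))
  verts <- list(); vkey <- character(0)
  tris <- matrix(0L, 0, 3)
  add_octant <- function(A, B, C) {
    idx <- matrix(0L, n + 1, n + 1) # idx[r+1, q+1]
    for (r in 0:n) for (q in 0:r) {
      p <- (n - r) * A + (r - q) * B + q * C
      p <- p / sqrt(sum(p^2))
      k <- key(matrix(p, 1))
      j <- match(k, vkey)
      if (is.na(k) || is.na(j)) {
        verts[[length(verts) + 1]] <<- p
        vkey[length(vkey) + 1] <<- k
        j <- length(verts)
      }
      idx[r + 1, q + 1] <- j
    }
    for (r in 1:n) for (q in 0:(r - 1)) {
      tris <<- rbind(tris, c(idx[r, q + 1], idx[r + 1, q + 1], idx[r + 1, q + 2]))
      if (q < r - 1)
        tris <<- rbind(tris, c(idx[r, q + 1], idx[r + 1, q + 2], idx[r, q + 2]))
    }
  }
  add_octant(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  add_octant(c(0, 0, -1), c(1, 0, 0), c(0, 1, 0))
  V <- do.call(rbind, verts)
  # orient all triangles outward (counterclockwise seen from outside)
  for (t in seq_len(nrow(tris))) {
    a <- V[tris[t, 1], ]; b <- V[tris[t, 2], ]; c_ <- V[tris[t, 3], ]
    nrm <- crossprod3(b - a, c_ - a)
    if (sum(nrm * (a + b + c_)) < 0) tris[t, 2:3] <- tris[t, 3:2]
  }
  # snap coordinates that should be exactly on the symmetry planes
  V[abs(V) < 1e-12] <- 0
  list(verts = V, tris = tris)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Conforming 3-tet split of the prism (b1,b2,b3 | t1,t2,t3) given global ids.
prism_perms <- list(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
                    c(4, 6, 5, 1, 3, 2), c(6, 5, 4, 3, 2, 1), c(5, 4, 6, 2, 1, 3))

split_prism <- function(g) {
  imin <- which.min(g)
  perm <- prism_perms[[which(vapply(prism_perms, function(p) p[1] == imin, logical(1)))[1]]]
  v <- g[perm]
  if (min(v[2], v[6]) < min(v[3], v[5])) {
    rbind(c(v[1], v[2], v[3], v[6]), c(v[1], v[2], v[6], v[5]), c(v[1], v[5], v[6], v[4]))
  } else {
    rbind(c(v[1], v[2], v[3], v[5]), c(v[1], v[5], v[3], v[6]), c(v[1], v[5], v[6], v[4]))
  }
}

#' Build the reference mesh (quarter shell plus nucleoplasm)
#'
#' Generates a conforming tetrahedral mesh of the quarter domain
#' (X >= 0, Y >= 0): the NE shell between radii `R0 - DT` and `R0`, and the
#' enclosed nucleoplasm ball. The shell carries a quadratic (10-node)
#' displacement discretization with mid-edge nodes projected radially, so
#' curved spherical surfaces are represented to second order.
#'
#' @param shell A [shell_geometry()].
#' @param n_shell_layers Radial element layers through the shell thickness
#'   (default 1; the 0.2 um shell is thinner than typical edge lengths).
#' @param nuc_grading Geometric growth factor for radial spacing of
#'   nucleoplasm levels toward the center (default 1.6).
#' @return An object of class `ne_mesh`. Key fields: `verts`, `tets`,
#'   `region` (1 = NE shell, 2 = nucleoplasm), oriented surface
#'   triangulations `outer_tri`, `inner_tri`, the shell P2 node table and
#'   connectivity used by the mechanics solver, and the angular-column
#'   index maps used by the concentric surface mapping.
#' @export
build_reference_mesh <- function(shell, n_shell_layers = 1, nuc_grading = 1.6) {
  stopifnot(inherits(shell, "shell_geometry"))
  R0 <- shell$R0; DT <- shell$DT; Ri <- R0 - DT
  n <- max(4L, as.integer(ceiling((pi / 2) * R0 / shell$hedge)))
  oct <- octasphere_quarter(n)
  n_ang <- nrow(oct$verts); n_tri <- nrow(oct$tris)

  # radial levels: nucleoplasm graded from Ri toward the center, then shell
  dr <- shell$hedge * 1.25
  rn <- Ri
  nuc_r <- c()
  while (rn - dr > 0.35 * Ri * min(1, dr / Ri * 4) && rn - dr > 0.25) {
    rn <- rn - dr
    nuc_r <- c(rn, nuc_r)
    dr <- dr * nuc_grading
  }
  lev_r <- c(nuc_r, Ri + DT * (0:n_shell_layers) / n_shell_layers)
  L <- length(lev_r)
  shell_l0 <- length(nuc_r) + 1L       # level index of Gamma_inner

  ctr <- shell$center
  nv <- 1L + L * n_ang
  verts <- matrix(0, nv, 3)
  verts[1, ] <- ctr
  for (l in seq_len(L))
    verts[1L + (l - 1L) * n_ang + seq_len(n_ang), ] <-
      sweep(oct$verts * lev_r[l], 2, ctr, `+`)
  vid <- function(l, a) 1L + (l - 1L) * n_ang + a

  tets <- vector("list", L)
  region <- vector("list", L)
  # center fan to level 1
  fan <- cbind(1L, vid(1L, oct$tris[, 1]), vid(1L, oct$tris[, 2]), vid(1L, oct$tris[, 3]))
  tets[[1]] <- fan; region[[1]] <- rep(2L, n_tri)
  for (l in seq_len(L - 1L)) {
    tl <- matrix(0L, 3L * n_tri, 4L)
    for (t in seq_len(n_tri)) {
      g <- c(vid(l, oct$tris[t, ]), vid(l + 1L, oct$tris[t, ]))
      tl[(3L * t - 2L):(3L * t), ] <- split_prism(g)
    }
    tets[[l + 1L]] <- tl
    region[[l + 1L]] <- rep(if (l >= shell_l0) 1L else 2L, 3L * n_tri)
  }
  tets <- do.call(rbind, tets)
  region <- unlist(region)
  # orient all tets to positive volume
  v1 <- verts[tets[, 2], ] - verts[tets[, 1], ]
  v2 <- verts[tets[, 3], ] - verts[tets[, 1], ]
  v3 <- verts[tets[, 4], ] - verts[tets[, 1], ]
  vol6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  flip <- vol6 < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]

  outer_tri <- matrix(vid(L, oct$tris), ncol = 3)
  inner_tri <- matrix(vid(shell_l0, oct$tris), ncol = 3)

  mesh <- structure(list(
    shell = shell, verts = verts, tets = tets, region = region,
    n_ang = n_ang, n_levels = L, lev_r = lev_r, shell_l0 = shell_l0,
    surf_tris = oct$tris, surf_unit = oct$verts,
    outer_tri = outer_tri, inner_tri = inner_tri,
    center = ctr, n = n), class = "ne_mesh")
  mesh <- add_shell_p2(mesh, n_shell_layers)
  mesh
}

# Shell-local P2 (10-node tets) structures for the mechanics solve.
add_shell_p2 <- function(mesh, n_shell_layers) {
  shell_cells <- mesh$tets[mesh$region == 1L, , drop = FALSE]
  sv <- sort(unique(as.vector(shell_cells)))
  g2l <- integer(nrow(mesh$verts)); g2l[sv] <- seq_along(sv)
  cells4 <- matrix(g2l[shell_cells], ncol = 4)
  # unique edges
  e <- rbind(cells4[, c(1, 2)], cells4[, c(1, 3)], cells4[, c(1, 4)],
             cells4[, c(2, 3)], cells4[, c(2, 4)], cells4[, c(3, 4)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ekey <- e[, 1] * (length(sv) + 1) + e[, 2]
  ue <- !duplicated(ekey)
  edges <- e[ue, , drop = FALSE]
  eid <- integer(max(ekey))
  eid[ekey[ue]] <- seq_len(nrow(edges))
  ne <- nrow(edges); nsv <- length(sv)
  Xv <- mesh$verts[sv, , drop = FALSE]
  # mid-edge nodes, projected radially to the mean radius of the endpoints
  mid <- (Xv[edges[, 1], ] + Xv[edges[, 2], ]) / 2
  d <- sweep(mid, 2, mesh$center)
  r <- sqrt(rowSums(d^2))
  r1 <- sqrt(rowSums(sweep(Xv[edges[, 1], , drop = FALSE], 2, mesh$center)^2))
  r2 <- sqrt(rowSums(sweep(Xv[edges[, 2], , drop = FALSE], 2, mesh$center)^2))
  mid <- sweep(d * ((r1 + r2) / 2) / r, 2, mesh$center, `+`)
  Xp2 <- rbind(Xv, mid)
  # cells10: 4 vertices then edges (1-2, 1-3, 1-4, 2-3, 2-4, 3-4)
  epairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  cells10 <- matrix(0L, nrow(cells4), 10)
  cells10[, 1:4] <- cells4
  for (k in 1:6) {
    a <- pmin(cells4[, epairs[[k]][1]], cells4[, epairs[[k]][2]])
    b <- pmax(cells4[, epairs[[k]][1]], cells4[, epairs[[k]][2]])
    cells10[, 4 + k] <- nsv + eid[a * (nsv + 1) + b]
  }
  # boundary facets (outer / inner) with parent shell cell and P2 nodes
  facet_pack <- function(tri_global) {
    tri <- matrix(g2l[tri_global], ncol = 3)
    # parent shell cell: the unique shell cell containing all three vertices
    vin <- lapply(seq_len(nrow(cells4)), function(i) cells4[i, ])
    cellmat <- cells4
    parent <- integer(nrow(tri))
    # build map vertex -> cells
    v2c <- vector("list", nsv)
    for (i in seq_len(nrow(cellmat))) for (v in cellmat[i, ])
      v2c[[v]] <- c(v2c[[v]], i)
    for (f in seq_len(nrow(tri))) {
      cand <- Reduce(intersect, v2c[tri[f, ]])
      parent[f] <- cand[1]
    }
    nodes6 <- matrix(0L, nrow(tri), 6)
    nodes6[, 1:3] <- tri
    for (k in 1:3) {
      i1 <- tri[, k]; i2 <- tri[, (k %% 3) + 1]
      a <- pmin(i1, i2); b <- pmax(i1, i2)
      nodes6[, 3 + k] <- nsv + eid[a * (nsv + 1) + b]
    }
    list(tri = tri, parent = parent, nodes6 = nodes6)
  }
  mesh$shell_verts <- sv
  mesh$shell_g2l <- g2l
  mesh$cells4 <- cells4
  mesh$cells10 <- cells10
  mesh$Xp2 <- Xp2
  mesh$n_p2 <- nrow(Xp2)
  mesh$n_sv <- nsv
  mesh$outer_facets <- facet_pack(mesh$outer_tri)
  mesh$inner_facets <- facet_pack(mesh$inner_tri)
  # angular column ids for outer / inner surface vertices (shell-local)
  vid <- function(l, a) 1L + (l - 1L) * mesh$n_ang + a
  mesh$outer_vl <- g2l[vid(mesh$n_levels, seq_len(mesh$n_ang))]   # shell-local
  mesh$inner_vl <- g2l[vid(mesh$shell_l0, seq_len(mesh$n_ang))]
  mesh$outer_vg <- vid(mesh$n_levels, seq_len(mesh$n_ang))        # global
  mesh$inner_vg <- vid(mesh$shell_l0, seq_len(mesh$n_ang))
  # roof patches: outer facets within the roof radius; those touching the apex
  ctr <- mesh$center
  apex_a <- which.max(mesh$surf_unit[, 3])
  cent <- (mesh$verts[mesh$outer_tri[, 1], ] + mesh$verts[mesh$outer_tri[, 2], ] +
           mesh$verts[mesh$outer_tri[, 3], ]) / 3
  rho2 <- cent[, 1]^2 + cent[, 2]^2
  upper <- cent[, 3] > ctr[3]
  # roof cutoff; capped well below the shell radius so the patch stays a
  # small apex neighborhood on coarse meshes too
  droof <- min(mesh$shell$Droof, mesh$shell$R0 / 2)
  in_roof <- upper & rho2 <= droof^2
  apex_g <- vid(mesh$n_levels, apex_a)
  touches_apex <- apply(mesh$outer_tri, 1, function(v) apex_g %in% v)
  mesh$roof1 <- which(in_roof & touches_apex)
  mesh$roof2 <- which(in_roof & !touches_apex)
  if (length(mesh$roof2) == 0)
    mesh$roof2 <- which(upper & !touches_apex & rho2 <= (2 * droof)^2)
  mesh
}

#' @export
print.ne_mesh <- function(x, ...) {
  cat(sprintf("NE quarter mesh: %d vertices, %d tets (%d shell / %d nucleoplasm)\n",
              nrow(x$verts), nrow(x$tets), sum(x$region == 1), sum(x$region == 2)))
  cat(sprintf("  angular nodes %d, levels %d, shell P2 nodes %d\n",
              x$n_ang, x$n_levels, x$n_p2))
  invisible(x)
}

# deformed (or reference, u = 0) tet volumes of an arbitrary subset
tet_volumes <- function(verts, tets) {
  v1 <- verts[tets[, 2], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  v2 <- verts[tets[, 3], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  v3 <- verts[tets[, 4], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
   v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
   v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

tri_areas <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE]
  c_ <- verts[tris[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sqrt(rowSums(cx^2)) / 2
}
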