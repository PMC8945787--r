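#' Dielectric environment for continuum-electrostatics calculations
#'
#' @param eps_protein protein (solute interior) dielectric constant.
#' @param eps_water solvent dielectric constant.
#' @param ionic_strength dissolved 1:1 salt, mol/L.
#' @param probe_radius water probe radius, Angstrom.
#' @param temperature Kelvin.
#' @return a `dielectric_env` list.
#' @export
dielectric_env <- function(eps_protein = 4, eps_water = 80,
                           ionic_strength = 0.15, probe_radius = 1.4,
                           temperature = 298) {
  stopifnot(eps_water >= eps_protein, eps_protein >= 1, ionic_strength >= 0,
            temperature > 0)
  structure(list(eps_protein = eps_protein, eps_water = eps_water,
                 ionic_strength = ionic_strength, probe_radius = probe_radius,
                 temperature = temperature), class = "dielectric_env")
}

#' Finite-difference grid specification
#'
#' @param spacing node spacing, Angstrom (default 0.5).
#' @param padding minimum distance from any solute atom/charge to the box
#'   boundary at the finest level, Angstrom (default 5; the coarse level of
#'   a focused run doubles it).
#' @param focusing_levels number of focusing levels (1 = single pass).
#' @param extent optional fixed box bounds: 2 x 3 matrix (rows = lo, hi).
#'   When `NULL` the box is fitted around the solute with `padding`.
#'   Charges outside a fixed extent are an error.
#' @param tol SOR convergence tolerance, max potential update per sweep
#'   (kcal/mol/e).
#' @param max_iter SOR iteration cap.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(spacing = 0.5, padding = 5, focusing_levels = 1,
                      extent = NULL, tol = 1e-6, max_iter = 20000) {
  stopifnot(spacing > 0, padding >= 5, focusing_levels >= 1)
  if (!is.null(extent))
    stopifnot(is.matrix(extent), nrow(extent) == 2, ncol(extent) == 3,
              all(extent[1, ] < extent[2, ]))
  structure(list(spacing = spacing, padding = padding,
                 focusing_levels = as.integer(focusing_levels),
                 extent = extent, tol = tol, max_iter = as.integer(max_iter)),
            class = "grid_spec")
}

## Concrete grid (origin + node counts) covering the solute (atom surfaces,
## not centres) with the given padding.
make_grid <- function(points, spacing, padding, radii = 0) {
  lo <- apply(points - radii, 2, min) - padding
  hi <- apply(points + radii, 2, max) + padding
  n <- pmax(ceiling((hi - lo) / spacing) + 1, 9)
  list(origin = as.numeric(lo), n = as.integer(n), h = spacing)
}

grid_coords <- function(grid, d) grid$origin[d] + grid$h * (seq_len(grid$n[d]) - 1)

## Trilinear spread of point charges onto grid nodes.
spread_charges <- function(grid, charges) {
  src <- array(0, dim = grid$n)
  for (i in seq_len(nrow(charges))) {
    q <- charges$q[i]
    if (q == 0) next
    fr <- (c(charges$x[i], charges$y[i], charges$z[i]) - grid$origin) / grid$h
    i0 <- floor(fr)
    if (any(i0 < 1) || any(i0 > grid$n - 3))
      stop("charge ", i, " lies outside (or too close to the edge of) the grid")
    w <- fr - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      idx <- i0 + c(dx, dy, dz) + 1
      src[idx[1], idx[2], idx[3]] <- src[idx[1], idx[2], idx[3]] + q * wt
    }
  }
  src
}

## Screened-monopole (Debye-Hueckel) potential of the charge set at
## arbitrary points; uniform-dielectric Coulomb when kappa = 0.
dh_potential <- function(points, charges, eps, kappa = 0) {
  if (nrow(charges) == 0) return(numeric(nrow(points)))
  phi <- numeric(nrow(points))
  for (i in seq_len(nrow(charges))) {
    r <- sqrt((points[, 1] - charges$x[i])^2 + (points[, 2] - charges$y[i])^2 +
              (points[, 3] - charges$z[i])^2)
    r <- pmax(r, 1e-6)
    phi <- phi + COULOMB_K * charges$q[i] * exp(-kappa * r) / (eps * r)
  }
  phi
}

all_grid_points <- function(grid) {
  as.matrix(expand.grid(x = grid_coords(grid, 1), y = grid_coords(grid, 2),
                        z = grid_coords(grid, 3)))
}

#' Solve the linearized Poisson-Boltzmann equation on a grid
#'
#' Finite-difference successive over-relaxation solution with a molecular
#' (solvent-excluded) dielectric boundary built from the atom set, Debye
#' screening in the solvent region, and Dirichlet boundary conditions from
#' the screened-monopole approximation.  With `focusing_levels > 1` the
#' equation is first solved on a coarser, larger box and the fine-grid
#' boundary is interpolated from it.
#'
#' @param charges data frame with columns `x`, `y`, `z`, `q` (elementary
#'   charges).  All charges must lie inside the grid.
#' @param atoms data frame with `x`, `y`, `z`, `radius` defining the
#'   low-dielectric region, or `NULL` for a uniform solvent dielectric.
#' @param env a [dielectric_env()].
#' @param grid a [grid_spec()].
#' @param uniform_eps if non-`NULL`, solve with this uniform dielectric and
#'   no salt (the homogeneous reference used to cancel the grid
#'   self-energy).
#' @return a `pb_field` object (potential array in kcal/mol/e plus grid
#'   metadata); evaluate it with [pb_potential()].
#' @export
solve_pb <- function(charges, atoms, env, grid = grid_spec(),
                     uniform_eps = NULL) {
  pts <- as.matrix(charges[, c("x", "y", "z")])
  radii <- rep(0, nrow(pts))
  if (!is.null(atoms) && nrow(atoms) > 0) {
    pts <- rbind(pts, as.matrix(atoms[, c("x", "y", "z")]))
    radii <- c(radii, atoms$radius)
  }
  levels <- grid$focusing_levels
  field <- NULL
  for (lev in seq(levels, 1)) {
    fac <- 2^(lev - 1)
    g <- if (is.null(grid$extent)) {
      make_grid(pts, grid$spacing * fac, grid$padding * fac, radii)
    } else {
      ext <- grid$extent + (fac - 1) * grid$padding * rbind(-1, 1)[, c(1, 1, 1)]
      list(origin = as.numeric(ext[1, ]),
           n = as.integer(pmax(ceiling((ext[2, ] - ext[1, ]) /
                                         (grid$spacing * fac)) + 1, 9)),
           h = grid$spacing * fac)
    }
    field <- solve_pb_level(charges, atoms, env, g, grid, uniform_eps,
                            coarse = field)
  }
  field
}

solve_pb_level <- function(charges, atoms, env, g, spec, uniform_eps, coarse) {
  uniform <- !is.null(uniform_eps)
  eps_out <- if (uniform) uniform_eps else env$eps_water
  eps_in <- if (uniform) uniform_eps else env$eps_protein
  kbar2 <- if (uniform || env$ionic_strength == 0) 0 else
    salt_kbar2(env$ionic_strength, env$temperature)
  kappa <- if (kbar2 > 0) sqrt(kbar2 / eps_out) else 0

  L <- if (uniform || is.null(atoms) || nrow(atoms) == 0) {
    rep(1, prod(g$n))  # all solvent (uniform dielectric)
  } else {
    level_set_cpp(g$n, g$origin, g$h,
                  as.matrix(atoms[, c("x", "y", "z", "radius")]),
                  env$probe_radius)
  }

  src <- spread_charges(g, charges) * 4 * pi * COULOMB_K / g$h

  ## Initial guess & Dirichlet boundary.
  phi <- array(0, dim = g$n)
  if (is.null(coarse)) {
    bidx <- boundary_indices(g$n)
    bpts <- cbind(grid_coords(g, 1)[bidx[, 1]], grid_coords(g, 2)[bidx[, 2]],
                  grid_coords(g, 3)[bidx[, 3]])
    phi[bidx] <- dh_potential(bpts, charges, eps_out, kappa)
  } else {
    ## focusing: boundary (and initial guess) from the coarser solution
    phi[] <- pb_potential(coarse, all_grid_points(g))
  }

  sol <- sor_solve_cpp(g$n, g$h, L, eps_in, eps_out, kbar2,
                       as.numeric(src), as.numeric(phi),
                       spec$tol, spec$max_iter, sor_omega(g$n))
  if (!sol$converged)
    stop("PB solver did not converge in ", spec$max_iter,
         " iterations (max update ", signif(sol$max_update, 3), ")")
  structure(list(phi = array(sol$phi, dim = g$n), grid = g,
                 iterations = sol$iterations, env = env,
                 uniform_eps = uniform_eps),
            class = "pb_field")
}

sor_omega <- function(n) 2 / (1 + pi / max(n))

boundary_indices <- function(n) {
  idx <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  on_b <- idx$i %in% c(1, n[1]) | idx$j %in% c(1, n[2]) | idx$k %in% c(1, n[3])
  as.matrix(idx[on_b, ])
}

#' Evaluate a solved PB field at arbitrary points
#'
#' Trilinear interpolation of the node potentials.
#'
#' @param field a `pb_field` from [solve_pb()].
#' @param points numeric matrix (n x 3) or data frame with `x`,`y`,`z`.
#' @return potential, kcal/mol/e.
#' @export
pb_potential <- function(field, points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  g <- field$grid
  fr <- sweep(points, 2, g$origin) / g$h
  i0 <- pmin(pmax(floor(fr), 0), matrix(rep(g$n - 2, each = nrow(fr)),
                                        ncol = 3))
  w <- fr - i0
  out <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    out <- out + wt * field$phi[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                      i0[, 3] + dz + 1)]
  }
  out
}

## Heterogeneous + homogeneous-reference solve pair on a common grid.
## The difference potential psi = phi_het - phi_hom is the reaction
## potential: smooth at the sources, so the grid self-energy cancels.
pb_reaction_pair <- function(charges, atoms, env, grid = grid_spec()) {
  het <- solve_pb(charges, atoms, env, grid)
  hom <- solve_pb(charges, atoms, env, grid, uniform_eps = env$eps_protein)
  structure(list(het = het, hom = hom, charges = charges, env = env),
            class = "pb_reaction_pair")
}

reaction_potential <- function(pair, points) {
  pb_potential(pair$het, points) - pb_potential(pair$hom, points)
}

## 0.5 * sum q_i * psi(r_i): reaction-field energy of the charge set.
rf_energy <- function(pair) {
  pts <- as.matrix(pair$charges[, c("x", "y", "z")])
  0.5 * sum(pair$charges$q * reaction_potential(pair, pts))
}

## Interaction of the solved charge set with target charges: analytic
## Coulomb at the interior dielectric plus the interpolated reaction part.
interaction_energy <- function(pair, targets) {
  if (nrow(targets) == 0 || all(targets$q == 0) ||
      all(pair$charges$q == 0)) return(0)
  pts <- as.matrix(targets[, c("x", "y", "z")])
  coul <- dh_potential(pts, pair$charges, pair$env$eps_protein, 0)
  sum(targets$q * (coul + reaction_potential(pair, pts)))
}
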