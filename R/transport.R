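#' Convert a Peclet number to channel flow velocity and volumetric rate
#'
#' Flows in the device are parameterized by the Peclet number
#' \eqn{Pe = U L / D}, the ratio of advective to diffusive oxygen transport.
#' The characteristic length \eqn{L} is the channel width (this choice
#' reproduces the published velocity/flow-rate conversions: gas Pe = 100
#' with a 1 mm channel gives Q = 18 ml/min; medium Pe = 500 with a 500 um
#' channel gives U = 2.0e-3 m/s). The mean velocity is \eqn{U = Pe D / W}
#' and the volumetric rate \eqn{Q = U W h} per channel.
#'
#' @param Pe Dimensionless Peclet number, >= 0.
#' @param fluid `"gas"` or `"medium"`.
#' @param W Channel width (m), the characteristic length.
#' @param h Channel height (m).
#' @param materials Property table, by default [default_materials()].
#' @return An object of class `flow_spec`: list with `Pe`, `fluid`, `W`,
#'   `h`, `D`, mean velocity `U` (m/s) and flow rate `Q_ml_min` (ml/min).
#' @examples
#' pe_to_flow(100, "gas", W = 1e-3, h = 150e-6)$Q_ml_min    # 18 ml/min
#' pe_to_flow(500, "medium", W = 500e-6, h = 150e-6)$U      # 2e-3 m/s
#' @export
pe_to_flow <- function(Pe, fluid = c("gas", "medium"), W, h,
                       materials = default_materials()) {
  fluid <- match.arg(fluid)
  stopifnot(is.numeric(Pe), length(Pe) == 1L, Pe >= 0, W > 0, h > 0)
  D <- materials$D[match(if (fluid == "gas") "gas" else "medium",
                         materials$name)]
  U <- Pe * D / W
  Q <- U * W * h              # m^3/s
  structure(
    list(Pe = Pe, fluid = fluid, W = W, h = h, D = D,
         U = U, Q_ml_min = Q * 1e6 * 60),
    class = "flow_spec"
  )
}

#' @export
print.flow_spec <- function(x, ...) {
  cat(sprintf("flow_spec: %s, Pe = %g, U = %.3g m/s, Q = %.3g ml/min\n",
              x$fluid, x$Pe, x$U, x$Q_ml_min))
  invisible(x)
}

#' Boundary conditions for an oxygen transport solve
#'
#' Oxygen tensions are percent of 1 atm (21 = ambient air). The gas-channel
#' walls are fixed-composition (Dirichlet) surfaces, which is valid when the
#' gas supply keeps the channel composition constant along its length
#' (gas Peclet number >= 10); pass the gas `flow_spec` via `gas_flow` to
#' have this checked. The outer PDMS surface (sides and, above the film,
#' the top) is held at the ambient tension per Henry's law. The floor is
#' the glass coverslip: zero flux by default, or a numeric tension for
#' custom column geometries.
#'
#' @param gas_left,gas_right Oxygen tension (%O2, in \[0, 21\]) supplied to
#'   the left / right gas channel. `gas_right` defaults to `gas_left`.
#' @param ambient Ambient oxygen tension at the outer device surface
#'   (default 21), or `NULL` for an insulated outer surface (useful for
#'   column setups; a solve then needs some other fixed-tension surface).
#' @param floor `"noflux"` (glass coverslip) or a numeric Dirichlet value.
#' @param sides `"ambient"` or `"noflux"`; no-flux sides support
#'   quasi-one-dimensional column setups.
#' @param gas_flow Optional `flow_spec` of the gas supply, used to warn when
#'   Pe < 10 and the fixed-composition wall assumption is doubtful.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(gas_left = 0, gas_right = gas_left, ambient = 21,
                         floor = "noflux", sides = "ambient",
                         gas_flow = NULL) {
  chk <- c(gas_left = gas_left, gas_right = gas_right, ambient = ambient)
  if (any(chk < 0 | chk > 21)) {
    stop("oxygen tensions must lie in [0, 21] %O2")
  }
  if (is.null(ambient)) ambient <- NA_real_
  if (!identical(floor, "noflux")) stopifnot(is.numeric(floor))
  sides <- match.arg(sides, c("ambient", "noflux"))
  if (!is.null(gas_flow) && inherits(gas_flow, "flow_spec") &&
      gas_flow$Pe < 10) {
    warning("gas supply Pe < 10: gas-channel walls may not hold a constant ",
            "composition; the Dirichlet wall assumption is unreliable")
  }
  structure(list(gas_left = gas_left, gas_right = gas_right,
                 ambient = ambient, floor = floor, sides = sides),
            class = "boundary_set")
}

# Assemble the finite-volume system A phi = b over non-gas cells.
# Permeability k = D*S per cell; face conductances use the harmonic mean
# (series resistance of the two half-cells), which enforces the Henry's-law
# partition condition exactly: partial pressure continuous, flux continuous,
# concentration jumping by the solubility ratio.
assemble_system <- function(grid, bc) {
  nx <- grid$nx; nz <- grid$nz
  dxv <- diff(grid$x_edges)
  dzv <- diff(grid$z_edges)
  k <- grid$k
  is_gas <- grid$material == "gas"
  solid <- !is_gas                      # unknown cells
  n_cells <- nx * nz
  uid <- matrix(NA_integer_, nz, nx)
  uid[solid] <- seq_len(sum(solid))
  n <- sum(solid)

  gas_value <- matrix(NA_real_, nz, nx)
  Xc <- matrix(grid$xc, nz, nx, byrow = TRUE)
  gas_value[is_gas & Xc < 0] <- bc$gas_left
  gas_value[is_gas & Xc >= 0] <- bc$gas_right

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  diag_add <- numeric(n)
  b <- numeric(n)
  any_dirichlet <- FALSE

  DXm <- matrix(dxv, nz, nx, byrow = TRUE)
  DZm <- matrix(dzv, nz, nx)

  ## x-direction faces (between columns ix and ix+1)
  if (nx > 1L) {
    a <- cbind(rep(seq_len(nz), nx - 1L),
               rep(seq_len(nx - 1L), each = nz))
    ia_lin <- (a[, 2] - 1L) * nz + a[, 1]
    ib_lin <- ia_lin + nz
    res <- 0.5 * DXm[ia_lin] / k[ia_lin] + 0.5 * DXm[ib_lin] / k[ib_lin]
    g <- DZm[ia_lin] / res
    au <- uid[ia_lin]; bu <- uid[ib_lin]
    both <- !is.na(au) & !is.na(bu) & is.finite(g)
    if (any(both)) {
      ti <- c(ti, au[both], bu[both], au[both], bu[both])
      tj <- c(tj, au[both], bu[both], bu[both], au[both])
      tv <- c(tv, g[both], g[both], -g[both], -g[both])
    }
    # unknown cell facing a gas (Dirichlet) cell: resistance is the
    # unknown half-cell only (wall composition fixed at the face)
    a_gas <- !is.na(au) & is.na(bu)
    if (any(a_gas)) {
      gD <- DZm[ia_lin[a_gas]] / (0.5 * DXm[ia_lin[a_gas]] / k[ia_lin[a_gas]])
      u <- au[a_gas]
      diag_add[u] <- diag_add[u] + gD
      b[u] <- b[u] + gD * gas_value[ib_lin[a_gas]]
      any_dirichlet <- TRUE
    }
    b_gas <- is.na(au) & !is.na(bu)
    if (any(b_gas)) {
      gD <- DZm[ib_lin[b_gas]] / (0.5 * DXm[ib_lin[b_gas]] / k[ib_lin[b_gas]])
      u <- bu[b_gas]
      diag_add[u] <- diag_add[u] + gD
      b[u] <- b[u] + gD * gas_value[ia_lin[b_gas]]
      any_dirichlet <- TRUE
    }
  }

  ## z-direction faces (between rows iz and iz+1)
  if (nz > 1L) {
    ia_lin <- which(row(k) < nz)           # cell below the face
    ib_lin <- ia_lin + 1L
    res <- 0.5 * DZm[ia_lin] / k[ia_lin] + 0.5 * DZm[ib_lin] / k[ib_lin]
    g <- DXm[ia_lin] / res
    au <- uid[ia_lin]; bu <- uid[ib_lin]
    both <- !is.na(au) & !is.na(bu) & is.finite(g)
    if (any(both)) {
      ti <- c(ti, au[both], bu[both], au[both], bu[both])
      tj <- c(tj, au[both], bu[both], bu[both], au[both])
      tv <- c(tv, g[both], g[both], -g[both], -g[both])
    }
    a_gas <- !is.na(au) & is.na(bu)
    if (any(a_gas)) {
      gD <- DXm[ia_lin[a_gas]] / (0.5 * DZm[ia_lin[a_gas]] / k[ia_lin[a_gas]])
      u <- au[a_gas]
      diag_add[u] <- diag_add[u] + gD
      b[u] <- b[u] + gD * gas_value[ib_lin[a_gas]]
      any_dirichlet <- TRUE
    }
    b_gas <- is.na(au) & !is.na(bu)
    if (any(b_gas)) {
      gD <- DXm[ib_lin[b_gas]] / (0.5 * DZm[ib_lin[b_gas]] / k[ib_lin[b_gas]])
      u <- bu[b_gas]
      diag_add[u] <- diag_add[u] + gD
      b[u] <- b[u] + gD * gas_value[ia_lin[b_gas]]
      any_dirichlet <- TRUE
    }
  }

  ## domain boundary faces
  add_boundary <- function(lin, g_face, value) {
    u <- uid[lin]
    ok <- !is.na(u) & is.finite(g_face)
    if (any(ok)) {
      diag_add[u[ok]] <<- diag_add[u[ok]] + g_face[ok]
      b[u[ok]] <<- b[u[ok]] + g_face[ok] * value
      any_dirichlet <<- TRUE
    }
  }
  if (!is.na(bc$ambient)) {
    if (bc$sides == "ambient") {
      left_lin <- seq_len(nz)
      add_boundary(left_lin, dzv / (0.5 * dxv[1] / k[, 1]), bc$ambient)
      right_lin <- (nx - 1L) * nz + seq_len(nz)
      add_boundary(right_lin, dzv / (0.5 * dxv[nx] / k[, nx]), bc$ambient)
    }
    top_lin <- (seq_len(nx) - 1L) * nz + nz
    add_boundary(top_lin, dxv / (0.5 * dzv[nz] / k[nz, ]), bc$ambient)
  }
  if (is.numeric(bc$floor)) {
    floor_lin <- (seq_len(nx) - 1L) * nz + 1L
    add_boundary(floor_lin, dxv / (0.5 * dzv[1] / k[1, ]), bc$floor)
  }

  if (!any_dirichlet) {
    stop("singular system: no Dirichlet (fixed-tension) surface anywhere")
  }

  A <- Matrix::sparseMatrix(i = c(ti, seq_len(n)), j = c(tj, seq_len(n)),
                            x = c(tv, diag_add), dims = c(n, n))
  list(A = Matrix::forceSymmetric(A), b = b, uid = uid,
       gas_value = gas_value, dxv = dxv, dzv = dzv)
}

#' Solve steady oxygen transport over a material grid
#'
#' Finite-volume solution of \eqn{\nabla \cdot (k \nabla \phi) = 0} in
#' partial-pressure form, with per-cell permeability \eqn{k = D S} and
#' harmonic-mean face conductances. Working in partial pressure makes the
#' Henry's-law partition condition automatic at every material interface:
#' \eqn{\phi} is continuous while the dissolved concentration jumps by the
#' solubility ratio. Gas-channel walls and the ambient-exposed outer
#' surface are Dirichlet; the glass floor is zero-flux. The sparse
#' symmetric positive-definite system is solved by direct Cholesky
#' factorization.
#'
#' @param grid A `material_grid`.
#' @param bc A [boundary_set()].
#' @return An object of class `oxygen_field`: list with the `grid`, the
#'   `nz x nx` matrix `phi` (%O2; gas cells carry their supply value), and
#'   `bc`.
#' @examples
#' g <- build_cross_section(device_spec(), resolution = c(100e-6, 100e-6))
#' f <- solve_steady(g, boundary_set(gas_left = 0, gas_right = 0))
#' center_oxygen(f)
#' @export
solve_steady <- function(grid, bc) {
  stopifnot(inherits(grid, "material_grid"), inherits(bc, "boundary_set"))
  sys <- assemble_system(grid, bc)
  ch <- Matrix::Cholesky(sys$A, perm = TRUE, LDL = FALSE)
  phi_u <- as.numeric(Matrix::solve(ch, sys$b))
  res <- as.numeric(sys$A %*% phi_u - sys$b)
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(sys$b^2)), .Machine$double.eps)
  if (!is.finite(rel) || rel > 1e-8) {
    stop(sprintf("steady solve did not converge: relative residual %.3g", rel))
  }
  phi <- matrix(NA_real_, grid$nz, grid$nx)
  phi[!is.na(sys$uid)] <- phi_u[sys$uid[!is.na(sys$uid)]]
  gas <- !is.na(sys$gas_value)
  phi[gas] <- sys$gas_value[gas]
  structure(list(grid = grid, phi = phi, bc = bc, time = NULL),
            class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("oxygen_field: %d x %d cells, phi in [%.3g, %.3g] %%O2\n",
              x$grid$nx, x$grid$nz, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Dissolved oxygen concentration of a field
#'
#' Converts partial pressure to concentration per cell via Henry's law,
#' \eqn{c = S (\phi / 100)} mM (S in mM/atm, \eqn{\phi} in % of 1 atm).
#' Gas cells, where solubility is undefined, return `NA`.
#'
#' @param field An `oxygen_field`.
#' @return `nz x nx` matrix of concentrations (mM).
#' @export
concentration <- function(field) {
  field$grid$S * field$phi / 100
}

#' Oxygen tension at the center of the gel channel
#'
#' Reads the cell nearest to x = 0 at the mid-height of the aqueous layer
#' (the published center readout `c_O`).
#'
#' @param field An `oxygen_field` or `oxygen_transient`.
#' @param ... Unused.
#' @return Scalar %O2 for a steady field; for a transient, the full
#'   `data.frame(t, phi_center)` trace.
#' @export
center_oxygen <- function(field, ...) UseMethod("center_oxygen")

center_index <- function(grid) {
  if (is.null(grid$spec)) stop("center readout requires a device-based grid")
  iz <- which.min(abs(grid$zc - grid$spec$channel_height / 2))
  ix <- which.min(abs(grid$xc))
  c(iz = iz, ix = ix)
}

#' @export
center_oxygen.oxygen_field <- function(field, ...) {
  id <- center_index(field$grid)
  field$phi[id["iz"], id["ix"]]
}

#' @export
center_oxygen.oxygen_transient <- function(field, ...) {
  field$trace
}

#' Net oxygen flux through each Dirichlet boundary of a steady field
#'
#' Recomputes the face fluxes into the domain through the gas-channel
#' walls, the ambient outer surface, and (if Dirichlet) the floor. At
#' steady state the components must cancel: what enters through the
#' ambient-exposed PDMS leaves through the gas channels.
#'
#' @param field A steady `oxygen_field`.
#' @return Named numeric vector (`gas_left`, `gas_right`, `ambient`,
#'   `floor`, `net`), flux in k-weighted pressure units per unit depth;
#'   positive into the domain.
#' @export
boundary_flux <- function(field) {
  grid <- field$grid; bc <- field$bc; phi <- field$phi
  nx <- grid$nx; nz <- grid$nz
  dxv <- diff(grid$x_edges); dzv <- diff(grid$z_edges)
  k <- grid$k
  is_gas <- grid$material == "gas"
  out <- c(gas_left = 0, gas_right = 0, ambient = 0, floor = 0)

  # faces between a solid cell and a gas cell
  for (ix in seq_len(nx)) {
    for (iz in seq_len(nz)) {
      if (!is_gas[iz, ix]) next
      val <- if (grid$xc[ix] < 0) bc$gas_left else bc$gas_right
      lab <- if (grid$xc[ix] < 0) "gas_left" else "gas_right"
      nb <- list(c(iz, ix - 1L, dzv[iz], dxv), c(iz, ix + 1L, dzv[iz], dxv),
                 c(iz - 1L, ix, dxv[ix], dzv), c(iz + 1L, ix, dxv[ix], dzv))
      for (d in seq_along(nb)) {
        jz <- nb[[d]][1]; jx <- nb[[d]][2]
        if (jz < 1 || jz > nz || jx < 1 || jx > nx) next
        if (is_gas[jz, jx]) next
        area <- nb[[d]][3]
        half <- if (d <= 2) 0.5 * dxv[jx] else 0.5 * dzv[jz]
        g <- area / (half / k[jz, jx])
        out[lab] <- out[lab] + g * (val - phi[jz, jx])
      }
    }
  }
  # ambient sides and top
  if (!is.na(bc$ambient)) {
    if (bc$sides == "ambient") {
      g <- dzv / (0.5 * dxv[1] / k[, 1])
      out["ambient"] <- out["ambient"] + sum(g * (bc$ambient - phi[, 1]))
      g <- dzv / (0.5 * dxv[nx] / k[, nx])
      out["ambient"] <- out["ambient"] + sum(g * (bc$ambient - phi[, nx]))
    }
    g <- dxv / (0.5 * dzv[nz] / k[nz, ])
    out["ambient"] <- out["ambient"] + sum(g * (bc$ambient - phi[nz, ]))
  }
  if (is.numeric(bc$floor)) {
    g <- dxv / (0.5 * dzv[1] / k[1, ])
    out["floor"] <- out["floor"] + sum(g * (bc$floor - phi[1, ]))
  }
  c(out, net = sum(out))
}

#' Solve transient oxygen transport
#'
#' Implicit (backward Euler) time stepping of
#' \eqn{S \, \partial\phi/\partial t = \nabla \cdot (k \nabla \phi)}:
#' the accumulation term uses the per-cell solubility so partial pressure
#' relaxes with the correct material capacitance (PDMS stores ~6x more
#' oxygen per unit tension than water). The system matrix is factorized
#' once and reused across steps. The gel-center trace is recorded at every
#' step; full-field snapshots are kept at the requested times.
#'
#' @param grid A `material_grid`.
#' @param bc A [boundary_set()] (the post-switch boundary condition).
#' @param initial Initial field: scalar %O2 (e.g. 21 for a device
#'   equilibrated with air) or an `oxygen_field` on the same grid.
#' @param t_end End time (s).
#' @param dt Time step (s), default 1.
#' @param snapshot_times Times (s) at which to store the full field;
#'   defaults to `t_end` only.
#' @return An object of class `oxygen_transient`: list with `grid`, `bc`,
#'   `times`, `snapshots` (list of phi matrices), and `trace`
#'   (`data.frame(t, phi_center)`; `NULL` for custom grids without a
#'   device spec).
#' @export
solve_transient <- function(grid, bc, initial, t_end, dt = 1,
                            snapshot_times = t_end) {
  stopifnot(inherits(grid, "material_grid"), inherits(bc, "boundary_set"))
  if (dt <= 0) stop("dt must be > 0")
  if (t_end < dt) stop("t_end must be >= dt")
  sys <- assemble_system(grid, bc)
  n <- length(sys$b)
  solid <- !is.na(sys$uid)

  if (inherits(initial, "oxygen_field")) {
    phi0 <- initial$phi
  } else {
    stopifnot(is.numeric(initial), length(initial) == 1L)
    phi0 <- matrix(initial, grid$nz, grid$nx)
  }
  phi_u <- phi0[solid][order(sys$uid[solid])]

  # capacitance: S * cell area (per unit depth)
  area <- outer(diff(grid$z_edges), diff(grid$x_edges))
  cap <- (grid$S * area)[solid][order(sys$uid[solid])]
  M_dt <- cap / dt

  B <- sys$A + Matrix::Diagonal(n, M_dt)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(B), perm = TRUE, LDL = FALSE)

  nt <- ceiling(t_end / dt - 1e-9)
  has_center <- !is.null(grid$spec)
  if (has_center) {
    id <- center_index(grid)
    center_lin_u <- sys$uid[id["iz"], id["ix"]]
    trace_t <- numeric(nt + 1L)
    trace_v <- numeric(nt + 1L)
    trace_t[1] <- 0
    trace_v[1] <- phi_u[center_lin_u]
  }
  snapshot_times <- sort(unique(pmin(snapshot_times, nt * dt)))
  snaps <- vector("list", length(snapshot_times))
  snap_steps <- pmax(1L, round(snapshot_times / dt))
  fill_field <- function(phi_u) {
    phi <- matrix(NA_real_, grid$nz, grid$nx)
    phi[solid] <- phi_u[sys$uid[solid]]
    gas <- !is.na(sys$gas_value)
    phi[gas] <- sys$gas_value[gas]
    phi
  }
  for (step in seq_len(nt)) {
    rhs <- sys$b + M_dt * phi_u
    phi_u <- as.numeric(Matrix::solve(ch, rhs))
    if (has_center) {
      trace_t[step + 1L] <- step * dt
      trace_v[step + 1L] <- phi_u[center_lin_u]
    }
    hit <- which(snap_steps == step)
    for (s in hit) snaps[[s]] <- fill_field(phi_u)
  }
  structure(
    list(grid = grid, bc = bc, times = snap_steps * dt, snapshots = snaps,
         trace = if (has_center) data.frame(t = trace_t, phi_center = trace_v) else NULL,
         initial = phi0, dt = dt),
    class = "oxygen_transient"
  )
}

#' @export
print.oxygen_transient <- function(x, ...) {
  cat(sprintf("oxygen_transient: %d snapshot(s), t up to %g s, dt = %g s\n",
              length(x$snapshots), max(x$times), x$dt))
  invisible(x)
}

#' Time for the gel-center tension to settle near its steady value
#'
#' First time at which the gel-center trace of a transient solve comes
#' within `tol` of the target steady value. The published readouts use
#' tol = 0.5 %O2 for a hypoxic step and 1 %O2 for reoxygenation to 21%.
#'
#' @param transient An `oxygen_transient` with a center trace.
#' @param steady_value Target steady gel-center tension (%O2).
#' @param tol Settling tolerance (%O2).
#' @return Time in seconds (`Inf` if never within `tol`).
#' @export
equilibration_time <- function(transient, steady_value, tol = 0.5) {
  stopifnot(inherits(transient, "oxygen_transient"), !is.null(transient$trace))
  tr <- transient$trace
  hit <- which(abs(tr$phi_center - steady_value) <= tol)
  if (length(hit) == 0L) return(Inf)
  tr$t[hit[1]]
}

#' Oxygen profile across the gel channel and its fitted gradient
#'
#' Samples the steady field at the mid-height of the aqueous layer across
#' the gel span and fits a least-squares line. Endpoints are the fitted
#' values at the gel walls (x = +/- gel_width/2), matching how gradient
#' conditions are summarized (e.g. "3% to 18% across the gel").
#'
#' @param field A steady `oxygen_field` on a device-based grid.
#' @return List with `profile` (`data.frame(x, phi)`, x in m),
#'   `slope_per_mm` (%O2 per mm), `endpoints` (named left/right, %O2) and
#'   the underlying `fit` (an `lm`).
#' @export
gel_gradient_profile <- function(field) {
  grid <- field$grid
  if (is.null(grid$spec)) stop("gel profile requires a device-based grid")
  spec <- grid$spec
  iz <- which.min(abs(grid$zc - spec$channel_height / 2))
  sel <- abs(grid$xc) < spec$gel_width / 2
  prof <- data.frame(x = grid$xc[sel], phi = field$phi[iz, sel])
  fit <- stats::lm(phi ~ x, data = prof)
  half <- spec$gel_width / 2
  ends <- stats::predict(fit, data.frame(x = c(-half, half)))
  list(profile = prof,
       slope_per_mm = unname(stats::coef(fit)[2]) * 1e-3,
       endpoints = c(left = unname(ends[1]), right = unname(ends[2])),
       fit = fit)
}

#' Steady-state design sweep over device geometries and gas conditions
#'
#' Runs [solve_steady()] for every combination of device spec and boundary
#' condition and tabulates the gel-center tension and gel profile. Solver
#' errors annotate the affected row instead of aborting the sweep.
#'
#' @param specs List of `device_spec` objects (e.g. from
#'   [sweep_geometries()]).
#' @param conditions Named list of [boundary_set()] objects.
#' @param resolution Grid resolution passed to [build_cross_section()].
#' @return Data frame with one row per (spec, condition): `H_g`, `H_f`
#'   (m), `condition`, `center_phi` (%O2), `error` (NA when the solve
#'   succeeded) and a `profile` list column of gel profiles.
#' @export
sweep_steady <- function(specs, conditions, resolution = c(25e-6, 25e-6)) {
  if (inherits(specs, "device_spec")) specs <- list(specs)
  if (inherits(conditions, "boundary_set")) conditions <- list(condition = conditions)
  if (is.null(names(conditions))) {
    names(conditions) <- paste0("condition", seq_along(conditions))
  }
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    grid <- try(build_cross_section(spec, resolution), silent = TRUE)
    for (ci in seq_along(conditions)) {
      row <- data.frame(H_g = spec$H_g, H_f = spec$H_f,
                        condition = names(conditions)[ci],
                        center_phi = NA_real_, error = NA_character_,
                        stringsAsFactors = FALSE)
      prof <- list(NULL)
      if (inherits(grid, "try-error")) {
        row$error <- conditionMessage(attr(grid, "condition"))
      } else {
        fld <- try(solve_steady(grid, conditions[[ci]]), silent = TRUE)
        if (inherits(fld, "try-error")) {
          row$error <- conditionMessage(attr(fld, "condition"))
        } else {
          row$center_phi <- center_oxygen(fld)
          prof <- list(gel_gradient_profile(fld))
        }
      }
      row$profile <- I(prof)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Quasi-one-dimensional axial oxygen profile along a flowing channel
#'
#' Plug-flow balance between axial advection and wall exchange:
#' \eqn{U \, d\phi/dy = (v_{ex}/h)(\phi_{wall} - \phi)}, integrated by an
#' implicit upwind march. `v_ex` is an effective wall exchange velocity;
#' the default `D_fluid / h` is the diffusive conductance across the
#' channel height. The solution relaxes toward the wall composition over
#' the length scale \eqn{\lambda = U h / v_{ex}}: fast flow (large Pe)
#' carries fluid out of the device before it equilibrates, which is why a
#' low medium flow rate is needed to hold a constant oxygen level while
#' high gas flow keeps the gas channels at their supply composition.
#'
#' @param flow A `flow_spec` from [pe_to_flow()].
#' @param wall_value Wall (equilibrium) oxygen tension, %O2.
#' @param inlet_value Inlet oxygen tension, %O2.
#' @param length Channel length (m).
#' @param n Number of axial steps.
#' @param exchange_velocity Wall exchange velocity v_ex (m/s); default
#'   `flow$D / flow$h`.
#' @return `data.frame(y, phi)` with attribute `lambda` (m; 0 when U = 0).
#' @export
channel_axis_model <- function(flow, wall_value, inlet_value, length,
                               n = 500, exchange_velocity = NULL) {
  stopifnot(inherits(flow, "flow_spec"), length > 0, n >= 1)
  v_ex <- if (is.null(exchange_velocity)) flow$D / flow$h else exchange_velocity
  y <- seq(0, length, length.out = n + 1L)
  if (flow$U == 0) {
    out <- data.frame(y = y, phi = rep(wall_value, n + 1L))
    attr(out, "lambda") <- 0
    return(out)
  }
  dy <- length / n
  a <- v_ex * dy / (flow$U * flow$h)
  phi <- numeric(n + 1L)
  phi[1] <- inlet_value
  for (i in seq_len(n)) phi[i + 1L] <- (phi[i] + a * wall_value) / (1 + a)
  out <- data.frame(y = y, phi = phi)
  attr(out, "lambda") <- flow$U * flow$h / v_ex
  out
}
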