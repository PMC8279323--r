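#' Steady incompressible laminar flow in a vessel
#'
#' Solves the stationary incompressible Navier-Stokes equations
#' `rho (u . grad) u = div[-p I + eta (grad u + grad u^T)] + F`,
#' `div u = 0`, on the voxelized lumen by pseudo-time marching of a
#' fractional-step (projection) scheme on the MAC grid: explicit upwind
#' advection, explicit viscous update with sub-cell wall distances (no-slip
#' at the true lumen wall), and an exact discrete pressure projection
#' (sparse Cholesky) every step, which enforces mass conservation to solver
#' precision. Boundary conditions: fully developed (parabolic) inlet profile
#' with the prescribed cross-section mean velocity, uniform outlet pressure,
#' no-slip walls.
#'
#' Marching stops when the normalized momentum residual
#' `max|du| * d / (dt u_ref^2)` (the velocity change per advective time unit,
#' relative to the inlet velocity) falls below `cond$steady_rel_tol`.
#'
#' @param domain a `fluid_domain` from [discretize()]
#' @param props a [fluid_properties()]
#' @param cond a [flow_conditions()]; the inlet mean velocity is
#'   `evaluate_waveform(cond$inlet, 0)` unless `u_mean` is given
#' @param u_mean optional inlet cross-section mean velocity, m/s (overrides
#'   the waveform)
#' @param max_steps pseudo-time step cap (default 20000)
#' @param init optional `flow_field` used as the initial state
#' @param on_nonconvergence `"error"` (default) or `"warn"`
#' @return an object of class `flow_field`: face velocity arrays (m/s),
#'   pressure (Pa), the domain, convergence diagnostics
#' @export
solve_steady <- function(domain, props, cond, u_mean = NULL,
                         max_steps = 20000L, init = NULL,
                         on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(domain, "fluid_domain"),
            inherits(props, "fluid_properties"),
            inherits(cond, "flow_conditions"))
  if (is.null(u_mean)) u_mean <- evaluate_waveform(cond$inlet, 0)
  re <- props$density * u_mean * domain$mean_diameter / props$viscosity
  if (re >= 2000)
    warning(sprintf("global Re = %.0f >= 2000: outside the laminar regime the solver assumes", re))
  st <- solver_state(domain, props, cond, u_mean, init)
  if (u_mean == 0) {     # rest state: u = 0, p = outlet pressure
    st$p_full[domain$poisson$free] <- mmhg_to_pa(cond$outlet_pressure_mmhg)
    return(flow_field_from_state(st, domain, props, cond, u_mean,
                                 converged = TRUE, residuals = numeric()))
  }
  resid <- numeric(0)
  tol <- cond$steady_rel_tol
  for (step in seq_len(max_steps)) {
    prev <- st$sol
    st <- advance(st, domain, props)
    res <- max(abs(unlist(st$sol) - unlist(prev))) *
      domain$mean_diameter / (st$dt * u_mean^2)
    resid <- c(resid, res)
    if (step > 20L && res < tol) {
      return(flow_field_from_state(st, domain, props, cond, u_mean,
                                   converged = TRUE, residuals = resid))
    }
  }
  msg <- sprintf("steady solve did not converge in %d steps (last residual %.3g, tol %.3g)",
                 max_steps, resid[length(resid)], tol)
  if (on_nonconvergence == "error") {
    err <- simpleError(msg)
    err$residual_history <- resid
    stop(err)
  }
  warning(msg)
  flow_field_from_state(st, domain, props, cond, u_mean,
                        converged = FALSE, residuals = resid)
}

#' Pulsatile incompressible laminar flow
#'
#' Time-dependent counterpart of [solve_steady()]: the inlet mean velocity
#' follows `cond$inlet` (sinusoid, square or sawtooth waveform), snapshots
#' are emitted every `cond$dt` seconds up to `cond$t_end` (default 1.5 s in
#' 0.05 s steps, longer than one pulse cycle at all measured pulse rates),
#' and the initial condition is the steady solution at the waveform's t = 0
#' velocity. Internally the scheme sub-steps at the advective CFL limit; the
#' per-snapshot discrete continuity residual (relative divergence norm) must
#' stay below `cond$transient_residual_tol`.
#'
#' @inheritParams solve_steady
#' @param init_max_steps pseudo-time step cap for the initial steady solve
#'   (a partially relaxed initial state only perturbs the first fraction of
#'   a cycle; the periodic regime is unaffected)
#' @return list of class `pulsatile_flow`: `snapshots` (list of
#'   `flow_field` at t = dt, 2dt, ..., t_end), `times`, `inlet_velocity`,
#'   `outlet_flux` (m^3/s at each snapshot)
#' @export
solve_pulsatile <- function(domain, props, cond, max_steps = 200000L,
                            init_max_steps = 4000L) {
  stopifnot(inherits(cond, "flow_conditions"), isTRUE(cond$transient))
  u0 <- evaluate_waveform(cond$inlet, 0)
  u_peak <- cond$inlet$u_max
  steady0 <- suppressWarnings(
    solve_steady(domain, props, cond, u_mean = u0,
                 max_steps = init_max_steps, on_nonconvergence = "warn"))
  st <- solver_state(domain, props, cond, u_peak, init = steady0,
                     u_init_mean = u0)
  times <- seq(cond$dt, cond$t_end, by = cond$dt)
  snaps <- vector("list", length(times))
  flux <- numeric(length(times))
  t_now <- 0
  for (k in seq_along(times)) {
    t_tar <- times[k]
    while (t_now < t_tar - 1e-12) {
      dt_sub <- min(st$dt, t_tar - t_now)
      st <- advance(st, domain, props, t_new = t_now + dt_sub, dt_use = dt_sub)
      t_now <- t_now + dt_sub
    }
    ff <- flow_field_from_state(st, domain, props, cond,
                                evaluate_waveform(cond$inlet, t_now),
                                converged = NA, residuals = numeric(),
                                time = t_now)
    if (ff$continuity_residual > cond$transient_residual_tol)
      stop(sprintf("transient step at t = %.2f s exceeded the residual tolerance", t_now))
    snaps[[k]] <- ff
    flux[k] <- flux_through(ff, s_frac = 0.9)
  }
  structure(list(snapshots = snaps, times = times,
                 inlet_velocity = evaluate_waveform(cond$inlet, times),
                 outlet_flux = flux, cond = cond),
            class = "pulsatile_flow")
}

#' @export
print.pulsatile_flow <- function(x, ...) {
  cat(sprintf("<pulsatile_flow> %d snapshots to t = %.2f s, inlet %.3g-%.3g m/s\n",
              length(x$snapshots), max(x$times),
              min(x$inlet_velocity), max(x$inlet_velocity)))
  invisible(x)
}

# ---- internal stepping machinery ------------------------------------------

solver_state <- function(domain, props, cond, u_scale, init = NULL,
                         u_init_mean = u_scale) {
  nu <- props$viscosity / props$density
  h <- domain$h
  # explicit stability: advective CFL (face peak ~ 2x mean for parabolic
  # profiles, plus margin) and viscous limit with the sub-cell floor
  dt_adv <- 0.35 * h / max(2.5 * u_scale, 1e-6)
  dt_visc <- 0.4 * 2 / (nu * max(vapply(domain$comp, function(cp) cp$max_diag,
                                        numeric(1L))))
  dt <- min(dt_adv, dt_visc)
  st <- list(dt = dt, t = 0,
             arr = lapply(1:3, function(d) array(0, domain$comp[[d]]$dims)),
             sol = lapply(1:3, function(d)
               numeric(length(domain$comp[[d]]$active))),
             p_full = numeric(prod(domain$dims)),
             inlet_vals = lapply(1:3, function(d)
               inlet_values(domain, d, u_init_mean)),
             p_out = mmhg_to_pa(cond$outlet_pressure_mmhg),
             waveform_eval = function(t) evaluate_waveform(cond$inlet, t),
             u_inlet_mean = u_scale, div_norm = 0)
  if (!is.null(init)) {
    for (d in 1:3) {
      st$arr[[d]] <- init[[c("u", "v", "w")[d]]]
      st$sol[[d]] <- st$arr[[d]][domain$comp[[d]]$active]
    }
    st$p_full <- init$p_full
  } else {
    # start from the fully developed profile carried along the local tangent
    uc <- init_parabolic(domain, u_init_mean)
    for (d in 1:3) {
      st$arr[[d]] <- uc[[d]]
      st$sol[[d]] <- st$arr[[d]][domain$comp[[d]]$active]
    }
  }
  st
}

# initial guess: parabolic profile along the local tangent on every face
init_parabolic <- function(domain, u_mean) {
  lapply(1:3, function(d) {
    cp <- domain$comp[[d]]
    a <- array(0, cp$dims)
    faces <- c(cp$active, cp$inlet_faces)
    if (length(faces)) {
      s_f <- pmin(cp$s[faces], max(domain$fine_s))
      r_f <- stats::approx(domain$fine_s, domain$fine_r, xout = s_f, rule = 2L)$y
      rho_d <- pmin(cp$dist[faces] / r_f, 1)
      st_s <- domain$geom$station_s * 1e-3
      t_d <- stats::approx(st_s, domain$geom$tangents[, d], xout = s_f,
                           rule = 2L)$y
      a[faces] <- u_mean * 2 * (1 - rho_d^2) * t_d
    }
    a
  })
}

# inlet face values for a given mean velocity: fully developed profile
inlet_values <- function(domain, d, u_mean) {
  cp <- domain$comp[[d]]
  if (is.null(cp$inlet_pref)) return(numeric(0))
  u_mean * cp$inlet_pref
}

# one projection step; t_new/dt_use only matter for transient runs
advance <- function(st, domain, props, t_new = NULL, dt_use = NULL) {
  h <- domain$h
  dt <- if (is.null(dt_use)) st$dt else dt_use
  nu <- props$viscosity / props$density
  u_in_mean <- if (is.null(t_new)) st$u_inlet_mean else st$waveform_eval(t_new)
  cps <- domain$comp
  arr <- st$arr
  star <- vector("list", 3L)
  for (d in 1:3) {
    cp <- cps[[d]]
    adv <- advect_component(arr, domain$adv_idx[[d]], cp, d, h)
    visc <- as.numeric(cp$L %*% st$sol[[d]])
    if (ncol(cp$C) > 0L)
      visc <- visc + as.numeric(cp$C %*% (st$inlet_vals[[d]]))
    star[[d]] <- st$sol[[d]] +
      dt * (-adv + nu * visc + props$body_force[d] / props$density)
  }
  # update inlet values (transient waveforms)
  if (!is.null(t_new)) {
    for (d in 1:3) st$inlet_vals[[d]] <- inlet_values(domain, d, u_in_mean)
  }
  for (d in 1:3) {
    a <- array(0, cps[[d]]$dims)
    a[cps[[d]]$active] <- star[[d]]
    a[cps[[d]]$inlet_faces] <- st$inlet_vals[[d]]
    arr[[d]] <- a
  }
  # pressure projection on FREE cells
  di <- domain$div_idx
  divu <- (arr[[1L]][di[[1L]]$p] - arr[[1L]][di[[1L]]$m] +
             arr[[2L]][di[[2L]]$p] - arr[[2L]][di[[2L]]$m] +
             arr[[3L]][di[[3L]]$p] - arr[[3L]][di[[3L]]$m]) / h
  rho <- props$density
  p_out <- st$p_out
  rhs <- (rho / dt) * divu - domain$poisson$out_coef * p_out
  p <- as.numeric(Matrix::solve(domain$poisson$chol, -rhs))
  p_full <- st$p_full
  p_full[domain$poisson$free] <- p
  p_full[domain$ctype == 3L] <- p_out
  for (d in 1:3) {
    cp <- cps[[d]]
    gl <- p_full[cp$left[cp$active]]
    gr <- p_full[cp$right[cp$active]]
    newv <- arr[[d]][cp$active] - (dt / rho) * (gr - gl) / h
    arr[[d]][cp$active] <- newv
    st$sol[[d]] <- newv
  }
  st$arr <- arr
  st$p_full <- p_full
  st$t <- st$t + dt
  # continuity residual after correction (projection is exact to solver eps)
  div2 <- (arr[[1L]][di[[1L]]$p] - arr[[1L]][di[[1L]]$m] +
             arr[[2L]][di[[2L]]$p] - arr[[2L]][di[[2L]]$m] +
             arr[[3L]][di[[3L]]$p] - arr[[3L]][di[[3L]]$m]) / h
  st$div_norm <- sqrt(mean(div2^2)) * h / max(st$u_inlet_mean, 1e-9)
  st
}

# first-order upwind advection of component d, evaluated at its active
# faces only (values at wall faces are zero, matching the no-slip ghost)
advect_component <- function(arr, ai, cp, d, h) {
  a <- arr[[d]]
  f <- a[cp$active]
  adv <- numeric(length(f))
  for (ax in 1:3) {
    fm <- a[ai$ax[[ax]]$m]
    fp <- a[ai$ax[[ax]]$p]
    vel <- if (ax == d) f else {
      cr <- ai$cross[[as.character(ax)]]
      ae <- arr[[cr$comp]]
      0.25 * (ae[cr$i1] + ae[cr$i2] + ae[cr$i3] + ae[cr$i4])
    }
    pos <- vel > 0
    adv <- adv + vel * (pos * (f - fm) + (!pos) * (fp - f)) / h
  }
  adv
}

# shift along axis ax by +1 (towards larger index reads smaller) with zero fill
shift_arr <- function(f, ax, by) {
  d <- dim(f)
  out <- array(0, d)
  n <- d[ax]
  src <- if (by > 0L) 1:(n - 1L) else 2:n
  dst <- if (by > 0L) 2:n else 1:(n - 1L)
  if (ax == 1L) out[dst, , ] <- f[src, , , drop = FALSE]
  else if (ax == 2L) out[, dst, ] <- f[, src, , drop = FALSE]
  else out[, , dst] <- f[, , src, drop = FALSE]
  out
}

flow_field_from_state <- function(st, domain, props, cond, u_mean,
                                  converged, residuals, time = 0) {
  structure(list(u = st$arr[[1L]], v = st$arr[[2L]], w = st$arr[[3L]],
                 p_full = st$p_full, p = st$p_full[domain$cell_index],
                 domain = domain, props = props, cond = cond,
                 inlet_mean_velocity = u_mean, time = time,
                 converged = converged, residual_history = residuals,
                 continuity_residual = st$div_norm,
                 shear_rate = NULL),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  uc <- cell_velocity(x)
  cat(sprintf(paste0("<flow_field> t = %.2f s, inlet mean %.3g m/s, ",
                     "max |u| %.3g m/s, %s\n"),
              x$time, x$inlet_mean_velocity, max(sqrt(rowSums(uc^2))),
              if (isTRUE(x$converged)) "converged" else "transient"))
  invisible(x)
}

#' Cell-centered velocity vectors of a flow field
#'
#' @param field a `flow_field`
#' @return matrix (fluid cells x 3) of velocity in m/s, ordered as
#'   `field$domain$cell_index`
#' @export
cell_velocity <- function(field) {
  dom <- field$domain
  dm <- dom$dims
  pos <- arrayInd(dom$cell_index, dm)
  fd <- lapply(dom$comp, `[[`, "dims")
  lin <- function(p, fdim) p[, 1L] + (p[, 2L] - 1L) * fdim[1L] +
    (p[, 3L] - 1L) * fdim[1L] * fdim[2L]
  m1 <- lin(pos, fd[[1L]])
  p2 <- pos; p2[, 1L] <- p2[, 1L] + 1L
  u <- 0.5 * (field$u[m1] + field$u[lin(p2, fd[[1L]])])
  m2 <- lin(pos, fd[[2L]])
  p2 <- pos; p2[, 2L] <- p2[, 2L] + 1L
  v <- 0.5 * (field$v[m2] + field$v[lin(p2, fd[[2L]])])
  m3 <- lin(pos, fd[[3L]])
  p2 <- pos; p2[, 3L] <- p2[, 3L] + 1L
  w <- 0.5 * (field$w[m3] + field$w[lin(p2, fd[[3L]])])
  cbind(u, v, w)
}

#' Volumetric flux through a cross-section
#'
#' Averages the axial velocity over fluid cells in a thin arclength band and
#' multiplies by cell volume over band thickness.
#'
#' @param field a `flow_field`
#' @param s_frac arclength fraction of the section (0 = inlet end)
#' @param thickness_mm band thickness (default 2 cells)
#' @return flux in m^3/s
#' @export
flux_through <- function(field, s_frac, thickness_mm = NULL) {
  dom <- field$domain
  h <- dom$h
  thick <- if (is.null(thickness_mm)) 2 * h else thickness_mm * 1e-3
  s0 <- s_frac * dom$s_total
  inband <- abs(dom$s_cell - s0) <= thick / 2 & dom$ctype[dom$cell_index] != 0L
  if (!any(inband)) stop("no fluid cells in the requested band")
  uc <- cell_velocity(field)
  ax <- rowSums(uc[inband, , drop = FALSE] * dom$tangent_cell[inband, , drop = FALSE])
  sum(ax) * h^3 / thick
}
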