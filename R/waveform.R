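#' Inlet velocity waveforms
#'
#' The pulsatile inlet is driven by a periodic waveform cycling between the
#' Doppler diastolic velocity `u_min` and peak systolic velocity `u_max` at
#' the pulse frequency `f` (pulse rate / 60). Supported shapes:
#'
#' * `constant` — `u_max` at all times.
#' * `sinusoid` — `(u_max - u_min) * sin(2 pi f t) + u_min`. The `"literal"`
#'   variant evaluates exactly that expression (it starts at `u_min`, peaks
#'   at quarter period, and dips to `2 u_min - u_max` at the trough); the
#'   `"clipped"` variant floors the trough at `u_min`, so the amplitude spans
#'   diastolic-to-systolic over the positive half-cycle only. Peak-phase
#'   behaviour is identical.
#' * `square` — `u_max` for the first `duty` fraction of each period, `u_min`
#'   for the rest (duty cycle 0.2 means peak systolic velocity for 20 percent
#'   of the pulse duration).
#' * `sawtooth` — slow linear rise `u_min -> u_max` over 80 percent of the
#'   period, fast linear fall over the remaining 20 percent (the
#'   diastolic-to-systolic transition is slower than systolic-to-diastolic).
#'
#' @param kind one of `"constant"`, `"sinusoid"`, `"square"`, `"sawtooth"`
#' @param u_max peak systolic velocity, m/s
#' @param u_min diastolic velocity, m/s (`u_max >= u_min >= 0`)
#' @param frequency pulse frequency in Hz (pulse rate / 60); required > 0
#'   for non-constant kinds
#' @param duty duty cycle in \[0, 1\] (square only; default 0.5)
#' @param variant `"literal"` or `"clipped"` (sinusoid only)
#' @return an object of class `inlet_waveform`
#' @export
inlet_waveform <- function(kind = c("constant", "sinusoid", "square", "sawtooth"),
                           u_max, u_min = u_max, frequency = NA_real_,
                           duty = 0.5, variant = c("literal", "clipped")) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  if (!(u_max >= u_min && u_min >= 0))
    stop("need u_max >= u_min >= 0")
  if (kind != "constant" && (!is.finite(frequency) || frequency <= 0))
    stop("non-constant waveforms need frequency > 0")
  if (duty < 0 || duty > 1) stop("duty must be in [0, 1]")
  structure(list(kind = kind, u_max = u_max, u_min = u_min,
                 frequency = frequency, duty = duty, variant = variant),
            class = "inlet_waveform")
}

#' Evaluate an inlet waveform
#'
#' @param w an [inlet_waveform()]
#' @param t time(s) in seconds (>= 0)
#' @return velocity in m/s. A literal sinusoid whose trough
#'   (`2 u_min - u_max`) is negative raises an error flagging the
#'   inconsistent `u_min`/`u_max` pair.
#' @export
evaluate_waveform <- function(w, t) {
  stopifnot(inherits(w, "inlet_waveform"), all(t >= 0))
  u <- switch(w$kind,
    constant = rep(w$u_max, length(t)),
    sinusoid = {
      v <- (w$u_max - w$u_min) * sin(2 * pi * w$frequency * t) + w$u_min
      if (w$variant == "clipped") pmax(v, w$u_min) else v
    },
    square = {
      ph <- (t * w$frequency) %% 1
      ifelse(ph < w$duty, w$u_max, w$u_min)
    },
    sawtooth = {
      ph <- (t * w$frequency) %% 1
      ifelse(ph < 0.8,
             w$u_min + (w$u_max - w$u_min) * ph / 0.8,
             w$u_max - (w$u_max - w$u_min) * (ph - 0.8) / 0.2)
    })
  if (any(u < 0))
    stop("waveform evaluates to a negative velocity; u_min/u_max are inconsistent (literal sinusoid trough is 2*u_min - u_max)")
  u
}

#' Flow conditions for a simulation
#'
#' @param inlet an [inlet_waveform()]
#' @param outlet_pressure_mmhg outlet pressure in mmHg (default 23, the
#'   approximate peak systolic pressure measured in the arch; pulsatile runs
#'   at the 3-month timepoint conventionally use 20)
#' @param transient `TRUE` for pulsatile (time-dependent) runs
#' @param dt output time step, s (default 0.05)
#' @param t_end simulated interval, s (default 1.5, in excess of one full
#'   pulse cycle at all measured pulse rates)
#' @param steady_rel_tol steady-state relative tolerance (default 0.001)
#' @param transient_residual_tol per-step residual tolerance for transient
#'   runs (default 0.01)
#' @return an object of class `flow_conditions`
#' @export
flow_conditions <- function(inlet, outlet_pressure_mmhg = 23,
                            transient = FALSE, dt = 0.05, t_end = 1.5,
                            steady_rel_tol = 1e-3,
                            transient_residual_tol = 1e-2) {
  stopifnot(inherits(inlet, "inlet_waveform"), dt > 0, t_end >= dt,
            steady_rel_tol > 0, transient_residual_tol > 0)
  structure(list(inlet = inlet, outlet_pressure_mmhg = outlet_pressure_mmhg,
                 transient = transient, dt = dt, t_end = t_end,
                 steady_rel_tol = steady_rel_tol,
                 transient_residual_tol = transient_residual_tol),
            class = "flow_conditions")
}

#' Fluid properties
#'
#' @param density blood density, kg/m^3 (default 1060)
#' @param viscosity dynamic viscosity, Pa s (default 3.45e-3, the whole-blood
#'   approximation; patient runs use the measured whole-blood viscosity,
#'   cP x 1e-3)
#' @param body_force volume force vector, N/m^3 (default zero; gravity is
#'   neglected)
#' @return an object of class `fluid_properties`
#' @export
fluid_properties <- function(density = 1060, viscosity = 3.45e-3,
                             body_force = c(0, 0, 0)) {
  stopifnot(density > 0, viscosity > 0, length(body_force) == 3L)
  structure(list(density = density, viscosity = viscosity,
                 body_force = as.numeric(body_force)),
            class = "fluid_properties")
}
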