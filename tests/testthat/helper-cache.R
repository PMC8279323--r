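# memoize expensive fixtures (solver runs, renders) across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# shared straight-tube Poiseuille benchmark: d = 9.5 mm, mean inlet 5 cm/s
poiseuille_run <- function() {
  cached("poiseuille", {
    geom <- suppressWarnings(
      make_idealized_arch(diameter = 0.95, bend_angle = 180,
                          arm_length_pre = 3, arm_length_post = 3))
    dom <- discretize(geom, 16L)
    props <- fluid_properties(1060, 3.45e-3)
    cond <- flow_conditions(inlet_waveform("constant", u_max = 0.05))
    field <- solve_steady(dom, props, cond, max_steps = 8000L)
    list(geom = geom, dom = dom, props = props, cond = cond, field = field)
  })
}

# shared idealized-arch runs at high and low inlet velocity (bend asymmetry)
arch_runs <- function() {
  cached("arch", {
    geom <- make_idealized_arch()
    dom <- discretize(geom, 12L)
    props <- fluid_properties(1060, 3.45e-3)
    hi <- suppressWarnings(
      solve_steady(dom, props,
                   flow_conditions(inlet_waveform("constant", u_max = 0.70)),
                   max_steps = 8000L, on_nonconvergence = "warn"))
    lo <- solve_steady(dom, props,
                       flow_conditions(inlet_waveform("constant", u_max = 0.01)),
                       max_steps = 8000L)
    bend <- which(geom$region_label == "bend")
    list(geom = geom, dom = dom, props = props, hi = hi, lo = lo,
         mid_station = bend[ceiling(length(bend) / 2)])
  })
}

# pulsatile runs with the P96 3-month parameters (0.66 cm, 133 degrees,
# 40% bend constriction; sinusoid 38.3-66.6 cm/s at 101 beats/min)
pulsatile_runs <- function() {
  cached("pulsatile", {
    geom <- make_idealized_arch(diameter = 0.66, bend_angle = 133,
                                arm_length_pre = 1.5, arm_length_post = 1.5,
                                bend_radius = 1.2,
                                stenoses = list(list(arclength_fraction = 0.5,
                                                     severity = 0.4,
                                                     extent = 0.5)))
    props <- fluid_properties(1060, 2.96e-3)
    dom <- discretize(geom, 11L)
    w <- inlet_waveform("sinusoid", u_max = 0.666, u_min = 0.383,
                        frequency = 101 / 60, variant = "clipped")
    cond <- flow_conditions(w, outlet_pressure_mmhg = 20, transient = TRUE)
    pulse <- suppressWarnings(solve_pulsatile(dom, props, cond))
    w10 <- inlet_waveform("sinusoid", u_max = 0.0666, u_min = 0.0383,
                          frequency = 101 / 60, variant = "clipped")
    pulse10 <- solve_pulsatile(dom, props,
                               flow_conditions(w10, outlet_pressure_mmhg = 20,
                                               transient = TRUE))
    dom2 <- discretize(geom, 14L)
    hi2 <- suppressWarnings(
      solve_steady(dom2, props,
                   flow_conditions(inlet_waveform("constant", u_max = 0.666),
                                   outlet_pressure_mmhg = 20),
                   max_steps = 8000L, on_nonconvergence = "warn"))
    lo2 <- solve_steady(dom2, props,
                        flow_conditions(inlet_waveform("constant",
                                                       u_max = 0.0666),
                                        outlet_pressure_mmhg = 20),
                        max_steps = 8000L)
    list(pulse = pulse, pulse10 = pulse10,
         recirc_hi_res2 = detect_recirculation(hi2)$flag,
         recirc_lo_res2 = detect_recirculation(lo2)$flag)
  })
}

# small synthetic arch imaging round trip (venogram + IVUS of a stenosed arch)
roundtrip_run <- function() {
  cached("roundtrip", {
    spec <- arch_spec(diameter = 0.95, bend_angle_deg = 125,
                      arm_length_pre = 5, arm_length_post = 5, bend_radius = 2,
                      stenoses = list(list(arclength_fraction = 0.5,
                                           severity = 0.4, extent = 1.5)),
                      seed = 42L)
    path <- make_arch_centerline(spec)
    veno <- render_venogram(path, spec$diameter, pixel_spacing = 0.2,
                            noise_sd = 0.05, seed = 42L)
    ivus <- render_ivus_stack(spec, frames_per_mm = 30L, image_px = 256L,
                              contour_noise_sd = 0.02, seed = 42L)
    list(spec = spec, path = path, veno = veno, ivus = ivus)
  })
}
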