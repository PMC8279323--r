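#' Reynolds number of vessel flow
#'
#' `Re = rho * u * L / eta`: the ratio of inertial to viscous forces. For the
#' cephalic arch, `u` is the Doppler peak systolic velocity (m/s), `L` the
#' average vein diameter from IVUS (m) and `eta` the measured whole-blood
#' viscosity (Pa s); flow in pipes is laminar below roughly 2000.
#'
#' @param rho blood density, kg/m^3 (default 1060, the whole-blood average)
#' @param u velocity, m/s (>= 0)
#' @param L characteristic length (vessel diameter), m
#' @param eta dynamic viscosity, Pa s
#' @param rounded if `TRUE` (default) round half away from zero to an
#'   integer, the convention used in clinical reporting tables
#' @return dimensionless Reynolds number
#' @export
reynolds <- function(rho = 1060, u, L, eta, rounded = TRUE) {
  if (any(L <= 0) || any(eta <= 0))
    stop("'L' and 'eta' must be positive")
  if (any(u < 0)) stop("'u' must be >= 0")
  if (any(rho <= 0)) stop("'rho' must be positive")
  re <- rho * u * L / eta
  if (rounded) round_half_up(re) else re
}

# round half away from zero (printed tables round 0.5 up, unlike round())
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Equivalent circular diameter from a cross-sectional area
#'
#' `2 * sqrt(area / pi)`: the diameter of the circle with the same area,
#' used to reduce traced IVUS lumen areas to an average vessel diameter.
#'
#' @param area cross-sectional area, cm^2 (> 0)
#' @return diameter in cm
#' @export
diameter_from_area <- function(area) {
  if (any(area <= 0)) stop("'area' must be positive")
  2 * sqrt(area / pi)
}

#' Convert pressure from mmHg to Pa
#' @param p pressure in mmHg
#' @return pressure in Pa (1 mmHg = 133.322 Pa)
#' @export
mmhg_to_pa <- function(p) p * 133.322

#' Load the packaged cohort of measured patient parameters
#'
#' Ten records (five brachiocephalic-fistula patients at 3 and 12 months
#' after fistula placement): Doppler systolic/diastolic velocities, whole
#' blood viscosity, blood pressure, pulse, IVUS lumen area and derived
#' diameter, Reynolds number and venogram arch angle.
#'
#' @return a data.frame with one row per patient/timepoint
#' @export
cephalic_cohort <- function() {
  f <- system.file("extdata", "table2_patient_parameters.csv",
                   package = "archflow", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Cohort summary statistics per timepoint
#'
#' Arithmetic means and sample standard deviations (n - 1) of velocity,
#' diameter, arch angle and Reynolds number per timepoint, with the Reynolds
#' number recomputed from each record's velocity, diameter and viscosity at
#' rho = 1060 kg/m^3 (not taken from any tabulated column). Per-patient
#' Reynolds averages across timepoints are also reported.
#'
#' @param records data.frame of patient records in the layout of
#'   [cephalic_cohort()] (columns `patient_id`, `timepoint`,
#'   `systolic_velocity_cm_s`, `vein_diameter_cm`, `wbv_cP`,
#'   `arch_angle_deg`)
#' @param rho blood density kg/m^3
#' @return list with `by_timepoint` (data.frame of mean/sd per timepoint) and
#'   `re_avg_by_patient` (data.frame of per-patient mean Reynolds number).
#'   With a single record in a timepoint the SD is reported as 0 and flagged
#'   in the `sd_defined` column.
#' @export
cohort_summary <- function(records, rho = 1060) {
  req <- c("patient_id", "timepoint", "systolic_velocity_cm_s",
           "vein_diameter_cm", "wbv_cP", "arch_angle_deg")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) < 1L) stop("need at least one record")
  re <- reynolds(rho,
                 u = records$systolic_velocity_cm_s / 100,
                 L = records$vein_diameter_cm / 100,
                 eta = records$wbv_cP * 1e-3)
  records$re <- re
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  tp <- sort(unique(records$timepoint))
  by_tp <- do.call(rbind, lapply(tp, function(t) {
    r <- records[records$timepoint == t, ]
    data.frame(timepoint = t, n = nrow(r),
               mean_velocity_cm_s = mean(r$systolic_velocity_cm_s),
               sd_velocity_cm_s = sd0(r$systolic_velocity_cm_s),
               mean_diameter_cm = mean(r$vein_diameter_cm),
               sd_diameter_cm = sd0(r$vein_diameter_cm),
               mean_arch_angle_deg = mean(r$arch_angle_deg),
               sd_arch_angle_deg = sd0(r$arch_angle_deg),
               mean_re = mean(r$re), sd_re = sd0(r$re),
               sd_defined = nrow(r) > 1L)
  }))
  pid <- unique(records$patient_id)
  re_avg <- do.call(rbind, lapply(pid, function(p) {
    r <- records[records$patient_id == p, ]
    data.frame(patient_id = p, n = nrow(r), re_avg = mean(r$re))
  }))
  list(by_timepoint = by_tp, re_avg_by_patient = re_avg)
}
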