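#' Image stacks
#'
#' Ordered grids of pixel intensities with physical pixel spacing (mm/pixel)
#' and, for pullback imaging, a frame spacing (mm/frame). Matrices are
#' indexed `[x, y]`.
#'
#' @param frames list of numeric matrices, all the same dimension
#' @param pixel_spacing mm per pixel (> 0)
#' @param frame_spacing mm per frame for pullback stacks, or `NA` for cine
#'   stacks of a fixed projection
#' @export
image_stack <- function(frames, pixel_spacing, frame_spacing = NA_real_) {
  stopifnot(length(frames) >= 1L, pixel_spacing > 0)
  dm <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), dm), logical(1L))))
    stop("all frames must have the same dimensions")
  structure(list(frames = frames, pixel_spacing = pixel_spacing,
                 frame_spacing = frame_spacing),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px at %.3g mm/px\n",
              length(x$frames), nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
              x$pixel_spacing))
  invisible(x)
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# min distance from grid pixels to a polyline, chunked per segment
polyline_distance_grid <- function(xs, ys, pts) {
  nx <- length(xs); ny <- length(ys)
  dmin <- matrix(Inf, nx, ny)
  gx <- matrix(xs, nx, ny)
  gy <- matrix(ys, nx, ny, byrow = TRUE)
  for (k in seq_len(nrow(pts) - 1L)) {
    a <- pts[k, ]; b <- pts[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t_ <- ((gx - a[1L]) * ab[1L] + (gy - a[2L]) * ab[2L]) / len2
    t_[t_ < 0] <- 0; t_[t_ > 1] <- 1
    d <- sqrt((gx - (a[1L] + t_ * ab[1L]))^2 + (gy - (a[2L] + t_ * ab[2L]))^2)
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Render a venogram-like projection of a vessel path
#'
#' Emulates a contrast venogram: the vessel appears darker than the
#' background (contrast convention of X-ray venography), and several cine
#' frames carry independent noise so that a minimum-intensity projection is
#' meaningful. The generating ground truth is attached as attribute `truth`.
#'
#' @param path a [centerline_path()] (planar; z ignored)
#' @param diameter vessel diameter in cm
#' @param pixel_spacing mm per pixel (default 0.2)
#' @param noise_sd intensity noise SD per frame (intensities are in \[0, 1\];
#'   vessel 0.25, background 0.75)
#' @param seed RNG seed (generator is a pure function of its arguments)
#' @param n_frames number of cine frames (default 5)
#' @param margin_mm blank margin around the vessel (default 3)
#' @param canvas_px optional `c(nx, ny)`; if given and too small to contain
#'   the vessel, an error reports the required size
#' @return an [image_stack()] with attribute `truth` (list: `centerline`,
#'   `diameter_cm`)
#' @export
render_venogram <- function(path, diameter, pixel_spacing = 0.2,
                            noise_sd = 0.05, seed = 1L, n_frames = 5L,
                            margin_mm = 3, canvas_px = NULL) {
  stopifnot(inherits(path, "centerline_path"), pixel_spacing > 0, diameter > 0)
  if (path_length(path) <= 0) stop("zero-length path")
  r <- diameter * 10 / 2
  pts <- resample_path(path, spacing = max(0.5, pixel_spacing))$points[, 1:2]
  lo <- apply(pts, 2L, min) - r - margin_mm
  hi <- apply(pts, 2L, max) + r + margin_mm
  need <- ceiling((hi - lo) / pixel_spacing)
  if (is.null(canvas_px)) {
    canvas_px <- need
  } else if (any(canvas_px < need)) {
    stop(sprintf("path exits frame: canvas %d x %d px required (got %d x %d)",
                 need[1L], need[2L], canvas_px[1L], canvas_px[2L]))
  }
  xs <- lo[1L] + (seq_len(canvas_px[1L]) - 0.5) * pixel_spacing
  ys <- lo[2L] + (seq_len(canvas_px[2L]) - 0.5) * pixel_spacing
  d <- polyline_distance_grid(xs, ys, pts)
  base <- ifelse(d <= r, 0.25, 0.75)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    f <- base + stats::rnorm(length(base), sd = noise_sd)
    dim(f) <- dim(base)
    pmin(pmax(f, 0), 1)
  }))
  out <- image_stack(frames, pixel_spacing)
  attr(out, "truth") <- list(centerline = path, diameter_cm = diameter,
                             origin_mm = lo)
  out
}

#' Render an IVUS-like pullback of an arch specification
#'
#' Produces per-frame lumen cross-sections along the vessel at `1 /
#' frames_per_mm` mm per frame: ground-truth contour polygons for every
#' frame, and binary lumen masks rasterized every `mask_stride` frames (by
#' default the every-30th-frame subset that downstream processing consumes;
#' rasterizing every frame of a long pullback would be gigabytes). The
#' pullback starts with an axillary-vein lead-in of distinctly larger lumen
#' so arch-start alignment is testable, then traverses the arch, whose
#' radius profile includes any specified stenoses.
#'
#' @param spec an [arch_spec()]
#' @param frames_per_mm frames recorded per mm of pullback (default 30)
#' @param image_px mask frames are `image_px x image_px` (default 500)
#' @param fov_mm physical field of view of a frame (default 16)
#' @param contour_noise_sd radial tracing noise SD in mm (default 0)
#' @param seed RNG seed
#' @param mask_stride frame stride for rasterized masks
#' @param lead_in_cm axillary lead-in length (default 1 cm)
#' @param lead_in_scale axillary/arch diameter ratio (default 1.5)
#' @param n_vertices contour vertices per frame (default 64)
#' @return list of class `ivus_pullback`: `images` (an [image_stack()] of the
#'   strided masks), `contours` (list of [lumen_contour()] for every frame),
#'   `mask_frames` (frame indices of the rasterized masks), and `truth`
#'   (per-frame arclength/radius/area, arch start frame, spec)
#' @export
render_ivus_stack <- function(spec, frames_per_mm = 30L, image_px = 500L,
                              fov_mm = 16, contour_noise_sd = 0, seed = 1L,
                              mask_stride = frames_per_mm, lead_in_cm = 1,
                              lead_in_scale = 1.5, n_vertices = 64L) {
  stopifnot(inherits(spec, "arch_spec"), frames_per_mm >= 1L)
  defl <- (180 - spec$bend_angle_deg) * pi / 180
  arch_len <- (spec$arm_length_pre + spec$arm_length_post +
                 spec$bend_radius * defl) * 10
  lead <- lead_in_cm * 10
  total <- lead + arch_len
  dz <- 1 / frames_per_mm
  s <- seq(0, total - 1e-9, by = dz)
  r_arch <- arch_radius_profile(spec, pmax(s - lead, 0), arch_len)
  r0 <- spec$diameter * 10 / 2
  # smooth 1 mm shoulder from the axillary lead-in down to the arch radius
  blend <- pmin(pmax((s - lead) / 1, 0), 1)
  w <- 0.5 * (1 - cos(pi * blend))
  radius <- (1 - w) * (lead_in_scale * r0) + w * r_arch
  radius[s >= lead + 1] <- r_arch[s >= lead + 1]
  if (2 * max(radius) + 1 > fov_mm)
    stop(sprintf("field of view %.1f mm smaller than lumen diameter %.1f mm",
                 fov_mm, 2 * max(radius)))
  ctr <- fov_mm / 2
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  contours <- with_seed(seed, lapply(seq_along(s), function(i) {
    rr <- radius[i] + if (contour_noise_sd > 0)
      stats::rnorm(n_vertices, sd = contour_noise_sd) else 0
    rr <- pmax(rr, 0.05 * radius[i])
    lumen_contour(i, cbind(ctr + rr * cos(ang), ctr + rr * sin(ang)))
  }))
  mask_frames <- seq(1L, length(s), by = mask_stride)
  px <- (seq_len(image_px) - 0.5) * (fov_mm / image_px)
  gx <- matrix(px, image_px, image_px) - ctr
  gy <- matrix(px, image_px, image_px, byrow = TRUE) - ctr
  gd <- sqrt(gx^2 + gy^2)
  gth <- atan2(gy, gx) %% (2 * pi)
  frames <- lapply(mask_frames, function(i) {
    vr <- sqrt(rowSums(sweep(contours[[i]]$vertices, 2L, c(ctr, ctr))^2))
    rfun <- stats::approx(c(ang, 2 * pi), c(vr, vr[1L]), xout = as.vector(gth))$y
    m <- (as.vector(gd) <= rfun) * 1
    dim(m) <- c(image_px, image_px)
    m
  })
  truth <- list(s_mm = s, radius_mm = radius,
                area_cm2 = pi * radius^2 / 100,
                arch_start_frame = which(s >= lead)[1L],
                lead_in_mm = lead, arch_length_mm = arch_len, spec = spec)
  structure(list(images = image_stack(frames, fov_mm / image_px, dz * mask_stride),
                 contours = contours, mask_frames = mask_frames, truth = truth),
            class = "ivus_pullback")
}

#' Generate synthetic patient parameter records
#'
#' Records span the observed clinical ranges of brachiocephalic-fistula
#' patients: systolic velocity uniform on \[9.4, 66.6\] cm/s with diastolic
#' strictly below systolic, whole blood viscosity on \[2.68, 4.63\] cP, pulse
#' on \[71, 101\] beats/min, vein diameter on \[0.66, 1.1\] cm and arch angle
#' on \[113, 152\] degrees. Because velocity, diameter and viscosity never
#' combine adversely in measured patients, records are rejection-resampled
#' until the implied Reynolds number lies in \[100, 2100\].
#'
#' @param n number of records (>= 1)
#' @param seed RNG seed; the output is a pure function of `(n, seed)`
#' @return data.frame in the layout of [cephalic_cohort()] (without the
#'   tabulated `reynolds` column; use [reynolds()] to compute it)
#' @export
gen_patient_records <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    draw <- function(m) {
      d <- stats::runif(m, 0.66, 1.1)
      data.frame(
        systolic_velocity_cm_s = round(stats::runif(m, 9.4, 66.6), 1),
        diastolic_velocity_cm_s = NA_real_,
        wbv_cP = round(stats::runif(m, 2.68, 4.63), 2),
        bp_systolic_mmHg = round(stats::runif(m, 99, 174)),
        bp_diastolic_mmHg = round(stats::runif(m, 60, 96)),
        pulse_bpm = round(stats::runif(m, 71, 101)),
        vein_diameter_cm = round(d, 2),
        vein_area_cm2 = round(pi * (d / 2)^2, 3),
        arch_angle_deg = round(stats::runif(m, 113, 152)))
    }
    rec <- draw(n)
    repeat {
      re <- reynolds(u = rec$systolic_velocity_cm_s / 100,
                     L = rec$vein_diameter_cm / 100,
                     eta = rec$wbv_cP * 1e-3, rounded = FALSE)
      bad <- re < 100 | re > 2100
      if (!any(bad)) break
      rec[bad, ] <- draw(sum(bad))
    }
    rec$diastolic_velocity_cm_s <-
      round(rec$systolic_velocity_cm_s * stats::runif(n, 0.25, 0.85), 1)
    cbind(data.frame(patient_id = sprintf("S%03d", seq_len(n)),
                     timepoint = rep(c("3mo", "12mo"), length.out = n)),
          rec)
  })
}
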