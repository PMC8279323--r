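#' Lumen contours and contour stacks
#'
#' A `lumen_contour` is one traced IVUS cross-section: a simple closed polygon
#' in frame coordinates (mm), with its area (cm^2) and centroid. A
#' `lumen_contour_stack` is an ordered pullback sequence of contours with a
#' uniform slice spacing (mm).
#'
#' @param frame_index integer frame number within the pullback
#' @param vertices k x 2 matrix of polygon vertices in mm (closed implicitly;
#'   do not repeat the first vertex)
#' @return object of class `lumen_contour`
#' @export
lumen_contour <- function(frame_index, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 8L)
    stop("degenerate contour: need at least 8 vertices")
  a <- polygon_area(vertices, check = FALSE)
  if (a <= 0) stop("contour area must be positive")
  structure(list(frame_index = as.integer(frame_index), vertices = vertices,
                 area_cm2 = a, centroid_mm = polygon_centroid(vertices)),
            class = "lumen_contour")
}

#' @param contours list of `lumen_contour` objects with strictly increasing
#'   frame indices
#' @param slice_spacing axial spacing between successive contours, mm
#' @rdname lumen_contour
#' @export
lumen_contour_stack <- function(contours, slice_spacing = 1.0) {
  stopifnot(length(contours) >= 1L, slice_spacing > 0)
  idx <- vapply(contours, function(ct) ct$frame_index, integer(1L))
  if (any(diff(idx) <= 0)) stop("frame indices must be strictly increasing")
  structure(list(contours = contours, slice_spacing = slice_spacing),
            class = "lumen_contour_stack")
}

#' @export
print.lumen_contour_stack <- function(x, ...) {
  a <- stack_areas(x)
  cat(sprintf("<lumen_contour_stack> %d slices at %.3g mm, area %.3f-%.3f cm^2\n",
              length(x$contours), x$slice_spacing, min(a), max(a)))
  invisible(x)
}

#' Per-slice areas (cm^2) of a contour stack
#' @param stack a `lumen_contour_stack`
#' @export
stack_areas <- function(stack) {
  vapply(stack$contours, function(ct) ct$area_cm2, numeric(1L))
}

#' Absolute (shoelace) area of a simple closed polygon
#'
#' Orientation-independent. Vertices are in mm; the area is returned in cm^2
#' (the IVUS reporting unit).
#'
#' @param vertices k x 2 matrix of vertices in mm
#' @param check if `TRUE` (default), reject self-intersecting polygons
#' @return area in cm^2
#' @export
polygon_area <- function(vertices, check = TRUE) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("polygon needs at least 3 vertices")
  if (check && polygon_self_intersects(v))
    stop("polygon is self-intersecting")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2 / 100   # mm^2 -> cm^2
}

# area-weighted centroid of a simple polygon (mm)
polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# any pair of non-adjacent edges intersects? vectorized over all edge pairs
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  p <- v
  q <- v[c(2:n, 1L), , drop = FALSE]
  ij <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  d1 <- cross2(q[i, ] - p[i, ], p[j, ] - p[i, ])
  d2 <- cross2(q[i, ] - p[i, ], q[j, ] - p[i, ])
  d3 <- cross2(q[j, ] - p[j, ], p[i, ] - p[j, ])
  d4 <- cross2(q[j, ] - p[j, ], q[i, ] - p[j, ])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(a, b) a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]

#' Extract the lumen contour from one binary mask frame
#'
#' Traces the boundary of the largest foreground component and converts it to
#' physical coordinates. Boundary pixel centers are pushed half a pixel
#' outward along the local contour normal so the polygon encloses the full
#' foreground (a boundary through pixel centers under-covers a digitized disk
#' by about one percent). Reading frames in the clinical convention of
#' 500 x 500 px over 16 x 16 mm corresponds to `pixel_spacing = 0.032`.
#'
#' @param mask_frame binary matrix (rows = x, cols = y), nonzero = lumen
#' @param pixel_spacing mm per pixel
#' @param frame_index frame number recorded in the contour
#' @return a [lumen_contour()]
#' @export
extract_contour <- function(mask_frame, pixel_spacing, frame_index = 1L) {
  m <- (as.matrix(mask_frame) != 0) * 1L
  if (!any(m == 1L)) stop("empty frame: no foreground component")
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0L])
  if (length(tab) > 1L)
    warning(sprintf("%d foreground components; keeping the largest", length(tab)))
  keep <- which.max(tab)
  m[lab != keep] <- 0L
  oc <- EBImage::ocontour(m)[[1L]]
  if (nrow(oc) < 8L) stop("degenerate contour: component smaller than 8 boundary pixels")
  v <- push_outward(oc, 0.5) * pixel_spacing
  lumen_contour(frame_index, v)
}

# offset a closed pixel-center chain outward along the local normal
push_outward <- function(v, by) {
  n <- nrow(v)
  nxt <- v[c(2:n, 1L), , drop = FALSE]
  prv <- v[c(n, 1:(n - 1L)), , drop = FALSE]
  t_ <- nxt - prv
  nrm <- cbind(t_[, 2L], -t_[, 1L])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  ctr <- colMeans(v)
  outward <- rowSums(nrm * sweep(v, 2L, ctr)) >= 0
  nrm[!outward, ] <- -nrm[!outward, , drop = FALSE]
  v + by * nrm
}

#' Subsample a pullback to the reporting slice spacing
#'
#' IVUS pullback at 1 mm/s recorded at 30 frames/s advances 1/30 mm per
#' frame; keeping every `frames_per_mm`-th frame yields ~1 mm slices.
#'
#' @param all_frames list of [lumen_contour()] objects for every recorded
#'   frame (ordered), or a `lumen_contour_stack` at per-frame spacing
#' @param frames_per_mm stride between retained frames (default 30)
#' @param frame_spacing_mm axial advance per recorded frame (default 1/30 mm)
#' @return a [lumen_contour_stack()] with
#'   `slice_spacing = frames_per_mm * frame_spacing_mm`
#' @export
subsample_to_spacing <- function(all_frames, frames_per_mm = 30L,
                                 frame_spacing_mm = 1 / 30) {
  if (inherits(all_frames, "lumen_contour_stack")) {
    frame_spacing_mm <- all_frames$slice_spacing
    all_frames <- all_frames$contours
  }
  stopifnot(frames_per_mm >= 1L)
  if (length(all_frames) < frames_per_mm)
    stop("fewer frames than one slice stride")
  keep <- seq(1L, length(all_frames), by = frames_per_mm)
  contours <- all_frames[keep]
  # renumber by retained order so indices stay strictly increasing
  contours <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]; ct$frame_index <- as.integer(keep[i]); ct
  })
  lumen_contour_stack(contours, slice_spacing = frames_per_mm * frame_spacing_mm)
}

#' Locate the axillary-to-cephalic transition in a pullback
#'
#' The IVUS pullback starts in the (larger) axillary vein; the rapid shift in
#' lumen diameter marks where the cephalic arch begins. The per-slice
#' equivalent diameter series is median-filtered over 3 slices, then the
#' first slice is returned at which the median diameter over the following
#' `window_mm` differs from the preceding window's median by more than
#' `rel_drop` (relative).
#'
#' @param stack a [lumen_contour_stack()]
#' @param rel_drop relative diameter change that counts as the transition
#'   (default 0.25)
#' @param window_mm comparison window on each side, mm (default 5)
#' @return 1-based slice index of the transition. If no shift is found, index
#'   1 is returned with attribute `found = FALSE` and a warning.
#' @export
find_arch_start <- function(stack, rel_drop = 0.25, window_mm = 5) {
  d <- diameter_from_area(stack_areas(stack))
  n <- length(d)
  w <- max(1L, round(window_mm / stack$slice_spacing))
  if (n < 2L * w) stop("stack shorter than twice the comparison window")
  d <- stats::runmed(d, k = 3L, endrule = "keep")
  for (i in 2:(n - w + 1L)) {
    prev <- d[max(1L, i - w):(i - 1L)]
    nxt <- d[i:(i + w - 1L)]
    if (abs(stats::median(nxt) - stats::median(prev)) / stats::median(prev) > rel_drop) {
      # the window comparison triggers a little before the true transition;
      # refine to the largest single-slice diameter step nearby
      lo <- max(2L, i - w)
      hi <- min(n, i + w)
      steps <- abs(diff(d[(lo - 1L):hi]))
      return(structure(lo + which.max(steps) - 1L, found = TRUE))
    }
  }
  warning("no diameter shift found; returning index 1")
  structure(1L, found = FALSE)
}

#' Summary statistics of a lumen contour stack
#'
#' Arithmetic mean and sample standard deviation (n - 1) of the per-slice
#' areas, plus the mean equivalent diameter computed from the mean area (not
#' as the mean of per-slice diameters, matching how an average vessel
#' diameter is derived from cross-sectional area).
#'
#' @param stack a [lumen_contour_stack()]
#' @return list with `mean_area_cm2`, `sd_area_cm2`, `mean_diameter_cm`,
#'   `n_slices`
#' @export
summarize_lumen <- function(stack) {
  a <- stack_areas(stack)
  list(mean_area_cm2 = mean(a),
       sd_area_cm2 = if (length(a) > 1L) stats::sd(a) else 0,
       mean_diameter_cm = diameter_from_area(mean(a)),
       n_slices = length(a))
}
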