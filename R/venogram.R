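#' Minimum-intensity projection of an image stack
#'
#' Collapses a cine stack to a single frame by taking the per-pixel minimum
#' over frames. With venogram contrast (vessel dark), this accumulates the
#' vessel across frames while suppressing background noise upward excursions.
#'
#' @param stack an [image_stack()] (>= 1 frame)
#' @return a matrix of the same dimension as one frame
#' @export
min_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 1L) stop("empty stack")
  Reduce(pmin, stack$frames)
}

#' Binarize a projected venogram and keep the vessel component
#'
#' Thresholds the image (Otsu by default, computed on the projected image),
#' takes the dark side as vessel, removes connected components smaller than
#' `min_component_px`, and keeps the largest remaining component.
#'
#' @param image numeric matrix of intensities in \[0, 1\]
#' @param threshold_method `"otsu"` or a numeric threshold
#' @param min_component_px minimum component size kept, px (default 20)
#' @return logical matrix, `TRUE` = vessel
#' @export
binarize_and_clean <- function(image, threshold_method = "otsu",
                               min_component_px = 20L) {
  stopifnot(is.matrix(image), length(image) > 0L)
  thr <- if (is.numeric(threshold_method)) threshold_method
  else EBImage::otsu(EBImage::Image(image), range = range(0, 1))
  fg <- image < thr
  if (!any(fg) || all(fg)) stop("no vessel found")
  lab <- EBImage::bwlabel(fg * 1L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_px)
  if (!length(keep)) stop("no vessel found")
  keep <- keep[which.max(sizes[keep])]
  lab == keep
}

# shift a padded logical matrix by (dx, dy); out-of-range = FALSE
shift_mat <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
  okx <- xs >= 1L & xs <= nx; oky <- ys >= 1L & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Reduces a single connected binary region to its one-pixel-wide medial
#' skeleton by iterative two-subcycle thinning.
#'
#' @param mask logical or 0/1 matrix with one connected foreground component
#' @return logical matrix of skeleton pixels
#' @export
skeletonize_mask <- function(mask) {
  m <- as.matrix(mask) != 0
  if (!any(m)) stop("empty mask")
  lab <- EBImage::bwlabel(m * 1L)
  if (max(lab) > 1L) stop("mask has multiple connected components")
  # neighbours P2..P9 clockwise from north; y+1 is taken as north
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, o[1L], o[2L]))
      B <- Reduce(`+`, nb)
      seqn <- c(nb, nb[1L])
      A <- Reduce(`+`, lapply(1:8, function(i) !seqn[[i]] & seqn[[i + 1L]]))
      if (step == 1L) {
        c1 <- !(nb[[1L]] & nb[[3L]] & nb[[5L]])
        c2 <- !(nb[[3L]] & nb[[5L]] & nb[[7L]])
      } else {
        c1 <- !(nb[[1L]] & nb[[3L]] & nb[[7L]])
        c2 <- !(nb[[1L]] & nb[[5L]] & nb[[7L]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Order a skeleton into a centerline path
#'
#' Builds the 8-connected pixel graph of the skeleton (edge weights 1 and
#' sqrt(2)), takes the longest geodesic path between endpoints (which prunes
#' side branches such as collateral spurs), converts to physical mm,
#' resamples at uniform arclength and smooths before computing tangents and
#' curvature.
#'
#' @param skeleton logical matrix of skeleton pixels
#' @param pixel_spacing mm per pixel
#' @param origin_mm physical position of the (0, 0) pixel corner (default
#'   `c(0, 0)`)
#' @param spacing_mm resampling interval (default 0.25)
#' @param smooth_mm moving-average smoothing window (default 2)
#' @return a [centerline_path()]
#' @export
extract_centerline <- function(skeleton, pixel_spacing, origin_mm = c(0, 0),
                               spacing_mm = 0.25, smooth_mm = 2) {
  sk <- as.matrix(skeleton) != 0
  if (!any(sk)) stop("empty skeleton")
  idx <- which(sk, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 3L) stop("skeleton too small to order")
  key <- idx[, 1L] + 1i * idx[, 2L]
  id <- seq_len(n)
  names(id) <- as.character(key)
  edges <- NULL; wts <- NULL
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- as.character((idx[, 1L] + o[1L]) + 1i * (idx[, 2L] + o[2L]))
    hit <- nb %in% names(id)
    if (any(hit)) {
      edges <- c(edges, rbind(id[hit], id[nb[hit]]))
      wts <- c(wts, rep(sqrt(sum(o^2)), sum(hit)))
    }
  }
  g <- igraph::make_graph(as.vector(edges), n = n, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (igraph::components(g)$no > 1L) stop("skeleton is disconnected")
  if (!any(igraph::degree(g) == 1L))
    stop("cyclic skeleton with no endpoints")
  # double sweep for the (weighted) graph diameter path
  d0 <- igraph::distances(g, v = 1L)[1L, ]
  u <- which.max(d0)
  du <- igraph::distances(g, v = u)[1L, ]
  v <- which.max(du)
  vp <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1L]]
  ord <- as.integer(vp)
  pts <- cbind(origin_mm[1L] + (idx[ord, 1L] - 0.5) * pixel_spacing,
               origin_mm[2L] + (idx[ord, 2L] - 0.5) * pixel_spacing)
  path <- centerline_path(pts)
  path <- resample_path(path, spacing_mm)
  smooth_path(path, smooth_mm)
}

#' Full venogram-to-centerline pipeline
#'
#' Minimum-intensity projection, Otsu binarization and cleaning,
#' skeletonization, and centerline ordering, in one call.
#'
#' @inheritParams binarize_and_clean
#' @param stack an [image_stack()]
#' @param pixel_spacing mm per pixel; defaults to the stack's own spacing
#' @param ... passed to [extract_centerline()]
#' @return a [centerline_path()]
#' @export
process_venogram <- function(stack, threshold_method = "otsu",
                             min_component_px = 20L, pixel_spacing = NULL, ...) {
  proj <- min_intensity_projection(stack)
  mask <- binarize_and_clean(proj, threshold_method, min_component_px)
  sk <- skeletonize_mask(mask)
  ps <- if (is.null(pixel_spacing)) stack$pixel_spacing else pixel_spacing
  origin <- attr(stack, "truth")$origin_mm
  if (is.null(origin)) origin <- c(0, 0)
  extract_centerline(sk, ps, origin_mm = origin, ...)
}
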