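#' Write a triangulated surface as ASCII STL
#'
#' STL is unitless; coordinates are written in millimetres (the package-wide
#' mesh convention).
#'
#' @param geom a `vessel_geometry` (or list with `vertices`, `faces`)
#' @param path output file
#' @export
write_stl <- function(geom, path) {
  v <- geom$vertices; f <- geom$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nrm <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
               u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
               u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vessel", con)
  writeLines(sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nrm[, 1L], nrm[, 2L], nrm[, 3L],
    a[, 1L], a[, 2L], a[, 3L], b[, 1L], b[, 2L], b[, 3L],
    c_[, 1L], c_[, 2L], c_[, 3L]), con)
  writeLines("endsolid vessel", con)
  invisible(path)
}

#' Write a triangulated surface as legacy VTK PolyData
#'
#' Optionally attaches per-vertex scalar fields (e.g. wall shear stress).
#'
#' @param geom a `vessel_geometry`
#' @param path output file
#' @param point_data named list of per-vertex numeric vectors
#' @export
write_vtk_surface <- function(geom, path, point_data = list()) {
  v <- geom$vertices; f <- geom$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%g %g %g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a flow field as legacy VTK structured points
#'
#' Velocity (vector, m/s), pressure (Pa) and shear rate (1/s) on the
#' voxelized lumen; cells outside the fluid are zero-filled.
#'
#' @param field a `flow_field`
#' @param path output file
#' @export
write_vtk_field <- function(field, path) {
  dom <- field$domain
  dm <- dom$dims
  full <- function(x) { out <- numeric(prod(dm)); out[dom$cell_index] <- x; out }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "lumen flow field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dm[1L], dm[2L], dm[3L]),
               sprintf("ORIGIN %g %g %g", dom$origin[1L], dom$origin[2L], dom$origin[3L]),
               sprintf("SPACING %g %g %g", dom$h, dom$h, dom$h),
               sprintf("POINT_DATA %d", prod(dm))), con)
  uc <- cell_velocity(field)
  writeLines("VECTORS velocity float", con)
  writeLines(sprintf("%g %g %g", full(uc[, 1L]), full(uc[, 2L]), full(uc[, 3L])), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", full(field$p)), con)
  if (!is.null(field$shear_rate)) {
    writeLines(c("SCALARS shear_rate float 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", full(field$shear_rate)), con)
  }
  invisible(path)
}

#' Write a centerline as CSV
#'
#' Columns: `s_mm, x_mm, y_mm, z_mm, kappa_per_mm`.
#'
#' @param path a [centerline_path()]
#' @param file output file
#' @export
write_centerline_csv <- function(path, file) {
  utils::write.csv(data.frame(
    s_mm = path$s, x_mm = path$points[, 1L], y_mm = path$points[, 2L],
    z_mm = path$points[, 3L], kappa_per_mm = path$curvature),
    file, row.names = FALSE)
  invisible(file)
}

#' Read a centerline written by [write_centerline_csv()]
#' @param file CSV file
#' @export
read_centerline_csv <- function(file) {
  d <- utils::read.csv(file)
  centerline_path(cbind(d$x_mm, d$y_mm, d$z_mm))
}

#' Write a contour stack as long-format CSV
#'
#' Columns: `frame_index, vertex_index, x_mm, y_mm`.
#'
#' @param stack a [lumen_contour_stack()]
#' @param file output file
#' @export
write_contours_csv <- function(stack, file) {
  rows <- do.call(rbind, lapply(stack$contours, function(ct)
    data.frame(frame_index = ct$frame_index,
               vertex_index = seq_len(nrow(ct$vertices)),
               x_mm = ct$vertices[, 1L], y_mm = ct$vertices[, 2L])))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read a contour stack from long-format CSV
#' @param file CSV with columns `frame_index, vertex_index, x_mm, y_mm`
#' @param slice_spacing axial spacing in mm (default 1)
#' @export
read_contours_csv <- function(file, slice_spacing = 1.0) {
  d <- utils::read.csv(file)
  contours <- lapply(sort(unique(d$frame_index)), function(i) {
    di <- d[d$frame_index == i, ]
    di <- di[order(di$vertex_index), ]
    lumen_contour(i, cbind(di$x_mm, di$y_mm))
  })
  lumen_contour_stack(contours, slice_spacing)
}

#' Write a contour stack as JSON
#'
#' One object per frame with `frame_index`, `area_cm2` and the vertex
#' coordinate arrays in mm.
#'
#' @param stack a [lumen_contour_stack()]
#' @param file output .json path
#' @export
write_contours_json <- function(stack, file) {
  obj <- list(slice_spacing_mm = stack$slice_spacing,
              contours = lapply(stack$contours, function(ct)
                list(frame_index = ct$frame_index, area_cm2 = ct$area_cm2,
                     x_mm = ct$vertices[, 1L], y_mm = ct$vertices[, 2L])))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write the ground truth of a synthetic pullback as a JSON sidecar
#'
#' @param pullback an `ivus_pullback` from [render_ivus_stack()]
#' @param file output .json path
#' @export
write_truth_json <- function(pullback, file) {
  tr <- pullback$truth
  jsonlite::write_json(list(s_mm = tr$s_mm, radius_mm = tr$radius_mm,
                            area_cm2 = tr$area_cm2,
                            arch_start_frame = tr$arch_start_frame,
                            lead_in_mm = tr$lead_in_mm,
                            arch_length_mm = tr$arch_length_mm),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write patient records as CSV in the cohort-table layout
#'
#' @param records data.frame as produced by [gen_patient_records()] or
#'   [cephalic_cohort()]
#' @param file output .csv path
#' @export
write_patient_records_csv <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE)
  invisible(file)
}

#' Write an image stack as multi-page TIFF
#' @param stack an [image_stack()]
#' @param file output .tif path
#' @export
write_image_stack_tiff <- function(stack, file) {
  tiff::writeTIFF(stack$frames, file)
  invisible(file)
}

#' Read a multi-page TIFF as an image stack
#' @param file .tif path
#' @param pixel_spacing mm per pixel
#' @param frame_spacing mm per frame (pullback) or `NA`
#' @export
read_image_stack_tiff <- function(file, pixel_spacing, frame_spacing = NA_real_) {
  frames <- tiff::readTIFF(file, all = TRUE)
  image_stack(frames, pixel_spacing, frame_spacing)
}

#' Write a per-station geometry table as CSV
#'
#' Columns: `station, s_mm, area_cm2, diameter_cm, region`.
#'
#' @param geom a `vessel_geometry`
#' @param file output file
#' @export
write_station_csv <- function(geom, file) {
  utils::write.csv(data.frame(
    station = seq_along(geom$station_s), s_mm = geom$station_s,
    area_cm2 = geom$station_area, diameter_cm = geom$station_diameter,
    region = geom$region_label), file, row.names = FALSE)
  invisible(file)
}
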