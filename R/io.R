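## Plain-text exchange formats. Surface meshes go out as legacy ASCII VTK
## polydata (readable by ParaView/VTK); masks as ASCII PGM (P2) with a JSON
## sidecar carrying pixel size, section position and the class-code map.
## TIFF is deliberately not used: it is a binary container and the text
## formats round-trip losslessly for integer class rasters.

#' Write a mesh with point data as legacy ASCII VTK polydata
#'
#' @param vertices `n x 3` coordinates, mm.
#' @param triangles `m x 3` 1-based vertex indices.
#' @param point_data named list of per-vertex numeric vectors (e.g.
#'   `list(TAWSS = ..., OSI = ...)`).
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_vtk_polydata <- function(vertices, triangles, point_data = list(),
                               path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "lumen surface with WSS metrics", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(vertices))), con)
  utils::write.table(format(vertices, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(triangles), 4 * nrow(triangles)),
             con)
  utils::write.table(cbind(3L, triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", nrow(vertices)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], trim = TRUE, digits = 9), con)
    }
  }
  invisible(path)
}

#' Write / read a section label mask as ASCII PGM plus JSON sidecar
#'
#' The raster goes to `<path>.pgm` (P2, one integer class code per pixel)
#' and the geometry metadata (pixel size, origin, center, angular reference,
#' lumen contour, class-code map, section id, axial position) to
#' `<path>.json`.
#'
#' @param mask a [section_label_mask()].
#' @param path output path without extension.
#' @return the base `path` invisibly; `read_mask` returns the mask.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "section_label_mask"))
  px <- mask$pixels
  con <- file(paste0(path, ".pgm"), "w")
  writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)),
               sprintf("%d", max(mask_class_codes()))), con)
  utils::write.table(px, con, row.names = FALSE, col.names = FALSE)
  close(con)
  meta <- list(pixel_size_mm = mask$pixel_size, origin_mm = mask$origin,
               center_mm = mask$center,
               angular_reference = mask$angular_reference,
               lumen_contour_mm = unname(as.matrix(mask$lumen_contour)),
               class_codes = as.list(mask_class_codes()),
               section_id = mask$section_id,
               axial_position_mm = mask$axial_position)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(paste0(path, ".pgm"))
  assert_that(lines[1] == "P2", "expected ASCII PGM (P2)")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- scan(text = paste(lines[-(1:3)], collapse = "\n"), quiet = TRUE)
  px <- matrix(as.integer(vals), nrow = dims[2], ncol = dims[1], byrow = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  section_label_mask(px, meta$pixel_size_mm, meta$center_mm,
                     meta$angular_reference,
                     lumen_contour = matrix(unlist(meta$lumen_contour_mm),
                                            ncol = 2),
                     origin = meta$origin_mm, section_id = meta$section_id,
                     axial_position = meta$axial_position_mm)
}

#' Write a centerline as CSV (x, y, z, arclength_mm, segment)
#' @param geometry a `vessel_geometry`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_centerline_csv <- function(geometry, path) {
  d <- data.frame(x_mm = geometry$centerline_points[, 1],
                  y_mm = geometry$centerline_points[, 2],
                  z_mm = geometry$centerline_points[, 3],
                  arclength_mm = geometry$arclength,
                  segment = geometry$segment_labels)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write an `lmm_result` as a two-part CSV (means, then contrasts)
#' @param result an `lmm_result`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_lmm_csv <- function(result, path) {
  est <- data.frame(group = names(result$estimated_means),
                    estimated_mean = as.numeric(result$estimated_means),
                    standard_error = as.numeric(result$standard_errors))
  pw <- result$pairwise
  est$outcome <- result$outcome
  pw$outcome <- result$outcome
  utils::write.csv(merge(est, pw, by = "outcome", all = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}
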