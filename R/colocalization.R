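#' Vessel centerline
#'
#' @param points ordered `n x 3` matrix of centerline coordinates, mm.
#' @return object of class `centerline` with fields `points` and `arclength`
#'   (cumulative, mm).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  assert_that(ncol(points) == 3 && nrow(points) >= 2,
              "centerline needs >= 2 points in 3D")
  seglen <- row_norms(diff(points))
  assert_that(all(seglen > 0), "centerline arclength must strictly increase")
  structure(list(points = points, arclength = c(0, cumsum(seglen))),
            class = "centerline")
}

#' Histology section frame
#'
#' The geometric frame of one histology section: its axial position along
#' the centerline, the in-plane center (the registered centerline point), the
#' section normal, and the angular reference direction defining sector 0.
#'
#' @param section_id,patient_id identifiers.
#' @param axial_position arclength position along the centerline, mm.
#' @param center 3D center point, mm.
#' @param normal unit section normal (the local vessel axis).
#' @param angular_reference unit vector in the section plane marking 0
#'   degrees; sectors advance counterclockwise about `normal`.
#' @return object of class `cross_section_frame`.
#' @export
cross_section_frame <- function(section_id, patient_id, axial_position,
                                center, normal, angular_reference) {
  normal <- normal/sqrt(sum(normal^2))
  angular_reference <- angular_reference/sqrt(sum(angular_reference^2))
  assert_that(abs(sum(normal * angular_reference)) < 1e-8,
              "normal and angular_reference must be orthogonal")
  structure(list(section_id = section_id, patient_id = patient_id,
                 axial_position = axial_position, center = center,
                 normal = normal, angular_reference = angular_reference),
            class = "cross_section_frame")
}

#' Cross-section frames for a generated vessel
#'
#' Builds one [cross_section_frame()] per section plane of a
#' [generate_vessel()] geometry, with the angular reference fixed to the
#' mesh's phi = 0 direction so synthetic WSS and histology share the frame.
#'
#' @param geometry a `vessel_geometry`.
#' @param patient_id identifier stored in every frame.
#' @return list of `cross_section_frame` objects.
#' @export
cross_section_frames <- function(geometry, patient_id = "P1") {
  stopifnot(inherits(geometry, "vessel_geometry"))
  lapply(seq_along(geometry$section_positions), function(i) {
    s <- geometry$section_positions[i]
    k <- which.min(abs(geometry$arclength - s))
    p <- geometry$centerline_points
    # local tangent by central difference on the centerline
    k0 <- max(1, k - 1); k1 <- min(nrow(p), k + 1)
    nrm <- p[k1, ] - p[k0, ]
    nrm <- nrm/sqrt(sum(nrm^2))
    # angular reference: mesh phi=0 direction projected into the plane
    aref <- c(1, 0, 0) - sum(c(1, 0, 0) * nrm) * nrm
    if (sum(aref^2) < 1e-12) aref <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
    aref <- aref/sqrt(sum(aref^2))
    cross_section_frame(section_id = sprintf("%s_S%02d", patient_id, i),
                        patient_id = patient_id, axial_position = s,
                        center = p[k, ], normal = nrm,
                        angular_reference = aref)
  })
}

#' Select vertices in the axial window of a section
#'
#' Projects every vertex to the arclength of its nearest centerline point and
#' selects those within `half_window` (default 0.3 mm, i.e. the -0.3 to
#' +0.3 mm axial averaging window) of the section's axial position.
#'
#' @param metric_map a [metric_map()] (or any object with a `vertices` field).
#' @param cl a [centerline()].
#' @param section a [cross_section_frame()].
#' @param half_window half-width of the axial window, mm.
#' @return integer vector of selected vertex indices (possibly empty; an
#'   empty result is the "no-coverage" condition handled downstream).
#' @export
axial_window_average <- function(metric_map, cl, section, half_window = 0.3) {
  stopifnot(inherits(cl, "centerline"))
  assert_that(half_window > 0, "half_window must be > 0")
  s <- project_to_arclength(metric_map$vertices, cl)
  which(abs(s - section$axial_position) <= half_window)
}

# arclength of the nearest centerline point, per vertex
project_to_arclength <- function(vertices, cl) {
  p <- cl$points
  n <- nrow(vertices)
  idx <- integer(n)
  # chunked nearest-neighbour search to bound memory
  chunk <- 20000L
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    d2 <- outer(rowSums(vertices[st:en, , drop = FALSE]^2), rowSums(p^2), "+") -
      2 * vertices[st:en, , drop = FALSE] %*% t(p)
    idx[st:en] <- max.col(-d2, ties.method = "first")
  }
  cl$arclength[idx]
}

#' Assign points to 45-degree radial sectors
#'
#' Computes the in-plane angle of each point about the section center,
#' measured counterclockwise (about the section normal) from the angular
#' reference, and maps it to `n_bins` half-open sectors
#' `[k * 360/n_bins, (k+1) * 360/n_bins)`, 0-based.
#'
#' @param points `n x 3` matrix, mm.
#' @param section a [cross_section_frame()].
#' @param n_bins number of sectors (8 gives the 45-degree bins).
#' @return integer vector of bin indices in `0:(n_bins-1)`.
#' @export
assign_sectors <- function(points, section, n_bins = 8) {
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  points <- matrix(points, ncol = 3)
  v <- sweep(points, 2, section$center)
  e1 <- section$angular_reference
  e2 <- cross3(section$normal, e1)
  x <- as.vector(v %*% e1)
  y <- as.vector(v %*% e2)
  if (any(x == 0 & y == 0)) {
    stop_input("point coincides with section center; sector undefined")
  }
  theta <- atan2(y, x) %% (2 * pi)
  bin <- floor(theta/(2 * pi/n_bins))
  # guard against theta == 2*pi from rounding
  as.integer(pmin(bin, n_bins - 1))
}

#' Per-section, per-sector WSS averages
#'
#' Applies the axial window and sector assignment to a metric map and
#' averages TAWSS and OSI per sector. Sectors with no vertices in the window
#' are flagged `no-coverage`.
#'
#' @param map a [metric_map()].
#' @param cl a [centerline()].
#' @param sections list of [cross_section_frame()]s.
#' @param n_bins sectors per section.
#' @param half_window axial half-window, mm.
#' @param area_weighted if `TRUE`, vertices are weighted by one-ring triangle
#'   area (requires `triangles` attribute); default is the unweighted vertex
#'   mean.
#' @param triangles optional triangle index matrix for area weighting.
#' @return data.frame with one row per (section, bin): `patient_id`,
#'   `section_id`, `bin_index`, `tawss_mean`, `osi_mean`, `n_vertices`,
#'   `no_coverage`.
#' @export
wss_bin_means <- function(map, cl, sections, n_bins = 8, half_window = 0.3,
                          area_weighted = FALSE, triangles = NULL) {
  w <- NULL
  if (area_weighted) {
    assert_that(!is.null(triangles), "area weighting needs triangles")
    w <- vertex_areas(map$vertices, triangles)
  }
  rows <- lapply(sections, function(sec) {
    sel <- axial_window_average(map, cl, sec, half_window)
    out <- data.frame(patient_id = rep(sec$patient_id, n_bins),
                      section_id = sec$section_id,
                      bin_index = 0:(n_bins - 1),
                      tawss_mean = NA_real_, osi_mean = NA_real_,
                      n_vertices = 0L, no_coverage = TRUE,
                      stringsAsFactors = FALSE)
    if (length(sel) == 0) return(out)
    bins <- assign_sectors(map$vertices[sel, , drop = FALSE], sec, n_bins)
    for (k in 0:(n_bins - 1)) {
      i <- sel[bins == k]
      if (length(i) == 0) next
      wk <- if (is.null(w)) rep(1, length(i)) else w[i]
      out$tawss_mean[k + 1] <- sum(map$tawss[i] * wk)/sum(wk)
      out$osi_mean[k + 1] <- sum(map$osi[i] * wk)/sum(wk)
      out$n_vertices[k + 1] <- length(i)
      out$no_coverage[k + 1] <- FALSE
    }
    out
  })
  do.call(rbind, rows)
}

# one-ring triangle area per vertex (third of each incident triangle)
vertex_areas <- function(vertices, triangles) {
  v <- vertices; tr <- triangles
  a <- v[tr[, 2], ] - v[tr[, 1], ]
  b <- v[tr[, 3], ] - v[tr[, 1], ]
  area <- 0.5 * row_norms(cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1]))
  w <- numeric(nrow(v))
  for (j in 1:3) {
    acc <- rowsum(area/3, group = tr[, j])
    i <- as.integer(rownames(acc))
    w[i] <- w[i] + acc[, 1]
  }
  w
}

#' Join WSS sector means with histology sector measures
#'
#' Produces the analysis table with one row per (section, sector): the
#' `BinRecord` layout written by the pipeline. Exclusion flags are merged
#' with precedence no-coverage > histology-artifact > registration-mismatch.
#'
#' @param wss_bins output of [wss_bin_means()].
#' @param plaque_bins data.frame of per-sector plaque measures with columns
#'   `section_id`, `bin_index`, `nc_area`, `fibrin_area`, `macrophage_area`,
#'   `cap_thickness`, `intima_area`, and optionally `excluded`/`reason`.
#' @param registration_mismatch optional data.frame (`section_id`,
#'   `bin_index`) of bins failing lumen-registration checks.
#' @return data.frame of bin records with columns `patient_id`, `section_id`,
#'   `bin_index`, `tawss_mean`, `osi_mean`, `nc_area_mm2`, `fibrin_area_mm2`,
#'   `macrophage_area_mm2`, `cap_thickness_mm`, `intima_area_mm2`,
#'   `included`, `exclusion_reason`.
#' @export
build_bin_table <- function(wss_bins, plaque_bins,
                            registration_mismatch = NULL) {
  miss <- setdiff(unique(wss_bins$section_id), unique(plaque_bins$section_id))
  if (length(miss) > 0) {
    stop_input("section_id mismatch between WSS and histology inputs: %s",
               paste(miss, collapse = ", "))
  }
  key <- function(d) paste(d$section_id, d$bin_index)
  m <- match(key(wss_bins), key(plaque_bins))
  assert_that(!anyNA(m), "histology bins missing for some WSS bins")
  pb <- plaque_bins[m, ]
  rec <- data.frame(patient_id = wss_bins$patient_id,
                    section_id = wss_bins$section_id,
                    bin_index = wss_bins$bin_index,
                    tawss_mean = wss_bins$tawss_mean,
                    osi_mean = wss_bins$osi_mean,
                    nc_area_mm2 = pb$nc_area,
                    fibrin_area_mm2 = pb$fibrin_area,
                    macrophage_area_mm2 = pb$macrophage_area,
                    cap_thickness_mm = pb$cap_thickness,
                    intima_area_mm2 = pb$intima_area,
                    included = TRUE,
                    exclusion_reason = "",
                    stringsAsFactors = FALSE)
  hit <- function(tbl) !is.na(match(key(rec), key(tbl)))
  if (!is.null(registration_mismatch) && nrow(registration_mismatch) > 0) {
    i <- hit(registration_mismatch)
    rec$included[i] <- FALSE
    rec$exclusion_reason[i] <- "registration-mismatch"
  }
  if (!is.null(plaque_bins$excluded)) {
    i <- pb$excluded %in% TRUE
    rec$included[i] <- FALSE
    rec$exclusion_reason[i] <- pb$reason[i]
  }
  i <- wss_bins$no_coverage
  rec$included[i] <- FALSE
  rec$exclusion_reason[i] <- "no-coverage"
  rec
}
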