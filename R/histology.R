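#' Class codes used in section label masks
#'
#' Integer codes of the class-coded histology raster: `background` (0,
#' includes the lumen interior), `intima` (1, plaque/vessel-wall tissue not
#' otherwise classified), `nc` (2, necrotic core), `fibrin` (3, fibrin
#' deposits nested inside the necrotic-core complex, so a fibrin pixel counts
#' toward both fibrin and NC area), `macrophage` (4, CD68-positive tissue
#' outside NC/artifact), `artifact` (5, histological processing artifact).
#'
#' @return named integer vector of class codes.
#' @export
mask_class_codes <- function() {
  c(background = 0L, intima = 1L, nc = 2L, fibrin = 3L,
    macrophage = 4L, artifact = 5L)
}

#' Class-coded histology section mask
#'
#' @param pixels integer matrix of class codes (rows = y, cols = x).
#' @param pixel_size pixel edge length, mm.
#' @param center 2D section-plane coordinates of the registered centerline
#'   point, mm.
#' @param angular_reference 2D unit vector marking sector 0; sectors advance
#'   counterclockwise.
#' @param lumen_contour closed `n x 2` polygon of the lumen boundary, mm
#'   (first point not repeated).
#' @param origin mm coordinates of the center of pixel `[1, 1]`
#'   (x = columns, y = rows).
#' @param cd68 optional logical matrix of CD68 positivity (macrophage stain);
#'   defaults to `pixels == macrophage code`.
#' @param section_id,axial_position metadata.
#' @return object of class `section_label_mask`.
#' @export
section_label_mask <- function(pixels, pixel_size, center, angular_reference,
                               lumen_contour, origin = c(0, 0), cd68 = NULL,
                               section_id = "S01", axial_position = NA_real_) {
  pixels <- as.matrix(pixels)
  assert_that(pixel_size > 0, "pixel_size must be > 0")
  assert_that(all(pixels %in% mask_class_codes()),
              "pixels contain codes outside the declared class map")
  angular_reference <- angular_reference/sqrt(sum(angular_reference^2))
  if (is.null(cd68)) cd68 <- pixels == mask_class_codes()[["macrophage"]]
  assert_that(all(dim(cd68) == dim(pixels)), "cd68 must match pixel grid")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 center = as.numeric(center),
                 angular_reference = as.numeric(angular_reference),
                 lumen_contour = as.matrix(lumen_contour),
                 origin = as.numeric(origin), cd68 = cd68,
                 section_id = section_id, axial_position = axial_position),
            class = "section_label_mask")
}

# pixel-center coordinates and polar frame about mask$center
mask_pixel_frame <- function(mask) {
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  x <- mask$origin[1] + (seq_len(nc) - 1) * mask$pixel_size
  y <- mask$origin[2] + (seq_len(nr) - 1) * mask$pixel_size
  X <- matrix(rep(x, each = nr), nr, nc)
  Y <- matrix(rep(y, nc), nr, nc)
  dx <- X - mask$center[1]
  dy <- Y - mask$center[2]
  e1 <- mask$angular_reference
  e2 <- c(-e1[2], e1[1])   # counterclockwise orthogonal
  u <- dx * e1[1] + dy * e1[2]
  v <- dx * e2[1] + dy * e2[2]
  list(r = sqrt(dx^2 + dy^2), theta = atan2(v, u) %% (2 * pi))
}

# 0-based sector index per pixel
mask_sector_index <- function(mask, n_bins = 8) {
  fr <- mask_pixel_frame(mask)
  idx <- floor(fr$theta/(2 * pi/n_bins))
  matrix(as.integer(pmin(idx, n_bins - 1)), nrow(mask$pixels))
}

#' Plaque component areas per radial sector
#'
#' Counts class-coded pixels per 45-degree sector about the mask center and
#' converts to areas (`count * pixel_size^2`). Necrotic-core area counts both
#' `nc` and nested `fibrin` pixels; fibrin area counts `fibrin` pixels;
#' macrophage area counts CD68-positive pixels excluding those lying on NC,
#' fibrin, artifact or background pixels (artifact and NC tissue are removed
#' from the CD68-positive selection); intima area is all tissue pixels
#' (intima + NC + fibrin + macrophage). The artifact fraction is the share of
#' artifact pixels among all sector tissue-or-artifact pixels.
#'
#' @param mask a [section_label_mask()].
#' @param n_bins number of sectors.
#' @return data.frame with one row per sector: `section_id`, `bin_index`,
#'   `nc_area`, `fibrin_area`, `macrophage_area`, `intima_area`,
#'   `artifact_fraction` (areas in mm2).
#' @export
component_area_per_bin <- function(mask, n_bins = 8) {
  stopifnot(inherits(mask, "section_label_mask"))
  cc <- mask_class_codes()
  px <- mask$pixels
  tissue <- px %in% cc[c("intima", "nc", "fibrin", "macrophage")]
  if (!any(tissue)) stop_input("empty-section error: mask has no intima pixels")
  sec <- mask_sector_index(mask, n_bins)
  a1 <- mask$pixel_size^2
  cnt <- function(which_mat) {
    tab <- tabulate(sec[which_mat] + 1L, nbins = n_bins)
    tab
  }
  nc_n <- cnt(px == cc[["nc"]] | px == cc[["fibrin"]])
  fib_n <- cnt(px == cc[["fibrin"]])
  mac_ok <- mask$cd68 &
    (px == cc[["intima"]] | px == cc[["macrophage"]])
  mac_n <- cnt(mac_ok)
  int_n <- cnt(matrix(tissue, nrow(px)))
  art_n <- cnt(px == cc[["artifact"]])
  denom <- int_n + art_n
  data.frame(section_id = mask$section_id, bin_index = 0:(n_bins - 1),
             nc_area = nc_n * a1, fibrin_area = fib_n * a1,
             macrophage_area = mac_n * a1, intima_area = int_n * a1,
             artifact_fraction = ifelse(denom > 0, art_n/denom, 0),
             stringsAsFactors = FALSE)
}

#' Fibrous-cap thickness per radial sector
#'
#' Casts rays from the mask center at `ray_step_deg` increments. Along each
#' ray the cap thickness is the distance from the lumen-contour crossing to
#' the first necrotic-core pixel (codes `nc` or `fibrin`). The per-sector
#' value is the minimum over rays that hit NC; sectors whose rays never hit
#' NC get `NA` (defined absence: no cap to measure).
#'
#' @param mask a [section_label_mask()].
#' @param n_bins number of sectors.
#' @param ray_step_deg angular ray spacing, degrees.
#' @return numeric vector of length `n_bins` (mm, `NA` where no NC).
#' @export
cap_thickness_per_bin <- function(mask, n_bins = 8, ray_step_deg = 1) {
  stopifnot(inherits(mask, "section_label_mask"))
  cc <- mask_class_codes()
  px <- mask$pixels
  nr <- nrow(px); ncp <- ncol(px)
  ps <- mask$pixel_size
  e1 <- mask$angular_reference
  e2 <- c(-e1[2], e1[1])
  r_max <- ps * sqrt(nr^2 + ncp^2)
  step <- ps/3
  rr <- seq(step, r_max, by = step)
  out <- rep(NA_real_, n_bins)
  angles <- seq(0, 360 - ray_step_deg, by = ray_step_deg)
  for (ang in angles) {
    th <- ang * pi/180
    dirv <- cos(th) * e1 + sin(th) * e2
    lum_r <- ray_polygon_distance(mask$center, dirv, mask$lumen_contour)
    if (!is.finite(lum_r)) next
    xs <- mask$center[1] + rr * dirv[1]
    ys <- mask$center[2] + rr * dirv[2]
    ci <- round((xs - mask$origin[1])/ps) + 1L
    ri <- round((ys - mask$origin[2])/ps) + 1L
    ok <- ci >= 1 & ci <= ncp & ri >= 1 & ri <= nr & rr >= lum_r
    if (!any(ok)) next
    code <- px[cbind(ri[ok], ci[ok])]
    hit <- which(code == cc[["nc"]] | code == cc[["fibrin"]])
    if (length(hit) == 0) next
    thick <- max(rr[ok][hit[1]] - lum_r, 0)
    b <- floor((th %% (2 * pi))/(2 * pi/n_bins)) + 1
    b <- min(b, n_bins)
    if (is.na(out[b]) || thick < out[b]) out[b] <- thick
  }
  out
}

# distance from point along direction to the first crossing of a closed
# polygon (mm); Inf when the ray misses
ray_polygon_distance <- function(p0, dirv, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), ]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  det <- dirv[1] * (-ey) - dirv[2] * (-ex)
  wx <- a[, 1] - p0[1]; wy <- a[, 2] - p0[2]
  tt <- (wx * (-ey) - wy * (-ex))/det
  ss <- (dirv[1] * wy - dirv[2] * wx)/det
  ok <- is.finite(tt) & tt > 0 & ss >= 0 & ss <= 1
  if (!any(ok)) return(Inf)
  min(tt[ok])
}

#' Flag sectors exceeding the artifact threshold
#'
#' @param measures data.frame from [component_area_per_bin()] (must contain
#'   `artifact_fraction`).
#' @param artifact_threshold maximum tolerated artifact fraction; sectors
#'   above it are flagged excluded with reason `histology-artifact`.
#' @return `measures` with logical `excluded` and character `reason` columns
#'   added (existing flags are preserved and only upgraded).
#' @export
exclude_bins <- function(measures, artifact_threshold = 0) {
  assert_that(artifact_threshold >= 0 && artifact_threshold <= 1,
              "artifact_threshold must lie in [0, 1]")
  if (is.null(measures$excluded)) {
    measures$excluded <- FALSE
    measures$reason <- ""
  }
  i <- measures$artifact_fraction > artifact_threshold & !measures$excluded
  measures$excluded[i] <- TRUE
  measures$reason[i] <- "histology-artifact"
  measures
}
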