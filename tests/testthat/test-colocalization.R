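make_frame <- function(aref = c(1, 0, 0), normal = c(0, 0, 1),
                       center = c(0, 0, 0), pos = 0) {
  cross_section_frame("S01", "P01", axial_position = pos, center = center,
                      normal = normal, angular_reference = aref)
}

test_that("sector assignment uses half-open 45-degree bins, counterclockwise", {
  fr <- make_frame()
  ang <- c(0, 44.999, 45, 90, 315, 359.999) * pi/180
  pts <- cbind(cos(ang), sin(ang), 0)
  expect_identical(assign_sectors(pts, fr), c(0L, 0L, 1L, 2L, 7L, 7L))

  # one point per bin at the sector midpoints
  mid <- (22.5 + 45 * 0:7) * pi/180
  pts <- cbind(cos(mid), sin(mid), 0)
  expect_identical(assign_sectors(pts, fr), 0:7)

  expect_error(assign_sectors(matrix(c(0, 0, 0), 1), fr), "center")
})

test_that("sectors partition random point clouds", {
  fr <- make_frame()
  set.seed(12)
  for (rep in 1:5) {
    pts <- cbind(stats::rnorm(200), stats::rnorm(200), stats::rnorm(200))
    keep <- rowSums(pts[, 1:2]^2) > 1e-6
    b <- assign_sectors(pts[keep, ], fr)
    expect_true(all(b >= 0 & b <= 7))       # all points in exactly one bin
    expect_length(b, sum(keep))
  }
})

test_that("axial window selects symmetric neighbourhoods", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 3,
                         n_circ = 12)
  cl <- centerline(geo$centerline_points)
  frames <- cross_section_frames(geo, "P01")
  wf <- flow_waveform(rep(5, 16), 1)
  m <- metric_map(generate_wss_field(geo, wf, n_time = 16))

  sel <- axial_window_average(m, cl, frames[[1]], half_window = 0.3)
  expect_gt(length(sel), 0)
  s <- geo$arclength[geo$ring_index[sel]]
  expect_true(all(abs(s - frames[[1]]$axial_position) <= 0.3))

  # constant field: windowed mean equals the field value
  expect_equal(mean(m$tawss[sel]), m$tawss[1], tolerance = 1e-12)

  # linear-in-arclength field: symmetric window recovers the midpoint value
  m2 <- m
  m2$tawss <- geo$arclength[geo$ring_index]
  bins <- wss_bin_means(m2, cl, frames[1])
  expect_equal(bins$tawss_mean, rep(frames[[1]]$axial_position, 8),
               tolerance = geo$arclength[2])

  # a section beyond the mesh is a no-coverage exclusion
  far <- make_frame(pos = 1e4)
  far$patient_id <- "P01"; far$section_id <- "FAR"
  bins_far <- wss_bin_means(m, cl, list(far))
  expect_true(all(bins_far$no_coverage))
})

test_that("bin table bookkeeping: n_sections x 8 records, joined exclusions", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 3,
                         n_circ = 12)
  cl <- centerline(geo$centerline_points)
  frames <- cross_section_frames(geo, "P01")
  wf <- flow_waveform(rep(5, 16), 1)
  m <- metric_map(generate_wss_field(geo, wf, n_time = 16))
  wb <- wss_bin_means(m, cl, frames)
  expect_equal(nrow(wb), 3 * 8)

  plaque <- data.frame(section_id = wb$section_id, bin_index = wb$bin_index,
                       nc_area = 1, fibrin_area = 0.2, macrophage_area = 0.1,
                       cap_thickness = 0.3, intima_area = 5,
                       artifact_fraction = 0)
  plaque$excluded <- FALSE; plaque$reason <- ""
  plaque$excluded[1] <- TRUE; plaque$reason[1] <- "histology-artifact"
  mism <- data.frame(section_id = wb$section_id[2],
                     bin_index = wb$bin_index[2])
  rec <- build_bin_table(wb, plaque, registration_mismatch = mism)
  expect_equal(nrow(rec), 24)
  expect_equal(sum(!rec$included), 2)
  expect_setequal(rec$exclusion_reason[!rec$included],
                  c("histology-artifact", "registration-mismatch"))

  bad <- plaque; bad$section_id <- paste0("X", bad$section_id)
  expect_error(build_bin_table(wb, bad), "mismatch")
})

test_that("binning is rotation-equivariant", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 2,
                         n_circ = 24)
  cl <- centerline(geo$centerline_points)
  frames <- cross_section_frames(geo, "P01")
  # turn every angular reference off the mesh vertex angles so no vertex
  # sits exactly on a sector boundary (boundary pixels may legitimately
  # flip bins under floating-point rotation)
  frames <- lapply(frames, function(fr) {
    e2 <- shearplaque:::cross3(fr$normal, fr$angular_reference)
    d <- 0.123
    fr$angular_reference <- cos(d) * fr$angular_reference + sin(d) * e2
    fr
  })
  wf <- random_waveform(31)
  m <- metric_map(generate_wss_field(geo, wf, n_time = 8))
  # break the rotational symmetry with an angle-dependent field
  m$tawss <- m$tawss * (1 + 0.5 * cos(atan2(m$vertices[, 2], m$vertices[, 1])))
  base <- wss_bin_means(m, cl, frames)

  th <- 73 * pi/180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  m_rot <- m
  m_rot$vertices <- m$vertices %*% t(Rz)
  frames_rot <- lapply(frames, function(fr) {
    fr$center <- as.vector(Rz %*% fr$center)
    fr$normal <- as.vector(Rz %*% fr$normal)
    fr$angular_reference <- as.vector(Rz %*% fr$angular_reference)
    fr
  })
  cl_rot <- centerline(geo$centerline_points %*% t(Rz))
  rot <- wss_bin_means(m_rot, cl_rot, frames_rot)
  expect_equal(rot$tawss_mean, base$tawss_mean, tolerance = 1e-9)
  expect_equal(rot$osi_mean, base$osi_mean, tolerance = 1e-9)
})
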