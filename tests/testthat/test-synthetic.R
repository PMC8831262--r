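test_that("vessel radius profiles follow the construction", {
  g0 <- generate_vessel("straight", base_radius = 3, n_sections = 4)
  expect_true(all(g0$radius_profile == 3))
  expect_silent(validate_vessel_geometry(g0))
  # flow extensions: five local radii on each side of the core
  core <- range(g0$arclength[g0$segment_labels == "CCA"])
  expect_equal(core[1], 5 * 3, tolerance = g0$arclength[2])

  g1 <- generate_vessel("stenotic", base_radius = 3, stenosis_degree = 0.5,
                        n_sections = 4)
  expect_equal(min(g1$radius_profile), 1.5, tolerance = 1e-9)

  # throat/inlet area ratio is (1 - degree)^2 by the closed form
  g2 <- generate_vessel("stenotic", base_radius = 3, stenosis_degree = 0.7,
                        n_sections = 4)
  ratio <- (min(g2$radius_profile)/g2$base_radius)^2
  expect_equal(ratio, 0.09, tolerance = 1e-9)

  expect_error(generate_vessel("stenotic", stenosis_degree = 1),
               "invalid geometry")
})

test_that("bifurcation geometry carries all segment labels and validates", {
  g <- generate_vessel("bifurcation", base_radius = 3, stenosis_degree = 0.4,
                       n_sections = 6, n_circ = 16)
  expect_setequal(unique(g$segment_labels),
                  c("extension", "CCA", "ICA", "ECA"))
  expect_silent(validate_vessel_geometry(g))
  expect_length(g$section_positions, 6)
})

test_that("steady flow gives the Poiseuille magnitude on every vertex", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 2,
                         n_circ = 12)
  wf <- flow_waveform(rep(5, 16), period = 1)
  fld <- generate_wss_field(geo, wf, n_time = 16)
  mag <- sqrt(fld$wss[, , 1]^2 + fld$wss[, , 2]^2 + fld$wss[, , 3]^2)
  expect_equal(max(abs(mag - 4 * 0.0035 * 5e-6/(pi * 27e-9))), 0,
               tolerance = 1e-9)
})

test_that("straight-tube pulsatile field equals the Womersley oracle", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 2,
                         n_circ = 12)
  wf <- random_waveform(3)
  fld <- generate_wss_field(geo, wf, n_time = 16)
  w <- womersley_wall_shear(wf, 3, n_time = 16)
  # every vertex's axial component reproduces the analytic series
  for (v in c(1, 57, nrow(fld$vertices))) {
    expect_equal(fld$wss[v, , 3], w$wall_shear_series,
                 tolerance = 1e-6)
  }
})

test_that("stenotic throat shear follows the quasi-steady cube law", {
  geo <- generate_vessel("stenotic", base_radius = 3, stenosis_degree = 0.5,
                         n_sections = 4, n_circ = 12)
  wf <- flow_waveform(rep(5, 16), period = 1)
  fld <- generate_wss_field(geo, wf, n_time = 16, recirc_strength = 0)
  mag <- sqrt(fld$wss[, , 1]^2 + fld$wss[, , 2]^2 + fld$wss[, , 3]^2)
  throat_ring <- which.min(geo$radius_profile)
  vthroat <- which(geo$ring_index == throat_ring)[1]
  vin <- 1
  expect_equal(mean(mag[vthroat, ])/mean(mag[vin, ]), (3/1.5)^3,
               tolerance = 1e-6)
})

test_that("recirculation zone downstream of the throat raises OSI", {
  geo <- generate_vessel("stenotic", base_radius = 3, stenosis_degree = 0.6,
                         n_sections = 4, n_circ = 12)
  wf <- random_waveform(9)
  fld <- generate_wss_field(geo, wf, n_time = 32, recirc_strength = 1.5)
  m <- metric_map(fld)
  s <- geo$arclength[geo$ring_index]
  th <- geo$throat_arclength
  down <- s > th & s <= th + geo$stenosis_width/2
  up <- s < th - geo$stenosis_width
  expect_gt(mean(m$osi[down]), mean(m$osi[up]) + 0.1)
})

test_that("WSS vectors are tangent to the surface", {
  geo <- generate_vessel("stenotic", base_radius = 3, stenosis_degree = 0.5,
                         n_sections = 4, n_circ = 12)
  wf <- random_waveform(4)
  fld <- generate_wss_field(geo, wf, n_time = 8)
  # outward surface normal for the revolved profile r = R(z) is
  # (radial - R'(z) * axial)/norm; R'(z) estimated by the same central
  # difference resolution as the mesh rings
  cl <- geo$centerline_points[geo$ring_index, ]
  radial <- (fld$vertices - cl)
  radial <- radial/sqrt(rowSums(radial^2))
  v1 <- fld$wss[, 1, ]
  nring <- nrow(geo$centerline_points)
  i0 <- pmax(seq_len(nring) - 1, 1); i1 <- pmin(seq_len(nring) + 1, nring)
  drds <- (geo$radius_profile[i1] - geo$radius_profile[i0])/
    (geo$arclength[i1] - geo$arclength[i0])
  dr <- drds[geo$ring_index]
  axial <- matrix(rep(c(0, 0, 1), each = nrow(v1)), ncol = 3)
  normal <- radial - dr * axial
  normal <- normal/sqrt(rowSums(normal^2))
  dots <- abs(rowSums(v1 * normal))/pmax(sqrt(rowSums(v1^2)), 1e-12)
  expect_lt(max(dots), 1e-9)
})

test_that("zero-area triangles raise a mesh-quality error", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 2,
                         n_circ = 12)
  geo$vertices[2, ] <- geo$vertices[1, ]   # collapse one edge
  wf <- flow_waveform(rep(5, 16), 1)
  expect_error(generate_wss_field(geo, wf), "mesh-quality")
})

test_that("noise-free masks realize the programmed areas to pixel precision", {
  effects <- list(
    nc = effect_spec("nc", "tawss_tertile", c(1, 1, 2)),
    macrophage = effect_spec("macrophage", "osi_tertile", c(0.8, 0.6, 0.4)))
  targets <- data.frame(nc = rep(c(1, 2), 4), fibrin = 0,
                        macrophage = rep(0.6, 8), cap = 0.3)
  gm <- generate_section_mask(3, targets, pixel_size = 0.05)
  meas <- component_area_per_bin(gm$mask)
  px <- 0.05^2
  expect_true(all(abs(meas$nc_area - targets$nc) <= px + 1e-12))
  expect_true(all(abs(meas$macrophage_area - targets$macrophage) <= px + 1e-12))
  # measured areas equal the generator's recorded realization exactly
  expect_equal(meas$nc_area, gm$realized$nc, tolerance = 1e-12)
  expect_equal(meas$macrophage_area, gm$realized$macrophage, tolerance = 1e-12)
})

test_that("over-large component targets are capped with a warning", {
  targets <- data.frame(nc = c(1e3, rep(0.5, 7)), fibrin = 0,
                        macrophage = 0, cap = 0.3)
  expect_warning(gm <- generate_section_mask(3, targets), "capped")
  expect_true(gm$realized$capped[1])
})

test_that("mask generation is deterministic under a fixed seed", {
  geo <- generate_vessel("straight", base_radius = 3, n_sections = 2,
                         n_circ = 12)
  frames <- cross_section_frames(geo, "P01")
  bt <- data.frame(section_id = rep(sapply(frames, `[[`, "section_id"),
                                    each = 8),
                   bin_index = rep(0:7, 2),
                   tawss_tertile = "mid", osi_tertile = "low")
  eff <- default_effects()
  ic <- c(nc = 0.1, fibrin = 0, macrophage = -0.05, cap = 0)
  h1 <- generate_histology_sections(geo, frames, bt, eff, ic, seed = 7)
  h2 <- generate_histology_sections(geo, frames, bt, eff, ic, seed = 7)
  expect_identical(h1$masks[[1]]$pixels, h2$masks[[1]]$pixels)
  expect_identical(h1$truth, h2$truth)
})

test_that("study counting and determinism contracts hold", {
  s1 <- generate_study(n_patients = 2, sections_per_patient = 3, seed = 11,
                       rasterize = FALSE)
  expect_equal(nrow(s1$wss_bins), 2 * 3 * 8)
  expect_equal(length(unique(s1$wss_bins$section_id)), 6)
  s2 <- generate_study(n_patients = 2, sections_per_patient = 3, seed = 11,
                       rasterize = FALSE)
  expect_identical(study_bin_table(s1), study_bin_table(s2))
  expect_error(generate_study(n_patients = 1), "configuration error")
})

test_that("small rasterized study runs end-to-end with finite outputs", {
  study <- generate_study(n_patients = 2, sections_per_patient = 3,
                          seed = 23, n_circ = 24)
  rec <- study_bin_table(study, measure_cap = FALSE)
  expect_equal(nrow(rec), 48)
  inc <- rec[rec$included, ]
  expect_true(all(is.finite(inc$tawss_mean)))
  expect_true(all(is.finite(inc$nc_area_mm2)))
  expect_true(all(inc$nc_area_mm2 >= 0))
  # ground-truth closure: measured areas match the recorded realization
  tr <- study$truth
  key_r <- paste(rec$section_id, rec$bin_index)
  key_t <- paste(tr$section_id, tr$bin_index)
  m <- match(key_r, key_t)
  expect_true(all(abs(rec$nc_area_mm2 - tr$nc[m]) <= 1e-9))
  expect_true(all(abs(rec$macrophage_area_mm2 - tr$macrophage[m]) <= 1e-9))
})
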