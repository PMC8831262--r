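#' Effect specification for synthetic plaque composition
#'
#' Encodes how a plaque component responds to the local WSS environment in
#' synthetic studies: a mean outcome per tertile of the driving metric, a
#' per-patient random-intercept standard deviation, and a residual (within
#' patient, between bin) standard deviation. Areas are in mm2, cap thickness
#' in mm.
#'
#' @param component one of `"nc"`, `"fibrin"`, `"macrophage"`, `"cap"`.
#' @param driver `"tawss_tertile"` or `"osi_tertile"`.
#' @param group_means numeric length-3 vector of means for (low, mid, high).
#' @param patient_sd random-intercept SD (>= 0).
#' @param residual_sd residual SD (>= 0).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(component = c("nc", "fibrin", "macrophage", "cap"),
                        driver = c("tawss_tertile", "osi_tertile"),
                        group_means, patient_sd = 0, residual_sd = 0) {
  component <- match.arg(component)
  driver <- match.arg(driver)
  assert_that(length(group_means) == 3 && all(is.finite(group_means)),
              "group_means must be 3 finite values (low, mid, high)")
  assert_that(patient_sd >= 0 && residual_sd >= 0, "sd values must be >= 0")
  structure(list(component = component, driver = driver,
                 group_means = stats::setNames(as.numeric(group_means),
                                               c("low", "mid", "high")),
                 patient_sd = patient_sd, residual_sd = residual_sd),
            class = "effect_spec")
}

#' Default synthetic effect structure
#'
#' Mirrors the qualitative findings the statistics layer should detect:
#' necrotic core and macrophage area increase with TAWSS tertile and with
#' *decreasing* OSI respectively, fibrin is null, and cap thickness is
#' largest at low OSI. Magnitudes are mm2-scale plaque areas with moderate
#' between-patient and residual noise.
#'
#' @return named list of [effect_spec()]s.
#' @export
default_effects <- function() {
  list(
    nc = effect_spec("nc", "tawss_tertile", c(1.0, 1.2, 2.0),
                     patient_sd = 0.3, residual_sd = 0.5),
    fibrin = effect_spec("fibrin", "tawss_tertile", c(0.4, 0.4, 0.4),
                         patient_sd = 0.15, residual_sd = 0.25),
    macrophage = effect_spec("macrophage", "osi_tertile", c(0.9, 0.7, 0.5),
                             patient_sd = 0.2, residual_sd = 0.3),
    cap = effect_spec("cap", "osi_tertile", c(0.40, 0.30, 0.25),
                      patient_sd = 0.05, residual_sd = 0.08)
  )
}

# per-patient random intercepts, one per effect, N(0, patient_sd)
draw_patient_intercepts <- function(effects, n_patients, seed) {
  set.seed(derive_seed(seed, 101))
  out <- sapply(effects, function(e) stats::rnorm(n_patients, 0, e$patient_sd))
  out <- matrix(out, nrow = n_patients,
                dimnames = list(NULL, names(effects)))
  out
}

# Draw per-bin component outcomes: group mean of the driving tertile plus
# patient intercept plus residual noise, clipped at zero. `tertiles` is a
# data.frame with tawss_tertile and osi_tertile columns; `intercepts` a named
# numeric vector for this patient.
simulate_bin_outcomes <- function(tertiles, effects, intercepts) {
  n <- nrow(tertiles)
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(effects)) {
    e <- effects[[nm]]
    lab <- as.character(tertiles[[e$driver]])
    mu <- e$group_means[lab] + intercepts[[nm]]
    val <- mu + stats::rnorm(n, 0, e$residual_sd)
    out[[nm]] <- pmax(val, 0)
  }
  out
}

#' Synthetic pulsatile WSS field on a vessel surface
#'
#' Straight (constant-radius) rings carry the exact analytic Womersley wall
#' shear for the local radius, so ground truth is analytic. Rings inside a
#' stenosis carry the quasi-steady Poiseuille scaling
#' `tau(t) * (R_plateau/R(z))^3` of the plateau-segment series, and rings in
#' a configurable recirculation zone downstream of the throat are given an
#' attenuated forward component plus a reversing sinusoid, which creates the
#' high-OSI pocket expected downstream of a stenosis. Vectors point along
#' the local surface tangent in the axial direction.
#'
#' @param geometry a [generate_vessel()] result.
#' @param waveform a [flow_waveform()] (inflow, ml/s).
#' @param fluid a [fluid_properties()].
#' @param n_time time samples per cycle.
#' @param n_harmonics Womersley harmonics retained.
#' @param recirc_strength amplitude of the reversing component, as a
#'   multiple of the plateau TAWSS (0 disables the recirculation zone).
#' @param recirc_length axial length of the recirculation zone, mm
#'   (default: half the stenosis width).
#' @return a [surface_wss_series()] over the mesh vertices.
#' @export
generate_wss_field <- function(geometry, waveform,
                               fluid = fluid_properties(), n_time = 16,
                               n_harmonics = 8, recirc_strength = 1.5,
                               recirc_length = NULL) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  validate_vessel_geometry(geometry)
  T <- waveform$period
  times <- (seq_len(n_time) - 1) * T/n_time
  nrings <- nrow(geometry$centerline_points)
  rad <- geometry$radius_profile
  plateau <- geometry$plateau_radius
  if (is.null(plateau)) plateau <- rep(max(rad), nrings)

  # exact analytic series per unique plateau radius
  base_series <- new.env()
  series_for <- function(R) {
    key <- sprintf("%.9f", R)
    if (is.null(base_series[[key]])) {
      w <- womersley_wall_shear(waveform, R, fluid, n_time = n_time,
                                n_harmonics = n_harmonics, n_radial = 3)
      base_series[[key]] <- w$wall_shear_series
    }
    base_series[[key]]
  }

  # per-ring signed axial wall-shear series [nrings x n_time]
  tau_ring <- matrix(0, nrings, n_time)
  straightish <- abs(rad - plateau) < 1e-9
  for (i in seq_len(nrings)) {
    base <- series_for(plateau[i])
    tau_ring[i, ] <- if (straightish[i]) base else base * (plateau[i]/rad[i])^3
  }
  if (!is.na(geometry$throat_arclength) && recirc_strength > 0) {
    if (is.null(recirc_length)) recirc_length <- geometry$stenosis_width/2
    s <- geometry$arclength
    zone <- s > geometry$throat_arclength &
      s <= geometry$throat_arclength + recirc_length
    if (any(zone)) {
      amp <- recirc_strength * mean(abs(series_for(plateau[which(zone)[1]])))
      osc <- -amp * sin(2 * pi * times/T)
      tau_ring[zone, ] <- 0.3 * tau_ring[zone, ] +
        matrix(osc, sum(zone), n_time, byrow = TRUE)
    }
  }

  # local axial surface tangent per vertex: axis + dR/ds * radial direction
  cl <- geometry$centerline_points
  i0 <- pmax(seq_len(nrings) - 1, 1); i1 <- pmin(seq_len(nrings) + 1, nrings)
  axis <- (cl[i1, , drop = FALSE] - cl[i0, , drop = FALSE])
  axis <- axis/row_norms(axis)
  ds <- geometry$arclength[i1] - geometry$arclength[i0]
  drds <- (rad[i1] - rad[i0])/ds
  ri <- geometry$ring_index
  radial <- geometry$vertices - cl[ri, , drop = FALSE]
  radial <- radial/pmax(row_norms(radial), 1e-12)
  tangent <- axis[ri, , drop = FALSE] + drds[ri] * radial
  tangent <- tangent/row_norms(tangent)

  nv <- nrow(geometry$vertices)
  wss <- array(0, dim = c(nv, n_time, 3))
  for (k in 1:3) {
    wss[, , k] <- tau_ring[ri, , drop = FALSE] * tangent[, k]
  }
  surface_wss_series(geometry$vertices, times, wss, period = T)
}

#' Rasterize one synthetic histology section
#'
#' Paints a class-coded section mask: a circular lumen of the local radius,
#' an intima annulus of `wall_thickness`, and per 45-degree sector a necrotic
#' core band starting `cap` mm behind the lumen (with a nested fibrin band at
#' its outer edge), a macrophage band at the outer wall, or a full-sector
#' artifact. Component pixel counts are chosen to match the target areas;
#' the realized (quantized) areas are returned alongside the mask.
#'
#' @param lumen_radius local lumen radius, mm.
#' @param targets data.frame with one row per sector: `nc`, `fibrin`,
#'   `macrophage` (mm2) and `cap` (mm).
#' @param pixel_size raster resolution, mm (default 0.05).
#' @param wall_thickness intima annulus thickness, mm.
#' @param artifact_bins 0-based sector indices to blank with artifact.
#' @param n_bins sectors per section.
#' @param section_id,axial_position metadata stored in the mask.
#' @return list with `mask` (a [section_label_mask()]) and `realized`
#'   (data.frame of per-sector realized areas/cap, plus `capped` flag).
#' @export
generate_section_mask <- function(lumen_radius, targets, pixel_size = 0.05,
                                  wall_thickness = 2.5,
                                  artifact_bins = integer(0), n_bins = 8,
                                  section_id = "S01",
                                  axial_position = NA_real_) {
  outer_r <- lumen_radius + wall_thickness
  half <- outer_r + 0.3
  n <- 2L * ceiling(half/pixel_size) + 1L
  origin <- c(-(n - 1)/2 * pixel_size, -(n - 1)/2 * pixel_size)
  xs <- origin[1] + (seq_len(n) - 1) * pixel_size
  X <- matrix(rep(xs, each = n), n, n)
  Y <- matrix(rep(xs, n), n, n)
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X) %% (2 * pi)
  sector <- pmin(floor(theta/(2 * pi/n_bins)), n_bins - 1)
  cc <- mask_class_codes()
  px <- matrix(cc[["background"]], n, n)
  annulus <- r > lumen_radius & r <= outer_r
  px[annulus] <- cc[["intima"]]

  a1 <- pixel_size^2
  realized <- data.frame(bin_index = 0:(n_bins - 1), nc = 0, fibrin = 0,
                         macrophage = 0, cap = NA_real_, intima = 0,
                         artifact = FALSE, capped = FALSE)
  for (k in 0:(n_bins - 1)) {
    in_sec <- annulus & sector == k
    realized$intima[k + 1] <- sum(in_sec) * a1
    if (k %in% artifact_bins) {
      px[in_sec] <- cc[["artifact"]]
      realized$artifact[k + 1] <- TRUE
      realized$intima[k + 1] <- 0
      next
    }
    tg <- targets[k + 1, ]
    cap_k <- if (is.null(tg$cap) || is.na(tg$cap)) 0.25 else tg$cap
    # necrotic-core band: nearest-to-lumen pixels at radius >= lumen + cap
    idx <- which(in_sec & r >= lumen_radius + cap_k)
    if (length(idx) > 0 && tg$nc > 0) {
      idx <- idx[order(r[idx], theta[idx])]
      n_nc <- round(tg$nc/a1)
      if (n_nc > length(idx)) {
        n_nc <- length(idx)
        realized$capped[k + 1] <- TRUE
        warning(sprintf("section %s bin %d: NC target exceeds sector area; capped",
                        section_id, k), call. = FALSE)
      }
      take <- idx[seq_len(n_nc)]
      px[take] <- cc[["nc"]]
      n_fib <- min(round(tg$fibrin/a1), n_nc)
      if (n_fib > 0) {
        # fibrin nests at the outer (deep) edge of the necrotic complex
        px[take[seq.int(n_nc - n_fib + 1, n_nc)]] <- cc[["fibrin"]]
      }
      realized$nc[k + 1] <- n_nc * a1
      realized$fibrin[k + 1] <- n_fib * a1
      realized$cap[k + 1] <- min(r[take]) - lumen_radius
    }
    # macrophage band at the outer wall, away from the cap measurement
    n_mac <- round(tg$macrophage/a1)
    if (n_mac > 0) {
      free <- which(in_sec & px == cc[["intima"]])
      free <- free[order(-r[free], theta[free])]
      if (n_mac > length(free)) {
        n_mac <- length(free)
        realized$capped[k + 1] <- TRUE
        warning(sprintf("section %s bin %d: macrophage target exceeds free area; capped",
                        section_id, k), call. = FALSE)
      }
      px[free[seq_len(n_mac)]] <- cc[["macrophage"]]
      realized$macrophage[k + 1] <- n_mac * a1
    }
  }
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  contour <- cbind(lumen_radius * cos(phi), lumen_radius * sin(phi))
  mask <- section_label_mask(px, pixel_size, center = c(0, 0),
                             angular_reference = c(1, 0),
                             lumen_contour = contour, origin = origin,
                             section_id = section_id,
                             axial_position = axial_position)
  list(mask = mask, realized = realized)
}

#' Generate histology masks for all sections of one patient
#'
#' @param geometry a `vessel_geometry`.
#' @param sections list of [cross_section_frame()]s for the patient.
#' @param bin_tertiles data.frame with `section_id`, `bin_index`,
#'   `tawss_tertile`, `osi_tertile` for every sector.
#' @param effects named list of [effect_spec()]s.
#' @param intercepts named numeric vector of this patient's random
#'   intercepts (one per effect).
#' @param pixel_size raster resolution, mm.
#' @param seed RNG seed for the residual noise.
#' @param artifact_bins data.frame (`section_id`, `bin_index`) of sectors to
#'   blank with artifact, or NULL.
#' @param wall_thickness intima thickness, mm.
#' @return list with `masks` (one [section_label_mask()] per section) and
#'   `truth` (per-sector targets and realized areas).
#' @export
generate_histology_sections <- function(geometry, sections, bin_tertiles,
                                        effects, intercepts,
                                        pixel_size = 0.05, seed = 1,
                                        artifact_bins = NULL,
                                        wall_thickness = 2.5) {
  assert_that(pixel_size > 0, "pixel_size must be > 0")
  lv <- c("low", "mid", "high")
  assert_that(all(as.character(bin_tertiles$tawss_tertile) %in% lv) &&
                all(as.character(bin_tertiles$osi_tertile) %in% lv),
              "tertile labels must be low/mid/high")
  set.seed(derive_seed(seed, 202))
  masks <- list()
  truth <- list()
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    bt <- bin_tertiles[bin_tertiles$section_id == sec$section_id, ]
    bt <- bt[order(bt$bin_index), ]
    out <- simulate_bin_outcomes(bt, effects, as.list(intercepts))
    targets <- data.frame(nc = out$nc %||% 0, fibrin = out$fibrin %||% 0,
                          macrophage = out$macrophage %||% 0,
                          cap = out$cap %||% 0.25)
    ab <- integer(0)
    if (!is.null(artifact_bins)) {
      ab <- artifact_bins$bin_index[artifact_bins$section_id == sec$section_id]
    }
    k <- which.min(abs(geometry$arclength - sec$axial_position))
    gm <- generate_section_mask(geometry$radius_profile[k], targets,
                                pixel_size = pixel_size,
                                wall_thickness = wall_thickness,
                                artifact_bins = ab,
                                section_id = sec$section_id,
                                axial_position = sec$axial_position)
    masks[[sec$section_id]] <- gm$mask
    tr <- cbind(section_id = sec$section_id, gm$realized,
                target_nc = targets$nc, target_fibrin = targets$fibrin,
                target_macrophage = targets$macrophage,
                target_cap = targets$cap,
                tawss_tertile = as.character(bt$tawss_tertile),
                osi_tertile = as.character(bt$osi_tertile),
                stringsAsFactors = FALSE)
    truth[[i]] <- tr
  }
  list(masks = masks, truth = do.call(rbind, truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic study
#'
#' Builds `n_patients` vessels (alternating straight and stenotic), scales a
#' random pulsatile waveform to the 0.9 Pa common-carotid setpoint, applies
#' a per-patient magnitude factor (so absolute WSS ranges differ between
#' patients and patient-specific tertiles are genuinely needed), computes
#' the synthetic WSS field and its per-sector means, derives the tertile
#' labels, and (optionally) rasterizes histology masks whose component areas
#' follow the programmed effect structure.
#'
#' @param n_patients number of patients (>= 2).
#' @param sections_per_patient histology sections per patient.
#' @param effects named list of [effect_spec()]s.
#' @param seed master RNG seed; the study is a pure function of it.
#' @param base_radius CCA radius, mm.
#' @param pixel_size histology raster resolution, mm.
#' @param n_time WSS time samples per cycle.
#' @param n_circ mesh vertices per ring.
#' @param wss_scale_range per-patient multiplicative range on the scaled
#'   waveform.
#' @param stenotic_fraction fraction of patients given a stenotic vessel.
#' @param artifact_bins_per_patient number of randomly chosen sectors per
#'   patient blanked with artifact.
#' @param rasterize if `FALSE`, skip mask painting and keep only the
#'   simulated per-bin outcome table (fast path for repeated statistical
#'   simulation).
#' @param target_tawss common-carotid TAWSS setpoint, Pa.
#' @return object of class `synthetic_study`: `patients`, `geometries`,
#'   `wss_series`, `metric_maps`, `sections`, `masks`, `truth` (per-bin
#'   table incl. tertiles, targets, realized areas), `wss_bins`,
#'   `intercepts`, `effects`, `seed`.
#' @export
generate_study <- function(n_patients = 11, sections_per_patient = 8,
                           effects = default_effects(), seed = 1,
                           base_radius = 3, pixel_size = 0.05, n_time = 16,
                           n_circ = 48, wss_scale_range = c(0.6, 1.8),
                           stenotic_fraction = 0.5,
                           artifact_bins_per_patient = 0,
                           rasterize = TRUE, target_tawss = 0.9) {
  if (n_patients < 2) {
    stop_input("configuration error: need >= 2 patients for the random-intercept model")
  }
  patients <- sprintf("P%02d", seq_len(n_patients))
  intercepts <- draw_patient_intercepts(effects, n_patients, seed)
  set.seed(derive_seed(seed, 1))
  degrees <- stats::runif(n_patients, 0.3, 0.7)
  scales <- stats::runif(n_patients, wss_scale_range[1], wss_scale_range[2])
  stenotic <- seq_len(n_patients) <= round(stenotic_fraction * n_patients)

  geometries <- list(); wss_series <- list(); metric_maps <- list()
  sections <- list(); masks <- list(); truth <- list(); wss_bins <- list()
  for (p in seq_len(n_patients)) {
    pid <- patients[p]
    geo <- generate_vessel(kind = if (stenotic[p]) "stenotic" else "straight",
                           base_radius = base_radius,
                           stenosis_degree = if (stenotic[p]) degrees[p] else 0,
                           n_sections = sections_per_patient,
                           n_circ = n_circ)
    wf <- random_waveform(seed = derive_seed(seed, 1000 + p))
    sc <- scale_waveform_to_target_wss(wf, base_radius,
                                       target_tawss = target_tawss,
                                       n_time = max(n_time, 32))
    wf_p <- scale_waveform(sc$waveform, scales[p])
    fld <- generate_wss_field(geo, wf_p, n_time = n_time)
    mm <- metric_map(fld)
    cl <- centerline(geo$centerline_points)
    frames <- cross_section_frames(geo, patient_id = pid)
    wb <- wss_bin_means(mm, cl, frames)
    wb$tawss_tertile <- factor(NA, c("low", "mid", "high"))
    wb$osi_tertile <- factor(NA, c("low", "mid", "high"))
    ok <- !wb$no_coverage
    wb$tawss_tertile[ok] <- patient_tertiles(wb$tawss_mean[ok])$labels
    wb$osi_tertile[ok] <- patient_tertiles(wb$osi_mean[ok])$labels

    ab <- NULL
    if (artifact_bins_per_patient > 0) {
      set.seed(derive_seed(seed, 3000 + p))
      pick <- sample(nrow(wb), min(artifact_bins_per_patient, nrow(wb)))
      ab <- wb[pick, c("section_id", "bin_index")]
    }
    if (rasterize) {
      hs <- generate_histology_sections(geo, frames, wb, effects,
                                        intercepts[p, ],
                                        pixel_size = pixel_size,
                                        seed = derive_seed(seed, 2000 + p),
                                        artifact_bins = ab)
      masks[[pid]] <- hs$masks
      tr <- hs$truth
    } else {
      set.seed(derive_seed(derive_seed(seed, 2000 + p), 202))
      out <- simulate_bin_outcomes(wb, effects, as.list(intercepts[p, ]))
      tr <- data.frame(section_id = wb$section_id, bin_index = wb$bin_index,
                       nc = out$nc %||% 0, fibrin = out$fibrin %||% 0,
                       macrophage = out$macrophage %||% 0,
                       cap = out$cap %||% 0.25,
                       intima = NA_real_, artifact = FALSE, capped = FALSE,
                       tawss_tertile = as.character(wb$tawss_tertile),
                       osi_tertile = as.character(wb$osi_tertile),
                       stringsAsFactors = FALSE)
      if (!is.null(ab)) {
        tr$artifact[paste(tr$section_id, tr$bin_index) %in%
                      paste(ab$section_id, ab$bin_index)] <- TRUE
      }
    }
    tr$patient_id <- pid
    geometries[[pid]] <- geo
    wss_series[[pid]] <- fld
    metric_maps[[pid]] <- mm
    sections[[pid]] <- frames
    truth[[pid]] <- tr
    wss_bins[[pid]] <- wb
  }
  structure(list(patients = patients, geometries = geometries,
                 wss_series = wss_series, metric_maps = metric_maps,
                 sections = sections, masks = masks,
                 truth = do.call(rbind, truth),
                 wss_bins = do.call(rbind, wss_bins),
                 intercepts = intercepts, effects = effects, seed = seed),
            class = "synthetic_study")
}

#' Bin-record table of a synthetic study
#'
#' Measures every rasterized mask with [component_area_per_bin()] and
#' [cap_thickness_per_bin()], applies the artifact exclusion filter, and
#' joins the per-sector plaque measures with the per-sector WSS means into
#' the analysis-ready bin-record table. For studies generated with
#' `rasterize = FALSE` the simulated outcome table is used directly.
#'
#' @param study a [generate_study()] result.
#' @param artifact_threshold artifact-fraction threshold for exclusion.
#' @param measure_cap if `FALSE`, skip ray-cast cap measurement and use the
#'   generator's realized cap values (faster).
#' @return bin-record data.frame with tertile columns
#'   (see [build_bin_table()], [add_patient_tertiles()]).
#' @export
study_bin_table <- function(study, artifact_threshold = 0,
                            measure_cap = TRUE) {
  stopifnot(inherits(study, "synthetic_study"))
  if (length(study$masks) > 0) {
    plaque <- list()
    for (pid in study$patients) {
      for (sid in names(study$masks[[pid]])) {
        m <- study$masks[[pid]][[sid]]
        meas <- component_area_per_bin(m)
        if (measure_cap) {
          meas$cap_thickness <- cap_thickness_per_bin(m)
        } else {
          tr <- study$truth[study$truth$section_id == sid, ]
          meas$cap_thickness <- tr$cap[order(tr$bin_index)]
        }
        plaque[[length(plaque) + 1]] <- meas
      }
    }
    plaque <- do.call(rbind, plaque)
    plaque <- exclude_bins(plaque, artifact_threshold)
  } else {
    tr <- study$truth
    plaque <- data.frame(section_id = tr$section_id,
                         bin_index = tr$bin_index,
                         nc_area = tr$nc, fibrin_area = tr$fibrin,
                         macrophage_area = tr$macrophage,
                         cap_thickness = tr$cap, intima_area = tr$intima,
                         artifact_fraction = as.numeric(tr$artifact),
                         stringsAsFactors = FALSE)
    plaque <- exclude_bins(plaque, artifact_threshold)
  }
  rec <- build_bin_table(study$wss_bins, plaque)
  add_patient_tertiles(rec)
}
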