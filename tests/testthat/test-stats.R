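test_that("patient tertiles split 1..9 into balanced thirds", {
  t9 <- patient_tertiles(1:9)
  expect_identical(as.character(t9$labels),
                   rep(c("low", "mid", "high"), each = 3))
  expect_false(t9$degenerate)

  tied <- patient_tertiles(rep(2, 6))
  expect_true(tied$degenerate)
  expect_true(all(tied$labels == "high"))   # value >= upper boundary

  expect_error(patient_tertiles(c(1, 2)), "fewer than 3")
})

test_that("tertile group sizes match the sort-based oracle on random input", {
  set.seed(17)
  for (rep in 1:5) {
    v <- stats::rnorm(300)
    lab <- patient_tertiles(v)$labels
    expect_true(all(abs(table(lab) - 100) <= 1))
    # oracle: sorting splits the sample into thirds
    o <- sort(v)
    expect_true(all(v[lab == "low"] <= o[101]))
    expect_true(all(v[lab == "high"] >= o[200]))
  }
})

test_that("co-occurrence table cross-tabulates and conserves totals", {
  lv <- c("low", "mid", "high")
  # perfectly inverse labels: all mass on the anti-diagonal
  ta <- rep(lv, times = c(5, 7, 9))
  os <- rep(rev(lv), times = c(5, 7, 9))
  m <- cooccurrence_table(ta, os)
  expect_equal(sum(m), 21)
  expect_equal(m["low", "high"], 5L)
  expect_equal(m["mid", "mid"], 7L)
  expect_equal(m["high", "low"], 9L)
  expect_equal(sum(diag(m[, 3:1])), 21L)

  set.seed(3)
  n <- 9000
  m2 <- cooccurrence_table(sample(lv, n, TRUE), sample(lv, n, TRUE))
  expect_equal(sum(m2), n)
  expect_true(all(abs(m2 - 1000) <= 100))

  expect_equal(sum(cooccurrence_table(character(0), character(0))), 0)
  expect_error(cooccurrence_table("bad", "low"), "low/mid/high")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 1), c(0.2, 0.04))
  expect_error(bonferroni_adjust(1.2, 3), "\\[0, 1\\]")
})

test_that("noise-free LMM recovers programmed group means exactly", {
  eff <- list(nc = effect_spec("nc", "tawss_tertile", c(1, 1, 2)))
  rec <- simulated_records(4, 30, eff, seed = 5)
  fit <- fit_tertile_lmm(rec, "nc_area_mm2", "tawss_tertile")
  expect_equal(unname(fit$estimated_means[c("low", "mid", "high")]),
               c(1, 1, 2), tolerance = 1e-9)
  hl <- fit$pairwise[fit$pairwise$contrast == "high - low", ]
  expect_equal(hl$estimate, 1, tolerance = 1e-9)
})

test_that("zero patient variance reduces estimated means to group means", {
  eff <- list(nc = effect_spec("nc", "tawss_tertile", c(1, 1.5, 2),
                               patient_sd = 0, residual_sd = 0.4))
  rec <- simulated_records(5, 40, eff, seed = 9)
  fit <- fit_tertile_lmm(rec, "nc_area_mm2", "tawss_tertile")
  gm <- tapply(rec$nc_area_mm2, rec$tawss_tertile, mean)
  expect_equal(unname(fit$estimated_means[names(gm)]), as.numeric(gm),
               tolerance = 1e-6)
  expect_true(fit$model_converged)
})

test_that("noisy simulation recovers the programmed effect without bias", {
  eff <- list(nc = effect_spec("nc", "tawss_tertile", c(1, 1, 2),
                               patient_sd = 0.3, residual_sd = 0.5))
  est <- replicate(25, {
    rec <- simulated_records(11, 46, eff,
                             seed = sample.int(1e6, 1))
    fit <- fit_tertile_lmm(rec, "nc_area_mm2", "tawss_tertile")
    fit$pairwise$estimate[fit$pairwise$contrast == "high - low"]
  })
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("combined model estimates cell means and suppresses empty cells", {
  eff <- list(cap = effect_spec("cap", "osi_tertile", c(0.4, 0.3, 0.25),
                                patient_sd = 0, residual_sd = 0))
  rec <- simulated_records(4, 30, eff, seed = 31)
  fit <- fit_combined_lmm(rec, "cap_thickness_mm")
  # cell low.low (TAWSS.OSI) mean is the programmed low-OSI cap value
  expect_equal(unname(fit$estimated_means[["low.low"]]), 0.4,
               tolerance = 1e-9)
  # contrasts only within rows or columns of the 3x3 grid
  for (ct in fit$pairwise$contrast) {
    cells <- strsplit(strsplit(ct, " - ")[[1]], ".", fixed = TRUE)
    expect_true(cells[[1]][1] == cells[[2]][1] ||
                  cells[[1]][2] == cells[[2]][2])
  }
  rec1 <- rec[rec$patient_id == "P01", ]
  expect_error(fit_combined_lmm(rec1, "cap_thickness_mm"), "2 patients")
  expect_error(fit_tertile_lmm(rec1, "cap_thickness_mm", "osi_tertile"),
               "2 patients")
})

test_that("combined model recovers a programmed within-row cell contrast", {
  # cap thickness larger at low OSI than high OSI within the low-TAWSS row
  eff <- list(cap = effect_spec("cap", "osi_tertile", c(0.5, 0.4, 0.3),
                                patient_sd = 0.03, residual_sd = 0.05))
  est <- replicate(10, {
    rec <- simulated_records(8, 45, eff, seed = sample.int(1e6, 1))
    fit <- fit_combined_lmm(rec, "cap_thickness_mm")
    pw <- fit$pairwise
    i <- grep("^low\\.low - low\\.high$|^low\\.high - low\\.low$",
              pw$contrast)
    if (length(i) == 0) NA_real_ else {
      sgn <- if (startsWith(pw$contrast[i[1]], "low.low")) 1 else -1
      sgn * pw$estimate[i[1]]
    }
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.2), 0.05)
})
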