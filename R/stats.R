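#' Patient-specific tertile assignment
#'
#' Splits one patient's bin-averaged metric values into low / mid / high
#' tertiles at the 33.3 and 66.7 percentiles (linear-interpolation
#' percentiles, `stats::quantile` type 7). A value is `low` when strictly
#' below the low-mid boundary, `high` when at or above the mid-high
#' boundary, `mid` otherwise.
#'
#' @param values numeric metric values (one per included bin) of a single
#'   patient; at least 3 required.
#' @return list of class `tertile_assignment` with `boundary_low_mid`,
#'   `boundary_mid_high`, `labels` (factor low/mid/high), and `degenerate`
#'   (TRUE when the two boundaries coincide, e.g. all values tied).
#' @examples
#' patient_tertiles(1:9)$labels
#' @export
patient_tertiles <- function(values) {
  assert_that(is.numeric(values) && all(is.finite(values)),
              "values must be finite numeric")
  if (length(values) < 3) {
    stop_input("patient has fewer than 3 included bins; tertiles undefined")
  }
  qs <- stats::quantile(values, probs = c(1, 2)/3, type = 7, names = FALSE)
  labels <- ifelse(values < qs[1], "low",
                   ifelse(values >= qs[2], "high", "mid"))
  structure(list(boundary_low_mid = qs[1], boundary_mid_high = qs[2],
                 labels = factor(labels, levels = c("low", "mid", "high")),
                 degenerate = qs[1] == qs[2]),
            class = "tertile_assignment")
}

#' Add patient-specific TAWSS and OSI tertile columns to a bin table
#'
#' Computes tertiles of `tawss_mean` and `osi_mean` per patient over the
#' included bins and appends `tawss_tertile` and `osi_tertile` factor
#' columns (NA for excluded bins and for patients with < 3 included bins).
#'
#' @param records bin-record data.frame (see [build_bin_table()]).
#' @return `records` with tertile columns; the per-patient boundary table is
#'   attached as attribute `"boundaries"` (the Table-1-style layout).
#' @export
add_patient_tertiles <- function(records) {
  records$tawss_tertile <- factor(NA, levels = c("low", "mid", "high"))
  records$osi_tertile <- factor(NA, levels = c("low", "mid", "high"))
  bounds <- list()
  for (p in unique(records$patient_id)) {
    i <- which(records$patient_id == p & records$included)
    if (length(i) < 3) next
    tt <- patient_tertiles(records$tawss_mean[i])
    ot <- patient_tertiles(records$osi_mean[i])
    records$tawss_tertile[i] <- tt$labels
    records$osi_tertile[i] <- ot$labels
    bounds[[length(bounds) + 1]] <- data.frame(
      patient_id = p,
      tawss_low_mid = tt$boundary_low_mid,
      tawss_mid_high = tt$boundary_mid_high,
      tawss_min = min(records$tawss_mean[i]),
      tawss_max = max(records$tawss_mean[i]),
      osi_low_mid = ot$boundary_low_mid,
      osi_mid_high = ot$boundary_mid_high,
      osi_min = min(records$osi_mean[i]),
      osi_max = max(records$osi_mean[i]),
      stringsAsFactors = FALSE)
  }
  attr(records, "boundaries") <- do.call(rbind, bounds)
  records
}

#' Co-occurrence table of TAWSS and OSI tertiles
#'
#' @param tawss_labels,osi_labels paired per-bin tertile labels
#'   (low/mid/high), equal length.
#' @return 3x3 integer matrix (rows = TAWSS tertile, cols = OSI tertile).
#' @export
cooccurrence_table <- function(tawss_labels, osi_labels) {
  lv <- c("low", "mid", "high")
  assert_that(length(tawss_labels) == length(osi_labels),
              "label vectors must have equal length")
  ta <- as.character(tawss_labels); os <- as.character(osi_labels)
  if (length(ta) > 0 && (!all(ta %in% lv) || !all(os %in% lv))) {
    stop_input("labels must be low/mid/high")
  }
  tab <- table(factor(ta, levels = lv), factor(os, levels = lv))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(TAWSS = lv, OSI = lv))
  m
}

#' Bonferroni adjustment
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m number of comparisons in the family (default: the number of
#'   p-values supplied).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  assert_that(m >= 1, "m must be >= 1")
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  pmin(1, p_values * m)
}

# Fit y ~ 0 + group + (1 | patient) by REML, with an OLS fallback when the
# mixed fit is degenerate (e.g. zero residual variance in noise-free data).
fit_group_means_lmm <- function(y, group, patient) {
  dat <- data.frame(y = y, group = droplevels(factor(group)),
                    patient = factor(patient))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 0 + group + (1 | patient), data = dat, REML = TRUE))),
    error = function(e) NULL)
  singular <- FALSE
  if (!is.null(fit)) {
    singular <- lme4::isSingular(fit, tol = 1e-6)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    backend <- "lmer"
  }
  if (is.null(fit)) {
    # degenerate data (no residual noise or no patient replication):
    # plain per-group means with OLS standard errors
    fit <- stats::lm(y ~ 0 + group, data = dat)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    V[!is.finite(V)] <- 0
    backend <- "lm"
  }
  names(beta) <- sub("^group", "", names(beta))
  list(means = beta, vcov = V, levels = levels(dat$group),
       converged = TRUE, singular = singular, backend = backend,
       n = nrow(dat))
}

wald_contrast <- function(est, V, i, j) {
  delta <- est[i] - est[j]
  se <- sqrt(max(V[i, i] + V[j, j] - 2 * V[i, j], 0))
  z <- if (se > 0) delta/se else ifelse(delta == 0, 0, Inf * sign(delta))
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
  c(estimate = unname(delta), se = unname(se), z = unname(z), p = unname(p))
}

#' Tertile linear mixed-effects model
#'
#' Fits `outcome ~ 0 + tertile + (1 | patient)` by REML on the included bins
#' with non-missing outcome, giving the estimated mean and standard error of
#' the outcome per tertile (low/mid/high) and the three pairwise Wald-z
#' contrasts with Bonferroni adjustment (m = 3). When the mixed fit is
#' degenerate (zero residual variance, as in noise-free synthetic data) a
#' fixed-effects fallback reports the plain group means.
#'
#' @param records bin-record table with tertile columns
#'   (see [add_patient_tertiles()]).
#' @param outcome name of the outcome column (e.g. `"nc_area_mm2"`).
#' @param factor_name `"tawss_tertile"` or `"osi_tertile"`.
#' @return object of class `lmm_result`: `outcome`, `factor_name`,
#'   `estimated_means` (named), `standard_errors`, `pairwise` (data.frame
#'   with contrast, estimate, se, z, p_raw, p_adjusted), `model_converged`,
#'   `singular`, `backend`, `n`.
#' @export
fit_tertile_lmm <- function(records, outcome,
                            factor_name = c("tawss_tertile", "osi_tertile")) {
  factor_name <- match.arg(factor_name)
  keep <- records$included & !is.na(records[[outcome]]) &
    !is.na(records[[factor_name]])
  d <- records[keep, ]
  if (nrow(d) == 0) stop_input("empty-analysis error: no usable bins")
  if (length(unique(d$patient_id)) < 2) {
    stop_input("random intercept unidentifiable with < 2 patients")
  }
  f <- fit_group_means_lmm(d[[outcome]], d[[factor_name]], d$patient_id)
  lev <- f$levels
  pairs <- utils::combn(seq_along(lev), 2)
  pw <- apply(pairs, 2, function(ij) {
    wald_contrast(f$means, f$vcov, ij[2], ij[1])
  })
  pw <- as.data.frame(t(pw))
  pw$contrast <- apply(pairs, 2, function(ij) {
    paste(lev[ij[2]], "-", lev[ij[1]])
  })
  pw$p_raw <- pw$p
  pw$p_adjusted <- bonferroni_adjust(pw$p_raw, m = 3)
  structure(list(outcome = outcome, factor_name = factor_name,
                 estimated_means = f$means,
                 standard_errors = sqrt(pmax(diag(f$vcov), 0)),
                 pairwise = pw[, c("contrast", "estimate", "se", "z",
                                   "p_raw", "p_adjusted")],
                 model_converged = f$converged, singular = f$singular,
                 backend = f$backend, n = f$n),
            class = "lmm_result")
}

#' Combined TAWSS x OSI tertile mixed model
#'
#' Fits the cell-means form of the two-factor model with interaction,
#' `outcome ~ 0 + tawss:osi cell + (1 | patient)`, over the (up to nine)
#' occupied tertile cells. Reported contrasts are all within-row pairs
#' (same TAWSS tertile, differing OSI tertile) and all within-column pairs,
#' Bonferroni-adjusted over the emitted family; contrasts involving empty
#' cells are suppressed.
#'
#' @param records bin-record table with both tertile columns.
#' @param outcome outcome column name.
#' @return an `lmm_result` whose group labels are `tawssTertile.osiTertile`
#'   cells; `pairwise$family_size` records the Bonferroni family.
#' @export
fit_combined_lmm <- function(records, outcome) {
  keep <- records$included & !is.na(records[[outcome]]) &
    !is.na(records$tawss_tertile) & !is.na(records$osi_tertile)
  d <- records[keep, ]
  if (nrow(d) == 0) stop_input("empty-analysis error: no usable bins")
  if (length(unique(d$patient_id)) < 2) {
    stop_input("random intercept unidentifiable with < 2 patients")
  }
  cell <- interaction(d$tawss_tertile, d$osi_tertile, drop = TRUE, sep = ".")
  f <- fit_group_means_lmm(d[[outcome]], cell, d$patient_id)
  lev <- f$levels
  parts <- do.call(rbind, strsplit(lev, ".", fixed = TRUE))
  contrasts <- list()
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (i >= j) next
      same_row <- parts[i, 1] == parts[j, 1]
      same_col <- parts[i, 2] == parts[j, 2]
      if (!same_row && !same_col) next
      contrasts[[length(contrasts) + 1]] <-
        c(list(i = i, j = j), as.list(
          wald_contrast(f$means, f$vcov, i, j)))
    }
  }
  if (length(contrasts) == 0) {
    pw <- data.frame(contrast = character(0), estimate = numeric(0),
                     se = numeric(0), z = numeric(0), p_raw = numeric(0),
                     p_adjusted = numeric(0), family_size = integer(0))
  } else {
    pw <- do.call(rbind, lapply(contrasts, as.data.frame))
    pw$contrast <- paste(lev[pw$i], "-", lev[pw$j])
    pw$p_raw <- pw$p
    pw$p_adjusted <- bonferroni_adjust(pw$p_raw, m = nrow(pw))
    pw$family_size <- nrow(pw)
    pw <- pw[, c("contrast", "estimate", "se", "z", "p_raw", "p_adjusted",
                 "family_size")]
  }
  structure(list(outcome = outcome, factor_name = "tawss_tertile:osi_tertile",
                 estimated_means = f$means,
                 standard_errors = sqrt(pmax(diag(f$vcov), 0)),
                 pairwise = pw, model_converged = f$converged,
                 singular = f$singular, backend = f$backend, n = f$n),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Mixed-model result: %s by %s (n = %d, backend = %s%s)\n",
              x$outcome, x$factor_name, x$n, x$backend,
              if (isTRUE(x$singular)) ", singular fit" else ""))
  est <- data.frame(group = names(x$estimated_means),
                    mean = as.numeric(x$estimated_means),
                    se = as.numeric(x$standard_errors))
  print(est, row.names = FALSE)
  cat("Pairwise contrasts (Bonferroni-adjusted):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
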