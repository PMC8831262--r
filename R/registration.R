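#' Binary lumen segmentation
#'
#' @param mask logical (or 0/1) matrix, `TRUE` inside the lumen.
#' @param pixel_size pixel edge length, mm.
#' @param contour optional closed `n x 2` polygon of the lumen boundary, mm.
#' @return object of class `lumen_segmentation`.
#' @export
lumen_segmentation <- function(mask, pixel_size = 0.05, contour = NULL) {
  mask <- mask > 0
  assert_that(any(mask), "lumen mask must be non-empty")
  structure(list(mask = mask, pixel_size = pixel_size, contour = contour),
            class = "lumen_segmentation")
}

#' Dice similarity coefficient
#'
#' DSC = 2|A intersect B| / (|A| + |B|) between two binary segmentations on
#' the same grid.
#'
#' @param a,b `lumen_segmentation` objects or logical matrices.
#' @return DSC in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "lumen_segmentation")) a$mask else a > 0
  mb <- if (inherits(b, "lumen_segmentation")) b$mask else b > 0
  assert_that(all(dim(ma) == dim(mb)), "masks must share the grid")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) stop_input("both masks empty: Dice undefined")
  2 * sum(ma & mb)/(na + nb)
}

#' Resample a closed contour at uniform arclength
#'
#' @param contour `n x 2` polygon, mm (closed implicitly).
#' @param step target arclength spacing, mm.
#' @return resampled `m x 2` matrix.
#' @export
resample_contour <- function(contour, step = 0.05) {
  contour <- as.matrix(contour)
  assert_that(nrow(contour) >= 3, "contour needs >= 3 points")
  assert_that(all(is.finite(contour)), "contour has non-finite coordinates")
  closed <- rbind(contour, contour[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0) stop_input("degenerate contour: zero total length")
  s <- c(0, cumsum(seg))
  m <- max(8L, ceiling(total/step))
  tgt <- (seq_len(m) - 1) * total/m
  x <- stats::approx(s, closed[, 1], xout = tgt)$y
  y <- stats::approx(s, closed[, 2], xout = tgt)$y
  cbind(x, y)
}

# min distance from each point in pts to polyline segments of closed contour
points_to_contour_distance <- function(pts, contour) {
  a <- contour
  b <- contour[c(2:nrow(contour), 1), ]
  ab <- b - a
  len2 <- rowSums(ab^2)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(a))) {
    ap <- sweep(pts, 2, a[i, ])
    t <- (ap[, 1] * ab[i, 1] + ap[, 2] * ab[i, 2])/max(len2[i], 1e-300)
    t <- pmin(pmax(t, 0), 1)
    dx <- ap[, 1] - t * ab[i, 1]
    dy <- ap[, 2] - t * ab[i, 2]
    dmin <- pmin(dmin, dx * dx + dy * dy)
  }
  sqrt(dmin)
}

#' Average (and maximum) Hausdorff distance between contours
#'
#' Both contours are resampled at uniform arclength; the average Hausdorff
#' distance is the symmetric average surface distance (mean distance from A
#' to contour B averaged with the reverse direction). The classical
#' max-Hausdorff is reported alongside.
#'
#' @param a,b closed `n x 2` contours, mm.
#' @param resample_step resampling arclength step, mm.
#' @return list with `avg_hd` and `max_hd`, mm.
#' @export
average_hausdorff <- function(a, b, resample_step = 0.05) {
  ra <- resample_contour(a, resample_step)
  rb <- resample_contour(b, resample_step)
  dab <- points_to_contour_distance(ra, rb)
  dba <- points_to_contour_distance(rb, ra)
  list(avg_hd = (mean(dab) + mean(dba))/2,
       max_hd = max(max(dab), max(dba)))
}

#' Rigid 2D contour alignment
#'
#' Least-squares rigid (rotation + translation) alignment of `moving` onto
#' `fixed`. Both contours are resampled to `n_points` uniform-arclength
#' correspondences; a cyclic-shift search over the starting index (both
#' orientations) picks the correspondence with the smallest residual, and
#' the identity transform is kept if it beats the best fit.
#'
#' @param moving,fixed closed `n x 2` contours, mm.
#' @param n_points number of resampled correspondences.
#' @return list with `rotation` (2x2 matrix), `translation` (length 2),
#'   `aligned` (transformed moving contour, original vertices) and
#'   `residual` (mean correspondence distance after alignment).
#' @export
rigid_align <- function(moving, fixed, n_points = 128) {
  assert_that(all(is.finite(as.matrix(moving))) &&
                all(is.finite(as.matrix(fixed))),
              "contours must have finite coordinates")
  assert_that(nrow(as.matrix(moving)) >= 3 && nrow(as.matrix(fixed)) >= 3,
              "contours need >= 3 points")
  pm <- resample_to_n(moving, n_points)
  pf <- resample_to_n(fixed, n_points)
  best <- list(res = Inf)
  for (orient in c(1L, -1L)) {
    q <- if (orient == 1L) pm else pm[rev(seq_len(n_points)), ]
    for (s in 0:(n_points - 1)) {
      qs <- q[((seq_len(n_points) - 1 + s) %% n_points) + 1, ]
      k <- kabsch2d(qs, pf)
      if (k$res < best$res) best <- k
    }
  }
  identity_res <- mean(sqrt(rowSums((pm - pf)^2)))
  if (identity_res <= best$res) {
    best <- list(Rm = diag(2), tv = c(0, 0), res = identity_res)
  }
  aligned <- sweep(as.matrix(moving) %*% t(best$Rm), 2, -best$tv)
  list(rotation = best$Rm, translation = best$tv, aligned = aligned,
       residual = best$res)
}

resample_to_n <- function(contour, n) {
  contour <- as.matrix(contour)
  closed <- rbind(contour, contour[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0) stop_input("degenerate contour: zero total length")
  s <- c(0, cumsum(seg))
  tgt <- (seq_len(n) - 1) * total/n
  cbind(stats::approx(s, closed[, 1], xout = tgt)$y,
        stats::approx(s, closed[, 2], xout = tgt)$y)
}

# proper-rotation Kabsch in 2D: R, t minimizing ||R q + t - p||
kabsch2d <- function(q, p) {
  cq <- colMeans(q); cp <- colMeans(p)
  qc <- sweep(q, 2, cq); pc <- sweep(p, 2, cp)
  H <- t(qc) %*% pc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  tv <- cp - as.vector(Rm %*% cq)
  moved <- sweep(q %*% t(Rm), 2, -tv)
  list(Rm = Rm, tv = tv, res = mean(sqrt(rowSums((moved - p)^2))))
}
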