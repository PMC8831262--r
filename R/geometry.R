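#' Idealized vessel geometry generator
#'
#' Builds a triangulated lumen surface swept along a straight centerline,
#' with an optional cosine-bump stenosis, and appends flow extensions of
#' length five times the local radius at the inlet and outlet (the standard
#' CFD practice this package emulates). The `bifurcation` kind attaches two
#' straight daughter branches (ICA with the stenosis, ECA plain) to the
#' common-carotid trunk as an idealized planar Y; sections are placed along
#' the CCA/ICA path.
#'
#' @param kind one of `"straight"`, `"stenotic"`, `"bifurcation"`.
#' @param base_radius lumen radius away from the stenosis, mm.
#' @param stenosis_degree fractional diameter reduction at the throat,
#'   in `[0, 1)`; the throat radius is `(1 - stenosis_degree) * base_radius`.
#' @param n_sections number of histology section planes placed along the
#'   vessel core (evenly spaced by `section_spacing`).
#' @param section_spacing axial spacing between section planes, mm.
#' @param stenosis_width axial full width of the cosine bump, mm
#'   (default 60\% of the core length).
#' @param n_circ vertices per circumferential ring.
#' @param axial_step centerline/ring spacing, mm.
#' @param branch_angle_deg half-angle between daughter branches
#'   (bifurcation kind).
#' @return an object of class `vessel_geometry` with fields
#'   `centerline_points` (n x 3, mm), `arclength`, `radius_profile`,
#'   `segment_labels` (CCA/ICA/ECA/extension), `vertices`, `triangles`,
#'   `ring_index`, `ring_angle`, `section_positions` (arclength of each
#'   section plane), `n_circ`, `kind`, `base_radius`, `stenosis_degree`,
#'   `throat_arclength` (NA unless stenotic).
#' @examples
#' g <- generate_vessel("stenotic", base_radius = 3, stenosis_degree = 0.5,
#'                      n_sections = 4)
#' min(g$radius_profile)   # 1.5 mm at the throat
#' @export
generate_vessel <- function(kind = c("straight", "stenotic", "bifurcation"),
                            base_radius = 3, stenosis_degree = 0,
                            n_sections = 8, section_spacing = 1,
                            stenosis_width = NULL,
                            n_circ = 48, axial_step = 0.25,
                            branch_angle_deg = 25) {
  kind <- match.arg(kind)
  assert_that(is_scalar_number(base_radius) && base_radius > 0,
              "base_radius must be > 0")
  if (!is_scalar_number(stenosis_degree) || stenosis_degree < 0 ||
      stenosis_degree >= 1) {
    stop_input("invalid geometry: stenosis_degree must lie in [0, 1)")
  }
  assert_that(n_sections >= 1, "need at least one section")
  core_len <- max((n_sections + 1) * section_spacing, 4 * section_spacing)
  ext_len <- 5 * base_radius
  if (is.null(stenosis_width)) stenosis_width <- 0.6 * core_len

  if (kind == "bifurcation") {
    return(generate_bifurcation(base_radius, stenosis_degree, n_sections,
                                section_spacing, stenosis_width, n_circ,
                                axial_step, branch_angle_deg))
  }

  total_len <- core_len + 2 * ext_len
  z <- seq(0, total_len, by = axial_step)
  if (z[length(z)] < total_len) z <- c(z, total_len)
  radius <- rep(base_radius, length(z))
  throat_s <- NA_real_
  if (kind == "stenotic" && stenosis_degree > 0) {
    throat_s <- ext_len + core_len/2
    inb <- abs(z - throat_s) < stenosis_width/2
    # cosine bump: radius dips smoothly to (1 - degree) * base at the throat
    radius[inb] <- base_radius *
      (1 - stenosis_degree/2 * (1 + cos(2 * pi * (z[inb] - throat_s)/stenosis_width)))
  }
  seg <- ifelse(z < ext_len | z > ext_len + core_len, "extension", "CCA")
  cl <- cbind(x = 0, y = 0, z = z)
  mesh <- sweep_tube(cl, radius, n_circ)
  sections <- ext_len + section_spacing * seq_len(n_sections)

  structure(list(centerline_points = cl, arclength = z,
                 radius_profile = radius, segment_labels = seg,
                 plateau_radius = rep(base_radius, length(z)),
                 vertices = mesh$vertices, triangles = mesh$triangles,
                 ring_index = mesh$ring_index, ring_angle = mesh$ring_angle,
                 section_positions = sections, n_circ = n_circ, kind = kind,
                 base_radius = base_radius,
                 stenosis_degree = stenosis_degree,
                 stenosis_width = stenosis_width,
                 throat_arclength = throat_s),
            class = "vessel_geometry")
}

# Triangulated tube swept along a polyline centerline (rings of n_circ
# vertices in the local normal plane; straight centerlines use fixed frames).
sweep_tube <- function(centerline, radius, n_circ, axis = c(0, 0, 1)) {
  nr <- nrow(centerline)
  phi <- 2 * pi * (seq_len(n_circ) - 1)/n_circ
  # frame perpendicular to the (straight) axis
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  if (abs(axis[1]) > 0.9) { e1 <- c(0, 1, 0); e2 <- c(0, 0, 1) }
  axis <- axis/sqrt(sum(axis^2))
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1/sqrt(sum(e1^2))
  e2 <- cross3(axis, e1)
  verts <- matrix(0, nr * n_circ, 3)
  for (i in seq_len(nr)) {
    ring <- centerline[rep(i, n_circ), , drop = FALSE] +
      radius[i] * (outer(cos(phi), e1) + outer(sin(phi), e2))
    verts[(i - 1) * n_circ + seq_len(n_circ), ] <- ring
  }
  tri <- matrix(0L, 2 * (nr - 1) * n_circ, 3)
  k <- 1L
  for (i in seq_len(nr - 1)) {
    a <- (i - 1) * n_circ + seq_len(n_circ)
    b <- (i - 1) * n_circ + c(seq_len(n_circ)[-1], 1L)
    tri[k:(k + n_circ - 1), ] <- cbind(a, b, a + n_circ)
    tri[(k + n_circ):(k + 2 * n_circ - 1), ] <- cbind(b, b + n_circ, a + n_circ)
    k <- k + 2L * n_circ
  }
  list(vertices = verts, triangles = tri,
       ring_index = rep(seq_len(nr), each = n_circ),
       ring_angle = rep(phi, nr))
}

# Idealized planar-Y bifurcation: CCA trunk along +z, ICA/ECA branches in the
# x-z plane. Each segment is meshed as its own tube; the junction is not
# stitched watertight (binning and metrics are per-vertex and unaffected).
generate_bifurcation <- function(base_radius, stenosis_degree, n_sections,
                                 section_spacing, stenosis_width, n_circ,
                                 axial_step, branch_angle_deg) {
  ext_len <- 5 * base_radius
  cca_len <- max(4, ceiling(n_sections/2) + 1) * section_spacing
  br_rad <- base_radius * 0.75
  br_ext <- 5 * br_rad
  ica_core <- max(4, floor(n_sections/2) + 1) * section_spacing
  th <- branch_angle_deg * pi/180

  # CCA + extension, along z
  z_cca <- seq(0, ext_len + cca_len, by = axial_step)
  r_cca <- rep(base_radius, length(z_cca))
  cl_cca <- cbind(0, 0, z_cca)
  lab_cca <- ifelse(z_cca < ext_len, "extension", "CCA")

  apex <- c(0, 0, ext_len + cca_len)
  make_branch <- function(sign, label, degree) {
    s <- seq(axial_step, ica_core + br_ext, by = axial_step)
    dirv <- c(sign * sin(th), 0, cos(th))
    cl <- t(apex + outer(dirv, s))
    r <- rep(br_rad, length(s))
    if (degree > 0) {
      throat <- ica_core/2
      w <- min(stenosis_width, 0.8 * ica_core)
      inb <- abs(s - throat) < w/2
      r[inb] <- br_rad * (1 - degree/2 * (1 + cos(2 * pi * (s[inb] - throat)/w)))
    }
    lab <- ifelse(s > ica_core, "extension", label)
    list(cl = cl, r = r, lab = lab, s = s, dirv = dirv)
  }
  ica <- make_branch(+1, "ICA", stenosis_degree)
  eca <- make_branch(-1, "ECA", 0)

  m_cca <- sweep_tube(cl_cca, r_cca, n_circ)
  m_ica <- sweep_tube(ica$cl, ica$r, n_circ, axis = ica$dirv)
  m_eca <- sweep_tube(eca$cl, eca$r, n_circ, axis = eca$dirv)

  verts <- rbind(m_cca$vertices, m_ica$vertices, m_eca$vertices)
  off <- c(0L, nrow(m_cca$vertices), nrow(m_cca$vertices) + nrow(m_ica$vertices))
  tri <- rbind(m_cca$triangles,
               m_ica$triangles + off[2],
               m_eca$triangles + off[3])
  cl_all <- rbind(cl_cca, ica$cl, eca$cl)
  arc <- c(z_cca, max(z_cca) + ica$s, max(z_cca) + eca$s)
  ring_off <- c(0L, length(z_cca), length(z_cca) + length(ica$s))
  ring_index <- c(m_cca$ring_index, m_ica$ring_index + ring_off[2],
                  m_eca$ring_index + ring_off[3])
  lab <- c(lab_cca, ica$lab, eca$lab)
  rad <- c(r_cca, ica$r, eca$r)

  # sections along the CCA then continuing up the ICA
  n_cca_sec <- min(n_sections, floor(cca_len/section_spacing))
  sec_cca <- ext_len + section_spacing * seq_len(n_cca_sec)
  n_ica_sec <- n_sections - n_cca_sec
  sec_ica <- max(z_cca) + section_spacing * seq_len(n_ica_sec)
  structure(list(centerline_points = cl_all, arclength = arc,
                 radius_profile = rad, segment_labels = lab,
                 plateau_radius = c(rep(base_radius, length(z_cca)),
                                    rep(br_rad, length(ica$s)),
                                    rep(br_rad, length(eca$s))),
                 vertices = verts, triangles = tri,
                 ring_index = ring_index,
                 ring_angle = c(m_cca$ring_angle, m_ica$ring_angle,
                                m_eca$ring_angle),
                 section_positions = c(sec_cca, sec_ica), n_circ = n_circ,
                 kind = "bifurcation", base_radius = base_radius,
                 stenosis_degree = stenosis_degree,
                 stenosis_width = stenosis_width,
                 throat_arclength = if (stenosis_degree > 0)
                   max(z_cca) + ica_core/2 else NA_real_),
            class = "vessel_geometry")
}

#' Validate a vessel geometry
#'
#' Checks the structural invariants: strictly positive radii, strictly
#' increasing arclength within each segment run, and every surface vertex
#' lying within tolerance of its ring radius. Also rejects meshes with
#' zero-area triangles (mesh-quality guard used by the WSS field generator).
#'
#' @param geometry a `vessel_geometry`.
#' @param tol radial tolerance, mm.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_vessel_geometry <- function(geometry, tol = 1e-6) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  assert_that(all(geometry$radius_profile > 0), "radii must be positive")
  d <- geometry$vertices - geometry$centerline_points[geometry$ring_index, ]
  r <- row_norms(d)
  assert_that(max(abs(r - geometry$radius_profile[geometry$ring_index])) < tol,
              "vertex off its ring radius")
  v <- geometry$vertices; tr <- geometry$triangles
  a <- v[tr[, 2], ] - v[tr[, 1], ]
  b <- v[tr[, 3], ] - v[tr[, 1], ]
  cx <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- row_norms(cx)
  if (any(area2 <= .Machine$double.eps)) {
    stop_input("mesh-quality error: zero-area triangle present")
  }
  invisible(TRUE)
}
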