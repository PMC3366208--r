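## Parametric construction of the circular actin track and the two-headed
## myosin model at the three hierarchy levels (molecule -> domain -> SSE
## stick). All geometry is schematic: behaviour depends on centroids,
## binding-domain placement and leg length; sticks are retained for
## rendering and steric volume.

# leg lengths (nm) by IQ-motif count
LEG_LENGTH_TABLE <- c(`2` = 9.3, `4` = 14.60, `6` = 19.90)

# sphere radii (nm) of the schematic domains
ACTIN_UNIT_RADIUS <- 2.8
FOOT_CORE_RADIUS <- 3.0
BINDING_DOMAIN_RADIUS <- 0.7
IQ_SEGMENT_RADIUS <- 1.3

# foot template in the foot-local frame: x = heel->toe axis (plus end when
# aligned), z = away from the filament. The binding domains sit below the
# core centroid so that "both binding domains closer to the actin than the
# foot centroid" holds in a well-posed approach.
FOOT_TEMPLATE <- matrix(c(
   0.0, 0, 0.0,    # core
   2.2, 0, -2.5,   # toe binding domain
  -2.2, 0, -2.5),  # heel binding domain
  ncol = 3, byrow = TRUE,
  dimnames = list(c("core", "toe", "heel"), c("x", "y", "z")))

# pre-powerstroke leg elevation in the foot frame, measured from the foot
# normal (z) toward the toe (+x): the lever starts 13.55 degrees backward
# of the foot normal so that the 70 degree stroke carries it to 56.45
# degrees forward, i.e. 33.55 degrees off the filament axis.
PRESTROKE_LEG_ANGLE <- -13.55 * pi / 180

#' Build a closed circular actin filament track
#'
#' Constructs a ring of `n_dimers` actin dimer units with centres equally
#' spaced on a circle in the xy-plane (normal +z), the plus (barbed) end
#' direction being that of increasing unit index. Each unit carries two
#' monomer spheres and, per monomer, an outward-facing myosin-binding
#' domain whose azimuth follows the helical twist; the twist is distributed
#' so that an integer number of half repeats closes the ring with no seam.
#'
#' @param n_dimers number of actin dimer units (default 52).
#' @param unit_spacing distance between consecutive unit centres in nm
#'   (default 5.70).
#' @param half_repeat nominal half period of the filament helix in nm
#'   (default 36); rounded to the nearest integer number of half repeats
#'   around the ring.
#' @return object of class `actin_ring`.
#' @examples
#' ring <- build_actin_ring()
#' ring$circumference            # 296.4 nm
#' ring$circumference / pi       # diameter just over 90 nm
#' @export
build_actin_ring <- function(n_dimers = 52L, unit_spacing = 5.70,
                             half_repeat = 36) {
  if (n_dimers < 8) stop("n_dimers too small to close a ring without overlap")
  if (unit_spacing <= 0) stop("unit_spacing must be positive")
  n <- as.integer(n_dimers)
  circumference <- n * unit_spacing
  radius <- circumference / (2 * pi)
  n_half <- max(1L, round(circumference / half_repeat))
  twist_per_unit <- n_half * 180 / n    # degrees; closes seam exactly
  phi <- 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(radius * cos(phi), radius * sin(phi), 0)
  tangents <- cbind(-sin(phi), cos(phi), 0)    # plus direction
  radials <- cbind(cos(phi), sin(phi), 0)      # outward
  # per-unit twist angle (radians) of the binding azimuth about the tangent
  psi <- (seq_len(n) - 1) * twist_per_unit * pi / 180
  # monomers at +/- spacing/4 along the tangent, binding domains offset
  # outward from the (twisted) radial
  normals <- cbind(0, 0, rep(1, n))
  bind_dir <- function(psi_i, i) {
    # rotate the outward radial about the local tangent by the twist
    rotate_about(radials[i, ], tangents[i, ], psi_i)
  }
  binding_dirs <- t(vapply(seq_len(n),
                           function(i) bind_dir(psi[i], i), numeric(3)))
  structure(list(
    n_dimers = n, unit_spacing = unit_spacing,
    circumference = circumference, radius = radius,
    ring_center = c(0, 0, 0), ring_normal = c(0, 0, 1),
    plus_direction = 1L,
    n_half_repeats = n_half,
    half_repeat = circumference / n_half,
    twist_per_unit = twist_per_unit,
    unit_centers = centers, tangents = tangents, radials = radials,
    binding_dirs = binding_dirs,
    unit_radius = ACTIN_UNIT_RADIUS), class = "actin_ring")
}

#' @export
print.actin_ring <- function(x, ...) {
  cat(sprintf(paste0("actin ring: %d dimer units, spacing %.2f nm, ",
                     "circumference %.1f nm (diameter %.1f nm)\n"),
              x$n_dimers, x$unit_spacing, x$circumference,
              2 * x$radius))
  cat(sprintf("  %d half repeats of %.2f nm; twist %.2f deg/unit\n",
              x$n_half_repeats, x$half_repeat, x$twist_per_unit))
  invisible(x)
}

#' Cyclic unit index
#'
#' Wraps an arbitrary integer onto the 1-based cyclic unit indexing of a
#' ring of `n` units.
#' @param i integer (vector).
#' @param n ring size.
#' @return index in `1..n`.
#' @export
wrap_unit <- function(i, n) ((i - 1L) %% n) + 1L

#' Signed shortest arc between two units
#'
#' @param to,from 1-based unit indices.
#' @param n ring size.
#' @return signed offset in `(-n/2, n/2]`, positive toward the plus end.
#' @keywords internal
unit_offset <- function(to, from, n) {
  d <- (to - from) %% n
  ifelse(d > n / 2, d - n, d)
}

#' Build a two-headed myosin model
#'
#' Constructs a myosin dimer with `n_iq` IQ segments per leg in its native
#' (pre-powerstroke) conformation: two congruent halves joined at a common
#' virtual hinge point, each half a foot (core + toe + heel binding
#' domains) and a leg of IQ-segment spheres. Leg length follows the
#' 9.3 / 14.60 / 19.90 nm table for 2 / 4 / 6 IQ motifs.
#'
#' @param n_iq number of IQ segments per leg: 2, 4 or 6.
#' @return object of class `myosin_dimer`. Each half carries node
#'   coordinates `X` (rows core, toe, heel, seg1..segN, hinge), node radii,
#'   and binding-state bookkeeping (`state`, `swung`, `swing`,
#'   `bound_unit`).
#' @export
build_myosin_dimer <- function(n_iq = 6L) {
  if (!n_iq %in% c(2L, 4L, 6L)) stop("n_iq must be 2, 4 or 6")
  L <- unname(LEG_LENGTH_TABLE[as.character(n_iq)])
  n <- as.integer(n_iq)
  alpha0 <- PRESTROKE_LEG_ANGLE
  leg_dir <- c(sin(alpha0), 0, cos(alpha0))
  d <- L / (n + 1)
  segs <- t(vapply(seq_len(n), function(i) i * d * leg_dir, numeric(3)))
  hinge <- L * leg_dir
  X1 <- rbind(FOOT_TEMPLATE, segs, hinge = hinge)
  rownames(X1) <- c("core", "toe", "heel", paste0("iq", seq_len(n)), "hinge")
  # half 2: reflect half 1 through the vertical plane containing the hinge
  X2 <- X1
  X2[, 1] <- 2 * hinge[1] - X1[, 1]
  radii <- c(FOOT_CORE_RADIUS, BINDING_DOMAIN_RADIUS, BINDING_DOMAIN_RADIUS,
             rep(IQ_SEGMENT_RADIUS, n), 0)
  mk_half <- function(X) {
    list(X = X, radii = radii, n_iq = n, leg_length = L,
         state = 0L, swung = FALSE, swing = 0, bound_unit = NA_integer_,
         lap = 0L)
  }
  structure(list(n_iq = n, leg_length = L, seg_spacing = d,
                 halves = list(mk_half(X1), mk_half(X2))),
            class = "myosin_dimer")
}

#' @export
print.myosin_dimer <- function(x, ...) {
  cat(sprintf("myosin-V dimer: %d IQ segments per leg, leg length %.2f nm\n",
              x$n_iq, x$leg_length))
  sts <- vapply(x$halves, function(h)
    c("FREE", "LOOSE", "TIGHT")[h$state + 1L], "")
  cat(sprintf("  head states: %s / %s\n", sts[1], sts[2]))
  invisible(x)
}

## node index helpers for a half with n IQ segments
half_node_index <- function(n_iq) {
  list(core = 1L, toe = 2L, heel = 3L,
       segs = 3L + seq_len(n_iq), hinge = 4L + n_iq,
       n_nodes = 4L + n_iq)
}

#' Ideal bound pose of a myosin half on a ring unit
#'
#' Places the foot template in tight-binding registration on a given unit:
#' foot axis along the local plus tangent, binding face radially inward,
#' core resting on the unit sphere; the leg ascends at the pre-powerstroke
#' elevation (or at `swing` radians past it).
#'
#' @param ring `actin_ring`.
#' @param half a half from [build_myosin_dimer()].
#' @param unit 1-based unit index.
#' @param swing powerstroke angle already swung (radians).
#' @return node coordinate matrix for the half.
#' @keywords internal
ideal_bound_pose <- function(ring, half, unit, swing = 0) {
  i <- wrap_unit(unit, ring$n_dimers)
  t_hat <- ring$tangents[i, ]
  r_hat <- ring$radials[i, ]
  b_hat <- pracma_cross(r_hat, t_hat)
  Fm <- cbind(t_hat, b_hat, r_hat)            # local x,y,z -> world
  ## 0.3 nm clearance above hard contact so the seat is not in permanent
  ## steric conflict with the unit sphere
  core_pos <- ring$unit_centers[i, ] +
    (ring$unit_radius + FOOT_CORE_RADIUS + 0.3) * r_hat
  n <- half$n_iq
  L <- half$leg_length
  alpha <- PRESTROKE_LEG_ANGLE + swing
  leg_dir_loc <- c(sin(alpha), 0, cos(alpha))
  d <- L / (n + 1)
  Xloc <- rbind(FOOT_TEMPLATE,
                t(vapply(seq_len(n), function(k) k * d * leg_dir_loc,
                         numeric(3))),
                L * leg_dir_loc)
  sweep(Xloc %*% t(Fm), 2, core_pos, `+`)
}

#' Binding restraint target distances
#'
#' Distances from the foot domains to the outward binding-site points of
#' the central and neighbouring actin units, measured in the ideal bound
#' pose on the actual ring geometry (so filament curvature is accounted
#' for). Restraining to surface site points rather than unit centres pins
#' the azimuth of the foot around the filament, which distances to the
#' (nearly collinear) unit centres cannot do.
#'
#' @param ring `actin_ring`.
#' @return named numeric: `core_site`, `toe_site`, `toe_plus`,
#'   `heel_site`, `heel_minus`, plus `core_central` (centre-to-centre
#'   seat distance, used by the optional initial attraction).
#' @keywords internal
binding_targets <- function(ring) {
  dummy <- build_myosin_dimer(2L)
  Xi <- ideal_bound_pose(ring, dummy$halves[[1]], 1L)
  site_of <- function(i) {
    i <- wrap_unit(i, ring$n_dimers)
    ring$unit_centers[i, ] + ring$unit_radius * ring$radials[i, ]
  }
  c(core_site = vnorm(Xi[1, ] - site_of(1L)),
    toe_site = vnorm(Xi[2, ] - site_of(1L)),
    toe_plus = vnorm(Xi[2, ] - site_of(2L)),
    heel_site = vnorm(Xi[3, ] - site_of(1L)),
    heel_minus = vnorm(Xi[3, ] - site_of(0L)),
    core_central = ring$unit_radius + FOOT_CORE_RADIUS)
}

#' Place a myosin dimer at its starting position on the track
#'
#' Half 1 is posed in ideal binding registration on `start_unit` (well
#' inside the loose-capture distance, so it is captured on the first
#' binding update); half 2 shares the common hinge point and is rotated up
#' and away from the filament so that it starts free.
#'
#' @param ring `actin_ring`.
#' @param dimer `myosin_dimer`.
#' @param start_unit 1-based unit index for the bound half.
#' @return the dimer with placed coordinates and `start_unit` recorded.
#' @export
place_dimer_initial <- function(ring, dimer, start_unit = 1L) {
  i <- wrap_unit(start_unit, ring$n_dimers)
  idx <- half_node_index(dimer$n_iq)
  X1 <- ideal_bound_pose(ring, dimer$halves[[1]], i)
  hinge <- X1[idx$hinge, ]
  b_hat <- pracma_cross(ring$radials[i, ], ring$tangents[i, ])
  # swing half 2 up over the hinge, foot away from the track
  X2 <- rotate_about(X1, b_hat, -140 * pi / 180, pivot = hinge)
  # steric check against the ring
  for (X in list(X1, X2)) {
    dd <- sqrt(outer(rowSums(X^2), rep(1, ring$n_dimers)) -
                 2 * X %*% t(ring$unit_centers) +
                 outer(rep(1, nrow(X)), rowSums(ring$unit_centers^2)))
    lim <- outer(dimer$halves[[1]]$radii, rep(ring$unit_radius, ring$n_dimers),
                 `+`)
    keep <- dimer$halves[[1]]$radii > 0
    if (any(dd[keep, ] < lim[keep, ] - 0.5))
      stop("initial placement collides with the actin ring")
  }
  dimer$halves[[1]]$X <- X1
  dimer$halves[[2]]$X <- X2
  dimer$start_unit <- i
  dimer$ring_axis_distance <- c(
    axis_distance(foot_centroid(X1), ring),
    axis_distance(foot_centroid(X2), ring))
  dimer
}

#' Distance from a point to the filament axis (ring centreline)
#'
#' @param p point (length-3) or n x 3 matrix.
#' @param ring `actin_ring`.
#' @return distance(s) in nm to the circular centreline.
#' @export
axis_distance <- function(p, ring) {
  one <- is.null(dim(p))
  if (one) p <- matrix(p, 1, 3)
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  out <- sqrt((rho - ring$radius)^2 + p[, 3]^2)
  if (one) out[1] else out
}

## centroid of the foot (core + toe + heel)
foot_centroid <- function(X) colMeans(X[1:3, , drop = FALSE])
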