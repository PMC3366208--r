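## Three-level hierarchic representation: molecule -> domain -> SSE stick.
## The simulator moves the schematic domain spheres; this module provides
## the full nested structure with bounding volumes for rendering, JSON
## export and containment checks.

ALPHA_STICK_RADIUS <- 1.0
BETA_STICK_RADIUS <- 0.5

#' Create an SSE stick
#'
#' Secondary-structure elements are reduced to their axial line segments;
#' alpha helices are rendered thicker than beta strands.
#'
#' @param end_a,end_b stick endpoints (length-3, nm).
#' @param kind `"alpha"` or `"beta"`.
#' @param radius stick radius in nm; defaults by kind.
#' @return list of class `sse_stick`.
#' @export
sse_stick <- function(end_a, end_b, kind = c("alpha", "beta"),
                      radius = NULL) {
  kind <- match.arg(kind)
  if (is.null(radius))
    radius <- if (kind == "alpha") ALPHA_STICK_RADIUS else BETA_STICK_RADIUS
  if (radius <= 0) stop("stick radius must be positive")
  if (vnorm(end_a - end_b) < 1e-9) stop("degenerate stick: end_a == end_b")
  structure(list(end_a = end_a, end_b = end_b, radius = radius, kind = kind),
            class = "sse_stick")
}

#' Create a domain node
#'
#' A domain groups SSE sticks under a bounding sphere that contains all
#' stick endpoints plus their radii.
#'
#' @param id character identifier.
#' @param role one of the domain role tags (`foot_core`, `toe_binding`,
#'   `heel_binding`, `iq_segment`, `actin_core`, `actin_myosin_binding`).
#' @param sticks list of [sse_stick()] objects.
#' @param centroid optional centroid override; defaults to the mean of the
#'   stick endpoints.
#' @return list of class `domain_node`.
#' @export
domain_node <- function(id, role, sticks, centroid = NULL) {
  pts <- do.call(rbind, lapply(sticks, function(s) rbind(s$end_a, s$end_b)))
  if (is.null(centroid)) centroid <- colMeans(pts)
  rads <- rep(vapply(sticks, function(s) s$radius, 0), each = 2)
  br <- max(sqrt(rowSums(sweep(pts, 2, centroid)^2)) + rads)
  structure(list(id = id, role = role, centroid = centroid,
                 bounding_radius = br, children = sticks),
            class = "domain_node")
}

#' Create a molecule node over a set of domains
#'
#' @param id character identifier.
#' @param domains list of [domain_node()] objects.
#' @return list of class `molecule_node` whose bounding sphere contains all
#'   child domain spheres.
#' @export
molecule_node <- function(id, domains) {
  cents <- do.call(rbind, lapply(domains, function(d) d$centroid))
  centroid <- colMeans(cents)
  br <- max(sqrt(rowSums(sweep(cents, 2, centroid)^2)) +
              vapply(domains, function(d) d$bounding_radius, 0))
  structure(list(id = id, centroid = centroid, bounding_radius = br,
                 children = domains),
            class = "molecule_node")
}

#' Expand a model into its molecule/domain/stick hierarchy
#'
#' @param x an `actin_ring` or `myosin_dimer`.
#' @param ... unused.
#' @return a `molecule_node` (ring) or list of two `molecule_node`s (dimer
#'   halves).
#' @export
as_hierarchy <- function(x, ...) UseMethod("as_hierarchy")

#' @export
as_hierarchy.actin_ring <- function(x, ...) {
  n <- x$n_dimers
  sp <- x$unit_spacing
  domains <- list()
  for (i in seq_len(n)) {
    ctr <- x$unit_centers[i, ]
    t_hat <- x$tangents[i, ]
    for (m in c(-1, 1)) {  # two monomers per dimer unit
      mon_ctr <- ctr + m * sp / 4 * t_hat
      # monomer twist: halfway step between unit twists
      psi <- (i - 1 + (m + 1) / 4) * x$twist_per_unit * pi / 180
      bdir <- rotate_about(x$radials[i, ], t_hat, psi)
      mono <- domain_node(
        sprintf("actin%03d%s", i, if (m < 0) "a" else "b"), "actin_core",
        list(sse_stick(mon_ctr - 1.4 * t_hat, mon_ctr + 1.4 * t_hat,
                       "alpha")),
        centroid = mon_ctr)
      bctr <- mon_ctr + (x$unit_radius + 0.8) * bdir
      bnd <- domain_node(
        sprintf("abind%03d%s", i, if (m < 0) "a" else "b"),
        "actin_myosin_binding",
        list(sse_stick(bctr - 0.8 * t_hat, bctr + 0.8 * t_hat, "beta")),
        centroid = bctr)
      domains <- c(domains, list(mono, bnd))
    }
  }
  molecule_node("actin_ring", domains)
}

#' @export
as_hierarchy.myosin_dimer <- function(x, ...) {
  idx <- half_node_index(x$n_iq)
  lapply(1:2, function(h) {
    X <- x$halves[[h]]$X
    up <- vhat(X[idx$core, ] - (X[idx$toe, ] + X[idx$heel, ]) / 2)
    axis <- vhat(X[idx$toe, ] - X[idx$heel, ])
    core <- domain_node(
      sprintf("foot_core_%d", h), "foot_core",
      list(sse_stick(X[idx$core, ] - 1.8 * axis, X[idx$core, ] + 1.8 * axis,
                     "alpha"),
           sse_stick(X[idx$core, ] - 1.5 * up, X[idx$core, ] + 1.5 * up,
                     "alpha")),
      centroid = X[idx$core, ])
    toe <- domain_node(sprintf("toe_%d", h), "toe_binding",
                       list(sse_stick(X[idx$toe, ] - 0.6 * axis,
                                      X[idx$toe, ] + 0.6 * axis, "beta")),
                       centroid = X[idx$toe, ])
    heel <- domain_node(sprintf("heel_%d", h), "heel_binding",
                        list(sse_stick(X[idx$heel, ] - 0.6 * axis,
                                       X[idx$heel, ] + 0.6 * axis, "beta")),
                        centroid = X[idx$heel, ])
    segs <- lapply(seq_along(idx$segs), function(k) {
      p <- X[idx$segs[k], ]
      nxt <- if (k < length(idx$segs)) X[idx$segs[k + 1], ] else X[idx$hinge, ]
      dirv <- vhat(nxt - p)
      domain_node(sprintf("iq%d_%d", k, h), "iq_segment",
                  list(sse_stick(p - 0.9 * dirv, p + 0.9 * dirv, "alpha")),
                  centroid = p)
    })
    molecule_node(sprintf("myosin_half_%d", h),
                  c(list(core, toe, heel), segs))
  })
}

#' Check hierarchy containment invariants
#'
#' Verifies that every stick endpoint (inflated by its radius) lies inside
#' its domain bounding sphere, and every domain sphere inside its molecule
#' sphere.
#'
#' @param node a `molecule_node`.
#' @param tol numeric slack in nm.
#' @return `TRUE` (invisibly) or an error.
#' @export
check_containment <- function(node, tol = 1e-9) {
  for (d in node$children) {
    dd <- vnorm(d$centroid - node$centroid) + d$bounding_radius
    if (dd > node$bounding_radius + tol)
      stop("domain ", d$id, " escapes molecule bounding volume")
    for (s in d$children) {
      for (e in list(s$end_a, s$end_b)) {
        if (vnorm(e - d$centroid) + s$radius > d$bounding_radius + tol)
          stop("stick endpoint escapes domain ", d$id)
      }
    }
  }
  invisible(TRUE)
}
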