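## Inertia-free fixed-step dynamics primitives: random rigid moves with
## state-dependent damping, pairwise distance restraints with equal and
## opposite reaction, and hinge restoration. The only "forces" in the model
## are restraint correction steps and steric push-apart; there is no
## thermal-energy calibration and no inertia (a node's move at frame t is
## independent of its move at t-1).

#' Move specification for one hierarchy level
#'
#' @param translation_step translation magnitude in nm per frame.
#' @param rotation_step rotation magnitude in radians per frame.
#' @param damping_translation,damping_rotation dimensionless divisors
#'   (>= 1); `Inf` is the "no random translational motion" sentinel.
#' @return list of class `move_spec`.
#' @export
move_spec <- function(translation_step = 0.5, rotation_step = 0.05,
                      damping_translation = 1, damping_rotation = 1) {
  if (translation_step < 0 || rotation_step < 0)
    stop("step sizes must be >= 0")
  if (damping_translation < 1 || damping_rotation < 1)
    stop("damping divisors must be >= 1")
  structure(list(translation_step = translation_step,
                 rotation_step = rotation_step,
                 damping_translation = damping_translation,
                 damping_rotation = damping_rotation),
            class = "move_spec")
}

#' Random rigid move of a node group
#'
#' Translates all rows of `X` by a uniformly random direction times
#' `translation_step / damping_translation` and rotates them rigidly about
#' a random axis through the pivot by
#' `rotation_step / damping_rotation`. Infinite translation damping
#' freezes translation entirely. Consumes the global RNG stream.
#'
#' @param X n x 3 coordinate matrix (child nodes move rigidly with it).
#' @param move a [move_spec()].
#' @param pivot rotation centre; defaults to the centroid of `X`.
#' @return displaced coordinate matrix.
#' @export
random_move <- function(X, move, pivot = NULL) {
  one <- is.null(dim(X))
  if (one) X <- matrix(X, 1, 3)
  if (is.null(pivot)) pivot <- colMeans(X)
  step <- move$translation_step / move$damping_translation
  if (is.finite(step) && step > 0) {
    X <- sweep(X, 2, step * random_unit_vectors(1)[1, ], `+`)
  }
  ang <- move$rotation_step / move$damping_rotation
  if (is.finite(ang) && ang > 0 && nrow(X) > 1) {
    X <- rotate_about(X, random_unit_vectors(1)[1, ], ang, pivot = pivot)
  }
  if (one) X[1, ] else X
}

#' State-dependent damping schedule
#'
#' Returns the (translation, rotation) damping divisors for a head in the
#' given binding state: free heads move undamped; initial loose capture
#' damps translation five-fold; a loosely bound head close to the filament
#' loses random translation and has ten-fold damped rotation; tight
#' binding damps rotation by a further factor of ten.
#'
#' @param state binding state (0 free, 1 loose, 2 tight).
#' @param in_zone logical: inside the loose-binding interaction zone.
#' @return numeric `c(translation, rotation)` divisors (`Inf` = frozen).
#' @export
damping_schedule <- function(state, in_zone = FALSE) {
  if (state == 0L) c(1, 1)
  else if (state == 1L && !in_zone) c(5, 1)
  else if (state == 1L) c(Inf, 10)
  else c(Inf, 100)
}

#' Apply a single distance restraint
#'
#' If the separation deviates from the target by more than the tolerance,
#' both endpoints are shifted along the separation line toward the target,
#' by at most `correction_step` of separation change split equally between
#' the two ends (an immobile end routes the full shift to the other side).
#' One-sided restraints act only when the pair is too far apart
#' (attraction without repulsion). Coincident endpoints with a non-zero
#' target are broken by a small random perturbation.
#'
#' @param x_a,x_b endpoint positions (length-3).
#' @param target target distance in nm (>= 0).
#' @param correction_step maximum separation change per application (nm).
#' @param tolerance dead-band in nm.
#' @param mobile_a,mobile_b logical; an immobile end does not move.
#' @param one_sided logical; `TRUE` makes the restraint attractive only.
#' @return list with new positions `a` and `b`.
#' @export
apply_restraint <- function(x_a, x_b, target, correction_step = 0.25,
                            tolerance = 0.05, mobile_a = TRUE,
                            mobile_b = TRUE, one_sided = FALSE) {
  if (target < 0) stop("target distance must be >= 0")
  v <- x_a - x_b
  d <- vnorm(v)
  if (d < 1e-9 && target > tolerance) {
    # tie-break: random separation direction, then correct
    v <- 1e-6 * random_unit_vectors(1)[1, ]
    d <- vnorm(v)
  }
  viol <- d - target
  if (abs(viol) <= tolerance || (one_sided && viol < 0))
    return(list(a = x_a, b = x_b))
  u <- if (d < 1e-9) random_unit_vectors(1)[1, ] else v / d
  shift <- sign(viol) * min(correction_step, abs(viol))
  if (mobile_a && mobile_b) {
    list(a = x_a - (shift / 2) * u, b = x_b + (shift / 2) * u)
  } else if (mobile_a) {
    list(a = x_a - shift * u, b = x_b)
  } else if (mobile_b) {
    list(a = x_a, b = x_b + shift * u)
  } else list(a = x_a, b = x_b)
}

## Vectorised restraint pass over a table of pairs.
## tab columns: i, j (row indices into X), target, step, one_sided
## (0 = two-sided, 1 = attract-only, -1 = repel-only) and optionally w_i,
## the fraction of the correction routed to node i (default 0.5 =
## symmetric; 0 flags node i immobile for this pair).
## Returns the displacement matrix to add to X.
apply_restraints_batch <- function(X, tab, tolerance = 0.05) {
  delta <- matrix(0, nrow(X), 3)
  if (is.null(tab) || nrow(tab) == 0) return(delta)
  I <- tab[, 1]; J <- tab[, 2]
  wi <- if (ncol(tab) >= 6) tab[, 6] else rep(0.5, nrow(tab))
  v <- X[I, , drop = FALSE] - X[J, , drop = FALSE]
  d <- sqrt(rowSums(v * v))
  zero <- d < 1e-9
  if (any(zero)) {
    v[zero, ] <- 1e-6 * random_unit_vectors(sum(zero))
    d[zero] <- 1e-6
  }
  viol <- d - tab[, 3]
  act <- abs(viol) > tolerance & !(tab[, 5] > 0 & viol < 0) &
    !(tab[, 5] < 0 & viol > 0)
  if (!any(act)) return(delta)
  I <- I[act]; J <- J[act]; wi <- wi[act]
  u <- v[act, , drop = FALSE] / d[act]
  ## proportional correction, capped at the fixed step: behaves like a
  ## stiff spring near the target and like a fixed-size displacement when
  ## far, so frustrated multi-restraint states relax instead of stalling
  shift <- sign(viol[act]) * pmin(tab[act, 4], 0.75 * abs(viol[act]))
  contrib <- rbind(-shift * wi * u, shift * (1 - wi) * u)
  ids <- c(I, J)
  acc <- rowsum(contrib, group = ids)
  rows <- as.integer(rownames(acc))
  delta[rows, ] <- delta[rows, ] + acc
  delta
}

## Restraints from a node toward a fixed point rigidly attached to another
## node (e.g. the binding site on an actin unit). ptab columns: node row,
## px, py, pz, target, step, one_sided, reaction row. The correction is
## split equally between the node and the carrier of the point, keeping
## the reaction symmetry of pair restraints.
apply_point_restraints_batch <- function(X, ptab, tolerance = 0.05) {
  delta <- matrix(0, nrow(X), 3)
  if (is.null(ptab) || nrow(ptab) == 0) return(delta)
  I <- ptab[, 1]
  v <- X[I, , drop = FALSE] - ptab[, 2:4, drop = FALSE]
  d <- sqrt(rowSums(v * v))
  zero <- d < 1e-9
  if (any(zero)) {
    v[zero, ] <- 1e-6 * random_unit_vectors(sum(zero))
    d[zero] <- 1e-6
  }
  viol <- d - ptab[, 5]
  act <- abs(viol) > tolerance & !(ptab[, 7] > 0 & viol < 0) &
    !(ptab[, 7] < 0 & viol > 0)
  if (!any(act)) return(delta)
  I <- I[act]; R <- ptab[act, 8]
  u <- v[act, , drop = FALSE] / d[act]
  shift <- sign(viol[act]) * pmin(ptab[act, 6], 0.75 * abs(viol[act])) / 2
  contrib <- rbind(-shift * u, shift * u)
  acc <- rowsum(contrib, group = c(I, R))
  rows <- as.integer(rownames(acc))
  delta[rows, ] <- delta[rows, ] + acc
  delta
}

#' Which half moves during hinge restoration
#'
#' Encodes the restoration rules for the dimer hip joint: with both heads
#' free, both halves translate to the common midpoint; with one bound and
#' one free, only the free half moves; tight + loose moves the loose half
#' only; equal bound states (both loose or both tight) pick a half at
#' random.
#'
#' @param state1,state2 binding states (0/1/2).
#' @param u uniform random draw in `[0, 1)` used only for the tie cases.
#' @return 0 (both halves move half-way), 1 or 2 (that half moves fully).
#' @export
hinge_restore_side <- function(state1, state2, u = stats::runif(1)) {
  if (state1 == 0L && state2 == 0L) return(0L)
  if (state1 == 0L) return(1L)
  if (state2 == 0L) return(2L)
  if (state1 == 2L && state2 == 1L) return(2L)
  if (state1 == 1L && state2 == 2L) return(1L)
  if (u < 0.5) 1L else 2L
}

#' Restore the common virtual hinge point of a dimer
#'
#' Translates one or both halves rigidly so the two virtual hinge points
#' coincide, according to the binding-state rules of
#' [hinge_restore_side()]. The translation never rotates a half, so a
#' bound foot is disturbed only when its own half is chosen.
#'
#' @param dimer placed `myosin_dimer`.
#' @return the dimer with restored hinge.
#' @export
maintain_hinge <- function(dimer) {
  idx <- half_node_index(dimer$n_iq)
  h1 <- dimer$halves[[1]]$X[idx$hinge, ]
  h2 <- dimer$halves[[2]]$X[idx$hinge, ]
  side <- hinge_restore_side(dimer$halves[[1]]$state,
                             dimer$halves[[2]]$state)
  if (side == 0L) {
    m <- (h1 + h2) / 2
    dimer$halves[[1]]$X <- sweep(dimer$halves[[1]]$X, 2, m - h1, `+`)
    dimer$halves[[2]]$X <- sweep(dimer$halves[[2]]$X, 2, m - h2, `+`)
  } else if (side == 1L) {
    dimer$halves[[1]]$X <- sweep(dimer$halves[[1]]$X, 2, h2 - h1, `+`)
  } else {
    dimer$halves[[2]]$X <- sweep(dimer$halves[[2]]$X, 2, h1 - h2, `+`)
  }
  dimer
}
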