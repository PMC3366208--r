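## The actin-myosin binding state machine: loose capture within 15 nm of
## the filament axis, zone-gated loose restraints, tight binding with
## toe/heel polarity and non-physical yaw/roll correction, the incremental
## 70 degree powerstroke, the recovery stroke and the optional forced
## ratchet. No nucleotide species are modelled; the conformational states
## correspond to stages of the ATPase cycle (loose ~ ADP-Pi, tight
## post-powerstroke ~ rigor, recovery ~ hydrolysis re-priming).

#' Binding parameters
#'
#' @param capture_axis_distance loose-capture distance from the filament
#'   axis in nm (default 15).
#' @param zone distance (nm) within which the loose-binding restraints on
#'   the binding domains are activated (default 12). Values below 3 are
#'   interpreted as the legacy tenth-of-nm convention and multiplied by 10.
#' @param align_tolerance yaw/roll tolerance (radians) required for the
#'   powerstroke (default 1.0, about 60 degrees).
#' @param tight_distance axis distance (nm) within which a loosely bound,
#'   well-oriented foot attempts (and maintains) tight binding; about
#'   2 nm above the seated contact distance, so tight binding demotes
#'   cleanly when strain lifts the foot (default 7).
#' @param initial_attraction logical; add the weak foot-to-actin
#'   attraction on first capture (default `FALSE`, the "initial attraction
#'   off" default).
#' @param powerstroke_total total powerstroke rotation in radians
#'   (70 degrees).
#' @param powerstroke_step rotation per eligible frame (0.05 rad).
#' @param recovery_step reverse rotation per free frame (0.1 rad, double
#'   the powerstroke rate; binding is forbidden during recovery).
#' @param yawroll_step maximum per-frame non-physical yaw/roll correction
#'   in radians.
#' @return list of class `binding_params`.
#' @export
binding_params <- function(capture_axis_distance = 15, zone = 12,
                           align_tolerance = 1.0, tight_distance = 7,
                           initial_attraction = FALSE,
                           powerstroke_total = 70 * pi / 180,
                           powerstroke_step = 0.05, recovery_step = 0.1,
                           yawroll_step = 0.05) {
  if (zone < 3) {
    warning("zone < 3 nm: interpreting as legacy tenths (zone * 10 nm)")
    zone <- zone * 10
  }
  if (zone <= 0 || zone > capture_axis_distance)
    stop("need 0 < zone <= capture_axis_distance")
  if (align_tolerance <= 0) stop("align_tolerance must be positive")
  structure(list(capture_axis_distance = capture_axis_distance,
                 zone = zone, align_tolerance = align_tolerance,
                 tight_distance = tight_distance,
                 initial_attraction = initial_attraction,
                 powerstroke_total = powerstroke_total,
                 powerstroke_step = powerstroke_step,
                 recovery_step = recovery_step,
                 yawroll_step = yawroll_step),
            class = "binding_params")
}

#' Foot orientation frame from the three foot domains
#'
#' @param core,toe,heel foot domain centres.
#' @return list with unit vectors `x_f` (heel to toe axis), `z_f`
#'   (binding-face "up", away from the filament when bound), `y_f`, and
#'   the foot `centroid`.
#' @keywords internal
foot_frame <- function(core, toe, heel) {
  x_f <- vhat(toe - heel)
  up_raw <- core - (toe + heel) / 2
  up_raw <- up_raw - sum(up_raw * x_f) * x_f
  z_f <- vhat(up_raw)
  list(x_f = x_f, z_f = z_f, y_f = pracma_cross(z_f, x_f),
       centroid = (core + toe + heel) / 3)
}

#' Yaw, roll and tilt of a myosin foot relative to the filament
#'
#' Yaw is the signed angle between the heel-to-toe foot axis and the local
#' plus-end tangent, measured about the outward radial; roll is the signed
#' angle of the foot normal away from the outward radial, measured about
#' the foot axis; tilt (the fore-aft pitch of the foot axis out of the
#' filament surface plane) is reported but never corrected.
#'
#' @param X_foot matrix whose first three rows are core, toe, heel (a half
#'   node matrix works directly).
#' @param ring `actin_ring`.
#' @param capture maximum axis distance at which alignment is defined
#'   (default 15 nm); beyond it an error is thrown.
#' @return list with `yaw`, `roll`, `tilt` (radians), the local frame
#'   `t_hat`, `r_hat`, and the foot frame.
#' @export
compute_alignment <- function(X_foot, ring, capture = 15) {
  core <- X_foot[1, ]; toe <- X_foot[2, ]; heel <- X_foot[3, ]
  ff <- foot_frame(core, toe, heel)
  p <- ff$centroid
  ad <- axis_distance(p, ring)
  if (ad > capture)
    stop("foot is beyond the capture range; alignment undefined")
  phi <- atan2(p[2], p[1])
  q <- ring$radius * c(cos(phi), sin(phi), 0)    # nearest axis point
  t_hat <- c(-sin(phi), cos(phi), 0) * ring$plus_direction
  r_raw <- p - q
  r_hat <- if (vnorm(r_raw) < 1e-9) c(cos(phi), sin(phi), 0) else vhat(r_raw)
  yaw <- signed_angle_about(t_hat, ff$x_f, r_hat)
  roll <- signed_angle_about(r_hat, ff$z_f, ff$x_f)
  tilt <- asin(max(-1, min(1, sum(ff$x_f * r_hat))))
  list(yaw = yaw, roll = roll, tilt = tilt,
       t_hat = t_hat, r_hat = r_hat, frame = ff, axis_dist = ad)
}

#' One binding-state transition for a head
#'
#' Pure transition function of the two-stage binding machine, total over
#' all (state, geometry) inputs: free heads are captured within the
#' capture distance; loosely bound heads are promoted to tight when both
#' binding domains lie closer to the filament axis than the foot centroid
#' (inside the zone); tight binding is demoted by the same criteria, and
#' loose binding is lost beyond the capture distance.
#'
#' @param state current state (0 free, 1 loose, 2 tight).
#' @param ad axis distance of the foot centroid (nm).
#' @param ad_toe,ad_heel axis distances of the binding domains (nm).
#' @param params [binding_params()].
#' @param binding_allowed `FALSE` during the recovery stroke.
#' @param ad_core axis distance of the foot core domain; the orientation
#'   criterion compares the binding domains against the foot body proper
#'   (defaults to `ad`).
#' @return list with `state` (new state) and `in_zone`.
#' @export
binding_transition <- function(state, ad, ad_toe, ad_heel, params,
                               binding_allowed = TRUE, ad_core = ad) {
  in_zone <- ad < params$zone
  oriented <- ad_toe < ad_core && ad_heel < ad_core
  new_state <-
    if (!binding_allowed) 0L
    else if (ad >= params$capture_axis_distance) 0L
    else if (state >= 1L && in_zone && oriented &&
             ad < params$tight_distance) 2L
    else 1L
  list(state = new_state, in_zone = in_zone)
}

#' Advance the powerstroke of a tightly bound head
#'
#' The 70 degree lever swing proceeds in 0.05 rad increments, one per
#' frame on which the head is tightly bound and aligned within the yaw and
#' roll tolerance; on completion the head is flagged `swung`
#' (post-powerstroke). A mid-swing loss of tight binding or alignment
#' halts the swing at its current angle and reverts the head to loose
#' binding (handled by the caller via the returned `revert` flag).
#'
#' @param half myosin half (list with `state`, `swung`, `swing`).
#' @param params [binding_params()].
#' @param aligned logical: yaw and roll within tolerance.
#' @return the half, updated; field `revert` is `TRUE` when a mid-swing
#'   head lost eligibility this frame.
#' @export
powerstroke_step <- function(half, params, aligned = TRUE) {
  half$revert <- FALSE
  if (half$swung) return(half)
  eligible <- half$state == 2L && aligned
  if (eligible && half$swing < params$powerstroke_total) {
    half$swing <- min(half$swing + params$powerstroke_step,
                      params$powerstroke_total)
    if (half$swing >= params$powerstroke_total) half$swung <- TRUE
  } else if (!eligible && half$swing > 0 && half$state == 2L) {
    half$revert <- TRUE   # lost alignment mid-swing: revert to loose
  }
  half
}

#' Advance the recovery stroke of a free post-powerstroke head
#'
#' A free head in the swung conformation re-primes its lever at double
#' the powerstroke rate; binding is forbidden until the lever returns to
#' the pre-powerstroke angle, when `swung` is cleared.
#'
#' @param half myosin half.
#' @param params [binding_params()].
#' @return the half, updated; field `binding_allowed` reports whether the
#'   head may bind this frame.
#' @export
recovery_step <- function(half, params) {
  half$binding_allowed <- TRUE
  if (half$state != 0L) return(half)
  if (half$swung) {
    half$binding_allowed <- FALSE
    half$swing <- max(0, half$swing - params$recovery_step)
    if (half$swing <= 0) {
      half$swung <- FALSE
      half$binding_allowed <- TRUE
    }
  } else if (half$swing > 0) {
    # a halted partial swing relaxes at the same rate; such a head never
    # completed its stroke and remains binding-competent
    half$swing <- max(0, half$swing - params$recovery_step)
  }
  half
}

#' Forced ratchet release of the trailing head
#'
#' Variant rule: when the leading head attains tight binding while the
#' trailing head is in its post-powerstroke conformation, the trailing
#' head is set free in place (no immediate change of position).
#'
#' @param states integer vector of the two head states.
#' @param swungs logical vector.
#' @param upos numeric cumulative positions of the heads.
#' @param just_tight logical vector: attained tight binding this frame.
#' @return 0 if no release, else the index (1 or 2) of the head to free.
#' @export
ratchet_release <- function(states, swungs, upos, just_tight) {
  for (h in 1:2) {
    o <- 3 - h
    if (just_tight[h] && states[o] == 2L && swungs[o] &&
        !is.na(upos[h]) && !is.na(upos[o]) && upos[h] > upos[o])
      return(o)
  }
  0L
}
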