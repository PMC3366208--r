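## Synthetic staircase trajectories with known ground truth: programmed
## step separations, exponential dwell durations and fixed search gaps.
## These are the test harness for the analysis operations (round-trip
## recovery of steps, dwell rates, duty ratios).

#' Generate a synthetic staircase trajectory
#'
#' Builds a trajectory in which the two heads alternate programmed,
#' discrete stepping events separated by exponentially distributed
#' both-bound dwells and fixed one-head-free search gaps.
#'
#' Each element of `seps` programs one stepping event: a positive value
#' `s` detaches the trailing head and rebinds it `s` units ahead of the
#' leading head (a forward step with new separation `s`); a negative
#' value `-s` detaches the *leading* head and rebinds it `s` units ahead
#' of the trailing head -- when `s` is smaller than the current
#' separation this is a backstep (the dimer midpoint moves backward).
#'
#' @param seps signed integer step separations (units); none may be 0 and
#'   no event may reproduce the previous configuration.
#' @param k_dwell exponential dwell rate per frame; durations are drawn
#'   as `max(1, round(rexp(1, k_dwell)))`.
#' @param seed RNG seed.
#' @param initial_sep separation of the initial both-bound configuration.
#' @param search_frames fixed duration of the one-head-free gap between
#'   events.
#' @param n_units,spacing track geometry.
#' @param start 1-based starting unit of head 1 (shared distance origin).
#' @return `myo_trajectory` with ground truth attached as attributes
#'   `expected_steps` (data frame `separation`, `direction`),
#'   `dwell_durations` and `k_dwell`.
#' @export
make_fixture_staircase <- function(seps, k_dwell = 0.01, seed = 1L,
                                   initial_sep = 3L, search_frames = 20L,
                                   n_units = 52L, spacing = 5.70,
                                   start = 1L) {
  if (any(seps == 0)) stop("step separations must be non-zero")
  set.seed(as.integer(seed))
  n_ev <- length(seps) + 1L             # initial config + programmed steps
  dwell <- pmax(1, round(stats::rexp(n_ev, k_dwell)))
  d <- c(0, initial_sep)                # cumulative positions, shared origin
  configs <- matrix(NA_real_, n_ev, 2)
  mover <- integer(n_ev)                # head freed before event i (0 = none)
  configs[1, ] <- d
  for (i in seq_along(seps)) {
    s <- seps[i]
    lead <- which.max(d); trail <- 3L - lead
    if (s > 0) {                        # trailing head steps past the lead
      d[trail] <- d[lead] + s
      mover[i + 1L] <- trail
    } else {                            # leading head rebinds near the trail
      d[lead] <- d[trail] - s           # -s = |s| ahead of the trailing head
      mover[i + 1L] <- lead
    }
    if (all(configs[i, ] == d))
      stop("step ", i, " reproduces the previous configuration")
    configs[i + 1L, ] <- d
  }

  n_frames <- sum(dwell) + (n_ev - 1L) * search_frames
  state <- matrix(2L, n_frames, 2)
  swungm <- matrix(FALSE, n_frames, 2)
  dmat <- matrix(NA_real_, n_frames, 2)
  fr <- 0L
  for (i in seq_len(n_ev)) {
    if (i > 1L) {
      gap <- seq_len(search_frames) + fr
      state[gap, mover[i]] <- 0L
      # positions during the gap: stationary head holds, mover carries old d
      dmat[gap, mover[i]] <- configs[i - 1L, mover[i]]
      dmat[gap, 3L - mover[i]] <- configs[i, 3L - mover[i]]
      fr <- fr + search_frames
    }
    blk <- seq_len(dwell[i]) + fr
    dmat[blk, 1] <- configs[i, 1]
    dmat[blk, 2] <- configs[i, 2]
    # mark the leading head as post-powerstroke during the dwell
    swungm[blk, which.max(configs[i, ])] <- TRUE
    fr <- fr + dwell[i]
  }
  unit_of <- function(dv) ((start - 1L + round(dv)) %% n_units) + 1L
  frames <- data.frame(
    frame = seq_len(n_frames),
    state1 = state[, 1], state2 = state[, 2],
    swung1 = swungm[, 1], swung2 = swungm[, 2],
    unit1 = ifelse(state[, 1] > 0L, unit_of(dmat[, 1]), NA_integer_),
    unit2 = ifelse(state[, 2] > 0L, unit_of(dmat[, 2]), NA_integer_),
    d1 = dmat[, 1], d2 = dmat[, 2])
  traj <- new_trajectory(frames, n_units = n_units, spacing = spacing,
                         start1 = start, start2 = start,
                         seed = as.integer(seed), termination = "synthetic")
  mid <- rowMeans(configs)
  attr(traj, "expected_steps") <- data.frame(
    separation = abs(configs[, 2] - configs[, 1]),
    direction = c("forward",
                  ifelse(diff(mid) < 0, "back", "forward")))
  attr(traj, "dwell_durations") <- dwell
  attr(traj, "k_dwell") <- k_dwell
  traj
}

#' Draw exponential dwell durations (generator for recovery tests)
#'
#' @param n number of durations.
#' @param k rate per frame.
#' @param seed RNG seed.
#' @return integer durations (frames, >= 1).
#' @export
sample_dwells <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pmax(1, round(stats::rexp(n, k)))
}
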