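## Trajectory statistics: staircase distance, discrete steps, dwell times,
## duty ratios, velocities, binding-state coexistence and the closed-form
## geometric relations that link leg length to step size.

#' Cumulative distance along a circular track
#'
#' Unwraps a cyclic track position into a signed distance in actin units:
#' `D = C + L * N - S`, where `C` is the currently bound unit, `L` the lap
#' count, `S` the starting unit and `N` the track size.
#'
#' @param C current actin unit.
#' @param L signed lap count.
#' @param S starting actin unit.
#' @param N total number of actin units on the circular track.
#' @return signed distance in actin units (vectorised).
#' @examples
#' cumulative_distance(12, 0, 5, 52)  # 7
#' cumulative_distance(5, 1, 5, 52)   # 52, one full lap
#' cumulative_distance(3, 0, 5, 52)   # -2, a backward excursion
#' @export
cumulative_distance <- function(C, L, S, N) {
  if (any(N <= 0)) stop("N must be positive")
  C + L * N - S
}

#' Convert a step separation in actin units to nanometres
#'
#' @param separation separation in actin units.
#' @param spacing nm per actin unit (default 5.70, the mean inter-unit
#'   distance on a 52-unit circular filament).
#' @return distance in nm.
#' @examples
#' step_size_nm(7)  # 39.9 nm
#' @export
step_size_nm <- function(separation, spacing = 5.70) {
  if (spacing <= 0) stop("spacing must be positive")
  separation * spacing
}

#' Extract discrete steps from a trajectory
#'
#' Keeps only frames where both heads are attached (loose or tight), then
#' collapses consecutive attached frames sharing the same pair of cumulative
#' positions into a single step event, reported at the last frame of the
#' block. The separation is the unsigned number of actin units between the
#' leading and trailing foot; the event direction compares the dimer midpoint
#' position with the previous event (the first event counts as forward).
#'
#' @param traj `myo_trajectory`.
#' @return data frame of class `myo_steps`: `frame`, `lead_unit`,
#'   `trail_unit`, `d_lead`, `d_trail`, `d_mid`, `separation`, `direction`.
#' @export
extract_steps <- function(traj) {
  stopifnot(inherits(traj, "myo_trajectory"))
  att <- traj$state1 > 0L & traj$state2 > 0L
  sub <- traj[att, , drop = FALSE]
  out <- data.frame(frame = integer(), lead_unit = integer(),
                    trail_unit = integer(), d_lead = numeric(),
                    d_trail = numeric(), d_mid = numeric(),
                    separation = numeric(),
                    direction = character(), stringsAsFactors = FALSE)
  class(out) <- c("myo_steps", "data.frame")
  if (!nrow(sub)) return(out)
  key <- paste(sub$d1, sub$d2)
  new_block <- c(TRUE, key[-1] != key[-length(key)])
  block_id <- cumsum(new_block)
  last_idx <- which(c(new_block[-1], TRUE))       # last row of each block
  ev <- sub[last_idx, , drop = FALSE]
  lead1 <- ev$d1 >= ev$d2
  out <- data.frame(
    frame = ev$frame,
    lead_unit = ifelse(lead1, ev$unit1, ev$unit2),
    trail_unit = ifelse(lead1, ev$unit2, ev$unit1),
    d_lead = pmax(ev$d1, ev$d2),
    d_trail = pmin(ev$d1, ev$d2),
    d_mid = (ev$d1 + ev$d2) / 2,
    separation = abs(ev$d1 - ev$d2),
    stringsAsFactors = FALSE)
  out$direction <- c("forward",
                     ifelse(diff(out$d_mid) < 0, "back", "forward"))
  class(out) <- c("myo_steps", "data.frame")
  out
}

#' Count backsteps in a step-event list
#'
#' A backstep is a step event whose dimer midpoint position decreased
#' relative to the previous event (the newly placed foot landed behind).
#'
#' @param events step events from [extract_steps()].
#' @return list with `n_back`, `n_total` and `fraction`.
#' @export
count_backsteps <- function(events) {
  n_total <- nrow(events)
  if (is.null(n_total) || n_total == 0)
    return(list(n_back = 0L, n_total = 0L, fraction = NA_real_))
  n_back <- sum(events$direction == "back")
  list(n_back = n_back, n_total = n_total, fraction = n_back / n_total)
}

#' Fit a Gaussian to the step-size histogram
#'
#' Least-squares fit of `A * exp(-(x - mean)^2 / (2 sd^2))` to the histogram
#' of unit separations. Degenerate input (all separations equal) returns the
#' common value with sd 0, matching the behaviour of a saturated fit.
#'
#' @param events step events from [extract_steps()], or a numeric vector of
#'   separations.
#' @return named numeric `c(mean, sd)` in actin units.
#' @export
fit_step_gaussian <- function(events) {
  x <- if (is.data.frame(events)) events$separation else as.numeric(events)
  if (length(x) < 2) stop("need at least 2 step events to fit")
  if (stats::sd(x) == 0) return(c(mean = x[1], sd = 0))
  tab <- table(x)
  xs <- as.numeric(names(tab))
  ys <- as.numeric(tab)
  m0 <- mean(x); s0 <- stats::sd(x); a0 <- max(ys)
  obj <- function(p) {
    mu <- p[1]; sg <- exp(p[2]); A <- exp(p[3])
    sum((ys - A * exp(-(xs - mu)^2 / (2 * sg^2)))^2)
  }
  fit <- stats::optim(c(m0, log(s0), log(a0)), obj)
  if (fit$convergence != 0) return(c(mean = m0, sd = s0))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Extract dwell intervals from a trajectory
#'
#' A dwell is a maximal run of consecutive frames in which both heads are
#' attached and both bound positions remain constant. Each dwell is
#' attributed to the head whose position changed (or which detached) at the
#' end of the interval; the final dwell of a run has no attributed head.
#'
#' @param traj `myo_trajectory`.
#' @return data frame: `start_frame`, `end_frame`, `duration` (frames),
#'   `head` (1, 2 or `NA`).
#' @export
extract_dwells <- function(traj) {
  stopifnot(inherits(traj, "myo_trajectory"))
  n <- nrow(traj)
  att <- traj$state1 > 0L & traj$state2 > 0L
  # run-length encode (attached & constant positions)
  same_prev <- c(FALSE, att[-1] & att[-n] &
                   traj$d1[-1] == traj$d1[-n] &
                   traj$d2[-1] == traj$d2[-n] &
                   diff(traj$frame) == 1L)
  starts <- which(att & !same_prev)
  out <- data.frame(start_frame = integer(), end_frame = integer(),
                    duration = integer(), head = integer())
  if (!length(starts)) return(out)
  run_id <- cumsum(att & !same_prev)
  run_id[!att] <- 0L
  # runs can be split by non-attached frames: recompute ends per run
  ends <- vapply(seq_along(starts), function(i) {
    j <- starts[i]
    while (j < n && same_prev[j + 1L]) j <- j + 1L
    j
  }, integer(1))
  head_next <- vapply(seq_along(starts), function(i) {
    j <- ends[i]
    if (j >= n) return(NA_integer_)
    moved1 <- traj$state1[j + 1L] == 0L || traj$d1[j + 1L] != traj$d1[j]
    moved2 <- traj$state2[j + 1L] == 0L || traj$d2[j + 1L] != traj$d2[j]
    if (moved1 && !moved2) return(1L)
    if (moved2 && !moved1) return(2L)
    NA_integer_
  }, integer(1))
  data.frame(start_frame = traj$frame[starts],
             end_frame = traj$frame[ends],
             duration = ends - starts + 1L,
             head = head_next)
}

#' Fit a single-exponential rate to dwell-time distributions
#'
#' When both heads of a walking dimer are observed, the dwell-time
#' distribution follows `P(t) = k * exp(-k t)`. Durations are binned with
#' equal-width bins, the histogram is density-normalised and `k` is fitted
#' by unweighted least squares at the bin midpoints. Rates are returned for
#' each head's dwells separately (`k1`, `k2`) and for the pooled data
#' (`k12`), together with the mean lifetime `1/k` and the maximum-likelihood
#' cross-check `1/mean(t)`.
#'
#' @param dwells data frame from [extract_dwells()], or a numeric vector of
#'   durations (then only a pooled fit is returned).
#' @param bin_width histogram bin width in frames (default 50).
#' @param min_n minimum number of dwells required for a fit (default 10).
#' @return list with `k1`, `k2`, `k12`, `mean_lifetime` (= 1/k12), `k_ml`
#'   and `n` (dwell counts used).
#' @export
fit_dwell_rate <- function(dwells, bin_width = 50, min_n = 10) {
  if (is.data.frame(dwells)) {
    t_all <- dwells$duration
    t1 <- dwells$duration[!is.na(dwells$head) & dwells$head == 1L]
    t2 <- dwells$duration[!is.na(dwells$head) & dwells$head == 2L]
  } else {
    t_all <- as.numeric(dwells)
    t1 <- t2 <- numeric()
  }
  if (length(t_all) < min_n)
    stop("too few dwells for a rate fit (", length(t_all), " < ", min_n, ")")
  if (stats::sd(t_all) == 0)
    stop("degenerate dwell distribution: all durations equal")
  fit1 <- function(tt) {
    if (length(tt) < min_n) return(NA_real_)
    brks <- seq(0, max(tt) + bin_width, by = bin_width)
    h <- graphics::hist(tt, breaks = brks, plot = FALSE)
    dens <- h$counts / (length(tt) * bin_width)
    mids <- h$mids
    obj <- function(k) sum((dens - k * exp(-k * mids))^2)
    ## grid-then-refine: the least-squares objective is not unimodal in k
    ## (it flattens once the model decays inside the first bin), so seed
    ## a log-spaced grid around the moment estimate before polishing
    k0 <- 1 / mean(tt)
    grid <- exp(seq(log(k0 / 20), log(k0 * 20), length.out = 80))
    i <- which.min(vapply(grid, obj, 0))
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    k_hat <- stats::optimize(obj, c(lo, hi))$minimum
    if (k_hat <= 1e-8) stop("exponential fit failed: k <= 0")
    k_hat
  }
  k12 <- fit1(t_all)
  list(k1 = fit1(t1), k2 = fit1(t2), k12 = k12,
       mean_lifetime = 1 / k12, k_ml = 1 / mean(t_all),
       n = c(head1 = length(t1), head2 = length(t2), all = length(t_all)))
}

#' Duty ratio of a trajectory
#'
#' Fraction of frames spent in tight binding. For a single head this is the
#' fraction of frames that head is tight-bound; for `"either"` it is the
#' fraction of frames in which at least one head is tight-bound (the duty
#' ratio of the double-headed species).
#'
#' @param traj `myo_trajectory`.
#' @param head `1`, `2` or `"either"`.
#' @return fraction in `[0, 1]`.
#' @export
duty_ratio <- function(traj, head = "either") {
  stopifnot(inherits(traj, "myo_trajectory"))
  n <- nrow(traj)
  if (n == 0) return(NA_real_)
  tight1 <- traj$state1 == 2L
  tight2 <- traj$state2 == 2L
  if (identical(head, 1) || identical(head, 1L) || identical(head, "1"))
    return(mean(tight1))
  if (identical(head, 2) || identical(head, 2L) || identical(head, "2"))
    return(mean(tight2))
  if (identical(head, "either")) return(mean(tight1 | tight2))
  stop("head must be 1, 2 or \"either\"")
}

#' Predicted double-headed duty ratio from a single-head ratio
#'
#' Assuming the two heads bind independently, a single-head duty ratio `r`
#' predicts a dimer duty ratio of `1 - (1 - r)^2`.
#'
#' @param r single-head duty ratio in `[0, 1]`.
#' @return predicted dimer duty ratio (vectorised).
#' @examples
#' predict_dimer_duty(0.51)  # 0.7599
#' @export
predict_dimer_duty <- function(r) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  1 - (1 - r)^2
}

#' Fit the mean velocity from staircase data
#'
#' Ordinary least-squares slope of cumulative distance against frame number,
#' pooled over both heads and all supplied trajectories. Each trajectory
#' contributes its attached-frame positions over an initial window of
#' `window_frames` frames or `window_laps` laps, whichever ends first.
#'
#' @param trajs a `myo_trajectory` or a list of them.
#' @param window_frames frame window (default 3000).
#' @param window_laps lap window (default 2).
#' @return list with `slope` (actin units per frame), `intercept`, `n_points`.
#' @export
velocity_fit <- function(trajs, window_frames = 3000, window_laps = 2) {
  if (inherits(trajs, "myo_trajectory")) trajs <- list(trajs)
  xs <- numeric(); ys <- numeric()
  for (tr in trajs) {
    N <- attr(tr, "n_units")
    lim_d <- window_laps * N
    keep <- tr$frame <= window_frames &
      pmin(tr$d1, tr$d2) <= lim_d
    sub <- tr[keep, , drop = FALSE]
    a1 <- sub$state1 > 0L
    a2 <- sub$state2 > 0L
    xs <- c(xs, sub$frame[a1], sub$frame[a2])
    ys <- c(ys, sub$d1[a1], sub$d2[a2])
  }
  if (length(xs) < 2) stop("need at least 2 attached data points")
  if (stats::sd(xs) == 0) stop("degenerate frame window")
  fit <- stats::lm.fit(cbind(1, xs), ys)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_points = length(xs))
}

#' Binding-state coexistence table
#'
#' Tabulates, over all recorded frames, the joint binding state of the two
#' heads over the alphabet F (free), L (loose), T (tight) and S (tight,
#' post-powerstroke). The combined view adds symmetric off-diagonal counts
#' (e.g. ST + TS), reflecting the equivalence of the two legs.
#'
#' @param traj `myo_trajectory`.
#' @return list of class `coexistence_table` with 4x4 matrices `counts` and
#'   `combined`.
#' @export
coexistence_table <- function(traj) {
  stopifnot(inherits(traj, "myo_trajectory"))
  s1 <- state_letters(traj$state1, traj$swung1)
  s2 <- state_letters(traj$state2, traj$swung2)
  counts <- table(head1 = s1, head2 = s2)
  counts <- unclass(counts)
  combined <- counts + t(counts)
  diag(combined) <- diag(counts)
  structure(list(counts = counts, combined = combined),
            class = "coexistence_table")
}

#' @export
print.coexistence_table <- function(x, ...) {
  cat("Binding-state coexistence (rows head 1, cols head 2):\n")
  print(x$counts)
  cat("Symmetric-combined:\n")
  print(x$combined)
  invisible(x)
}

#' Apex angle between the two legs bridging a step
#'
#' For legs of length `L` (nm) spanning a step of size `s` (nm) with a
#' common hinge, the apex angle is
#' `theta = 180 - 2 * acos(s / (2 L))` degrees; the angle between each leg
#' and the filament axis is `(180 - theta) / 2`.
#'
#' @param L leg length in nm.
#' @param s step size in nm; must satisfy `0 < s <= 2 L`.
#' @return named numeric `c(theta, leg_axis_angle)` in degrees.
#' @examples
#' apex_angle(0.6 * 34.2, 34.2)  # L/s = 0.6: theta 112.9, leg-axis 33.55
#' @export
apex_angle <- function(L, s) {
  if (s <= 0) stop("step size must be positive")
  if (s > 2 * L) stop("step size exceeds the 2L reachable span")
  theta <- 180 - 2 * acos(s / (2 * L)) * 180 / pi
  c(theta = theta, leg_axis_angle = (180 - theta) / 2)
}

#' Linear fits of step size against leg length
#'
#' Least-squares lines relating mean step size to the IQ-motif count and to
#' the physical leg length, plus the reverse (leg on step) fit with an
#' optional through-origin variant.
#'
#' @param step_nm mean step sizes in nm, one per model.
#' @param n_iq IQ counts for each model (optional).
#' @param leg_nm leg lengths in nm for each model (optional).
#' @return list with components (each `c(slope, intercept)`):
#'   `vs_iq` (step on IQ count), `vs_leg` (step on leg length),
#'   `leg_vs_step` (leg on step), and scalar `leg_vs_step_origin`
#'   (through-origin slope of leg on step).
#' @export
fit_step_vs_leg <- function(step_nm, n_iq = NULL, leg_nm = NULL) {
  if (length(step_nm) < 2) stop("need at least 2 models to fit")
  ls_line <- function(x, y) {
    if (stats::sd(x) == 0) stop("degenerate predictor: all x equal")
    b <- stats::cov(x, y) / stats::var(x)
    c(slope = b, intercept = mean(y) - b * mean(x))
  }
  out <- list()
  if (!is.null(n_iq)) out$vs_iq <- ls_line(n_iq, step_nm)
  if (!is.null(leg_nm)) {
    out$vs_leg <- ls_line(leg_nm, step_nm)
    out$leg_vs_step <- ls_line(step_nm, leg_nm)
    out$leg_vs_step_origin <-
      c(slope = sum(step_nm * leg_nm) / sum(step_nm^2))
  }
  out
}
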