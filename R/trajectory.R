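## Trajectory container: one row per recorded frame, plus run metadata in
## attributes. All downstream statistics (steps, dwells, duty ratios,
## coexistence tables) are defined on this object.

#' Construct a trajectory object
#'
#' A trajectory is a data frame with one row per recorded frame and the
#' per-head binding bookkeeping needed by the analysis functions:
#'
#' * `frame` -- strictly increasing frame index (1-based).
#' * `state1`, `state2` -- binding state of each head: 0 = free, 1 = loose,
#'   2 = tight.
#' * `swung1`, `swung2` -- logical, post-powerstroke conformation.
#' * `unit1`, `unit2` -- 1-based actin unit currently bound (`NA` when free).
#' * `d1`, `d2` -- cumulative distance along the track in actin units,
#'   `D = C + L*N - S`; carried forward over detached intervals.
#'
#' @param frames data frame with the columns listed above.
#' @param n_units number of actin units (dimers) in the circular track.
#' @param spacing actin unit spacing in nm.
#' @param start1,start2 1-based starting actin unit of each head.
#' @param seed RNG seed used to generate the run (or `NA`).
#' @param config configuration list used for the run (may be `NULL`).
#' @param termination one of `"max_frames"`, `"laps_done"`, `"detached"`,
#'   `"synthetic"`.
#' @return object of class `myo_trajectory`.
#' @export
new_trajectory <- function(frames, n_units = 52L, spacing = 5.70,
                           start1 = 1L, start2 = 1L, seed = NA_integer_,
                           config = NULL, termination = "synthetic") {
  needed <- c("frame", "state1", "state2", "swung1", "swung2",
              "unit1", "unit2", "d1", "d2")
  missing <- setdiff(needed, names(frames))
  if (length(missing))
    stop("trajectory frames missing columns: ", paste(missing, collapse = ", "))
  if (nrow(frames) > 1 && any(diff(frames$frame) <= 0))
    stop("frame indices must be strictly increasing")
  bad1 <- xor(is.na(frames$unit1), frames$state1 == 0L)
  bad2 <- xor(is.na(frames$unit2), frames$state2 == 0L)
  if (any(bad1) || any(bad2))
    stop("bound unit must be NA exactly when the head is free")
  structure(as.data.frame(frames),
            n_units = as.integer(n_units), spacing = spacing,
            start1 = as.integer(start1), start2 = as.integer(start2),
            seed = seed, config = config, termination = termination,
            class = c("myo_trajectory", "data.frame"))
}

#' @export
print.myo_trajectory <- function(x, ...) {
  cat(sprintf("myosin-V trajectory: %d frames, track of %d units (%.2f nm)\n",
              nrow(x), attr(x, "n_units"), attr(x, "spacing")))
  cat(sprintf("  start units: %d / %d   termination: %s   seed: %s\n",
              attr(x, "start1"), attr(x, "start2"),
              attr(x, "termination"), format(attr(x, "seed"))))
  if (nrow(x)) {
    cat(sprintf("  final D: head1 %.0f, head2 %.0f units\n",
                x$d1[nrow(x)], x$d2[nrow(x)]))
  }
  invisible(x)
}

#' Binding-state letter codes for each frame
#'
#' Maps the per-head (state, swung) pair to the four-letter alphabet used in
#' coexistence tables: F (free), L (loose), T (tight, pre-powerstroke),
#' S (tight, post-powerstroke "swung").
#'
#' @param state integer vector of states (0/1/2).
#' @param swung logical vector.
#' @return factor with levels F, L, T, S.
#' @keywords internal
state_letters <- function(state, swung) {
  out <- character(length(state))
  out[state == 0L] <- "F"
  out[state == 1L] <- "L"
  out[state == 2L & !swung] <- "T"
  out[state == 2L & swung] <- "S"
  factor(out, levels = c("F", "L", "T", "S"))
}

#' Write a trajectory as JSON-lines
#'
#' The first line is a JSON header (track geometry, seed, config,
#' termination); each subsequent line is one frame record. A `.gz` suffix
#' triggers gzip compression.
#'
#' @param traj `myo_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  header <- list(
    n_units = attr(traj, "n_units"), spacing = attr(traj, "spacing"),
    start1 = attr(traj, "start1"), start2 = attr(traj, "start2"),
    seed = attr(traj, "seed"), termination = attr(traj, "termination"),
    config = {
      cfg <- attr(traj, "config")
      if (!is.null(cfg)) class(cfg) <- NULL
      cfg
    })
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                              digits = NA), con)
  if (nrow(traj)) {
    rows <- jsonlite::toJSON(as.data.frame(traj), dataframe = "rows",
                             na = "null", digits = NA)
    # one frame per line
    rows <- jsonlite::fromJSON(rows, simplifyVector = FALSE)
    writeLines(vapply(rows, function(r)
      as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null",
                                    digits = NA)), ""), con)
  }
  invisible(path)
}

#' Read a JSON-lines trajectory
#'
#' @param path file written by [write_trajectory()].
#' @return `myo_trajectory`.
#' @export
read_trajectory <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) stop("empty trajectory file")
  header <- jsonlite::fromJSON(lines[1])
  if (length(lines) > 1) {
    recs <- lapply(lines[-1], jsonlite::fromJSON)
    frames <- do.call(rbind, lapply(recs, function(r) {
      r[vapply(r, is.null, TRUE)] <- NA
      as.data.frame(r)
    }))
  } else {
    frames <- data.frame(frame = integer(), state1 = integer(),
                         state2 = integer(), swung1 = logical(),
                         swung2 = logical(), unit1 = integer(),
                         unit2 = integer(), d1 = numeric(), d2 = numeric())
  }
  new_trajectory(frames, n_units = header$n_units, spacing = header$spacing,
                 start1 = header$start1, start2 = header$start2,
                 seed = if (is.null(header$seed)) NA_integer_ else header$seed,
                 config = header$config, termination = header$termination)
}
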