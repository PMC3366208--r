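## shared helpers: small configurations and brute-force oracles

quick_config <- function(n_iq = 6L, max_frames = 1500L, n_laps = 99L) {
  cfg <- default_config(n_iq)
  cfg$stop$max_frames <- as.integer(max_frames)
  cfg$stop$n_laps <- as.integer(n_laps)
  cfg
}

## brute-force recount of binding-state coexistence
recount_coexistence <- function(traj) {
  lv <- c("F", "L", "T", "S")
  M <- matrix(0L, 4, 4, dimnames = list(lv, lv))
  for (i in seq_len(nrow(traj))) {
    s1 <- with(traj[i, ], if (state1 == 0) "F" else if (state1 == 1) "L"
               else if (swung1) "S" else "T")
    s2 <- with(traj[i, ], if (state2 == 0) "F" else if (state2 == 1) "L"
               else if (swung2) "S" else "T")
    M[s1, s2] <- M[s1, s2] + 1L
  }
  M
}

## brute-force frame scan for step events: last frame of each maximal
## stretch of both-attached frames sharing one (d1, d2) configuration
scan_steps_bruteforce <- function(traj) {
  out <- NULL
  prev_key <- NULL
  last_row <- NULL
  for (i in seq_len(nrow(traj))) {
    row <- traj[i, ]
    if (row$state1 > 0 && row$state2 > 0) {
      key <- paste(row$d1, row$d2)
      if (!is.null(prev_key) && key != prev_key)
        out <- rbind(out, last_row)
      prev_key <- key
      last_row <- row
    }
  }
  if (!is.null(last_row)) out <- rbind(out, last_row)
  out
}
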