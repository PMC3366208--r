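## Simulation configuration: defaults, validation, JSON loading.

#' Default simulation configuration
#'
#' The defaults encode the "new default" model: initial attraction off,
#' 12 nm zone, 1.0 rad alignment tolerance, braced (good) legs, hinge
#' restoration always on, no ratchet. Random-move and restraint-correction
#' magnitudes are the calibration constants of the engine (see the methods
#' vignette); they are expressed per frame.
#'
#' @param n_iq IQ segments per leg (2, 4 or 6).
#' @return nested configuration list of class `sim_config`.
#' @export
default_config <- function(n_iq = 6L) {
  structure(list(
    n_iq = as.integer(n_iq),
    n_units = 52L,
    unit_spacing = 5.70,
    half_repeat = 36,
    start_unit = 1L,
    stop = list(n_laps = 2L, max_frames = 20000L, detach_grace = 13L),
    record_stride = 1L,
    move = list(
      mol_translation = 0.8,    # nm/frame, molecule level
      mol_rotation = 0.08,      # rad/frame, molecule level
      foot_rotation = 0.05,     # rad/frame, foot domain group
      domain_translation = 0.10,# nm/frame per myosin domain (wobble)
      actin_translation = 0.08, # nm/frame per actin unit
      leg_servo = 0.15          # rad/frame lever-stiffness correction
    ),
    restraint = list(correction_step = 0.25, binding_step = 0.25,
                     tolerance = 0.05),
    binding = list(
      capture_axis_distance = 15, zone = 12, align_tolerance = 1.0,
      tight_distance = 7, initial_attraction = FALSE,
      powerstroke_total = 70 * pi / 180,
      powerstroke_step = 0.05, recovery_step = 0.1, yawroll_step = 0.05),
    variants = list(ratchet = FALSE, weak_leg = FALSE,
                    hinge_dislocate = FALSE, hinge_strong_link = FALSE)
  ), class = "sim_config")
}

#' Load a simulation configuration from a JSON file
#'
#' Reads a (possibly partial) JSON document and merges it over
#' [default_config()]; unknown keys and out-of-range values raise
#' descriptive errors. An empty file yields the full default
#' configuration.
#'
#' @param path JSON file path.
#' @return `sim_config` list.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  merge_into <- function(base, upd, where = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", where, k)
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        if (!is.list(upd[[k]]))
          stop("configuration key ", where, k, " must be an object")
        base[[k]] <- merge_into(base[[k]], upd[[k]],
                                paste0(where, k, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg <- merge_into(unclass(default_config()), user)
  validate_config(cfg)
}

#' Validate (and normalise) a configuration list
#'
#' @param cfg configuration list.
#' @return validated `sim_config`.
#' @export
validate_config <- function(cfg) {
  if (!cfg$n_iq %in% c(2L, 4L, 6L)) stop("n_iq must be 2, 4 or 6")
  b <- cfg$binding
  if (b$zone < 3) {
    warning("zone < 3 nm: interpreting as legacy tenths (zone * 10 nm)")
    cfg$binding$zone <- b$zone * 10
    b <- cfg$binding
  }
  if (b$zone <= 0 || b$zone > b$capture_axis_distance)
    stop("need 0 < zone <= capture_axis_distance")
  if (b$align_tolerance <= 0) stop("align_tolerance must be positive")
  if (cfg$stop$n_laps < 0 || cfg$stop$max_frames < 1)
    stop("invalid stop criteria")
  for (nm in names(cfg$move))
    if (cfg$move[[nm]] < 0) stop("move step ", nm, " must be >= 0")
  if (cfg$restraint$correction_step <= 0)
    stop("correction_step must be positive")
  class(cfg) <- "sim_config"
  cfg
}
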