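## Model serialization (JSON) and frame export for visualisation
## (multi-chain PDB with CA pseudo-atoms at sphere centres, or XYZ).

#' Write a model to a JSON document
#'
#' Serialises an `actin_ring` or (placed) `myosin_dimer` -- hierarchy
#' parameters, coordinates and per-head state -- so a model can be
#' inspected or rebuilt outside the package.
#'
#' @param x `actin_ring` or `myosin_dimer`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(x, path) {
  type <- class(x)[1]
  payload <- list(type = type, data = unclass(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file.
#' @return the model object with its class restored.
#' @export
read_model <- function(path) {
  payload <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                      collapse = ""),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  x <- payload$data
  for (nm in c("unit_centers", "tangents", "radials", "binding_dirs"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.matrix(x[[nm]])
  if (!is.null(x$halves))
    x$halves <- lapply(x$halves, function(h) {
      h$X <- as.matrix(h$X)
      h
    })
  class(x) <- payload$type
  x
}

#' Export a frame as a CA-only pseudo-atom PDB file
#'
#' Actin unit centres go to chain A; the two myosin halves to chains B
#' and C. Sphere centres are written as CA pseudo-atoms for quick
#' visualisation in any structure viewer.
#'
#' @param ring `actin_ring` (its current or ideal unit centres).
#' @param dimer placed `myosin_dimer`, or `NULL` for track only.
#' @param path output PDB path.
#' @param state optional `final_state` attribute of a trajectory, which
#'   overrides the coordinates.
#' @return `path`, invisibly.
#' @export
export_frame_pdb <- function(ring, dimer = NULL, path = "frame.pdb",
                             state = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  put <- function(X, chain) {
    for (i in seq_len(nrow(X))) {
      serial <<- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, chain, i, X[i, 1], X[i, 2], X[i, 3]), con)
    }
  }
  A <- if (!is.null(state)) state$actin else ring$unit_centers
  put(A, "A")
  if (!is.null(dimer) || !is.null(state)) {
    X1 <- if (!is.null(state)) state$half1 else dimer$halves[[1]]$X
    X2 <- if (!is.null(state)) state$half2 else dimer$halves[[2]]$X
    put(X1, "B")
    put(X2, "C")
  }
  writeLines("END", con)
  invisible(path)
}

#' Export a frame as an XYZ file
#'
#' @inheritParams export_frame_pdb
#' @param path output XYZ path.
#' @return `path`, invisibly.
#' @export
export_frame_xyz <- function(ring, dimer = NULL, path = "frame.xyz",
                             state = NULL) {
  A <- if (!is.null(state)) state$actin else ring$unit_centers
  X1 <- X2 <- NULL
  if (!is.null(state)) {
    X1 <- state$half1; X2 <- state$half2
  } else if (!is.null(dimer)) {
    X1 <- dimer$halves[[1]]$X; X2 <- dimer$halves[[2]]$X
  }
  pts <- rbind(A, X1, X2)
  el <- c(rep("C", nrow(A)),
          if (!is.null(X1)) rep("N", nrow(X1)),
          if (!is.null(X2)) rep("O", nrow(X2)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pts)), "myowalk frame"), con)
  writeLines(sprintf("%s %10.4f %10.4f %10.4f", el,
                     pts[, 1], pts[, 2], pts[, 3]), con)
  invisible(path)
}
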