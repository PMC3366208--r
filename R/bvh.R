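## Bounding-volume hierarchy over spheres: construction, contact queries by
## hierarchical descent, and steric resolution. Trees mirror the
## molecule -> domain -> leaf-sphere structure of the models; leaves are the
## schematic domain spheres the engine moves.

#' Build a bounding-volume tree over a set of spheres
#'
#' Either a two-level tree from an explicit grouping (mirroring the
#' molecule/domain structure), or a recursive median-split tree along the
#' longest axis.
#'
#' @param centers n x 3 matrix of sphere centres.
#' @param radii length-n sphere radii.
#' @param groups optional list of integer index vectors partitioning
#'   `1..n`; when given, one internal node per group under a single root.
#' @param leaf_size maximum leaves per node for the recursive build
#'   (default 4).
#' @return object of class `bvh`: parallel vectors `center`, `radius`,
#'   `children` (list of integer node ids; empty for leaves), `leaf`
#'   (original sphere index or `NA`), and `root`.
#' @export
bvh_build <- function(centers, radii, groups = NULL, leaf_size = 4L) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stopifnot(length(radii) == n)
  env <- new.env()
  env$center <- list(); env$radius <- numeric(); env$children <- list()
  env$leaf <- integer()
  add_node <- function(center, radius, children, leaf) {
    k <- length(env$radius) + 1L
    env$center[[k]] <- center
    env$radius[k] <- radius
    env$children[[k]] <- children
    env$leaf[k] <- leaf
    k
  }
  ## parent volume wraps the child NODE spheres, so containment holds at
  ## every level of the tree
  wrap_nodes <- function(node_ids) {
    cs <- do.call(rbind, env$center[node_ids])
    ctr <- colMeans(cs)
    r <- max(sqrt(rowSums(sweep(cs, 2, ctr)^2)) + env$radius[node_ids])
    list(ctr = ctr, r = r)
  }
  build_rec <- function(idx) {
    if (length(idx) == 1L)
      return(add_node(centers[idx, ], radii[idx], integer(), idx))
    kids <- if (length(idx) <= leaf_size) {
      vapply(idx, function(i)
        add_node(centers[i, ], radii[i], integer(), i), integer(1))
    } else {
      spans <- apply(centers[idx, , drop = FALSE], 2,
                     function(v) diff(range(v)))
      ax <- which.max(spans)
      ord <- idx[order(centers[idx, ax])]
      half <- length(ord) %/% 2
      c(build_rec(ord[seq_len(half)]), build_rec(ord[-seq_len(half)]))
    }
    w <- wrap_nodes(kids)
    add_node(w$ctr, w$r, kids, NA_integer_)
  }
  if (is.null(groups)) {
    root <- build_rec(seq_len(n))
  } else {
    kids <- vapply(groups, function(g) {
      leaf_ids <- vapply(g, function(i)
        add_node(centers[i, ], radii[i], integer(), i), integer(1))
      w <- wrap_nodes(leaf_ids)
      add_node(w$ctr, w$r, leaf_ids, NA_integer_)
    }, integer(1))
    w <- wrap_nodes(kids)
    root <- add_node(w$ctr, w$r, kids, NA_integer_)
  }
  structure(list(center = do.call(rbind, env$center), radius = env$radius,
                 children = env$children, leaf = env$leaf, root = root,
                 n_leaves = n),
            class = "bvh")
}

#' Overlapping leaf pairs between two bounding-volume trees
#'
#' Hierarchical descent: a node pair is expanded only if its bounding
#' spheres overlap, so separated subtrees are pruned after a single sphere
#' test. Returns the overlapping leaf-sphere pairs (original indices) with
#' the number of sphere-sphere tests performed as attribute `n_tests`.
#'
#' @param a,b `bvh` trees.
#' @return 2-column integer matrix (leaf index in `a`, leaf index in `b`)
#'   with attribute `n_tests`.
#' @export
bvh_contacts <- function(a, b) {
  pa <- a$root; pb <- b$root
  n_tests <- 0L
  out_a <- integer(); out_b <- integer()
  while (length(pa)) {
    dx <- a$center[pa, 1] - b$center[pb, 1]
    dy <- a$center[pa, 2] - b$center[pb, 2]
    dz <- a$center[pa, 3] - b$center[pb, 3]
    n_tests <- n_tests + length(pa)
    hit <- (dx * dx + dy * dy + dz * dz) <
      (a$radius[pa] + b$radius[pb])^2
    pa <- pa[hit]; pb <- pb[hit]
    if (!length(pa)) break
    leaf_a <- !is.na(a$leaf[pa]); leaf_b <- !is.na(b$leaf[pb])
    done <- leaf_a & leaf_b
    if (any(done)) {
      out_a <- c(out_a, a$leaf[pa[done]])
      out_b <- c(out_b, b$leaf[pb[done]])
    }
    pa2 <- integer(); pb2 <- integer()
    todo <- which(!done)
    for (k in todo) {
      ia <- pa[k]; ib <- pb[k]
      # expand the non-leaf side with the larger bounding sphere
      expand_a <- !leaf_a[k] &&
        (leaf_b[k] || a$radius[ia] >= b$radius[ib])
      if (expand_a) {
        kids <- a$children[[ia]]
        pa2 <- c(pa2, kids); pb2 <- c(pb2, rep(ib, length(kids)))
      } else {
        kids <- b$children[[ib]]
        pa2 <- c(pa2, rep(ia, length(kids))); pb2 <- c(pb2, kids)
      }
    }
    pa <- pa2; pb <- pb2
  }
  structure(cbind(a = out_a, b = out_b), n_tests = n_tests)
}

#' Brute-force overlapping sphere pairs (reference oracle)
#'
#' @param centers_a,centers_b sphere centre matrices.
#' @param radii_a,radii_b sphere radii.
#' @return 2-column integer matrix of overlapping pairs.
#' @export
brute_force_contacts <- function(centers_a, radii_a, centers_b, radii_b) {
  na <- nrow(centers_a); nb <- nrow(centers_b)
  d2 <- outer(rowSums(centers_a^2), rep(1, nb)) -
    2 * centers_a %*% t(centers_b) +
    outer(rep(1, na), rowSums(centers_b^2))
  lim <- outer(radii_a, radii_b, `+`)^2
  which(d2 < lim, arr.ind = TRUE) -> ij
  colnames(ij) <- c("a", "b")
  ij
}

#' Resolve steric overlaps between two trees
#'
#' Finds overlapping leaf pairs by hierarchical descent and pushes each
#' pair apart along the centre line by the overlap depth, split equally
#' between the two spheres (coincident centres are separated along a random
#' direction).
#'
#' @param tree_a,tree_b `bvh` trees (carrying current leaf centres).
#' @param split fraction of the push applied to side a (default 0.5).
#' @return list with `delta_a`, `delta_b` (displacement matrices for the
#'   leaf spheres of each tree) and `pairs` (the overlapping leaf pairs).
#' @export
resolve_steric <- function(tree_a, tree_b, split = 0.5) {
  pairs <- bvh_contacts(tree_a, tree_b)
  da <- matrix(0, tree_a$n_leaves, 3)
  db <- matrix(0, tree_b$n_leaves, 3)
  if (nrow(pairs)) {
    la <- match(pairs[, 1], tree_a$leaf)
    lb <- match(pairs[, 2], tree_b$leaf)
    for (k in seq_len(nrow(pairs))) {
      ca <- tree_a$center[la[k], ]; cb <- tree_b$center[lb[k], ]
      v <- ca - cb
      d <- vnorm(v)
      depth <- tree_a$radius[la[k]] + tree_b$radius[lb[k]] - d
      u <- if (d < 1e-9) random_unit_vectors(1)[1, ] else v / d
      da[pairs[k, 1], ] <- da[pairs[k, 1], ] + split * depth * u
      db[pairs[k, 2], ] <- db[pairs[k, 2], ] - (1 - split) * depth * u
    }
  }
  list(delta_a = da, delta_b = db, pairs = pairs)
}
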