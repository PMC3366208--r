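## Frame-loop orchestration: random moves at every hierarchy level,
## binding-state updates (powerstroke / recovery included), restraint
## satisfaction, hinge maintenance, steric exclusion, recording, and run
## termination. Steric exclusion is applied last so it always has the
## final word.

#' Run a walking simulation
#'
#' Builds the circular actin track and the myosin dimer from the
#' configuration, places the dimer with one head over `start_unit`, and
#' iterates the frame loop until the lap target is reached, the frame
#' budget is exhausted, or both heads have been free for longer than the
#' detachment grace window (one recovery duration).
#'
#' @param config configuration list from [default_config()] /
#'   [load_config()].
#' @param seed integer RNG seed; the trajectory is reproducible from
#'   (config, seed).
#' @param verbose if positive, print a one-line state digest every
#'   `verbose` frames (diagnostic aid; does not affect the dynamics).
#' @return a [new_trajectory()] object; the final model coordinates are
#'   attached as attribute `final_state`.
#' @export
run_sim <- function(config = default_config(), seed = 1L, verbose = 0L) {
  config <- validate_config(config)
  set.seed(as.integer(seed))
  N <- config$n_units
  ring <- build_actin_ring(N, config$unit_spacing, config$half_repeat)
  dimer <- place_dimer_initial(ring, build_myosin_dimer(config$n_iq),
                               config$start_unit)
  n <- config$n_iq
  m <- 4L + n                      # nodes per half (incl. virtual hinge)
  off <- c(N, N + m)
  rows_half <- list(off[1] + seq_len(m), off[2] + seq_len(m))
  hinge_g <- c(off[1] + m, off[2] + m)
  X <- rbind(ring$unit_centers, dimer$halves[[1]]$X, dimer$halves[[2]]$X)
  radii <- c(rep(ring$unit_radius, N), dimer$halves[[1]]$radii,
             dimer$halves[[2]]$radii)

  params <- do.call(binding_params, config$binding)
  mv <- config$move
  corr <- config$restraint$correction_step
  bcorr <- config$restraint$binding_step
  tol <- config$restraint$tolerance
  vr <- config$variants

  ## --- static restraints -------------------------------------------------
  ## actin: neighbour links at offsets 1, 2 and 4 hold the well-restrained
  ## closed filament (targets = ideal chord lengths); the short-range links
  ## are applied twice per frame -- restraint strength scales with how
  ## often a restraint is applied
  actin_tab <- do.call(rbind, lapply(c(1L, 1L, 2L, 2L, 4L), function(k) {
    tgt <- vnorm(ring$unit_centers[1, ] - ring$unit_centers[1 + k, ])
    cbind(seq_len(N), wrap_unit(seq_len(N) + k, N), tgt, corr, 0)
  }))
  myo_tab <- do.call(rbind, lapply(1:2, function(h) {
    half_structural_tab(n, dimer$seg_spacing, off[h], corr,
                        weak_leg = vr$weak_leg)
  }))
  stat_tab <- rbind(actin_tab, myo_tab)
  bt <- binding_targets(ring)

  ## steric bookkeeping: actin grouped in fours for the hierarchical test
  grp <- rep(seq_len(ceiling(N / 4)), each = 4L)[seq_len(N)]
  gidx <- split(seq_len(N), grp)
  n_grp <- length(gidx)
  myo_rows <- c(rows_half[[1]][seq_len(m - 1)], rows_half[[2]][seq_len(m - 1)])
  myo_rad <- radii[myo_rows]
  m1_rows <- rows_half[[1]][seq_len(m - 1)]
  m2_rows <- rows_half[[2]][seq_len(m - 1)]

  ## --- per-head state ----------------------------------------------------
  st <- c(0L, 0L); swung <- c(FALSE, FALSE); swing <- c(0, 0)
  in_zone <- c(FALSE, FALSE)
  bu <- c(NA_integer_, NA_integer_); last_u <- c(NA_integer_, NA_integer_)
  upos <- c(0, 0); bound_ever <- c(FALSE, FALSE)
  start_ref <- wrap_unit(config$start_unit, N)
  free_run <- 0L
  term <- "max_frames"

  max_frames <- config$stop$max_frames
  stride <- config$record_stride
  n_rec <- ceiling(max_frames / stride)
  rec <- matrix(NA_real_, n_rec, 9)
  n_out <- 0L

  total <- params$powerstroke_total
  alpha0 <- PRESTROKE_LEG_ANGLE
  seg_rows_loc <- 3L + seq_len(n + 1L)     # segs + hinge, local

  for (fr in seq_len(max_frames)) {
    ## ---- 1. random moves at every level --------------------------------
    if (mv$actin_translation > 0)
      X[seq_len(N), ] <- X[seq_len(N), ] +
        mv$actin_translation * random_unit_vectors(N)
    for (h in 1:2) {
      rws <- rows_half[[h]]
      dmp <- damping_schedule(st[h], in_zone[h])
      if (is.finite(dmp[1]) && mv$mol_translation > 0) {
        u <- (mv$mol_translation / dmp[1]) * random_unit_vectors(1)[1, ]
        X[rws, ] <- sweep(X[rws, ], 2, u, `+`)
      }
      ang <- mv$mol_rotation / dmp[2]
      if (ang > 1e-6) {
        ctr <- colMeans(X[rws, ])
        X[rws, ] <- rotate_about(X[rws, ], random_unit_vectors(1)[1, ],
                                 ang, pivot = ctr)
      }
      ang <- mv$foot_rotation / dmp[2]
      if (ang > 1e-6) {
        frws <- rws[1:3]
        ctr <- colMeans(X[frws, ])
        X[frws, ] <- rotate_about(X[frws, ], random_unit_vectors(1)[1, ],
                                  ang, pivot = ctr)
      }
      if (mv$domain_translation > 0) {
        jr <- rws[seq_len(m - 1)]          # hinge is virtual: no jiggle
        X[jr, ] <- X[jr, ] + mv$domain_translation *
          random_unit_vectors(m - 1L)
      }
    }

    ## ---- 2. binding update per head ------------------------------------
    if (fr == 1L && verbose < 0L) diagm <- matrix(NA_real_, max_frames, 8)
    bind_rows <- vector("list", 2)
    point_rows <- vector("list", 2)
    just_tight <- c(FALSE, FALSE); stroking <- c(FALSE, FALSE)
    for (h in 1:2) {
      rws <- rows_half[[h]]
      core <- X[rws[1], ]; toe <- X[rws[2], ]; heel <- X[rws[3], ]
      fc <- (core + toe + heel) / 3
      ad <- axis_distance(fc, ring)
      ad_toe <- axis_distance(toe, ring)
      ad_heel <- axis_distance(heel, ring)

      ## recovery stroke / re-priming of a halted swing
      binding_allowed <- TRUE
      if (st[h] == 0L && swing[h] > 0) {
        if (swung[h]) binding_allowed <- FALSE
        swing[h] <- max(0, swing[h] - params$recovery_step)
        if (swing[h] <= 0 && swung[h]) {
          swung[h] <- FALSE
          binding_allowed <- TRUE
        }
      }

      tr <- binding_transition(st[h], ad, ad_toe, ad_heel, params,
                               binding_allowed,
                               ad_core = axis_distance(core, ring))
      ns <- tr$state
      in_zone[h] <- tr$in_zone
      if (verbose < 0L)
        diagm[fr, (h - 1L) * 4 + 1:4] <-
          c(ad, vnorm(X[rws[m], ] - fc),
            axis_distance(X[rws[m], ], ring), st[h])

      if (ns >= 1L) {
        dv <- X[seq_len(N), ] - matrix(fc, N, 3, byrow = TRUE)
        d2u <- rowSums(dv * dv)
        ## occupied-site exclusion: tight binding engages the bound
        ## unit's neighbour sites too, so a bound foot blocks its unit
        ## and the two units either side for the partner
        ob <- bu[3L - h]
        if (!is.na(ob))
          d2u[wrap_unit(ob + (-2L:2L), N)] <- Inf
        cu <- which.min(d2u)               # ties: lower index
        ## no capturable site: everything within reach is occupied or
        ## beyond the capture distance -- the head stays free
        if (sqrt(d2u[cu]) >= params$capture_axis_distance) {
          ns <- 0L
          bu[h] <- NA_integer_
        } else {
          ## dead-band on the loose re-choice: switch binding partner
          ## only when the new unit is clearly closer, so a foot sitting
          ## over a boundary does not dither between neighbours
          if (st[h] >= 1L && !is.na(bu[h]) && cu != bu[h] &&
              is.finite(d2u[bu[h]]) &&
              sqrt(d2u[cu]) > sqrt(d2u[bu[h]]) - 2.0) {
            cu <- bu[h]
          }
          ## a loose head may re-choose its binding partner every frame;
          ## a tight head is registered to its unit -- being dragged
          ## nearer to a different unit breaks tight binding instead of
          ## sliding
          if (ns == 2L && st[h] == 2L && !is.na(bu[h]) && cu != bu[h]) {
            ns <- 1L
          } else if (ns == 2L && st[h] == 2L) {
            cu <- bu[h]
          }
          if (!bound_ever[h]) {
            upos[h] <- unit_offset(cu, start_ref, N)
            bound_ever[h] <- TRUE
          } else if (!is.na(last_u[h]) && cu != last_u[h]) {
            upos[h] <- upos[h] + unit_offset(cu, last_u[h], N)
          }
          last_u[h] <- cu
          bu[h] <- cu
        }
      } else {
        bu[h] <- NA_integer_
      }
      ## a still-swung head cannot re-engage rigor while the partner is
      ## itself in bound rigor (same double-rigor infeasibility)
      if (ns == 2L && st[h] < 2L && swung[h] &&
          st[3L - h] == 2L && swung[3L - h]) {
        ns <- 1L
      }
      just_tight[h] <- ns == 2L && st[h] < 2L

      ## non-physical orientation corrections. A loosely bound head in
      ## the zone has its binding face steered toward the filament (roll
      ## and pitch -> 0, both free of plus/minus polarity; yaw is left
      ## free). A tightly bound head additionally has yaw corrected
      ## toward the plus-end alignment.
      if (ns == 1L && in_zone[h]) {
        p <- fc
        phi <- atan2(p[2], p[1])
        q <- ring$radius * c(cos(phi), sin(phi), 0)
        rr <- p - q
        r_hat <- if (vnorm(rr) < 1e-9) c(cos(phi), sin(phi), 0)
                 else rr / vnorm(rr)
        ff <- foot_frame(core, toe, heel)
        roll <- signed_angle_about(r_hat, ff$z_f, ff$x_f)
        tiltv <- asin(max(-1, min(1, sum(ff$x_f * r_hat))))
        frws <- rws[1:3]
        if (abs(roll) > 1e-4) {
          cr <- -sign(roll) * min(params$yawroll_step, abs(roll))
          X[frws, ] <- rotate_about(X[frws, ], ff$x_f, cr, pivot = fc)
        }
        axp <- pracma_cross(r_hat, ff$x_f)
        if (abs(tiltv) > 1e-4 && vnorm(axp) > 1e-9) {
          ct <- sign(tiltv) * min(params$yawroll_step, abs(tiltv))
          X[frws, ] <- rotate_about(X[frws, ], axp, ct, pivot = fc)
        }
        core <- X[rws[1], ]; toe <- X[rws[2], ]; heel <- X[rws[3], ]
      }
      aligned <- FALSE
      if (ns == 2L) {
        p <- fc
        phi <- atan2(p[2], p[1])
        r_hat0 <- c(cos(phi), sin(phi), 0)
        q <- ring$radius * r_hat0
        t_hat <- c(-sin(phi), cos(phi), 0)
        rr <- p - q
        r_hat <- if (vnorm(rr) < 1e-9) r_hat0 else rr / vnorm(rr)
        ff <- foot_frame(core, toe, heel)
        yaw <- signed_angle_about(t_hat, ff$x_f, r_hat)
        roll <- signed_angle_about(r_hat, ff$z_f, ff$x_f)
        aligned <- abs(yaw) < params$align_tolerance &&
          abs(roll) < params$align_tolerance
        frws <- rws[1:3]
        if (abs(yaw) > 1e-4) {
          cy <- -sign(yaw) * min(params$yawroll_step, abs(yaw))
          X[frws, ] <- rotate_about(X[frws, ], r_hat, cy, pivot = fc)
        }
        if (abs(roll) > 1e-4) {
          cr <- -sign(roll) * min(params$yawroll_step, abs(roll))
          X[frws, ] <- rotate_about(X[frws, ], ff$x_f, cr, pivot = fc)
        }
        core <- X[rws[1], ]; toe <- X[rws[2], ]; heel <- X[rws[3], ]
      }

      ## powerstroke progression: an incremental rotation of the leg
      ## about the foot centroid in the plane containing the local
      ## filament tangent and the leg, one 0.05 rad step per eligible
      ## frame, driving the hinge toward the plus end
      prev_swing <- swing[h]
      if (ns == 2L && !swung[h]) {
        o <- 3L - h
        partner_rigor <- st[o] == 2L && swung[o]
        if (aligned && swing[h] < total) {
          inc <- min(params$powerstroke_step, total - swing[h])
          swing[h] <- swing[h] + inc
          if (swing[h] >= total && partner_rigor) {
            ## two bound post-powerstroke levers sharing one hinge are
            ## geometrically infeasible with stiff legs: completing the
            ## stroke forces one head or the other to detach, with even
            ## odds which one
            if (stats::runif(1) < 0.5) {
              ## this head lets go just before completion
              swing[h] <- swing[h] - inc
              ns <- 0L
              bu[h] <- NA_integer_
            } else {
              ## the strained rigor partner is wrenched free in place
              st[o] <- 0L
              bu[o] <- NA_integer_
              swung[h] <- TRUE
            }
          } else if (swing[h] >= total) swung[h] <- TRUE
          p <- fc
          phi <- atan2(p[2], p[1])
          t_hat <- c(-sin(phi), cos(phi), 0) * ring$plus_direction
          u_leg <- X[rws[m], ] - fc
          nu <- vnorm(u_leg)
          if (nu > 1e-6) {
            u_leg <- u_leg / nu
            angt <- angle_between(u_leg, t_hat)
            if (angt > inc && angt < pi - 1e-3) {
              axs <- pracma_cross(u_leg, t_hat)
              X[rws[seg_rows_loc], ] <- rotate_about(
                X[rws[seg_rows_loc], ], axs, inc, pivot = fc)
            }
          }
        } else if (!aligned && swing[h] > 0) {
          ns <- 1L    # mid-swing loss of alignment: revert to loose
        }
      }
      stroking[h] <- ns == 2L && swing[h] != prev_swing

      ## binding restraints for this frame. The helical twist covers the
      ## filament surface with binding sites, so the effective site of a
      ## unit sits on the tube surface at the azimuth from which the foot
      ## approaches: its off-axis position pins the foot azimuth without
      ## ever pulling the foot through the filament body.
      site_of <- function(i) {
        ctr <- X[i, ]
        t_loc <- X[wrap_unit(i + 1L, N), ] - X[wrap_unit(i - 1L, N), ]
        t_loc <- t_loc / max(vnorm(t_loc), 1e-9)
        w <- fc - ctr
        w <- w - sum(w * t_loc) * t_loc
        nw <- vnorm(w)
        if (nw < 1e-6) {
          rho <- sqrt(ctr[1]^2 + ctr[2]^2)
          w <- c(ctr[1], ctr[2], 0) / max(rho, 1e-9)
        } else w <- w / nw
        ctr + ring$unit_radius * w
      }
      if (ns == 1L && in_zone[h]) {
        ## loose: both binding domains attracted to the closest unit's
        ## site (polarity, no direction preference); repel-only rows keep
        ## the fat foot core out of the inter-unit valleys so the foot
        ## can only seat binding-face down
        cu <- bu[h]
        s0 <- site_of(cu)
        point_rows[[h]] <- rbind(
          c(rws[2], s0, bt["toe_site"], bcorr, 1, cu),
          c(rws[3], s0, bt["heel_site"], bcorr, 1, cu))
        bind_rows[[h]] <- rbind(
          c(rws[1], cu, bt["core_central"], corr, -1),
          c(rws[1], wrap_unit(cu + 1L, N), bt["core_central"], corr, -1),
          c(rws[1], wrap_unit(cu - 1L, N), bt["core_central"], corr, -1))
      } else if (ns == 1L && params$initial_attraction) {
        bind_rows[[h]] <- rbind(
          c(rws[1], bu[h], bt["core_central"], corr, 1))
      } else if (ns == 2L) {
        ## tight: toe to the central and plus-side sites, heel to the
        ## central and minus-side sites, core seated on the central site
        cu <- bu[h]
        s0 <- site_of(cu)
        sp_ <- site_of(wrap_unit(cu + 1L, N))
        sm_ <- site_of(wrap_unit(cu - 1L, N))
        point_rows[[h]] <- rbind(
          c(rws[1], s0, bt["core_site"], bcorr, 0, cu),
          c(rws[2], s0, bt["toe_site"], bcorr, 0, cu),
          c(rws[2], sp_, bt["toe_plus"], bcorr, 0, wrap_unit(cu + 1L, N)),
          c(rws[3], s0, bt["heel_site"], bcorr, 0, cu),
          c(rws[3], sm_, bt["heel_minus"], bcorr, 0, wrap_unit(cu - 1L, N)))
      }

      ## lever maintenance. The ankle is freely rotating while the head
      ## is loose or tight pre-powerstroke, so a landing head binds
      ## without lever strain. The post-powerstroke (rigor) lever is
      ## held at its swung elevation in the foot frame; a free head's
      ## lever is held at its conformational angle, which -- with the
      ## hinge pinned by the restoration -- sweeps the foot forward
      ## during the recovery stroke.
      if ((ns == 2L && swung[h]) || ns == 0L) {
        alpha <- alpha0 + (if (ns == 2L) total else swing[h])
        ff <- foot_frame(core, toe, heel)
        dstar <- sin(alpha) * ff$x_f + cos(alpha) * ff$z_f
        fc2 <- ff$centroid
        u_leg <- X[rws[m], ] - fc2
        if (vnorm(u_leg) > 1e-6) {
          u_leg <- u_leg / vnorm(u_leg)
          angm <- angle_between(u_leg, dstar)
          if (angm > 1e-3 && angm < pi - 1e-3) {
            ax <- pracma_cross(u_leg, dstar)
            step_ang <- min(angm, mv$leg_servo)
            X[rws[seg_rows_loc], ] <- rotate_about(
              X[rws[seg_rows_loc], ], ax, step_ang, pivot = fc2)
          }
        }
      }
      st[h] <- ns
    }

    ## ---- ratchet variant ------------------------------------------------
    if (vr$ratchet) {
      rel <- ratchet_release(st, swung, upos, just_tight)
      if (rel > 0L) {
        st[rel] <- 0L
        bu[rel] <- NA_integer_
      }
    }

    ## ---- 3. restraints --------------------------------------------------
    dislocated <- vr$hinge_dislocate && any(stroking)
    ## the hinge-hinge elastic link routes its correction to the less
    ## firmly bound half (the free/loose side absorbs the strain), and is
    ## shared when both are equally bound
    w1 <- if (st[1] > st[2]) 0 else if (st[2] > st[1]) 1 else 0.5
    hinge_tab <- matrix(c(hinge_g[1], hinge_g[2], 0, corr, 0, w1), 1)
    tab <- rbind(cbind(stat_tab, 0.5),
                 if (!is.null(bind_rows[[1]])) cbind(bind_rows[[1]], 0.5),
                 if (!is.null(bind_rows[[2]])) cbind(bind_rows[[2]], 0.5),
                 if (!dislocated || vr$hinge_strong_link) hinge_tab)
    X <- X + apply_restraints_batch(X, tab, tol)
    ptab <- rbind(point_rows[[1]], point_rows[[2]])
    if (!is.null(ptab)) X <- X + apply_point_restraints_batch(X, ptab, tol)

    ## ---- 4. hinge restoration -------------------------------------------
    if (!dislocated) {
      h1p <- X[hinge_g[1], ]; h2p <- X[hinge_g[2], ]
      side <- hinge_restore_side(st[1], st[2])
      if (side == 0L) {
        mm <- (h1p + h2p) / 2
        X[rows_half[[1]], ] <- sweep(X[rows_half[[1]], ], 2, mm - h1p, `+`)
        X[rows_half[[2]], ] <- sweep(X[rows_half[[2]], ], 2, mm - h2p, `+`)
      } else if (side == 1L) {
        X[rows_half[[1]], ] <- sweep(X[rows_half[[1]], ], 2, h2p - h1p, `+`)
      } else {
        X[rows_half[[2]], ] <- sweep(X[rows_half[[2]], ], 2, h1p - h2p, `+`)
      }
    }

    ## ---- 5. steric exclusion (always active, last word) -----------------
    X <- steric_pass(X, N, gidx, grp, ring$unit_radius, myo_rows, myo_rad,
                     m1_rows, m2_rows, radii)

    ## ---- 6. record -------------------------------------------------------
    if (fr %% stride == 0L) {
      n_out <- n_out + 1L
      rec[n_out, ] <- c(fr, st[1], swung[1], if (is.na(bu[1])) NA else bu[1],
                        upos[1], st[2], swung[2],
                        if (is.na(bu[2])) NA else bu[2], upos[2])
    }

    if (verbose > 0L && fr %% verbose == 0L) {
      dig <- vapply(1:2, function(h) {
        rws <- rows_half[[h]]
        fc <- colMeans(X[rws[1:3], ])
        c(axis_distance(fc, ring),
          axis_distance(X[rws[2], ], ring),
          axis_distance(X[rws[3], ], ring),
          axis_distance(X[rws[1], ], ring),
          vnorm(X[rws[m], ] - fc))
      }, numeric(5))
      message(sprintf(
        paste0("f%6d st=%d%d sw=%.2f/%.2f swung=%d%d u=%s/%s D=%.1f/%.1f ",
               "ad=%.1f/%.1f toe=%.1f/%.1f heel=%.1f/%.1f core=%.1f/%.1f ",
               "legr=%.1f/%.1f hsep=%.2f"),
        fr, st[1], st[2], swing[1], swing[2], swung[1], swung[2],
        format(bu[1]), format(bu[2]), upos[1], upos[2],
        dig[1, 1], dig[1, 2], dig[2, 1], dig[2, 2], dig[3, 1], dig[3, 2],
        dig[4, 1], dig[4, 2], dig[5, 1], dig[5, 2],
        vnorm(X[hinge_g[1], ] - X[hinge_g[2], ])))
    }

    ## ---- termination ----------------------------------------------------
    free_run <- if (st[1] == 0L && st[2] == 0L) free_run + 1L else 0L
    if (free_run > config$stop$detach_grace) {
      term <- "detached"
      break
    }
    if (config$stop$n_laps > 0 && all(bound_ever) &&
        (upos[1] + upos[2]) / 2 >= config$stop$n_laps * N) {
      term <- "laps_done"
      break
    }
  }

  rec <- rec[seq_len(n_out), , drop = FALSE]
  frames <- data.frame(
    frame = as.integer(rec[, 1]),
    state1 = as.integer(rec[, 2]), swung1 = rec[, 3] > 0,
    unit1 = as.integer(rec[, 4]), d1 = rec[, 5],
    state2 = as.integer(rec[, 6]), swung2 = rec[, 7] > 0,
    unit2 = as.integer(rec[, 8]), d2 = rec[, 9])
  ## lap counters derived from D = C + L*N - S
  for (hh in 1:2) {
    ucol <- paste0("unit", hh); dcol <- paste0("d", hh)
    offr <- (frames[[ucol]] - start_ref) %% N
    lap <- round((frames[[dcol]] - offr) / N)
    lap[is.na(lap)] <- NA_integer_
    frames[[paste0("lap", hh)]] <- as.integer(lap)
  }
  traj <- new_trajectory(frames, n_units = N, spacing = config$unit_spacing,
                         start1 = start_ref, start2 = start_ref,
                         seed = as.integer(seed), config = config,
                         termination = term)
  if (verbose < 0L) attr(traj, "diag") <- diagm[seq_len(fr), , drop = FALSE]
  attr(traj, "final_state") <- list(
    actin = X[seq_len(N), , drop = FALSE],
    half1 = X[rows_half[[1]], , drop = FALSE],
    half2 = X[rows_half[[2]], , drop = FALSE],
    frame = fr, ring = ring)
  traj
}

## structural restraint table for one half (global row offset `off`):
## foot triangle, leg chain (adjacent + adjacent-but-one, free ankle), the
## two long leg braces (dropped for weak legs) and the hinge-leg links.
half_structural_tab <- function(n_iq, d, off, corr, weak_leg = FALSE) {
  ft <- FOOT_TEMPLATE
  foot <- rbind(
    c(1, 2, vnorm(ft["core", ] - ft["toe", ]), corr, 0),
    c(1, 3, vnorm(ft["core", ] - ft["heel", ]), corr, 0),
    c(2, 3, vnorm(ft["toe", ] - ft["heel", ]), corr, 0))
  chain <- c(1L, 3L + seq_len(n_iq), 4L + n_iq)   # core, segs, hinge
  nc <- length(chain)
  ## leg links are applied twice per frame (restraint strength scales
  ## with application frequency): the lever must be close to inextensible
  ## for the stepping geometry to be reach-limited
  adj <- cbind(chain[-nc], chain[-1], d, corr, 0)
  adj <- rbind(adj, adj)
  ## adjacent-but-one, skipping the ankle (core-seg2): freely rotating ankle
  ab1 <- if (nc >= 3) {
    keep <- 2:(nc - 2)
    ab <- cbind(chain[keep], chain[keep + 2], 2 * d, corr, 0)
    rbind(ab, ab)
  }
  long <- if (!weak_leg) {
    first <- 3L + 1L; last <- 3L + n_iq
    tgt <- (n_iq - 1) * d
    rbind(c(first, last, tgt, corr, 0), c(first, last, tgt, corr, 0))
  }
  ## end-to-end braces: a straight chain has |core-hinge| = L for any
  ## ankle rotation, so these forbid arc compression of the lever without
  ## restricting the freely rotating ankle
  hinge_l <- 4L + n_iq
  e2e_row <- rbind(c(1L, hinge_l, (n_iq + 1) * d, corr, 0),
                   c(3L + 1L, hinge_l, n_iq * d, corr, 0))
  e2e <- e2e_row[rep(1:2, each = 2L), , drop = FALSE]
  tab <- rbind(foot, adj, ab1, long, e2e)
  tab[, 1] <- tab[, 1] + off
  tab[, 2] <- tab[, 2] + off
  tab
}

## one steric-resolution pass. The filament body is a closed chain of
## capsules (radius = unit radius) between consecutive unit centres, so
## its surface is smooth with no inter-unit pockets; myosin nodes
## overlapping a capsule are pushed out along the local perpendicular,
## with the equal-and-opposite reaction shared between the two carrier
## units. The two myosin halves then repel each other sphere-on-sphere.
steric_pass <- function(X, N, gidx, grp, ra, myo_rows, myo_rad,
                        m1_rows, m2_rows, radii) {
  A <- X[seq_len(N), , drop = FALSE]
  Gc <- rowsum(A, grp)
  cnt <- tabulate(grp)
  Gc <- Gc / cnt
  d2g <- rowSums((A - Gc[grp, , drop = FALSE])^2)
  grad <- sqrt(vapply(split(d2g, grp), max, 0)) + ra + 3  # + segment slack
  M <- X[myo_rows, , drop = FALSE]
  D2 <- outer(rowSums(M^2), rep(1, nrow(Gc))) - 2 * M %*% t(Gc) +
    outer(rep(1, nrow(M)), rowSums(Gc^2))
  lim <- outer(myo_rad, grad, `+`)^2
  hits <- which(D2 < lim, arr.ind = TRUE)
  if (nrow(hits)) {
    nodes <- rep(hits[, 1], vapply(gidx[hits[, 2]], length, 0L))
    segs <- unlist(gidx[hits[, 2]], use.names = FALSE)  # segment = (i, i+1)
    nxt <- wrap_unit(segs + 1L, N)
    P <- M[nodes, , drop = FALSE]
    A1 <- A[segs, , drop = FALSE]
    V <- A[nxt, , drop = FALSE] - A1
    tt <- rowSums((P - A1) * V) / pmax(rowSums(V * V), 1e-9)
    tt <- pmin(1, pmax(0, tt))
    Q <- A1 + tt * V
    dv <- P - Q
    dd <- sqrt(rowSums(dv * dv))
    depth <- myo_rad[nodes] + ra - dd
    ov <- depth > 0
    if (any(ov)) {
      nodes <- nodes[ov]; segs <- segs[ov]; nxt <- nxt[ov]; tt <- tt[ov]
      u <- dv[ov, , drop = FALSE] / pmax(dd[ov], 1e-9)
      push <- 0.5 * depth[ov] * u
      accn <- rowsum(push, group = nodes)
      rn <- as.integer(rownames(accn))
      X[myo_rows[rn], ] <- X[myo_rows[rn], ] + accn
      acca <- rowsum(rbind(-(1 - tt) * push, -tt * push),
                     group = c(segs, nxt))
      rn <- as.integer(rownames(acca))
      X[rn, ] <- X[rn, ] + acca
    }
  }
  ## half vs half
  M1 <- X[m1_rows, , drop = FALSE]; M2 <- X[m2_rows, , drop = FALSE]
  D2 <- outer(rowSums(M1^2), rep(1, nrow(M2))) - 2 * M1 %*% t(M2) +
    outer(rep(1, nrow(M1)), rowSums(M2^2))
  lim <- outer(radii[m1_rows], radii[m2_rows], `+`)^2
  hits <- which(D2 < lim, arr.ind = TRUE)
  if (nrow(hits)) {
    dv <- M1[hits[, 1], , drop = FALSE] - M2[hits[, 2], , drop = FALSE]
    dd <- sqrt(rowSums(dv * dv))
    depth <- radii[m1_rows][hits[, 1]] + radii[m2_rows][hits[, 2]] - dd
    u <- dv / pmax(dd, 1e-9)
    push <- 0.5 * depth * u
    acc1 <- rowsum(push, group = hits[, 1])
    rn <- as.integer(rownames(acc1))
    X[m1_rows[rn], ] <- X[m1_rows[rn], ] + acc1
    acc2 <- rowsum(-push, group = hits[, 2])
    rn <- as.integer(rownames(acc2))
    X[m2_rows[rn], ] <- X[m2_rows[rn], ] + acc2
  }
  X
}

#' Per-lap frame counts of a trajectory
#'
#' A lap is completed when the cumulative dimer position (mean of the two
#' heads' unwrapped distances) first crosses a multiple of the track size,
#' so backsteps and unit revisits do not double-count.
#'
#' @param traj `myo_trajectory`.
#' @return numeric vector of frames per completed lap (empty if none).
#' @export
lap_time <- function(traj) {
  stopifnot(inherits(traj, "myo_trajectory"))
  if (!nrow(traj)) return(numeric())
  N <- attr(traj, "n_units")
  d_mid <- (traj$d1 + traj$d2) / 2
  n_laps <- floor(max(d_mid) / N)
  if (n_laps < 1) return(numeric())
  crossings <- vapply(seq_len(n_laps), function(k)
    traj$frame[which(d_mid >= k * N)[1]], numeric(1))
  diff(c(traj$frame[1] - 1, crossings))
}
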