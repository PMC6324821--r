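# Flexible refinement: simulated-annealing rigid-body moves under the
# composite map + restraint energy, followed by conjugate-gradient
# minimization at bead level.

#' Refinement configuration
#'
#' Schedule and weights of the flexible refinement: a maximum of
#' `max_cycles` simulated-annealing cycles, each heating 0 -> `t_max` K
#' over at most `heat_steps` steps and cooling back over at most
#' `cool_steps`; the optimization terminates early when the CCC change
#' drops below `dccc_tol`; a final conjugate-gradient minimization runs
#' `cg_steps` steps with weights `W1 = W2 = W3 = 1` and `cg_steps` more
#' with `W1 = 0`.
#'
#' @param w1,w2,w3 energy weights (map term, harmonic/bond terms, excluded
#'   volume); defaults 1.
#' @param max_cycles maximal SA cycles (default 50).
#' @param t_max peak temperature (K, default 1000).
#' @param heat_steps,cool_steps maximal steps per ramp (defaults 100, 200).
#' @param dccc_tol CCC-change stopping tolerance (default 0.001).
#' @param cg_steps conjugate-gradient steps per stage (default 200).
#' @param kb Boltzmann scaling of the Metropolis criterion
#'   (energy units per K; default 1e-4).
#' @param trans_step,rot_step SA move sizes (nm, rad).
#' @param patience number of consecutive non-improving basin-hop cycles
#'   tolerated before the cycle loop stops (default 10).
#' @return a list of class `refinement_config`.
#' @export
refinement_config <- function(w1 = 1, w2 = 1, w3 = 1, max_cycles = 50,
                              t_max = 1000, heat_steps = 100,
                              cool_steps = 200, dccc_tol = 0.001,
                              cg_steps = 200, kb = 1e-4, trans_step = 10,
                              rot_step = 0.1, patience = 10) {
  stopifnot(max_cycles > 0, t_max > 0, heat_steps > 0, cool_steps > 0,
            dccc_tol > 0, cg_steps > 0, patience >= 1)
  structure(list(w1 = w1, w2 = w2, w3 = w3, max_cycles = max_cycles,
                 t_max = t_max, heat_steps = heat_steps,
                 cool_steps = cool_steps, dccc_tol = dccc_tol,
                 cg_steps = cg_steps, kb = kb, trans_step = trans_step,
                 rot_step = rot_step, patience = patience),
            class = "refinement_config")
}

# Validate a rigid-body partition: list of contiguous, non-overlapping
# index ranges covering all beads.
validate_partition <- function(partition, n_beads) {
  idx <- sort(unlist(partition))
  if (!identical(idx, seq_len(n_beads)))
    stop_ct("partition must cover all beads exactly once")
  for (b in partition)
    if (!identical(as.integer(b), as.integer(min(b):max(b))))
      stop_ct("partition ranges must be contiguous")
  lapply(partition, as.integer)
}

#' Composite flexible-fitting energy
#'
#' `E = W1 E_CCC + W2 (E_HLB + E_HUB + E_C) + W3 E_EV` where `E_CCC` is the
#' negative sum of cross-correlation coefficients between the map and the
#' rendered rigid bodies, the harmonic terms are one-sided quadratic
#' penalties at their equilibrium distances, `E_C` the connectivity bonds,
#' and `E_EV` a hard-sphere lower-bound term dropping to zero at `2r`.
#'
#' @param coords bead coordinates (n x 3) or a `bead_model`.
#' @param map target `density_map`.
#' @param restraints a `restraint_set`.
#' @param partition list of bead-index ranges (rigid bodies) covering the
#'   model.
#' @param config a [refinement_config()] (supplies the weights).
#' @return a list with `total` and components `e_ccc, e_lb, e_ub, e_c,
#'   e_ev` (unweighted), plus `ccc` (full-model CCC, for the stop rule).
#' @export
flex_energy <- function(coords, map, restraints, partition,
                        config = refinement_config()) {
  if (inherits(coords, "bead_model")) coords <- coords$coords
  partition <- validate_partition(partition, nrow(coords))
  rc <- restraint_codes(restraints)
  er <- cpp_restraint_energy(coords, rc$i, rc$j, rc$kind, rc$d0, rc$k,
                             restraints$r, restraints$k_ev,
                             want_grad = FALSE)
  target <- as.numeric(map$data)
  e_ccc <- -sum(vapply(partition, function(b) {
    v <- cpp_render_ccc(coords[b, , drop = FALSE], target, dim(map$data),
                        map$origin, map$voxel, map$sigma)
    if (is.na(v)) 0 else v
  }, numeric(1)))
  full_ccc <- cpp_render_ccc(coords, target, dim(map$data), map$origin,
                             map$voxel, map$sigma)
  total <- config$w1 * e_ccc +
    config$w2 * (er$e_lb + er$e_ub + er$e_c) + config$w3 * er$e_ev
  list(total = total, e_ccc = e_ccc, e_lb = er$e_lb, e_ub = er$e_ub,
       e_c = er$e_c, e_ev = er$e_ev, ccc = full_ccc)
}

# Gradient of the composite energy with respect to all bead coordinates.
flex_energy_grad <- function(coords, map, restraints, partition, w1, w2, w3) {
  rc <- restraint_codes(restraints)
  er <- cpp_restraint_energy(coords, rc$i, rc$j, rc$kind, rc$d0, rc$k,
                             restraints$r, restraints$k_ev,
                             w_pair = w2, w_ev = w3, want_grad = TRUE)
  g <- er$grad
  e <- w2 * (er$e_lb + er$e_ub + er$e_c) + w3 * er$e_ev
  if (w1 != 0) {
    target <- as.numeric(map$data)
    for (b in partition) {
      cg <- cpp_ccc_grad(coords[b, , drop = FALSE], target, dim(map$data),
                         map$origin, map$voxel, map$sigma)
      if (!is.na(cg$ccc)) {
        e <- e - w1 * cg$ccc
        g[b, ] <- g[b, ] - w1 * cg$grad
      }
    }
  }
  list(energy = e, grad = g)
}

#' Flexible refinement of a rigid fit
#'
#' Starting from a rigidly fitted bead model, runs up to
#' `config$max_cycles` simulated-annealing cycles of Metropolis rigid-body
#' moves (each body of the partition is perturbed by a small random
#' rotation + translation; the temperature ramps 0 -> `t_max` over at most
#' `heat_steps` steps and back over at most `cool_steps`). A cycle's
#' dynamics stop early once the per-step CCC change falls below
#' `dccc_tol`, and the cycle loop stops when a full cycle improves the CCC
#' by less than `dccc_tol`. A two-stage conjugate-gradient minimization
#' follows (`cg_steps` with `W1 = W2 = W3 = 1`, then `cg_steps` with
#' `W1 = 0`). The returned model is the candidate (per-cycle snapshots +
#' CG result) that maximizes CCC, ties broken by minimal clash score.
#'
#' @param start starting coordinates: a `bead_model`, an n x 3 matrix, or a
#'   `rigid_fit_ensemble` (its best fit is used).
#' @param map target `density_map`.
#' @param restraints a `restraint_set`.
#' @param partition list of bead-index ranges (rigid bodies).
#' @param config a [refinement_config()].
#' @param seed RNG seed.
#' @return an object of class `flex_refinement`: refined `model`,
#'   `trajectory` (cycle, step, temperature, E, CCC), `start_ccc`,
#'   `final_ccc`, `start_clash`, `final_clash`, `energy` components at the
#'   end.
#' @export
flexible_refine <- function(start, map, restraints, partition,
                            config = refinement_config(), seed = NULL) {
  if (inherits(start, "rigid_fit_ensemble")) {
    coords <- start$coords
    r <- start$model$r
    bin <- start$model$bin_size
  } else if (inherits(start, "bead_model")) {
    coords <- start$coords
    r <- start$r
    bin <- start$bin_size
  } else {
    coords <- as.matrix(start)
    r <- restraints$r
    bin <- restraints$bin_size
  }
  n <- nrow(coords)
  partition <- validate_partition(partition, n)
  target <- as.numeric(map$data)
  dm <- dim(map$data)

  e_of <- function(x) flex_energy(x, map, restraints, partition, config)
  ccc_of <- function(x) {
    v <- cpp_render_ccc(x, target, dm, map$origin, map$voxel, map$sigma)
    if (is.na(v)) -1 else v
  }

  e0 <- e_of(coords)
  start_ccc <- e0$ccc
  start_clash <- clash_score(coords, r = r)
  traj <- list(data.frame(cycle = 0L, step = 0L, temperature = 0,
                          energy = e0$total, ccc = e0$ccc))
  candidates <- list(list(coords = coords, ccc = start_ccc,
                          clash = start_clash))

  # pose gradient of the composite energy for one rigid body: map term from
  # the analytic per-body CCC gradient, restraint term from the net force
  # and torque of the restraint gradient on the body's beads. Moves are
  # displaced along this direction (the direction maximizing the body's
  # cross-correlation while honouring restraints), with thermal noise.
  rc <- restraint_codes(restraints)
  body_pose_grad <- function(coords, b) {
    cb <- colMeans(coords[b, , drop = FALSE])
    pg <- cpp_pose_ccc_grad(sweep(coords[b, , drop = FALSE], 2, cb),
                            diag(3), cb, target, dm, map$origin, map$voxel,
                            map$sigma)
    g <- -config$w1 * pg$grad  # d E_CCC / d pose (E_CCC = -sum ccc)
    er <- cpp_restraint_energy(coords, rc$i, rc$j, rc$kind, rc$d0, rc$k,
                               restraints$r, restraints$k_ev,
                               w_pair = config$w2, w_ev = config$w3,
                               want_grad = TRUE)
    gr <- er$grad[b, , drop = FALSE]
    rel <- sweep(coords[b, , drop = FALSE], 2, cb)
    g[1:3] <- g[1:3] + colSums(gr)
    g[4] <- g[4] + sum(rel[, 2] * gr[, 3] - rel[, 3] * gr[, 2])
    g[5] <- g[5] + sum(rel[, 3] * gr[, 1] - rel[, 1] * gr[, 3])
    g[6] <- g[6] + sum(rel[, 1] * gr[, 2] - rel[, 2] * gr[, 1])
    g  # gradient of E; moves descend along -g
  }

  run_sa <- function(coords) {
    e_cur <- e_of(coords)$total
    ccc_prev <- ccc_of(coords)
    best <- list(coords = coords, ccc = ccc_prev, e = e_cur)
    stall <- 0L
    for (cycle in seq_len(config$max_cycles)) {
      if (cycle > 1L) {
        # basin hop: restart from the best state and re-orient the worst
        # correlating body (alternating with the two worst jointly); each
        # hopped body takes the best of several candidate orientations
        coords <- best$coords
        bccc <- vapply(partition, function(b)
          cpp_render_ccc(coords[b, , drop = FALSE], target, dm,
                         map$origin, map$voxel, map$sigma), numeric(1))
        bccc[is.na(bccc)] <- -1
        ord <- order(bccc)
        hop <- if (stall %% 2L == 1L && length(partition) > 1L)
          ord[1:2] else ord[(stall %/% 2L) %% length(partition) + 1L]
        for (bi in hop) {
          b <- partition[[bi]]
          cb <- colMeans(coords[b, , drop = FALSE])
          rel <- sweep(coords[b, , drop = FALSE], 2, cb)
          # candidate orientations: random plus 180-degree flips about the
          # body's principal axes (the typical trapped states of elongated
          # bodies are near-flips)
          ax <- eigen(crossprod(rel), symmetric = TRUE)$vectors
          cands <- c(lapply(1:8, function(k) random_rotation()),
                     lapply(1:3, function(k)
                       rotation_matrix(pi * ax[, k])))
          trial_best <- NULL
          for (Rc in cands) {
            prop <- coords
            prop[b, ] <- sweep(rel %*% t(Rc), 2, cb, "+")
            ep <- e_of(prop)$total
            if (is.null(trial_best) || ep < trial_best$e)
              trial_best <- list(coords = prop, e = ep)
          }
          coords <- trial_best$coords
        }
        e_cur <- e_of(coords)$total
        ccc_prev <- ccc_of(coords)
      }
      temps <- c(seq(0, config$t_max, length.out = config$heat_steps),
                 seq(config$t_max, 0, length.out = config$cool_steps))
      for (s in seq_along(temps)) {
        Tk <- temps[s]
        hot <- Tk / config$t_max
        for (bi in seq_along(partition)) {
          b <- partition[[bi]]
          sub <- coords[b, , drop = FALSE]
          cb <- colMeans(sub)
          rg_b <- sqrt(mean(rowSums(sweep(sub, 2, cb)^2))) + 1e-9
          g <- body_pose_grad(coords, b)
          g[4:6] <- g[4:6] / rg_b
          gn <- sqrt(sum(g^2))
          dir <- if (is.finite(gn) && gn > 1e-14) -g / gn else numeric(6)
          move0 <- dir * config$trans_step * (1 - 0.5 * hot) +
            rnorm(6, sd = config$trans_step * hot)
          # backtracking on the directed move: accept the first improving
          # scale; failing that, a Metropolis decision on the full move
          for (scale in c(1, 0.5, 0.25, 0.125)) {
            move <- move0 * scale
            R <- rotation_matrix(move[4:6] / rg_b)
            prop <- coords
            prop[b, ] <- sweep(sweep(sub, 2, cb) %*% t(R), 2,
                               cb + move[1:3], "+")
            e_prop <- e_of(prop)$total
            dE <- e_prop - e_cur
            if (dE < 0) {
              coords <- prop
              e_cur <- e_prop
              break
            }
            if (scale == 1 && Tk > 0 &&
                runif(1) < exp(-dE / (config$kb * Tk))) {
              coords <- prop
              e_cur <- e_prop
              break
            }
          }
        }
        ccc_now <- ccc_of(coords)
        traj[[length(traj) + 1L]] <<- data.frame(
          cycle = cycle, step = s, temperature = Tk, energy = e_cur,
          ccc = ccc_now)
        # the per-step CCC-stall termination detects quench convergence;
        # it is evaluated on cooling steps (heating perturbs on purpose)
        if (s > config$heat_steps &&
            abs(ccc_now - ccc_prev) < config$dccc_tol) {
          ccc_prev <- ccc_now
          break
        }
        ccc_prev <- ccc_now
      }
      candidates[[length(candidates) + 1L]] <<- list(
        coords = coords, ccc = ccc_prev, clash = clash_score(coords, r = r))
      # the cycle loop ends once annealing stops improving the best CCC
      # (patience of 3 hop cycles)
      if (ccc_prev > best$ccc + config$dccc_tol) {
        best <- list(coords = coords, ccc = ccc_prev, e = e_cur)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    best$coords
  }
  coords <- with_seed(seed, run_sa(coords))

  # two-stage conjugate-gradient minimization at bead level
  cg_stage <- function(coords, w1) {
    par0 <- as.numeric(coords)
    fn <- function(p) {
      x <- matrix(p, n, 3)
      fe <- flex_energy_grad(x, map, restraints, partition, w1, config$w2,
                             config$w3)
      fe$energy
    }
    gr <- function(p) {
      x <- matrix(p, n, 3)
      as.numeric(flex_energy_grad(x, map, restraints, partition, w1,
                                  config$w2, config$w3)$grad)
    }
    opt <- optim(par0, fn, gr, method = "CG",
                 control = list(maxit = config$cg_steps))
    matrix(opt$par, n, 3)
  }
  coords <- cg_stage(coords, w1 = config$w1)
  candidates[[length(candidates) + 1L]] <- list(
    coords = coords, ccc = ccc_of(coords), clash = clash_score(coords, r = r))
  coords <- cg_stage(coords, w1 = 0)
  if (any(!is.finite(coords)))
    stop_ct("refinement diverged: non-finite coordinates")
  candidates[[length(candidates) + 1L]] <- list(
    coords = coords, ccc = ccc_of(coords), clash = clash_score(coords, r = r))

  # final selection: maximal CCC, ties (within dccc_tol) by minimal clash
  cccs <- vapply(candidates, function(c) c$ccc, numeric(1))
  clashes <- vapply(candidates, function(c) c$clash, numeric(1))
  near <- which(cccs >= max(cccs) - config$dccc_tol)
  best <- near[which.min(clashes[near])]
  final <- candidates[[best]]

  e_fin <- e_of(final$coords)
  structure(list(model = bead_model(final$coords, r = r, bin_size = bin),
                 trajectory = do.call(rbind, traj),
                 start_ccc = start_ccc, final_ccc = final$ccc,
                 start_clash = start_clash, final_clash = final$clash,
                 energy = e_fin, config = config),
            class = "flex_refinement")
}

#' @export
print.flex_refinement <- function(x, ...) {
  cat(sprintf("flex_refinement: CCC %.3f -> %.3f; clash %.2f -> %.2f\n",
              x$start_ccc, x$final_ccc, x$start_clash, x$final_clash))
  cat(sprintf("  %d SA cycles logged; final E = %.4g\n",
              max(x$trajectory$cycle), x$energy$total))
  invisible(x)
}
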