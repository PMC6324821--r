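# Restraint-based generation of bead-model ensembles.

#' Generate a restraint-satisfying model ensemble
#'
#' Generates `n_models` conformations by minimizing the restraint energy
#' (harmonic bounds + connectivity bonds + excluded volume) from random
#' initial coordinates, ranks them by final energy, and returns the best
#' `n_keep`.
#'
#' @param restraints a `restraint_set`.
#' @param n_models conformations to generate (default 5000).
#' @param n_keep conformations to retain (default 1000; `<= n_models`).
#' @param seed RNG seed.
#' @param max_iter gradient-descent iterations per model.
#' @param init_scale spread of the random initial coordinates (nm); default
#'   `max_dist`-like `2 r sqrt(n)`.
#' @return a list of class `model_ensemble`: `models` (list of
#'   `bead_model`s sorted by energy), `energies` (all final energies,
#'   sorted), `kept` (indices into the generated order).
#' @export
model_ensemble <- function(restraints, n_models = 5000, n_keep = 1000,
                           seed = NULL, max_iter = 300, init_scale = NULL) {
  if (n_keep > n_models) stop_ct("n_keep must be <= n_models")
  rc <- restraint_codes(restraints)
  n <- restraints$n_beads
  init_scale <- init_scale %||% (2 * restraints$r * sqrt(n))

  fits <- with_seed(seed, lapply(seq_len(n_models), function(mi) {
    x0 <- matrix(rnorm(3 * n, sd = init_scale / 2), n, 3)
    cpp_minimize_restraints(x0, rc$i, rc$j, rc$kind, rc$d0, rc$k,
                            restraints$r, restraints$k_ev,
                            max_iter = max_iter,
                            step0 = restraints$r)
  }))
  energies <- vapply(fits, function(f) f$energy, numeric(1))
  ord <- order(energies)
  kept <- ord[seq_len(n_keep)]
  models <- lapply(kept, function(i)
    bead_model(fits[[i]]$coords, r = restraints$r,
               bin_size = restraints$bin_size))
  structure(list(models = models, energies = energies[ord], kept = kept),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("model_ensemble: %d models kept (energy %.4g .. %.4g)\n",
              length(x$models), x$energies[1],
              x$energies[length(x$models)]))
  invisible(x)
}
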