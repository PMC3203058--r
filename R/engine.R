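#' Run Metropolis Monte Carlo dynamics
#'
#' Executes `sweeps` MC sweeps (one sweep = one attempted move per movable
#' entity on average).  Each attempt picks a bead or molecule uniformly;
#' molecules propose a uniform nearest-neighbour step, beads propose the
#' applicable local move (corner flip for right-angle interior beads, single
#' step rotation for chain ends, crankshaft for eligible U-shaped
#' quadruples); inapplicable selections are null moves and count as
#' attempts, so proposals stay symmetric.  Acceptance follows
#' `min(1, exp(-dE))` with incremental local energies.
#'
#' @param state Initial [new_system_state()].
#' @param params A [model_params()] object.
#' @param sweeps Number of MC sweeps (default from `params`).
#' @param record_every Sweeps between observable samples.
#' @param seed Optional RNG seed; runs are bitwise reproducible given the
#'   seed and configuration.
#' @param frame_every If positive, store coordinate frames at this sweep
#'   interval (for trajectory output).
#' @param validate_every If positive, re-check all state invariants at this
#'   sweep interval (aborts with a diagnostic on violation).
#' @return An object of class `mc_run`: list with `series` (a tibble of
#'   recorded observables: `sweep`, `P_alpha`, `P_beta`, `P`, `S`,
#'   `cluster_A`, `cluster_B`, `rho1`, `rho2`, `energy`, MSD columns),
#'   `final_state`, `acceptance` (per move kind), `energy` (initial /
#'   running / recomputed and their drift), `frames`, and the call
#'   configuration.
#' @export
#' @examples
#' p <- model_params(n = 1, L = 8, c = 0.02, sweeps = 200, record_every = 20)
#' st <- init_state(p, "open", seed = 1)
#' run <- run_mc(st, p, seed = 1)
#' tidy(run)
run_mc <- function(state, params, sweeps = params$sweeps,
                   record_every = params$record_every, seed = NULL,
                   frame_every = 0, validate_every = 0) {
  stopifnot(sweeps >= 0)
  if (sweeps > 0 && record_every > sweeps) record_every <- sweeps
  if (!is.null(seed)) set.seed(seed)
  a <- state_to_cpp(state, params)
  cols <- c("sweep", "P_alpha", "P_beta", "P", "S", "cluster_A", "cluster_B",
            "rho1", "rho2", "energy", "msd_molecules", "msd_com1", "msd_com2")
  if (sweeps == 0) {
    e <- total_energy(state, params)
    series <- as_tibble(setNames(as.data.frame(matrix(numeric(0), 0, 13)), cols))
    return(structure(
      list(series = series, final_state = state,
           acceptance = tibble(kind = character(0), attempts = numeric(0),
                               accepts = numeric(0), nulls = numeric(0)),
           energy = list(initial = e$total, running = e$total,
                         recomputed = e$total, drift = 0),
           frames = list(), params = params, sweeps = 0L,
           record_every = record_every, seed = seed),
      class = "mc_run"))
  }
  res <- cpp_run_mc(a$beads, a$btype, a$bpoly, a$bblock, a$mols, a$msp,
                    a$L, a$affinity, a$ehomo, a$valency, a$cap_total,
                    as.integer(sweeps), as.integer(record_every),
                    params$shell_radius, as.integer(frame_every),
                    as.integer(validate_every))
  series <- as_tibble(setNames(as.data.frame(res$series), cols))
  final_state <- new_system_state(
    state$L, res$beads, state$bead_type, state$bead_poly, state$bead_block,
    res$mols, state$mol_species
  )
  structure(
    list(
      series = series,
      final_state = final_state,
      acceptance = tibble(
        kind = as.character(res$move_kinds),
        attempts = res$attempts, accepts = res$accepts, nulls = res$nulls,
        rate = ifelse(res$attempts > 0, res$accepts / res$attempts, NA_real_)
      ),
      energy = list(
        initial = res$energy_initial,
        running = res$energy_running,
        recomputed = res$energy_final,
        drift = res$energy_running - res$energy_final
      ),
      frames = lapply(res$frames, function(f) {
        list(sweep = f$sweep,
             state = new_system_state(state$L, f$beads, state$bead_type,
                                      state$bead_poly, state$bead_block,
                                      f$mols, state$mol_species))
      }),
      params = params, sweeps = as.integer(sweeps),
      record_every = as.integer(record_every), seed = seed
    ),
    class = "mc_run"
  )
}

#' @export
print.mc_run <- function(x, ...) {
  cat("<mc_run>", x$sweeps, "sweeps,", nrow(x$series), "records\n")
  if (nrow(x$series)) {
    tail_n <- max(1, nrow(x$series) %/% 2)
    w <- tail(x$series, tail_n)
    cat("  tail means: P =", round(mean(w$P), 3),
        " S =", round(mean(w$S), 3),
        " E =", round(mean(w$energy), 2), "kT\n")
  }
  cat("  energy bookkeeping drift:", format(x$energy$drift), "kT\n")
  invisible(x)
}

#' @rdname run_mc
#' @param x An `mc_run` object.
#' @param ... Unused.
#' @export
tidy.mc_run <- function(x, ...) x$series

#' @rdname run_mc
#' @export
glance.mc_run <- function(x, ...) {
  w <- tail(x$series, max(1, nrow(x$series) %/% 2))
  tibble(
    sweeps = x$sweeps,
    records = nrow(x$series),
    P_mean = mean(w$P), S_mean = mean(w$S), S_abs_mean = mean(abs(w$S)),
    cluster_A = mean(w$cluster_A), cluster_B = mean(w$cluster_B),
    energy_mean = mean(w$energy),
    accept_rate = sum(x$acceptance$accepts) / max(1, sum(x$acceptance$attempts)),
    energy_drift = x$energy$drift
  )
}

# histogram sampler over canonical (translation-quotiented) microstate codes
# of the enumerable micro-system; used by the Boltzmann equivalence checks
run_histogram <- function(state, params, sweeps, sample_every_moves = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- state_to_cpp(state, params)
  counts <- cpp_run_histogram(a$beads, a$btype, a$bpoly, a$bblock, a$mols,
                              a$msp, a$L, a$affinity, a$ehomo, a$valency,
                              a$cap_total, as.numeric(sweeps),
                              as.integer(sample_every_moves))
  counts
}
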