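# state -> arguments for the compiled engine (0-based codes)
state_to_cpp <- function(state, params) {
  list(
    beads = state$bead_coords,
    btype = state$bead_type - 1L,
    bpoly = state$bead_poly - 1L,
    bblock = state$bead_block - 1L,
    mols = state$mol_coords,
    msp = state$mol_species - 1L,
    L = state$L,
    affinity = unname(params$affinity),
    ehomo = c(params$E_A, params$E_B),
    valency = params$valency,
    cap_total = identical(params$cap_scope, "total")
  )
}

#' Total energy of a microstate
#'
#' The state energy in kT units: heterotypic molecule-bead binding plus
#' homotypic molecule-molecule binding, both counted under the valency cap.
#' For each molecule the six nearest-neighbour sites are scanned in a fixed
#' lexicographic offset order; a cognate bead contributes `-affinity`, a
#' same-species molecule a homotypic bond candidate, and counting stops at
#' `valency` bonds.  A homotypic pair contributes `-E_A` (or `-E_B`) exactly
#' once, and only when the pair lies within the counted candidates of both
#' partners, which makes the energy a deterministic pure function of the
#' microstate.
#'
#' @param state A [new_system_state()] object.
#' @param params A [model_params()] object.
#' @return An object of class `energy_breakdown`: a list with
#'   `hetero_total`, `homo_total`, `total` (all in kT, non-positive) and a
#'   tibble `per_molecule` of counted hetero and homo bonds.
#' @export
#' @examples
#' p <- model_params(n = 1, L = 8, c = 0.02)
#' st <- init_state(p, "open", seed = 1)
#' total_energy(st, p)$total
total_energy <- function(state, params) {
  validate_state(state)
  a <- state_to_cpp(state, params)
  res <- cpp_total_energy(a$beads, a$btype, a$bpoly, a$bblock, a$mols, a$msp,
                          a$L, a$affinity, a$ehomo, a$valency, a$cap_total)
  structure(
    list(
      hetero_total = res$hetero_total,
      homo_total = res$homo_total,
      total = res$total,
      per_molecule = tibble(
        molecule = seq_along(res$hetero_bonds),
        species = SPECIES[state$mol_species],
        hetero_bonds = res$hetero_bonds,
        homo_bonds = res$homo_bonds
      )
    ),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> total =", x$total, "kT ( hetero",
      x$hetero_total, "+ homo", x$homo_total, ")\n")
  invisible(x)
}

#' Construct a proposed move
#'
#' Moves are the engine's proposal types: a molecule step, a single-bead
#' displacement (corner flip or end rotation), or a crankshaft rotation of
#' two interior beads.  Coordinates are the proposed absolute positions.
#'
#' @param kind One of `"molecule_step"`, `"bead_step"`, `"crankshaft"`.
#' @param index Target molecule index (molecule step) or bead index
#'   (bead step: the moved bead; crankshaft: the first bead `i` of the
#'   quadruple `i..i+3`).
#' @param to Proposed coordinates: one triple, or two rows for a crankshaft
#'   (new positions of beads `i+1` and `i+2`).
#' @return A `proposed_move` object.
#' @export
proposed_move <- function(kind = c("molecule_step", "bead_step", "crankshaft"),
                          index, to) {
  kind <- match.arg(kind)
  to <- matrix(as.integer(to), ncol = 3)
  if (kind == "crankshaft" && nrow(to) != 2) {
    abort("crankshaft moves need two proposed coordinates")
  }
  structure(list(kind = kind, index = as.integer(index), to = to),
            class = "proposed_move")
}

#' Apply a proposed move to a state
#'
#' Returns the new state (validated); used by [delta_energy()] and by tests.
#' @param state A [new_system_state()] object.
#' @param move A [proposed_move()].
#' @return The updated `system_state`.
#' @export
apply_move <- function(state, move) {
  L <- state$L
  if (move$kind == "molecule_step") {
    state$mol_coords[move$index, ] <- move$to %% L
  } else if (move$kind == "bead_step") {
    state$bead_coords[move$index, ] <- move$to %% L
  } else {
    state$bead_coords[move$index + 1L, ] <- move$to[1, ] %% L
    state$bead_coords[move$index + 2L, ] <- move$to[2, ] %% L
  }
  validate_state(state)
  state
}

#' Energy difference of a proposed move
#'
#' Reference form of the incremental energy: exactly
#' `total_energy(after) - total_energy(before)`.  The compiled engine
#' computes the same difference locally during a run; the agreement of the
#' two routes over long trajectories is part of the test suite.
#'
#' @inheritParams apply_move
#' @param params A [model_params()] object.
#' @return The energy difference in kT.
#' @export
delta_energy <- function(state, move, params) {
  after <- apply_move(state, move)
  total_energy(after, params)$total - total_energy(state, params)$total
}

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-delta_E))`; temperature is absorbed
#' into the kT energy units.
#'
#' @param delta_E Energy difference of the proposed move (kT).
#' @return Logical: accept the move?
#' @export
metropolis_accept <- function(delta_E) {
  delta_E <= 0 || runif(1) < exp(-delta_E)
}
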