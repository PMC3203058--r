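#' Default typed block layout of the polymer
#'
#' The canonical region architecture: two alpha blocks 5', a central gamma
#' block, two beta blocks 3', separated by inert spacers.  All blocks have
#' length `n` (the spacers share the functional block length).
#'
#' @param n Binding sites per region (block length), a positive integer.
#' @return A tibble with columns `block`, `type`, `length`.
#' @export
#' @examples
#' default_layout(4)
default_layout <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.")
  }
  tibble(
    block = 1:9,
    type = c("alpha", "inert", "alpha", "inert", "gamma",
             "inert", "beta", "inert", "beta"),
    length = as.integer(n)
  )
}

#' Typed polymer specification
#'
#' Describes the ordered block structure shared by both polymers.  The layout
#' must contain exactly two alpha blocks, two beta blocks and one gamma
#' block; per-block lengths are configurable (deletion/insertion scans), with
#' the default layout giving every block length `n`.
#'
#' @param n Binding sites per functional region (default block length).
#' @param layout Optional custom layout tibble (`block`, `type`, `length`).
#' @return An object of class `polymer_spec`.
#' @export
polymer_spec <- function(n = 4, layout = NULL) {
  layout <- layout %||% default_layout(n)
  stopifnot(all(c("type", "length") %in% names(layout)))
  layout$type <- as.character(layout$type)
  layout$length <- as.integer(layout$length)
  if (!all(layout$type %in% REGION_TYPES)) {
    abort("layout types must be among: alpha, beta, gamma, inert")
  }
  if (sum(layout$type == "alpha") != 2 || sum(layout$type == "beta") != 2 ||
      sum(layout$type == "gamma") != 1) {
    abort("layout must contain exactly two alpha, two beta and one gamma block")
  }
  if (any(layout$length < 1)) abort("all block lengths must be positive")
  layout$block <- seq_len(nrow(layout))
  structure(
    list(n = as.integer(n), layout = layout,
         n_beads = sum(layout$length)),
    class = "polymer_spec"
  )
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat("<polymer_spec> ", x$n_beads, " beads, n = ", x$n, "\n", sep = "")
  cat(paste0(x$layout$type, "(", x$layout$length, ")", collapse = " - "), "\n")
  invisible(x)
}

#' Species-by-region affinity matrix
#'
#' Heterotypic binding energies in kT units (positive magnitudes, applied as
#' negative energy contributions).  By default species A binds alpha and
#' gamma at `E_X`, species B binds beta and gamma at `E_X`.  The gamma
#' affinities can be skewed per species (`E_A_gamma`, `E_B_gamma`), the
#' asymmetric scenario relevant to the single-X (male) case.
#'
#' @param E_X Binding affinity of each species for its cognate regions (kT).
#' @param E_A_gamma,E_B_gamma Species-specific gamma affinities (default `E_X`).
#' @return A 2x4 numeric matrix, rows `A`,`B`, columns the region types.
#' @export
affinity_matrix <- function(E_X, E_A_gamma = E_X, E_B_gamma = E_X) {
  m <- matrix(0, 2, 4, dimnames = list(SPECIES, REGION_TYPES))
  m["A", "alpha"] <- E_X
  m["A", "gamma"] <- E_A_gamma
  m["B", "beta"] <- E_X
  m["B", "gamma"] <- E_B_gamma
  m
}

#' Model parameters
#'
#' Gathers every control parameter of the model: lattice, polymer layout,
#' binder concentration and energies, valency, and run-control defaults.
#'
#' @param n Binding sites per functional region.
#' @param L Lattice side length (sites per dimension, periodic boundaries).
#' @param c Volume fraction of each binder species (molecules per lattice
#'   site, `0 < c < 1`); each species independently has `round(c * L^3)`
#'   molecules.
#' @param E_X Heterotypic molecule-bead affinity in kT.
#' @param E_A,E_B Homotypic molecule-molecule affinities in kT.
#' @param valency Maximum number of counted bonds per molecule (default 4,
#'   the CTCF-like choice).
#' @param cap_scope Whether the valency cap applies to all counted bonds
#'   (`"total"`) or to homotypic bonds only (`"homo"`, default).
#' @param affinity Optional custom 2x4 affinity matrix (see
#'   [affinity_matrix()]).
#' @param layout Optional custom block layout (see [polymer_spec()]).
#' @param d0 Lattice spacing in nanometres (calibration input).
#' @param shell_radius Chebyshev radius (lattice units) of the density shell
#'   around gamma regions used by the symmetry-breaking parameter.
#' @param sweeps,record_every,equilibration_sweeps,replicates Run-control
#'   defaults used when not overridden at call sites.
#' @param seed Default RNG seed.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params(n = 4, L = 16, c = 0.01, E_X = 2.5)
#' n_molecules(p)
model_params <- function(n = 4, L = 16, c = 0.01, E_X = 2.5,
                         E_A = 0, E_B = 0, valency = 4,
                         cap_scope = c("homo", "total"),
                         affinity = NULL, layout = NULL,
                         d0 = 30, shell_radius = 2,
                         sweeps = 20000, record_every = 100,
                         equilibration_sweeps = NULL, replicates = 3,
                         seed = 1) {
  cap_scope <- match.arg(cap_scope)
  if (L < 4) abort("L must be at least 4")
  if (c <= 0 || c >= 1) abort("concentration c must satisfy 0 < c < 1")
  if (E_X < 0 || E_A < 0 || E_B < 0) {
    abort("energies are stored as positive magnitudes and must be >= 0")
  }
  if (valency < 2) abort("valency must be at least 2")
  if (d0 <= 0) abort("lattice spacing d0 must be positive")
  spec <- polymer_spec(n, layout)
  affinity <- affinity %||% affinity_matrix(E_X)
  stopifnot(is.matrix(affinity), nrow(affinity) == 2, ncol(affinity) == 4)
  dimnames(affinity) <- list(SPECIES, REGION_TYPES)
  structure(
    list(
      n = as.integer(n), L = as.integer(L), c = c,
      E_X = E_X, E_A = E_A, E_B = E_B,
      valency = as.integer(valency), cap_scope = cap_scope,
      affinity = affinity, polymer = spec,
      d0 = d0, shell_radius = as.integer(shell_radius),
      sweeps = as.integer(sweeps), record_every = as.integer(record_every),
      equilibration_sweeps = as.integer(equilibration_sweeps %||% (sweeps %/% 2)),
      replicates = as.integer(replicates), seed = seed
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  lattice:  L =", x$L, "(", x$L^3, "sites ), d0 =", x$d0, "nm\n")
  cat("  polymer:  n =", x$n, ",", x$polymer$n_beads, "beads per polymer\n")
  cat("  binders:  c =", x$c, "->", n_molecules(x), "molecules/species\n")
  cat("  energies: E_X =", x$E_X, "E_A =", x$E_A, "E_B =", x$E_B,
      "kT, valency", x$valency, paste0("(", x$cap_scope, " cap)\n"))
  invisible(x)
}

#' Number of molecules per binder species
#'
#' @param params A [model_params()] object.
#' @return `round(c * L^3)`, the per-species molecule count.
#' @export
n_molecules <- function(params) {
  as.integer(round(params$c * params$L^3))
}
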