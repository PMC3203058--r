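# neighbour sites (6 rows) of each coordinate row, as site indices
neighbour_sites <- function(coords, L) {
  coords <- matrix(coords, ncol = 3)
  out <- matrix(0L, nrow(coords) * 6, 3)
  for (k in 1:6) {
    out[seq(k, by = 6, length.out = nrow(coords)), ] <-
      sweep(coords, 2, UNIT_OFFSETS[k, ], `+`)
  }
  site_index(out %% L, L)
}

#' Per-block contact report
#'
#' For every alpha and beta block, reports whether it is in contact with the
#' gamma block of the same polymer.  A contact is either a bridge (a
#' molecule simultaneously nearest-neighbour to at least one bead of the
#' block and one gamma bead of the polymer) or direct bead adjacency.  Also
#' returns the number of distinct bridging molecules.
#'
#' @param state A [new_system_state()] object.
#' @param params A [model_params()] object.
#' @return A tibble with columns `polymer`, `block`, `type`, `contact`,
#'   `n_bridges`.
#' @export
contact_report <- function(state, params) {
  L <- state$L
  occ_bead <- integer(L^3)
  occ_bead[site_index(state$bead_coords, L) + 1L] <- seq_len(nrow(state$bead_coords))
  blocks <- tibble(
    block = state$bead_block, type = state$bead_type, polymer = state$bead_poly
  )
  blocks <- blocks[!duplicated(blocks$block), ]
  fun_blocks <- blocks[blocks$type %in% 1:2, ]
  gamma_of <- setNames(blocks$block[blocks$type == 3], blocks$polymer[blocks$type == 3])

  # which blocks does each molecule touch? only cognate regions (nonzero
  # affinity for the molecule's species) can be bridged
  touches <- function(j) {
    nb <- neighbour_sites(state$mol_coords[j, ], L)
    hit <- occ_bead[nb + 1L]
    hit <- hit[hit > 0]
    hit <- hit[params$affinity[state$mol_species[j], state$bead_type[hit]] > 0]
    unique(state$bead_block[hit])
  }
  mol_touch <- if (nrow(state$mol_coords)) {
    lapply(seq_len(nrow(state$mol_coords)), touches)
  } else list()

  res <- lapply(seq_len(nrow(fun_blocks)), function(i) {
    b <- fun_blocks$block[i]
    p <- fun_blocks$polymer[i]
    g <- gamma_of[[as.character(p)]]
    n_br <- sum(vapply(mol_touch, function(tb) (b %in% tb) && (g %in% tb), logical(1)))
    direct <- FALSE
    bead_idx <- which(state$bead_block == b)
    nb <- neighbour_sites(state$bead_coords[bead_idx, , drop = FALSE], L)
    hit <- occ_bead[nb + 1L]
    hit <- hit[hit > 0]
    if (length(hit)) {
      direct <- any(state$bead_block[hit] == g)
    }
    tibble(polymer = p, block = b,
           type = REGION_TYPES[fun_blocks$type[i]],
           contact = direct || n_br > 0, n_bridges = n_br)
  })
  bind_rows(res)
}

#' Region-pair contact
#'
#' Aggregates [contact_report()] over all blocks of `region_x`: for each
#' polymer, is any `region_x` block in contact with the `region_y` (gamma)
#' block, and how many distinct molecules bridge the pair.
#'
#' @inheritParams contact_report
#' @param region_x `"alpha"` or `"beta"`.
#' @param region_y Must be `"gamma"` (the bridging hub).
#' @return A tibble with columns `polymer`, `contact`, `n_bridges`.
#' @export
region_contact <- function(state, params, region_x = "alpha",
                           region_y = "gamma") {
  if (!region_x %in% REGION_TYPES || !region_y %in% REGION_TYPES) {
    abort("unknown region label")
  }
  if (region_y != "gamma") abort("contacts are measured against the gamma region")
  rep <- contact_report(state, params)
  rep <- rep[rep$type == region_x, ]
  rep |>
    group_by(.data$polymer) |>
    summarise(contact = any(.data$contact), n_bridges = sum(.data$n_bridges),
              .groups = "drop")
}

#' Interaction order parameter P
#'
#' `P_alpha` is the fraction of samples (over the window, polymers and alpha
#' blocks) with an alpha-gamma contact; `P_beta` analogously; the order
#' parameter is `P = (P_alpha + P_beta) / 2`.  `P = 0` is the open state,
#' `P = 1` the fully looped state, `P = 1/2` one stable loop pair.
#'
#' @param x An `mc_run` object, or a list of `system_state` objects.
#' @param params Required when `x` is a list of states.
#' @param window Number of trailing records to average (default: the second
#'   half of the series for runs; all states for lists).
#' @return A one-row tibble with `P_alpha`, `P_beta`, `P`, `n_samples`.
#' @export
interaction_parameter <- function(x, params = NULL, window = NULL) {
  if (inherits(x, "mc_run")) {
    if (nrow(x$series) == 0) abort("empty observation window")
    window <- window %||% max(1, nrow(x$series) %/% 2)
    w <- tail(x$series, window)
    return(tibble(P_alpha = mean(w$P_alpha), P_beta = mean(w$P_beta),
                  P = mean(w$P), n_samples = nrow(w)))
  }
  if (length(x) == 0) abort("empty observation window")
  if (is.null(params)) abort("`params` is required for state lists")
  reps <- bind_rows(lapply(x, contact_report, params = params))
  pa <- mean(reps$contact[reps$type == "alpha"])
  pb <- mean(reps$contact[reps$type == "beta"])
  tibble(P_alpha = pa, P_beta = pb, P = (pa + pb) / 2, n_samples = length(x))
}

#' Local binder density around a gamma region
#'
#' Number of molecules of one species within Chebyshev distance `R` of any
#' gamma bead of the polymer, divided by the site count of that union shell.
#'
#' @inheritParams contact_report
#' @param polymer Polymer id (1 or 2).
#' @param species `"A"` or `"B"`.
#' @param shell_radius Chebyshev radius in lattice units (default from
#'   `params`).
#' @return Density (molecules per shell site).
#' @export
local_density <- function(state, params, polymer, species = "A",
                          shell_radius = params$shell_radius) {
  if (shell_radius < 1) abort("shell radius must be >= 1")
  L <- state$L
  g <- which(state$bead_poly == polymer & state$bead_type == 3)
  if (length(g) == 0) abort("polymer has no gamma beads")
  offs <- as.matrix(expand.grid(-shell_radius:shell_radius,
                                -shell_radius:shell_radius,
                                -shell_radius:shell_radius))
  shell <- unique(as.vector(vapply(g, function(i) {
    site_index(sweep(offs, 2, state$bead_coords[i, ], `+`) %% L, L)
  }, numeric(nrow(offs)))))
  sp <- match(species, SPECIES)
  if (nrow(state$mol_coords) == 0) return(0)
  msites <- site_index(state$mol_coords, L)
  sum(msites %in% shell & state$mol_species == sp) / length(shell)
}

#' Symmetry-breaking order parameter S
#'
#' `S = (rho1 - rho2) / (rho1 + rho2)` where `rho_i` is the local density of
#' species-A molecules around the gamma region of polymer `i`.  `S` is near
#' zero while molecules are shared symmetrically and approaches +/-1 when a
#' single polymer monopolises the A aggregate.  Returns 0 when both
#' densities vanish.
#'
#' @inheritParams local_density
#' @return Value in `[-1, 1]`.
#' @export
symmetry_parameter <- function(state, params,
                               shell_radius = params$shell_radius) {
  r1 <- local_density(state, params, 1, "A", shell_radius)
  r2 <- local_density(state, params, 2, "A", shell_radius)
  if (r1 + r2 == 0) return(0)
  (r1 - r2) / (r1 + r2)
}

#' Largest same-species aggregate fraction
#'
#' Size of the largest nearest-neighbour-connected component of same-species
#' molecules divided by the species count (flood fill under periodic wrap).
#' Near `1/N` for a dispersed species, 1 for a single aggregate.
#'
#' @inheritParams contact_report
#' @param species `"A"` or `"B"`.
#' @return Fraction in `(0, 1]`.
#' @export
largest_cluster_fraction <- function(state, species = "A") {
  sp <- match(species, SPECIES)
  idx <- which(state$mol_species == sp)
  if (length(idx) == 0) abort("no molecules of the requested species")
  L <- state$L
  occ <- integer(L^3)
  occ[site_index(state$mol_coords[idx, , drop = FALSE], L) + 1L] <- seq_along(idx)
  seen <- logical(length(idx))
  best <- 0L
  for (s in seq_along(idx)) {
    if (seen[s]) next
    size <- 0L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      nb <- neighbour_sites(state$mol_coords[idx[cur], , drop = FALSE], L)
      hits <- occ[nb + 1L]
      hits <- hits[hits > 0]
      hits <- unique(hits[!seen[hits]])
      if (length(hits)) {
        seen[hits] <- TRUE
        queue <- c(queue, hits)
      }
    }
    best <- max(best, size)
  }
  best / length(idx)
}
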