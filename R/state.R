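#' System microstate
#'
#' A full microstate: bead coordinates and types for both polymers, molecule
#' coordinates and species.  Coordinates are 0-based integer triples wrapped
#' modulo `L`.  Constructed by [init_state()] or fixture helpers; all
#' invariants (self-avoidance, chain connectivity, no co-occupancy) are
#' enforced by [validate_state()].
#'
#' @param L Lattice side length.
#' @param bead_coords Integer matrix (`n_beads` x 3) of 0-based coordinates,
#'   polymers concatenated in order.
#' @param bead_type Integer vector of region codes (1 = alpha, 2 = beta,
#'   3 = gamma, 4 = inert).
#' @param bead_poly Integer vector of polymer ids (1-based).
#' @param bead_block Integer vector of global block ids (1-based,
#'   consecutive).
#' @param mol_coords Integer matrix (`n_mols` x 3).
#' @param mol_species Integer vector (1 = A, 2 = B).
#' @return An object of class `system_state`.
#' @keywords internal
#' @export
new_system_state <- function(L, bead_coords, bead_type, bead_poly, bead_block,
                             mol_coords, mol_species) {
  bead_coords <- matrix(as.integer(bead_coords %% L), ncol = 3)
  if (length(mol_coords) == 0) {
    mol_coords <- matrix(integer(0), ncol = 3)
  } else {
    mol_coords <- matrix(as.integer(mol_coords %% L), ncol = 3)
  }
  structure(
    list(
      L = as.integer(L),
      bead_coords = bead_coords,
      bead_type = as.integer(bead_type),
      bead_poly = as.integer(bead_poly),
      bead_block = as.integer(bead_block),
      mol_coords = mol_coords,
      mol_species = as.integer(mol_species)
    ),
    class = "system_state"
  )
}

#' @export
print.system_state <- function(x, ...) {
  cat("<system_state> L =", x$L, ":",
      nrow(x$bead_coords), "beads in", length(unique(x$bead_poly)),
      "polymer(s),", nrow(x$mol_coords), "molecules (",
      sum(x$mol_species == 1), "A /", sum(x$mol_species == 2), "B )\n")
  invisible(x)
}

#' @export
as_tibble.system_state <- function(x, ...) {
  beads <- tibble(
    entity = "bead",
    x = x$bead_coords[, 1], y = x$bead_coords[, 2], z = x$bead_coords[, 3],
    polymer = x$bead_poly,
    block = x$bead_block,
    type = REGION_TYPES[x$bead_type],
    species = NA_character_
  )
  mols <- tibble(
    entity = "molecule",
    x = x$mol_coords[, 1], y = x$mol_coords[, 2], z = x$mol_coords[, 3],
    polymer = NA_integer_, block = NA_integer_, type = NA_character_,
    species = SPECIES[x$mol_species]
  )
  bind_rows(beads, mols)
}

# site index (0-based) of coordinate rows, and its inverse
site_index <- function(coords, L) {
  coords[, 1] %% L + L * (coords[, 2] %% L) + L * L * (coords[, 3] %% L)
}
site_coords <- function(idx, L) {
  cbind(idx %% L, (idx %/% L) %% L, idx %/% (L * L))
}

#' Periodic Manhattan distance between lattice sites
#'
#' Minimal-image L1 distance on the periodic cubic lattice; the bond /
#' adjacency metric of the model (the 6 nearest neighbours are at distance 1).
#'
#' @param a,b Integer coordinate triples (vectors or matrices of rows).
#' @param L Lattice side length.
#' @return Integer distance(s).
#' @export
periodic_manhattan <- function(a, b, L) {
  a <- matrix(as.integer(a), ncol = 3)
  b <- matrix(as.integer(b), ncol = 3)
  d <- abs((a - b) %% L)
  d <- pmin(d, L - d)
  as.integer(rowSums(d))
}

# minimal-image componentwise difference b - a
mi_diff <- function(a, b, L) {
  d <- (b - a) %% L
  d - L * (d > L / 2)
}

#' Validate all microstate invariants
#'
#' Checks chain connectivity (consecutive beads at unit periodic Manhattan
#' distance), self-avoidance and mutual exclusion (no two entities share a
#' site), coordinate ranges, and species/type codes.  Independent R
#' implementation of the engine's internal validator.
#'
#' @param state A [new_system_state()] object.
#' @param params Optional [model_params()]; when supplied, molecule counts
#'   are checked against `round(c * L^3)` per species.
#' @return `TRUE` invisibly; aborts with a diagnostic message on violation.
#' @export
validate_state <- function(state, params = NULL) {
  L <- state$L
  nb <- nrow(state$bead_coords)
  if (any(state$bead_coords < 0) || any(state$bead_coords >= L) ||
      (nrow(state$mol_coords) > 0 &&
       (any(state$mol_coords < 0) || any(state$mol_coords >= L)))) {
    abort("coordinates out of lattice range")
  }
  sites <- c(site_index(state$bead_coords, L),
             if (nrow(state$mol_coords)) site_index(state$mol_coords, L))
  if (anyDuplicated(sites)) {
    abort("excluded volume violated: two entities share a lattice site")
  }
  for (p in unique(state$bead_poly)) {
    idx <- which(state$bead_poly == p)
    if (any(diff(idx) != 1)) abort("polymer beads must be contiguous and ordered")
    if (length(idx) > 1) {
      d <- periodic_manhattan(state$bead_coords[idx[-length(idx)], , drop = FALSE],
                              state$bead_coords[idx[-1], , drop = FALSE], L)
      if (any(d != 1)) {
        abort(paste0("chain connectivity broken in polymer ", p,
                     " at bond ", which(d != 1)[1]))
      }
    }
  }
  if (!all(state$bead_type %in% 1:4)) abort("invalid bead type code")
  if (length(state$mol_species) && !all(state$mol_species %in% 1:2)) {
    abort("invalid molecule species code")
  }
  if (!is.null(params)) {
    nm <- n_molecules(params)
    if (sum(state$mol_species == 1) != nm || sum(state$mol_species == 2) != nm) {
      abort("molecule counts do not match round(c * L^3) per species")
    }
  }
  invisible(TRUE)
}

# per-bead type/block vectors from a polymer spec
layout_vectors <- function(spec) {
  list(
    type = rep(match(spec$layout$type, REGION_TYPES), spec$layout$length),
    block = rep(spec$layout$block, spec$layout$length)
  )
}

#' Construct an initial microstate
#'
#' `init = "open"` grows each polymer as a random self-avoiding walk confined
#' to its own lattice octant (the two polymers start well separated) and
#' scatters the molecules uniformly over free sites.  `init = "looped"`
#' builds a deterministic compact conformation in which every alpha and beta
#' block is in contact (bridged or directly adjacent) with the gamma block of
#' its polymer -- the symmetric looped start used for symmetry-breaking runs
#' -- then scatters the remaining molecules.
#'
#' @param params A [model_params()] object.
#' @param init `"open"` or `"looped"`.
#' @param n_polymers Number of polymers (default 2).
#' @param seed Optional RNG seed (deterministic states for equal seeds).
#' @return A validated [new_system_state()].
#' @export
#' @examples
#' p <- model_params(n = 2, L = 12, c = 0.01)
#' st <- init_state(p, "open", seed = 1)
#' validate_state(st, p)
init_state <- function(params, init = c("open", "looped"), n_polymers = 2,
                       seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  L <- params$L
  spec <- params$polymer
  nm <- n_molecules(params)
  lay <- layout_vectors(spec)
  n_total <- n_polymers * spec$n_beads + 2L * nm
  if (n_total > L^3) {
    abort(paste0("cannot pack ", n_total, " entities on ", L^3,
                 " lattice sites; reduce c or increase L"))
  }

  if (init == "open") {
    occ <- integer(0)
    coords_list <- vector("list", n_polymers)
    octants <- list(c(0, 0, 0), c(1, 1, 1), c(1, 0, 0), c(0, 1, 1))
    h <- L %/% 2
    if (spec$n_beads > h^3) {
      abort("polymer does not fit in a lattice octant; increase L")
    }
    for (p in seq_len(n_polymers)) {
      lo <- unlist(octants[[p]]) * h
      coords_list[[p]] <- grow_saw(spec$n_beads, L, lo, lo + h - 1, occ)
      occ <- c(occ, site_index(coords_list[[p]], L))
    }
    bead_coords <- do.call(rbind, coords_list)
    seeded <- NULL
  } else {
    built <- build_looped_polymers(spec, L, n_polymers)
    bead_coords <- built$coords
    seeded <- built$bridges   # matrix of coords + species for seeded bridges
    occ <- site_index(bead_coords, L)
    if (!is.null(seeded)) {
      if (sum(seeded[, 4] == 1) > nm || sum(seeded[, 4] == 2) > nm) {
        abort("concentration too low to seed the bridging molecules of the looped state")
      }
      occ <- c(occ, site_index(seeded[, 1:3, drop = FALSE], L))
    }
  }

  free <- setdiff(seq_len(L^3) - 1L, occ)
  n_seed_A <- if (is.null(seeded)) 0L else sum(seeded[, 4] == 1)
  n_seed_B <- if (is.null(seeded)) 0L else sum(seeded[, 4] == 2)
  n_rand <- (nm - n_seed_A) + (nm - n_seed_B)
  if (n_rand > length(free)) abort("not enough free sites for the molecules")
  picked <- if (n_rand > 0) sample(free, n_rand) else integer(0)
  rand_coords <- site_coords(picked, L)
  rand_species <- rep(1:2, c(nm - n_seed_A, nm - n_seed_B))
  if (is.null(seeded)) {
    mol_coords <- rand_coords
    mol_species <- rand_species
  } else {
    mol_coords <- rbind(seeded[, 1:3, drop = FALSE], rand_coords)
    mol_species <- c(seeded[, 4], rand_species)
  }

  state <- new_system_state(
    L,
    bead_coords,
    rep(lay$type, n_polymers),
    rep(seq_len(n_polymers), each = spec$n_beads),
    rep(lay$block, n_polymers) +
      rep((seq_len(n_polymers) - 1L) * nrow(spec$layout), each = spec$n_beads),
    mol_coords, mol_species
  )
  validate_state(state, params)
  state
}

# random self-avoiding walk of `n` beads within box [lo, hi]^3 (inclusive,
# absolute coordinates), avoiding `occ` (site indices); retrying-rejection
grow_saw <- function(n, L, lo, hi, occ, max_restarts = 5000) {
  occ_set <- occ
  for (restart in seq_len(max_restarts)) {
    start <- floor((lo + hi) / 2)
    walk <- matrix(0L, n, 3)
    walk[1, ] <- as.integer(start)
    used <- c(occ_set, site_index(walk[1, , drop = FALSE], L))
    ok <- TRUE
    if (n > 1) {
      for (i in 2:n) {
        cur <- walk[i - 1, ]
        cand <- sweep(UNIT_OFFSETS, 2, cur, `+`)
        inbox <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
                 cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
                 cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
        cand <- cand[inbox, , drop = FALSE]
        if (nrow(cand)) {
          free <- !(site_index(cand, L) %in% used)
          cand <- cand[free, , drop = FALSE]
        }
        if (nrow(cand) == 0) { ok <- FALSE; break }
        pick <- cand[sample.int(nrow(cand), 1), ]
        walk[i, ] <- as.integer(pick)
        used <- c(used, site_index(walk[i, , drop = FALSE], L))
      }
    }
    if (ok) return(walk)
  }
  abort("self-avoiding walk growth failed; configuration too dense")
}
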