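# Deterministic hand-checkable microstates with manually enumerated
# expectations; used by tests and by the fixtures CLI subcommand.

FIXTURE_NAMES <- c("bridge-1", "bridge-2", "stretched", "enum-micro",
                   "two-cluster")

#' Construct a named test fixture
#'
#' Returns deterministic, hand-enumerable microstates together with their
#' expected energies, contacts and cluster fractions.
#'
#' Registry:
#' \describe{
#'   \item{bridge-1}{One molecule bridging an alpha bead and a gamma bead:
#'     alpha-gamma contact with exactly 1 bridge; energy `-2 E_X`.}
#'   \item{bridge-2}{Two molecules bridging two alpha blocks to gamma
#'     (no direct adjacency): contact with 2 bridges; energy `-4 E_X`.}
#'   \item{stretched}{A fully stretched polymer with no molecules: no
#'     contacts anywhere.}
#'   \item{enum-micro}{The enumerable micro-system (one 3-bead polymer, one
#'     A molecule, 4^3 periodic lattice, E_X = 2 kT) used by the Boltzmann
#'     oracle; pair with [micro_boltzmann_table()].}
#'   \item{two-cluster}{Species A in clusters of sizes 7 and 3 (fraction
#'     0.7); species B fully dispersed (fraction 1/3).}
#' }
#'
#' @param name Fixture name (see registry above).
#' @return A list: `state`, `params`, `expected` (named list).
#' @export
make_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES) {
    abort(paste0("unknown fixture '", name, "'; available: ",
                 paste(FIXTURE_NAMES, collapse = ", ")))
  }
  switch(
    name,
    "bridge-1" = {
      p <- model_params(n = 1, L = 8, c = 1 / 8^3, E_X = 2)
      st <- new_system_state(
        8,
        rbind(c(1, 1, 1), c(1, 2, 1), c(2, 2, 1)),
        c(1L, 4L, 3L), c(1L, 1L, 1L), c(1L, 2L, 3L),
        rbind(c(2, 1, 1)), 1L
      )
      list(state = st, params = p,
           expected = list(contact = TRUE, n_bridges = 1L, energy = -4))
    },
    "bridge-2" = {
      p <- model_params(n = 1, L = 8, c = 2 / 8^3, E_X = 2)
      st <- new_system_state(
        8,
        rbind(c(2, 0, 1), c(1, 0, 1), c(0, 0, 1), c(0, 1, 1), c(0, 2, 1),
              c(0, 3, 1), c(1, 3, 1), c(2, 3, 1), c(2, 2, 1)),
        c(1L, 4L, 4L, 4L, 1L, 4L, 4L, 4L, 3L),
        rep(1L, 9), c(1L, 2L, 2L, 2L, 3L, 4L, 4L, 4L, 5L),
        rbind(c(2, 1, 1), c(1, 2, 1)), c(1L, 1L)
      )
      list(state = st, params = p,
           expected = list(contact = TRUE, n_bridges = 2L, energy = -8))
    },
    "stretched" = {
      p <- model_params(n = 1, L = 12, c = 1 / 12^3, E_X = 2)
      st <- new_system_state(
        12,
        cbind(0:8, 1L, 1L),
        c(1L, 4L, 1L, 4L, 3L, 4L, 2L, 4L, 2L),
        rep(1L, 9), 1:9,
        rbind(c(6L, 6L, 6L)), 1L
      )
      list(state = st, params = p,
           expected = list(contact = FALSE, n_bridges = 0L))
    },
    "enum-micro" = {
      p <- model_params(n = 1, L = 4, c = 1 / 64, E_X = 2)
      st <- new_system_state(
        4,
        rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
        c(1L, 3L, 1L), rep(1L, 3), 1:3,
        rbind(c(3, 3, 3)), 1L
      )
      list(state = st, params = p,
           expected = list(n_states = 30L * 61L))
    },
    "two-cluster" = {
      p <- model_params(n = 1, L = 12, c = 10 / 12^3, E_X = 2)
      a7 <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(1, 2, 1),
                  c(2, 2, 1), c(3, 2, 1), c(2, 3, 1))
      a3 <- rbind(c(8, 8, 8), c(9, 8, 8), c(8, 9, 8))
      b3 <- rbind(c(5, 5, 5), c(5, 5, 8), c(11, 1, 5))
      st <- new_system_state(
        12,
        rbind(c(6, 10, 10), c(6, 10, 11)),
        c(4L, 4L), c(1L, 1L), c(1L, 1L),
        rbind(a7, a3, b3), c(rep(1L, 10), rep(2L, 3))
      )
      list(state = st, params = p,
           expected = list(cluster_A = 0.7, cluster_B = 1 / 3))
    }
  )
}

#' Exact Boltzmann distribution of the enumerable micro-system
#'
#' Exhaustively enumerates every microstate of the `enum-micro` fixture
#' class (a 3-bead polymer plus one molecule on a small periodic lattice),
#' up to global lattice translation: bead 1 is fixed at the origin, bead 2
#' ranges over its 6 neighbours, bead 3 over the 5 remaining neighbours of
#' bead 2, and the molecule over all free sites.  Each state is coded as
#' `(rel2 * L^3 + rel3) * L^3 + relm` (0-based site indices of the relative
#' positions), matching the canonical codes tallied by the MC histogram
#' sampler, and weighted by `exp(-E)`.
#'
#' @param fixture A fixture as returned by `make_fixture("enum-micro")`
#'   (any 3-bead, 1-molecule state works).
#' @return A tibble: `code`, `energy`, `prob` (normalised).
#' @export
micro_boltzmann_table <- function(fixture = make_fixture("enum-micro")) {
  st <- fixture$state
  p <- fixture$params
  L <- st$L
  L3 <- L^3
  stopifnot(nrow(st$bead_coords) == 3, nrow(st$mol_coords) == 1)
  rows <- list()
  for (k2 in 1:6) {
    b2 <- UNIT_OFFSETS[k2, ]
    for (k3 in 1:6) {
      b3 <- b2 + UNIT_OFFSETS[k3, ]
      if (all(b3 %% L == c(0, 0, 0))) next  # back onto bead 1
      bead_sites <- site_index(rbind(c(0, 0, 0), b2, b3) %% L, L)
      if (anyDuplicated(bead_sites)) next
      for (m in 0:(L3 - 1)) {
        if (m %in% bead_sites) next
        mc <- site_coords(m, L)
        s <- new_system_state(L, rbind(c(0, 0, 0), b2, b3) %% L,
                              st$bead_type, st$bead_poly, st$bead_block,
                              mc, st$mol_species)
        a <- state_to_cpp(s, p)
        e <- cpp_total_energy(a$beads, a$btype, a$bpoly, a$bblock, a$mols,
                              a$msp, a$L, a$affinity, a$ehomo, a$valency,
                              a$cap_total)$total
        code <- (bead_sites[2] * L3 + bead_sites[3]) * L3 + m
        rows[[length(rows) + 1L]] <- c(code, e)
      }
    }
  }
  tab <- do.call(rbind, rows)
  w <- exp(-tab[, 2])
  tibble(code = tab[, 1], energy = tab[, 2], prob = w / sum(w))
}
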