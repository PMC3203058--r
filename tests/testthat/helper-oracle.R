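# Independent brute-force energy oracle: same counting rule as the engine
# (fixed lexicographic neighbour scan, valency cap, mutual-counting homotypic
# pairs), implemented through a completely separate code path (hash-based
# site lookup, full pair enumeration).

ORACLE_OFFS <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1),
                     c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))

oracle_energy <- function(state, params) {
  L <- state$L
  aff <- params$affinity
  v <- params$valency
  cap_total <- identical(params$cap_scope, "total")
  ehomo <- c(params$E_A, params$E_B)
  key <- function(p) paste(p %% L, collapse = ",")
  bead_at <- new.env(parent = emptyenv())
  mol_at <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(state$bead_coords))) {
    assign(key(state$bead_coords[i, ]), i, bead_at)
  }
  for (j in seq_len(nrow(state$mol_coords))) {
    assign(key(state$mol_coords[j, ]), j, mol_at)
  }
  scan <- function(j) {
    sp <- state$mol_species[j]
    nb <- 0L; nhomo <- 0L; het <- 0; partners <- integer(0)
    for (k in 1:6) {
      pos <- (state$mol_coords[j, ] + ORACLE_OFFS[k, ]) %% L
      b <- bead_at[[key(pos)]]
      m <- mol_at[[key(pos)]]
      if (!is.null(b)) {
        a <- aff[sp, state$bead_type[b]]
        if (a > 0) {
          if (cap_total) {
            if (nb < v) { het <- het - a; nb <- nb + 1L }
          } else {
            het <- het - a
          }
        }
      } else if (!is.null(m) && state$mol_species[m] == sp) {
        cnt <- if (cap_total) nb else nhomo
        if (cnt < v) { partners <- c(partners, m); nb <- nb + 1L; nhomo <- nhomo + 1L }
      }
    }
    list(het = het, partners = partners)
  }
  nm <- nrow(state$mol_coords)
  scans <- lapply(seq_len(nm), scan)
  het <- sum(vapply(scans, function(s) s$het, numeric(1)))
  homo <- 0
  if (nm > 1) {
    for (j in seq_len(nm - 1)) {
      for (q in (j + 1):nm) {
        if (state$mol_species[j] == state$mol_species[q] &&
            q %in% scans[[j]]$partners && j %in% scans[[q]]$partners) {
          homo <- homo - ehomo[state$mol_species[j]]
        }
      }
    }
  }
  list(hetero = het, homo = homo, total = het + homo)
}

# exact mean squared end-to-end distance of an n-bead self-avoiding walk in
# free space, by direct enumeration (control for the null polymer model)
oracle_saw_r2 <- function(n_beads) {
  stopifnot(n_beads >= 2, n_beads <= 6)
  walks <- list(matrix(0L, 1, 3))
  for (step in seq_len(n_beads - 1)) {
    walks <- unlist(lapply(walks, function(w) {
      lapply(1:6, function(k) {
        nxt <- w[nrow(w), ] + ORACLE_OFFS[k, ]
        if (any(apply(w, 1, function(r) all(r == nxt)))) return(NULL)
        rbind(w, nxt)
      })
    }), recursive = FALSE)
    walks <- walks[!vapply(walks, is.null, logical(1))]
  }
  r2 <- vapply(walks, function(w) sum((w[nrow(w), ] - w[1, ])^2), numeric(1))
  mean(r2)
}

# small interacting test system: open state at moderate density
random_test_state <- function(seed, L = 8, c = 0.05, E_X = 2.5,
                              E_A = 1.5, E_B = 2, n = 1, sweeps = 0) {
  p <- model_params(n = n, L = L, c = c, E_X = E_X, E_A = E_A, E_B = E_B,
                    sweeps = max(sweeps, 1), record_every = max(sweeps, 1))
  st <- init_state(p, "open", seed = seed)
  if (sweeps > 0) {
    st <- run_mc(st, p, sweeps = sweeps, seed = seed + 1)$final_state
  }
  list(state = st, params = p)
}

# a molecule-only state: N free molecules on a regular sub-grid of an L-box
free_molecule_state <- function(n_mols, L) {
  step <- max(2L, floor(L / ceiling(n_mols^(1 / 3))))
  grid <- as.matrix(expand.grid(x = seq(0L, L - 1L, by = step),
                                y = seq(0L, L - 1L, by = step),
                                z = seq(0L, L - 1L, by = step)))
  stopifnot(nrow(grid) >= n_mols)
  new_system_state(L, matrix(integer(0), ncol = 3), integer(0), integer(0),
                   integer(0), grid[seq_len(n_mols), ], rep(1L, n_mols))
}
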