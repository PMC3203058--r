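# Deterministic construction of the symmetric looped initial state.
#
# Each polymer is folded so that its gamma block runs along x at the centre
# of a local frame, the four functional blocks run parallel to it on the four
# diagonal columns around the x-axis, and the inert blocks are exact-length
# self-avoiding connectors found by depth-first search.  One cognate
# bridging molecule per free face column is seeded next to the gamma line so
# that the contact predicate holds for every alpha and beta block by
# construction (on the bipartite cubic lattice direct block-gamma adjacency
# is impossible for some parities, so the looped state is molecule-bridged,
# which is also the physically stabilised configuration).

UNIT_OFFSETS <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, -1,
                         0, 0, 1, 0, 1, 0, 1, 0, 0),
                       ncol = 3, byrow = TRUE)

build_looped_polymers <- function(spec, L, n_polymers) {
  n <- spec$n
  def <- default_layout(n)
  if (!identical(spec$layout$type, def$type) ||
      !identical(spec$layout$length, def$length)) {
    abort("looped initial states require the default equal-length layout")
  }
  L_min <- if (n == 1) 8 else n + 6
  if (L < L_min) {
    abort(paste0("looped construction needs L >= ", L_min, " for n = ", n))
  }
  occupied <- logical(L^3)
  h <- L %/% 2
  base <- c(4L, 4L, 4L)
  offset_opts <- list(c(0L, 0L, 0L), c(h, h, h), c(h, h, 0L), c(h, 0L, 0L),
                      c(0L, h, 0L), c(0L, 0L, h), c(h, 0L, h), c(0L, h, h))
  coords <- vector("list", n_polymers)
  bridges <- NULL
  for (p in seq_len(n_polymers)) {
    placed <- NULL
    for (off in offset_opts) {
      placed <- build_one_looped(n, L, base + off, occupied)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) {
      abort("could not place looped polymers without overlap; increase L")
    }
    coords[[p]] <- placed$coords
    bridges <- rbind(bridges, placed$bridges)
    occupied[site_index(placed$coords, L) + 1L] <- TRUE
    occupied[site_index(placed$bridges[, 1:3, drop = FALSE], L) + 1L] <- TRUE
  }
  list(coords = do.call(rbind, coords), bridges = bridges)
}

build_one_looped <- function(n, L, offset, occupied) {
  if (n == 1) {
    chain <- rbind(
      c(0, 1, 1), c(-1, 1, 1), c(-1, 1, 0), c(-1, 0, 0), c(0, 0, 0),
      c(0, 0, 1), c(0, -1, 1), c(1, -1, 1), c(1, -1, 0)
    )
    bridge <- rbind(c(0, 1, 0, 1), c(0, -1, 0, 2))
  } else {
    s2a <- if (n %% 2 == 0) n - 2L else n - 1L   # A2 start (runs -x)
    s2b <- if (n %% 2 == 0) n else n - 1L        # B2 start (runs -x)
    xs <- 0:(n - 1)
    blocks <- list(
      A1 = cbind(xs, 1, 1),
      A2 = cbind(s2a - xs, -1, 1),
      G  = cbind(xs, 0, 0),
      B1 = cbind(xs, -1, -1),
      B2 = cbind(s2b - xs, 1, -1)
    )
    # one cognate bridging molecule per functional block (species A for the
    # alpha blocks, B for the beta blocks), each adjacent to a gamma bead
    bridge <- rbind(c(0, 1, 0, 1),    # A: bridges A1 to gamma
                    c(0, -1, 0, 1),   # A: bridges A2 to gamma
                    c(1, -1, 0, 2),   # B: bridges B1 to gamma
                    c(1, 1, 0, 2))    # B: bridges B2 to gamma
    fixed <- rbind(do.call(rbind, blocks), bridge[, 1:3])
    if (occupied_any(fixed, L, offset, occupied)) return(NULL)
    # connectors: exact-length self-avoiding paths (joint DFS with backtracking)
    box_lo <- c(-3, -3, -3); box_hi <- c(n + 2, 3, 3)
    conn <- solve_connectors(
      list(
        list(from = blocks$A1[n, ], to = blocks$A2[1, ], len = n),
        list(from = blocks$A2[n, ], to = blocks$G[1, ],  len = n),
        list(from = blocks$G[n, ],  to = blocks$B1[1, ], len = n),
        list(from = blocks$B1[n, ], to = blocks$B2[1, ], len = n)
      ),
      fixed, box_lo, box_hi, L, offset, occupied
    )
    if (is.null(conn)) return(NULL)
    chain <- rbind(blocks$A1, conn[[1]], blocks$A2, conn[[2]], blocks$G,
                   conn[[3]], blocks$B1, conn[[4]], blocks$B2)
  }
  abs_chain <- sweep(chain, 2, offset, `+`)
  abs_bridge <- cbind(sweep(bridge[, 1:3, drop = FALSE], 2, offset, `+`),
                      bridge[, 4])
  if (occupied_any(rbind(chain, bridge[, 1:3, drop = FALSE]), L, offset,
                   occupied)) {
    return(NULL)
  }
  list(coords = abs_chain %% L, bridges = cbind(abs_bridge[, 1:3] %% L,
                                                abs_bridge[, 4]))
}

occupied_any <- function(rel_coords, L, offset, occupied) {
  idx <- site_index(sweep(rel_coords, 2, offset, `+`), L)
  any(occupied[idx + 1L]) || anyDuplicated(idx) > 0
}

# joint depth-first search over all connectors; each connector is an
# exact-length path of `len` beads from adjacency-of-`from` to
# adjacency-of-`to`.  Deterministic (fixed direction order), with parity and
# distance pruning; returns a list of coordinate matrices or NULL.
solve_connectors <- function(connectors, fixed, box_lo, box_hi, L, offset,
                             occupied) {
  used <- new.env(parent = emptyenv())
  mark <- function(p) assign(paste(p, collapse = ","), TRUE, envir = used)
  unmark <- function(p) rm(list = paste(p, collapse = ","), envir = used)
  is_used <- function(p) {
    key <- paste(p, collapse = ",")
    if (!is.null(used[[key]])) return(TRUE)
    if (any(p < box_lo) || any(p > box_hi)) return(TRUE)
    occupied[site_index(matrix(p + offset, 1), L) + 1L]
  }
  apply(fixed, 1, mark)
  nodes <- 0L
  paths <- vector("list", length(connectors))

  solve_k <- function(k) {
    if (k > length(connectors)) return(TRUE)
    con <- connectors[[k]]
    path <- matrix(0L, con$len, 3)
    step <- function(t, cur) {
      nodes <<- nodes + 1L
      if (nodes > 300000L) abort("looped-state connector search exceeded its node budget")
      for (d in seq_len(6)) {
        nxt <- cur + UNIT_OFFSETS[d, ]
        if (is_used(nxt)) next
        rem <- con$len - t + 1          # steps left after placing this bead
        dist <- sum(abs(nxt - con$to))
        if (dist > rem || (rem - dist) %% 2 != 0) next
        path[t, ] <<- nxt
        mark(nxt)
        if (t == con$len) {
          if (dist == 1) {
            paths[[k]] <<- path + 0L
            if (solve_k(k + 1)) return(TRUE)
          }
        } else if (step(t + 1, nxt)) {
          return(TRUE)
        }
        unmark(nxt)
      }
      FALSE
    }
    step(1, con$from)
  }
  if (solve_k(1)) paths else NULL
}
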