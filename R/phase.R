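#' Parameter-grid phase scan
#'
#' Sweeps one or more control parameters (`c`, `E_X`, `E_A`, `E_B`, `n`),
#' running independent replicates at every grid point, discarding an
#' equilibration window, and aggregating the order parameters with
#' replicate-level standard errors.  Conformation scans start from the open
#' state; symmetry-breaking scans from the symmetric looped state.
#'
#' Grid points are independent jobs: each replicate derives its own seed from
#' the base seed and the point/replicate index, so results are identical
#' regardless of execution order.
#'
#' @param params Base [model_params()].
#' @param vary Named list of parameter value vectors to sweep (crossed).
#' @param replicates Replicates per grid point (>= 3 recommended for
#'   transition estimation).
#' @param sweeps,record_every Run length controls (defaults from `params`).
#' @param init Initial state: `"open"` (conformation switch) or `"looped"`
#'   (symmetry breaking).
#' @param equilibration_frac Fraction of records discarded before averaging.
#' @param seed Base seed.
#' @return A `phase_scan` tibble: one row per grid point with means and
#'   standard errors of `P`, `|S|` and the cluster fractions, plus the
#'   replicate-level values in the attribute `"replicates"`.
#' @export
phase_scan <- function(params, vary, replicates = params$replicates,
                       sweeps = params$sweeps,
                       record_every = params$record_every,
                       init = c("open", "looped"),
                       equilibration_frac = 0.5, seed = params$seed) {
  init <- match.arg(init)
  stopifnot(length(vary) >= 1, all(nzchar(names(vary))))
  allowed <- c("c", "E_X", "E_A", "E_B", "n")
  if (!all(names(vary) %in% allowed)) {
    abort(paste("scan axes must be among:", paste(allowed, collapse = ", ")))
  }
  grid <- expand.grid(vary, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(grid) == 0) abort("empty scan grid")

  rep_rows <- list()
  for (i in seq_len(nrow(grid))) {
    pt <- as.list(grid[i, , drop = FALSE])
    p_i <- do.call(update_params, c(list(params = params), pt))
    for (r in seq_len(replicates)) {
      s <- point_seed(seed, i, r)
      st <- init_state(p_i, init, seed = s)
      run <- run_mc(st, p_i, sweeps = sweeps, record_every = record_every,
                    seed = s + 1L)
      keep <- max(1, floor(nrow(run$series) * (1 - equilibration_frac)))
      w <- tail(run$series, keep)
      rep_rows[[length(rep_rows) + 1L]] <- tibble(
        point = i, replicate = r, !!!pt,
        P = mean(w$P), S = mean(w$S), S_abs = mean(abs(w$S)),
        cluster_A = mean(w$cluster_A), cluster_B = mean(w$cluster_B),
        S_final = w$S[nrow(w)],
        energy = mean(w$energy)
      )
    }
  }
  reps <- bind_rows(rep_rows)
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  out <- reps |>
    group_by(.data$point, across(all_of(names(vary)))) |>
    summarise(
      P_mean = mean(.data$P), P_se = se(.data$P),
      S_abs_mean = mean(.data$S_abs), S_abs_se = se(.data$S_abs),
      cluster_A_mean = mean(.data$cluster_A),
      cluster_B_mean = mean(.data$cluster_B),
      n_replicates = n(), .groups = "drop"
    ) |>
    arrange(.data$point)
  attr(out, "replicates") <- reps
  attr(out, "axes") <- names(vary)
  attr(out, "init") <- init
  class(out) <- c("phase_scan", class(out))
  out
}

#' @importFrom dplyr across all_of
update_params <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  # rebuild dependent structures
  model_params(
    n = params$n, L = params$L, c = params$c, E_X = params$E_X,
    E_A = params$E_A, E_B = params$E_B, valency = params$valency,
    cap_scope = params$cap_scope,
    affinity = if ("E_X" %in% names(upd)) NULL else params$affinity,
    d0 = params$d0, shell_radius = params$shell_radius,
    sweeps = params$sweeps, record_every = params$record_every,
    equilibration_sweeps = params$equilibration_sweeps,
    replicates = params$replicates, seed = params$seed
  )
}

# deterministic per-point, per-replicate seed below 2^31
point_seed <- function(base, point, replicate) {
  as.integer((as.numeric(base) + 999983 * point + 7919 * replicate) %% 2147483647L)
}

#' Interpolate a transition threshold along a scanned axis
#'
#' Finds the first crossing of `level` by the response means along the
#' ordered scan axis and linearly interpolates between the bracketing grid
#' points.  When the response never crosses the level the result is an
#' explicit no-crossing row (not an error).
#'
#' @param scan A `phase_scan` result (or any tibble).
#' @param x Name of the scanned axis column.
#' @param response Name of the response mean column (default `"P_mean"`).
#' @param level Crossing level (default 0.5, the midpoint convention for
#'   sharp sigmoidal transitions).
#' @return A one-row tibble: `threshold`, `bracket_lo`, `bracket_hi`,
#'   `crossed` (logical).
#' @export
#' @examples
#' d <- tibble::tibble(c = 1:4, P_mean = c(0, 0, 1, 1))
#' estimate_threshold(d, "c")
estimate_threshold <- function(scan, x, response = "P_mean", level = 0.5) {
  d <- as_tibble(scan)[, c(x, response)]
  names(d) <- c("x", "y")
  d <- d[order(d$x), ]
  if (nrow(d) < 2) abort("need at least two grid points")
  above <- d$y >= level
  cross <- which(above[-1] != above[-nrow(d)])
  if (length(cross) == 0 || all(above) || all(!above)) {
    return(tibble(threshold = NA_real_, bracket_lo = NA_real_,
                  bracket_hi = NA_real_, crossed = FALSE))
  }
  i <- cross[1]
  x0 <- d$x[i]; x1 <- d$x[i + 1]; y0 <- d$y[i]; y1 <- d$y[i + 1]
  thr <- x0 + (level - y0) / (y1 - y0) * (x1 - x0)
  tibble(threshold = thr, bracket_lo = x0, bracket_hi = x1, crossed = TRUE)
}

#' @export
print.phase_scan <- function(x, ...) {
  cat("<phase_scan> init =", attr(x, "init"), "; axes:",
      paste(attr(x, "axes"), collapse = ", "), "\n")
  NextMethod()
}

#' @rdname phase_scan
#' @param x A `phase_scan` object.
#' @param ... Unused.
#' @export
tidy.phase_scan <- function(x, ...) attr(x, "replicates")

#' @rdname phase_scan
#' @export
glance.phase_scan <- function(x, ...) {
  tibble(
    points = nrow(x),
    replicates = max(x$n_replicates),
    P_range_lo = min(x$P_mean), P_range_hi = max(x$P_mean),
    S_abs_range_lo = min(x$S_abs_mean), S_abs_range_hi = max(x$S_abs_mean)
  )
}
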