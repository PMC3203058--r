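# Config file dialect: single YAML file with a versioned schema.  Unknown
# keys are rejected (typo protection).

CONFIG_VERSION <- 1L
MODEL_KEYS <- c("n", "L", "c", "E_X", "E_A", "E_B", "valency", "cap_scope",
                "d0", "shell_radius")
RUN_KEYS <- c("sweeps", "record_every", "equilibration_sweeps", "replicates",
              "seed", "init")
SCAN_KEYS <- c("axes", "replicates", "init")
CAL_KEYS <- c("d0", "D_real")
TOP_KEYS <- c("version", "model", "run", "scan", "calibration")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(paste0("unknown config key(s) in ", where, ": ",
                 paste(bad, collapse = ", ")))
  }
}

#' Read a model/run configuration file
#'
#' Parses the YAML configuration (versioned schema; unknown keys rejected)
#' into a [model_params()] object plus run, scan and calibration blocks.
#'
#' @param path Path to the YAML config.
#' @return A list with elements `params`, `run`, `scan`, `calibration`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, TOP_KEYS, "top level")
  if (is.null(cfg$version) || cfg$version != CONFIG_VERSION) {
    abort("config must declare `version: 1`")
  }
  check_keys(cfg$model %||% list(), MODEL_KEYS, "model")
  check_keys(cfg$run %||% list(), RUN_KEYS, "run")
  check_keys(cfg$scan %||% list(), SCAN_KEYS, "scan")
  check_keys(cfg$calibration %||% list(), CAL_KEYS, "calibration")
  run <- cfg$run %||% list()
  params <- do.call(model_params, c(
    cfg$model %||% list(),
    run[intersect(names(run), c("sweeps", "record_every",
                                "equilibration_sweeps", "replicates", "seed"))]
  ))
  list(params = params,
       run = modifyList(list(init = "open", seed = params$seed), run),
       scan = cfg$scan, calibration = cfg$calibration)
}

#' Write a configuration file
#'
#' @param params A [model_params()] object.
#' @param path Output path.
#' @param run,scan,calibration Optional blocks to include.
#' @return The path, invisibly.
#' @export
write_config <- function(params, path, run = NULL, scan = NULL,
                         calibration = NULL) {
  cfg <- list(
    version = CONFIG_VERSION,
    model = params[MODEL_KEYS]
  )
  if (!is.null(run)) cfg$run <- run
  if (!is.null(scan)) cfg$scan <- scan
  if (!is.null(calibration)) cfg$calibration <- calibration
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write / read an observable series as TSV
#'
#' One file per replicate, tab-separated with a header:
#' sweep, P_alpha, P_beta, P, S, clusterA, clusterB, rho1, rho2 (plus energy
#' and MSD diagnostics).
#'
#' @param series The `series` tibble of an `mc_run` (or the run itself).
#' @param path Output path.
#' @return The path (write) or a tibble (read).
#' @export
write_observables <- function(series, path) {
  if (inherits(series, "mc_run")) series <- series$series
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Write a phase-diagram table as CSV
#'
#' @param scan A `phase_scan` result.
#' @param path Output path.
#' @export
write_phase_table <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' Write / read an XYZ-style trajectory
#'
#' Plain-text frames: an atom count line, a comment line carrying the sweep
#' index, then one `LABEL x y z` record per bead and molecule.  Bead labels
#' encode polymer and region (`P1_ALPHA`), molecule labels the species
#' (`MOL_A`).
#'
#' @param run An `mc_run` with recorded frames (`frame_every > 0`), or a
#'   list of `list(sweep=, state=)` entries.
#' @param path Output path.
#' @export
write_trajectory_xyz <- function(run, path) {
  frames <- if (inherits(run, "mc_run")) run$frames else run
  if (length(frames) == 0) abort("no frames recorded; set `frame_every`")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    st <- f$state
    nb <- nrow(st$bead_coords); nm <- nrow(st$mol_coords)
    writeLines(as.character(nb + nm), con)
    writeLines(paste0("sweep=", f$sweep, " L=", st$L), con)
    labs <- paste0("P", st$bead_poly, "_", toupper(REGION_TYPES[st$bead_type]))
    writeLines(paste(labs, st$bead_coords[, 1], st$bead_coords[, 2],
                     st$bead_coords[, 3]), con)
    if (nm) {
      writeLines(paste(paste0("MOL_", SPECIES[st$mol_species]),
                       st$mol_coords[, 1], st$mol_coords[, 2],
                       st$mol_coords[, 3]), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @param path Path to an XYZ trajectory written by [write_trajectory_xyz()].
#' @return A list of `list(sweep=, state=)` frames.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    nat <- as.integer(lines[i])
    hdr <- strsplit(lines[i + 1], " ")[[1]]
    sweep <- as.integer(sub("sweep=", "", hdr[1]))
    L <- as.integer(sub("L=", "", hdr[2]))
    rec <- do.call(rbind, strsplit(lines[(i + 2):(i + 1 + nat)], " "))
    lab <- rec[, 1]
    xyz <- matrix(as.integer(rec[, 2:4]), ncol = 3)
    is_mol <- startsWith(lab, "MOL_")
    bead_lab <- lab[!is_mol]
    poly <- as.integer(sub("^P(\\d+)_.*$", "\\1", bead_lab))
    type <- match(tolower(sub("^P\\d+_", "", bead_lab)), REGION_TYPES)
    # reconstruct per-polymer block ids from contiguous runs of equal type
    block <- integer(length(type))
    b <- 0L
    for (k in seq_along(type)) {
      if (k == 1 || type[k] != type[k - 1] || poly[k] != poly[k - 1]) b <- b + 1L
      block[k] <- b
    }
    st <- new_system_state(L, xyz[!is_mol, , drop = FALSE], type, poly, block,
                           xyz[is_mol, , drop = FALSE],
                           match(sub("MOL_", "", lab[is_mol]), SPECIES))
    frames[[length(frames) + 1]] <- list(sweep = sweep, state = st)
    i <- i + 2 + nat
  }
  frames
}

#' Write a run manifest
#'
#' Plain-text manifest: config snapshot, seed, sweep range, and the output
#' file inventory with MD5 checksums -- sufficient to reproduce the run
#' bit-exactly.
#'
#' @param path Manifest path.
#' @param params A [model_params()] object.
#' @param seed Seed used.
#' @param sweeps Sweep count.
#' @param files Character vector of output files to inventory.
#' @export
write_manifest <- function(path, params, seed, sweeps, files) {
  sums <- tools::md5sum(files)
  lines <- c(
    "# xicsim run manifest (checksums: MD5)",
    paste0("seed: ", seed),
    paste0("sweeps: ", sweeps),
    paste0("config: n=", params$n, " L=", params$L, " c=", params$c,
           " E_X=", params$E_X, " E_A=", params$E_A, " E_B=", params$E_B,
           " valency=", params$valency, " cap_scope=", params$cap_scope,
           " d0=", params$d0, " shell_radius=", params$shell_radius),
    paste0(basename(files), "  ", sums)
  )
  writeLines(lines, path)
  invisible(path)
}
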