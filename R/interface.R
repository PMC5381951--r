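#' Load a run configuration
#'
#' Reads a YAML key-value file of physical-constant overrides and run
#' settings on top of the package defaults. Unknown keys are rejected by
#' name, so configuration typos cannot silently revert to defaults.
#'
#' @param path path to a YAML file; an empty or missing-keys file yields the
#'   pure defaults (300 ns timestep, D = 253 nm\eqn{^2}/s, 500 ns gate
#'   attempt time, 0.6 s per-bead translation time, ...).
#' @return A list of class `run_config` with elements `constants` (see
#'   [sec_constants()]) and `run` (ensemble/guard/io settings).
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    abort(paste0("config file not found: ", path))
  if (is.null(raw)) raw <- list()
  run_defaults <- list(
    geometry = NULL, fasta = NULL, ss = NULL,
    seed = 1, n_traj = 50, t_trans = NULL, max_time = 10,
    out_dir = ".", save_every = 0,
    lambda_qqq_helix = c(0.60, 0.55), lambda_qqq_coil = c(0.35, 0.30)
  )
  const_defaults <- sec_constants()
  known <- c(names(const_defaults), names(run_defaults))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  const_over <- raw[intersect(names(raw), names(const_defaults))]
  constants <- do.call(sec_constants, const_over)
  run <- run_defaults
  run_over <- raw[intersect(names(raw), names(run_defaults))]
  run[names(run_over)] <- run_over
  if (is.null(run$t_trans)) run$t_trans <- constants$t_trans_s
  structure(list(constants = constants, run = run), class = "run_config")
}

#' Write a run configuration
#'
#' Serializes the non-default entries of a config (plus every physical
#' constant, for provenance) as YAML; [load_config()] of the result
#' round-trips.
#'
#' @param config a `run_config` from [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- c(config$constants, config$run)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write and read trajectory frames
#'
#' Extended-XYZ text serialization: per frame, a bead-count line, a comment
#' line with `time_s`, `gate_state` and `n_translated` fields, then one
#' `CG x y z` line per translated bead (positions in \eqn{\sigma}).
#'
#' @param traj a `sec_trajectory` from [run_trajectory()] with saved frames.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a list with `frames` (list of coordinate
#'   matrices), `times`, `gate_states`, `n_translated`.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj$frames)) abort("trajectory has no saved frames")
  con <- file(path, "w")
  on.exit(close(con))
  nt <- dim(traj$frames)[3]
  gate <- traj$state$gate
  for (k in seq_len(nt)) {
    fr <- traj$frames[, , k, drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
    placed <- is.finite(fr[, 1])
    writeLines(as.character(sum(placed)), con)
    writeLines(sprintf("time_s=%.9g gate_state=%s n_translated=%d",
                       traj$frame_times[k], gate, sum(placed)), con)
    writeLines(sprintf("CG %.10g %.10g %.10g",
                       fr[placed, 1], fr[placed, 2], fr[placed, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  gates <- character()
  ntr <- integer()
  i <- 1
  while (i <= length(lines)) {
    nb <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nb)) abort(paste0("malformed frame header at line ", i))
    hdr <- lines[i + 1]
    fld <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
    times <- c(times, as.numeric(fld("time_s")))
    gates <- c(gates, fld("gate_state"))
    ntr <- c(ntr, as.integer(fld("n_translated")))
    block <- lines[i + 1 + seq_len(nb)]
    xyz <- do.call(rbind, lapply(strsplit(block, " +"), function(p) {
      as.numeric(p[2:4])
    }))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nb
  }
  list(frames = frames, times = times, gate_states = gates,
       n_translated = ntr)
}

#' Report assay results to TSV and JSON
#'
#' Writes the per-frame and averaged assay table as TSV and a JSON summary
#' (including the seed and a hash of the effective configuration) so a
#' result artifact can be regenerated from its own metadata.
#'
#' @param result a `sec_assay` tibble.
#' @param path_prefix output path without extension; writes
#'   `<prefix>.tsv` and `<prefix>.json`.
#' @param seed,config optional provenance fields embedded in the JSON.
#' @return invisible character vector of the two paths.
#' @export
report_assay <- function(result, path_prefix, seed = NULL, config = NULL) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  write.table(result, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    seed = seed,
    config_hash = if (!is.null(config)) {
      sum(utf8ToInt(paste(deparse(config), collapse = "")))
    } else NULL,
    results = result
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(tsv, json))
}
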