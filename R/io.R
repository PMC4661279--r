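#' Write / read a gamble table
#'
#' Tab-separated table with columns condition, level, type1_count, the four
#' conflict message counts, sure_gain and win_payoff.
#'
#' @param gambles Output of [generate_gamble_set()].
#' @param path File path.
#' @return `write_gamble_table` returns `path` invisibly; `read_gamble_table`
#'   returns the gamble data frame.
#' @export
write_gamble_table <- function(gambles, path) {
  cols <- c("gamble_id", "condition", "level", "type1_count",
            "msg_a_type2", "msg_a_type3", "msg_b_type2", "msg_b_type3",
            "sure_gain", "win_payoff")
  utils::write.table(gambles[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gamble_table
#' @export
read_gamble_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read session events
#'
#' BIDS-style events: one TSV per run with onset (s), duration (s),
#' trial_type, level and gamble_id. `write_events` writes
#' `<prefix>_run-<r>_events.tsv` files.
#'
#' @param session A [build_session()] schedule.
#' @param prefix Output path prefix.
#' @return Written file paths (invisibly).
#' @export
write_events <- function(session, prefix) {
  paths <- vapply(seq_len(session$n_runs), function(r) {
    ev <- session$trials[session$trials$run == r,
                         c("onset", "duration", "trial_type", "level", "gamble_id")]
    p <- sprintf("%s_run-%d_events.tsv", prefix, r)
    utils::write.table(ev, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "n/a")
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_events
#' @param path One events TSV path.
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "n/a")
}

#' Write / read fitted subject parameters as JSON
#'
#' @param params Data frame of per-subject parameters (e.g. [fit_cohort()]
#'   output, optionally with model-free `ra`, `aa`, `ca` columns).
#' @param path File path.
#' @return `write_parameters_json` returns `path` invisibly.
#' @export
write_parameters_json <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Export one subject run as NIfTI-1
#'
#' Optional interoperability export of a voxels-by-volumes run matrix to a
#' 4-D NIfTI file (requires the RNifti package).
#'
#' @param run Voxels-by-volumes matrix from an `ambicon_voxel_dataset`.
#' @param grid_dim Grid dimensions.
#' @param tr Repetition time in seconds.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_run_nifti <- function(run, grid_dim, tr, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI export")
  img <- array(run, dim = c(grid_dim, ncol(run)))
  nim <- RNifti::asNifti(img)
  RNifti::pixdim(nim) <- c(1, 1, 1, tr)
  RNifti::writeNifti(nim, path)
  invisible(path)
}
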