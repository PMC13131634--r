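# Plain-text interchange: parcel-by-volume run tables (TSV), events tables,
# framewise-displacement vectors, model archives and attractor sets.

MODEL_ARCHIVE_VERSION <- "mindyx-model-1"

#' Write / read a parcel-by-volume run table
#'
#' Tab-separated text with parcels as rows and volumes as columns; the header
#' row carries volume indices. Condition labels travel in the companion
#' events table, not in the matrix.
#'
#' @param run a `bold_run` (or `neural_run`).
#' @param path file path.
#' @return `write_run_tsv` returns `path` invisibly; `read_run_tsv` returns a
#'   `bold_run`.
#' @export
write_run_tsv <- function(run, path) {
  d <- run$data
  colnames(d) <- seq_len(ncol(d))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_run_tsv
#' @param tr repetition time of the stored run (not encoded in the TSV).
#' @param condition,run_id,modality passed to [bold_run()].
#' @export
read_run_tsv <- function(path, tr, condition = NULL, run_id = basename(path),
                         modality = "rest") {
  d <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  dimnames(d) <- NULL
  bold_run(d, tr = tr, condition = condition, run_id = run_id,
           modality = modality)
}

#' Write / read an events table
#'
#' Columns `onset` (s), `duration` (s), `trial_type`.
#'
#' @param events data frame of events.
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a framewise-displacement vector
#'
#' Single-column text file, one nonnegative value per volume.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_fd <- function(path) {
  fd <- utils::read.table(path, header = FALSE)[[1]]
  if (any(fd < 0)) stopf("FD values must be nonnegative")
  as.numeric(fd)
}

#' Write / read a model archive
#'
#' Key-value numeric container (JSON at full double precision) with datasets
#' `Ws`, `W1`, `W2`, `alpha`, `D`, `B` and scalar attributes `b`, `n`, `k`,
#' `TR` plus a format-version string. Identical parameters produce
#' byte-identical archives.
#'
#' @param params a [mindyx_params()].
#' @param path file path (conventionally `.json`).
#' @export
write_model_archive <- function(params, path) {
  obj <- list(format = MODEL_ARCHIVE_VERSION,
              n = params$n, k = params$k, m = params$m,
              b = params$b, TR = params$tr,
              Ws = params$Ws, W1 = params$W1, W2 = params$W2,
              alpha = params$alpha, D = params$D, B = params$B)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_archive
#' @export
read_model_archive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_ARCHIVE_VERSION)) {
    stopf("unrecognized model archive format: %s", obj$format)
  }
  mindyx_params(obj$Ws, matrix(obj$W1, obj$n), matrix(obj$W2, obj$n),
                obj$alpha, obj$D, matrix(obj$B, obj$n), tr = obj$TR)
}

#' Write an attractor set as JSON
#'
#' Equilibria (state vectors and basin counts), limit cycles (orbit arrays and
#' periods), the probing input, topology label and flags.
#'
#' @param attrs an `attractor_set`.
#' @param path file path.
#' @export
write_attractors_json <- function(attrs, path) {
  obj <- list(
    input = attrs$input,
    topology = attrs$topology,
    unclassified_flag = attrs$unclassified_flag,
    n_diverged = attrs$n_diverged,
    equilibria = lapply(attrs$equilibria, function(eq) {
      list(x_star = eq$x_star, basin_count = eq$basin_count)
    }),
    cycles = lapply(attrs$cycles, function(lc) {
      list(period = lc$period, orbit = lc$orbit)
    }))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
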