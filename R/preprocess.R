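# Time-series preparation: run containers, normalization, confound regression,
# motion scrubbing, canonical HRF and Wiener deconvolution.

#' Construct a BOLD run
#'
#' A single scan: a parcel-by-volume matrix with its repetition time,
#' per-volume condition labels and identifiers. Labels are `"rest"`,
#' `"interval"` (task block gaps) or condition names such as `"cond_1"`.
#'
#' @param data n x T numeric matrix (parcels by volumes).
#' @param tr repetition time in seconds.
#' @param condition character vector of length T; default all `"rest"`.
#' @param run_id identifier string.
#' @param modality `"rest"` or `"task"`.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, condition = NULL, run_id = "run",
                     modality = c("rest", "task")) {
  data <- as.matrix(data)
  modality <- match.arg(modality)
  if (ncol(data) < 2L) stopf("a run needs at least 2 volumes")
  if (is.null(condition)) condition <- rep("rest", ncol(data))
  if (length(condition) != ncol(data)) {
    stopf("condition labels (%d) must match volumes (%d)",
          length(condition), ncol(data))
  }
  if (tr <= 0) stopf("tr must be positive")
  structure(list(data = data, tr = tr, condition = as.character(condition),
                 run_id = run_id, modality = modality),
            class = "bold_run")
}

#' Mark a run as deconvolved neural activity
#'
#' @param run a `bold_run` whose data are deconvolved neural states.
#' @return The run with class `neural_run` prepended.
#' @export
as_neural_run <- function(run) {
  class(run) <- unique(c("neural_run", class(run)))
  run
}

#' @export
print.bold_run <- function(x, ...) {
  kind <- if (inherits(x, "neural_run")) "neural_run" else "bold_run"
  cat(sprintf("<%s> '%s': %d parcels x %d volumes, TR = %g s, %s\n",
              kind, x$run_id, nrow(x$data), ncol(x$data), x$tr, x$modality))
  invisible(x)
}

# Per-parcel mean/sd over selected volumes (default: all). Task runs are
# conventionally normalized by their block-interval statistics.
run_stats <- function(run, volumes = NULL) {
  d <- if (is.null(volumes)) run$data else run$data[, volumes, drop = FALSE]
  list(mean = rowMeans(d), sd = apply(d, 1, stats::sd))
}

#' Normalize a run (detrend and standardize)
#'
#' Linearly detrends each parcel series, then standardizes it as
#' `(y - ref_mean) / ref_sd`. When no reference statistics are supplied they
#' are the run's own post-detrend statistics (giving mean 0, sd 1 per parcel);
#' task runs can instead pass the statistics of their block intervals so that
#' interval volumes are standardized analogously to resting state.
#'
#' @param run a `bold_run`.
#' @param ref_mean,ref_sd optional length-n reference statistics; `ref_sd`
#'   must be positive.
#' @return The normalized run.
#' @export
normalize_run <- function(run, ref_mean = NULL, ref_sd = NULL) {
  d <- run$data
  T <- ncol(d)
  tt <- seq_len(T)
  X <- cbind(1, tt - mean(tt))
  # per-parcel linear detrend (removes mean and linear drift)
  beta <- t(qr.solve(X, t(d)))
  d <- d - beta %*% t(X)
  if (is.null(ref_mean)) ref_mean <- rowMeans(d)
  if (is.null(ref_sd)) {
    ref_sd <- apply(d, 1, stats::sd)
  }
  if (any(ref_sd < 1e-10)) {
    stopf("degenerate (near-constant) parcel series: sd below 1e-10")
  }
  run$data <- (d - ref_mean) / ref_sd
  run
}

#' Regress confound time series out of a run
#'
#' Replaces each parcel series by its OLS residual after regression on the
#' supplied confounds plus an intercept. Rank-deficient confound matrices are
#' handled by pseudo-inverse with a warning.
#'
#' @param run a `bold_run`.
#' @param confounds T x c numeric matrix of per-volume confounds.
#' @return The residualized run.
#' @export
regress_confounds <- function(run, confounds) {
  confounds <- as.matrix(confounds)
  T <- ncol(run$data)
  if (nrow(confounds) != T) {
    stopf("confound rows (%d) must match volumes (%d)", nrow(confounds), T)
  }
  X <- cbind(1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudo-inverse")
    H <- X %*% MASS::ginv(X)
    run$data <- run$data - run$data %*% t(H)
  } else {
    beta <- qr.coef(qx, t(run$data))
    run$data <- run$data - t(X %*% beta)
  }
  dimnames(run$data) <- NULL
  run
}

#' Scrub high-motion volumes by linear interpolation
#'
#' Volumes whose framewise displacement exceeds `threshold` are replaced by
#' linear interpolation between the nearest unflagged neighbors; flagged
#' volumes at the run boundaries copy the nearest unflagged value. The flagged
#' fraction is attached as attribute `"flagged_fraction"` so callers can apply
#' an exclusion rule (e.g. more than 1/3 high-motion volumes).
#'
#' @param run a `bold_run`.
#' @param fd nonnegative framewise-displacement vector, one value per volume.
#' @param threshold scrubbing threshold in mm (conventionally 0.2 for rest,
#'   0.9 for task).
#' @return The scrubbed run, with attribute `flagged_fraction`.
#' @export
scrub_interpolate <- function(run, fd, threshold) {
  T <- ncol(run$data)
  if (length(fd) != T) stopf("fd length (%d) must match volumes (%d)", length(fd), T)
  if (any(fd < 0)) stopf("fd must be nonnegative")
  bad <- fd > threshold
  if (all(bad)) stopf("all volumes flagged at threshold %g", threshold)
  if (any(bad)) {
    good <- which(!bad)
    run$data <- t(apply(run$data, 1, function(y) {
      stats::approx(good, y[good], xout = seq_len(T), rule = 2)$y
    }))
  }
  attr(run, "flagged_fraction") <- mean(bad)
  run
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention kernel sampled at the repetition time: a gamma density
#' peaking at 6 s minus a 16 s undershoot gamma scaled by 1/6, both with unit
#' dispersion, over a 32 s support, rescaled to unit peak. The kernel vanishes
#' at t = 0 and has its maximum near 5 s.
#'
#' @param tr repetition time in seconds.
#' @param duration kernel support in seconds (default 32).
#' @return An object of class `hrf_kernel` with fields `h` and `tr`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  if (tr <= 0) stopf("tr must be positive")
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  structure(list(h = h, tr = tr), class = "hrf_kernel")
}

#' Construct an HRF kernel from samples
#'
#' @param h numeric impulse-response samples (length >= 2) at spacing `tr`.
#' @param tr sampling interval in seconds.
#' @return An `hrf_kernel`.
#' @export
hrf_kernel <- function(h, tr) {
  h <- as.numeric(h)
  if (length(h) < 2L) stopf("kernel needs at least 2 samples")
  assert_finite(h, "hrf kernel")
  structure(list(h = h, tr = tr), class = "hrf_kernel")
}

#' Wiener deconvolution of BOLD into neural activity
#'
#' Minimum mean-squared-error inverse filtering in the frequency domain:
#' `X(f) = Conj(H(f)) Y(f) / (|H(f)|^2 + 1/snr)`, applied per parcel over the
#' full run with zero padding to the next power of two. Each parcel series is
#' de-meaned before the FFT (avoiding a step artifact at the padding
#' boundary) and the removed mean is restored through the filter's DC
#' response, so a constant offset is deconvolved consistently with every
#' other frequency.
#'
#' @param run a `bold_run`.
#' @param hrf an [hrf_kernel()]; defaults to the canonical HRF at the run's TR.
#' @param snr assumed signal-to-noise variance ratio (default 50).
#' @return A `neural_run` of the same shape and labels.
#' @export
wiener_deconvolve <- function(run, hrf = canonical_hrf(run$tr), snr = 50) {
  if (snr <= 0) stopf("snr must be positive")
  d <- run$data
  T <- ncol(d)
  L <- length(hrf$h)
  if (T < L) stopf("run (%d volumes) shorter than kernel support (%d)", T, L)
  nfft <- next_pow2(T + L)
  mu <- rowMeans(d)
  pad <- matrix(0, nrow(d), nfft)
  pad[, seq_len(T)] <- d - mu
  H <- stats::fft(c(hrf$h, rep(0, nfft - L)))
  G <- Conj(H) / (Mod(H)^2 + 1 / snr)
  Yf <- stats::mvfft(t(pad))
  Xt <- Re(stats::mvfft(Yf * G, inverse = TRUE)) / nfft
  run$data <- t(Xt)[, seq_len(T), drop = FALSE] + mu * Re(G[1])
  as_neural_run(run)
}

#' Build the per-volume task-input design
#'
#' Encodes each volume's condition label as a one-hot vector over the task
#' conditions; `"rest"` and `"interval"` volumes get the zero vector (block
#' intervals are treated analogously to resting state).
#'
#' @param condition length-T character vector of labels.
#' @param conditions ordered character vector of task condition names.
#' @return An object of class `task_design` with fields `u` (m x T) and
#'   `conditions`.
#' @export
build_design <- function(condition, conditions) {
  known <- c("rest", "interval", conditions)
  unknown <- setdiff(unique(condition), known)
  if (length(unknown)) stopf("unknown condition label(s): %s",
                             paste(unknown, collapse = ", "))
  u <- vapply(condition, function(lab) as.numeric(conditions == lab),
              numeric(length(conditions)))
  u <- matrix(u, nrow = length(conditions), ncol = length(condition))
  rownames(u) <- conditions
  structure(list(u = u, conditions = conditions), class = "task_design")
}

#' Per-volume condition labels from an events table
#'
#' @param events data frame with columns `onset` and `duration` (seconds) and
#'   `trial_type`.
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param baseline label for volumes not covered by any event
#'   (`"interval"` for task runs).
#' @return Character vector of length `n_volumes`.
#' @export
condition_from_events <- function(events, n_volumes, tr, baseline = "interval") {
  lab <- rep(baseline, n_volumes)
  t0 <- (seq_len(n_volumes) - 1) * tr
  eps <- 1e-6 * tr  # guard against floating-point onset comparisons
  for (i in seq_len(nrow(events))) {
    sel <- t0 >= events$onset[i] - eps &
      t0 < events$onset[i] + events$duration[i] - eps
    lab[sel] <- as.character(events$trial_type[i])
  }
  lab
}
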