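# Forward integration of a model: deterministic (attractor probing),
# noise-driven (surrogate neural data), and BOLD synthesis.

#' Noise specification for simulation
#'
#' @param process_sd per-parcel process-noise standard deviation (scalar is
#'   recycled).
#' @param obs_snr observed signal-to-noise variance ratio for BOLD synthesis
#'   (default 50).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(process_sd = 0, obs_snr = 50) {
  if (any(process_sd < 0)) stopf("process_sd must be nonnegative")
  if (obs_snr <= 0) stopf("obs_snr must be positive")
  structure(list(process_sd = process_sd, obs_snr = obs_snr),
            class = "noise_spec")
}

new_trajectory <- function(states, input, seed = NULL, diverged = FALSE) {
  structure(list(states = states, input = input, seed = seed,
                 diverged = diverged), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d parcels x %d steps%s\n", nrow(x$states),
              ncol(x$states), if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Deterministic forward simulation under constant input
#'
#' Iterates the noise-free one-step map from `x0` for `steps` steps under a
#' constant input. Trajectories whose state exceeds 1e6 in magnitude are
#' truncated and flagged divergent.
#'
#' @param params a [mindyx_params()].
#' @param u_const constant input vector of length m (`NULL` = zero input).
#' @param x0 initial state (length n).
#' @param steps number of iterations (the trajectory has `steps + 1` columns,
#'   starting at `x0`).
#' @return A `trajectory`.
#' @export
simulate_noise_free <- function(params, u_const = NULL, x0, steps) {
  if (steps < 1L) stopf("steps must be >= 1")
  W <- assemble_connectivity(params)
  bu <- if (is.null(u_const)) rep(0, params$n) else drop(params$B %*% u_const)
  states <- matrix(0, params$n, steps + 1L)
  states[, 1L] <- x0
  x <- as.numeric(x0)
  diverged <- FALSE
  for (t in seq_len(steps)) {
    x <- x + drop(W %*% activation(x, params$alpha)) - params$D * x + bu
    if (max(abs(x)) > 1e6) {
      states <- states[, 1:t, drop = FALSE]
      diverged <- TRUE
      break
    }
    states[, t + 1L] <- x
  }
  new_trajectory(states, input = if (is.null(u_const)) rep(0, params$m) else u_const,
                 diverged = diverged)
}

#' Noise-driven forward simulation of a full design
#'
#' Runs a zero-input warm-up of `warmup` steps with process noise (discarded),
#' then iterates the dynamics through the per-volume inputs of `design`,
#' injecting independent Gaussian process noise into each parcel at each step.
#'
#' @param params a [mindyx_params()].
#' @param design a [build_design()] object giving `u_t` for every output step.
#' @param noise a [noise_spec()]; `process_sd` sets the per-parcel noise sd.
#' @param warmup number of discarded warm-up steps (default 1000).
#' @param seed optional integer seed.
#' @param x0 initial state; default standard-normal entries.
#' @return A `trajectory` with one column per design volume.
#' @export
simulate_noise_driven <- function(params, design, noise = noise_spec(),
                                  warmup = 1000, seed = NULL, x0 = NULL) {
  U <- design$u
  T <- ncol(U)
  if (T < 1L) stopf("design must cover at least one volume")
  n <- params$n
  sd_vec <- rep(noise$process_sd, length.out = n)
  W <- assemble_connectivity(params)
  with_seed(seed, {
    x <- if (is.null(x0)) stats::rnorm(n) else as.numeric(x0)
    diverged <- FALSE
    for (t in seq_len(warmup)) {
      x <- x + drop(W %*% activation(x, params$alpha)) - params$D * x +
        stats::rnorm(n, 0, sd_vec)
      if (max(abs(x)) > 1e6) { diverged <- TRUE; break }
    }
    states <- matrix(0, n, T)
    if (!diverged) {
      for (t in seq_len(T)) {
        x <- x + drop(W %*% activation(x, params$alpha)) - params$D * x +
          drop(params$B %*% U[, t]) + stats::rnorm(n, 0, sd_vec)
        if (max(abs(x)) > 1e6) {
          states <- states[, seq_len(t - 1L), drop = FALSE]
          diverged <- TRUE
          break
        }
        states[, t] <- x
      }
    }
    new_trajectory(states, input = design, seed = seed, diverged = diverged)
  })
}

#' Synthesize BOLD from a neural trajectory
#'
#' Convolves each parcel's neural series causally with the HRF kernel and adds
#' Gaussian observation noise whose per-parcel variance is the neural
#' signal's variance divided by `obs_snr` (the signal-to-noise ratio is
#' defined against the neural series, matching the Wiener prior of
#' [wiener_deconvolve()]).
#'
#' @param traj a `trajectory` (or n x T matrix of neural states).
#' @param hrf an [hrf_kernel()].
#' @param noise a [noise_spec()] (its `obs_snr` is used; `Inf`-like behavior
#'   can be had with a very large value).
#' @param tr repetition time of the output run (defaults to the kernel's).
#' @param condition optional per-volume labels for the output run.
#' @param seed optional integer seed for the observation noise.
#' @param run_id,modality passed to [bold_run()].
#' @return A `bold_run` of the same shape as the trajectory.
#' @export
generate_bold <- function(traj, hrf, noise = noise_spec(), tr = hrf$tr,
                          condition = NULL, seed = NULL, run_id = "sim",
                          modality = "rest") {
  X <- if (inherits(traj, "trajectory")) traj$states else as.matrix(traj)
  T <- ncol(X)
  L <- length(hrf$h)
  if (T <= L) stopf("trajectory (%d) must be longer than kernel support (%d)", T, L)
  Y <- t(apply(X, 1, function(x) {
    # causal convolution sum y_t = sum_l h_l x_{t-l}
    stats::convolve(x, rev(hrf$h), type = "open")[seq_len(T)]
  }))
  with_seed(seed, {
    sds <- sqrt(apply(X, 1, stats::var) / noise$obs_snr)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, rep(sds, ncol(Y))), nrow(Y))
    bold_run(Y, tr = tr, condition = condition, run_id = run_id,
             modality = modality)
  })
}
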