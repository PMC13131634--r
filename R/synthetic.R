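# Synthetic ground truth and full surrogate sessions: generates models with a
# controlled attractor regime and rest + block-design task runs with the
# generative structure the pipeline assumes (process noise, HRF convolution,
# observation noise), so every stage is testable without restricted data.

#' Synthetic-session configuration
#'
#' Desk-scale mirror of a working-memory scanning session: by default 15
#' parcels, two resting runs of 1000 volumes and one task run of 400 volumes
#' at TR 0.72 s with four 25 s blocks per condition (conditions `cond_1` and
#' `cond_2`, emulating 0-back- and 2-back-like blocks).
#'
#' @param n_parcels number of parcels n.
#' @param rank_k rank of the low-rank connectivity component.
#' @param regime target attractor regime at rest: `"monostable"`,
#'   `"multistable"`, `"oscillatory"` or `"mixed"`.
#' @param n_rest_runs,rest_T resting runs and volumes per run.
#' @param n_task_runs,task_T task runs and volumes per run.
#' @param block_length_s task block length in seconds.
#' @param n_blocks_per_condition blocks per condition per task run.
#' @param tr repetition time in seconds.
#' @param process_sd process-noise standard deviation injected at every step.
#' @param obs_snr observation signal-to-noise variance ratio (default 50).
#' @param conditions task condition labels.
#' @param seed integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_parcels = 15, rank_k = 5,
                         regime = c("multistable", "monostable",
                                    "oscillatory", "mixed"),
                         n_rest_runs = 2, rest_T = 1000,
                         n_task_runs = 1, task_T = 400,
                         block_length_s = 25, n_blocks_per_condition = 4,
                         tr = 0.72, process_sd = 0.3, obs_snr = 50,
                         conditions = c("cond_1", "cond_2"), seed = NULL) {
  regime <- match.arg(regime)
  if (n_parcels < 3L || rank_k < 1L) stopf("need n_parcels >= 3, rank_k >= 1")
  if (tr <= 0) stopf("tr must be positive")
  if (min(n_rest_runs, rest_T, n_task_runs, task_T,
          n_blocks_per_condition) < 1L) stopf("counts must be positive")
  structure(as.list(environment()), class = "synth_config")
}

# Draw a sparse-plus-low-rank background connectivity scaled so that the
# linearization at the origin, I - diag(D) + W diag(g), has spectral radius
# `rho` (near-critical, stable). Near-criticality gives the slow,
# low-frequency, roughly unit-variance fluctuations characteristic of
# resting-state activity; the activation's decreasing gain away from zero
# keeps the nonlinear map bounded.
draw_background <- function(n, k, g, D, rho = 0.9) {
  Ws <- matrix(stats::rnorm(n * n) * (stats::runif(n * n) < 0.3), n, n)
  W1 <- matrix(stats::rnorm(n * k, 0, 0.5), n, k)
  W2 <- matrix(stats::rnorm(n * k, 0, 0.5), n, k)
  W <- Ws + W1 %*% t(W2)
  spec <- function(s) {
    max(Mod(eigen(diag(1 - D) + s * W %*% diag(g),
                  only.values = TRUE)$values))
  }
  lo <- 0; hi <- 1
  while (spec(hi) < rho) hi <- 2 * hi
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (spec(mid) < rho) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  list(Ws = s * Ws, W1 = s * W1, W2 = W2)
}

#' Generate a ground-truth model with a controlled attractor regime
#'
#' Builds a sparse-plus-low-rank connectivity with a globally contractive
#' background (monostable), optionally augmented with strongly self-excited
#' parcels whose input-output curve has two stable roots (multistable) or a
#' rotational pair with supercritical gain saturating into a limit cycle
#' (oscillatory); `"mixed"` plants both. Decay rates lie in [0.2, 0.8],
#' activation curvatures around 5, and the task-input matrix `B` carries a
#' planted task-positive / task-negative parcel split. The realized rest
#' regime is verified post hoc with [find_attractors()] and the draw is
#' retried (new randomness) up to `max_tries` times.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @param max_tries bounded retries before failing with an error naming the
#'   regime.
#' @return A [mindyx_params()] ground truth.
#' @export
make_ground_truth <- function(cfg = synth_config(), seed = cfg$seed,
                              max_tries = 5) {
  n <- cfg$n_parcels; k <- cfg$rank_k
  m <- length(cfg$conditions)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      alpha <- stats::runif(n, 4, 6)
      D <- stats::runif(n, 0.2, 0.8)
      g <- activation_slope_at_zero(alpha)
      bg <- draw_background(n, k, g, D, rho = 0.9)
      Ws <- bg$Ws

      if (cfg$regime %in% c("multistable", "mixed")) {
        planted <- 1:2
        for (i in planted) {
          Ws[i, -i] <- 0.1 * Ws[i, -i]
          Ws[-i, i] <- 0.1 * Ws[-i, i]
          Ws[i, i] <- 1.6 * D[i] / g[i]  # self-gain above decay: two stable roots
        }
      }
      if (cfg$regime %in% c("oscillatory", "mixed")) {
        ij <- if (cfg$regime == "mixed") c(3L, 4L) else c(1L, 2L)
        alpha[ij] <- 5; D[ij] <- 0.5
        g <- activation_slope_at_zero(alpha)
        r <- 1.15; theta <- 2 * pi / 40  # unstable spiral, ~40-step rotation
        A <- r * cos(theta) - (1 - D[ij[1]])
        C <- r * sin(theta)
        Ws[ij, ] <- 0.05 * Ws[ij, ]; Ws[, ij] <- 0.05 * Ws[, ij]
        Ws[ij[1], ij[1]] <- A / g[ij[1]]
        Ws[ij[1], ij[2]] <- -C / g[ij[2]]
        Ws[ij[2], ij[1]] <- C / g[ij[1]]
        Ws[ij[2], ij[2]] <- A / g[ij[2]]
      }

      sgn <- rep(c(1, -1), each = ceiling(n / 2))[1:n]  # task +/- parcel split
      B <- vapply(seq_len(m), function(j) {
        sgn * stats::runif(n, 0.15, 0.4) * (1 + 0.5 * (j - 1))
      }, numeric(n))
      B <- matrix(B, n, m)

      params <- mindyx_params(Ws, bg$W1, bg$W2, alpha, D, B, tr = cfg$tr)
      aset <- find_attractors(params, NULL, n_init = 30, steps = 1600,
                              seed = sample.int(.Machine$integer.max, 1))
      ok <- !aset$unclassified_flag && !is.na(aset$topology) &&
        switch(cfg$regime,
               monostable = aset$topology == "monostable",
               multistable = aset$topology == "multistable",
               oscillatory = aset$topology == "oscillatory",
               mixed = aset$topology %in% c("multistable", "oscillatory"))
      if (ok) return(params)
    }
    stopf("failed to realize a '%s' regime after %d tries", cfg$regime, max_tries)
  })
}

# Condition labels and events for one block-design task run: alternating
# condition blocks separated by intervals, any leftover volumes appended to
# the final interval.
task_block_labels <- function(cfg) {
  block_len <- max(1L, round(cfg$block_length_s / cfg$tr))
  n_blocks <- cfg$n_blocks_per_condition * length(cfg$conditions)
  order <- rep(cfg$conditions, cfg$n_blocks_per_condition)
  needed <- n_blocks * block_len
  if (needed + n_blocks + 1L > cfg$task_T) {
    stopf("task_T = %d too short for %d blocks of %d volumes",
          cfg$task_T, n_blocks, block_len)
  }
  gap <- (cfg$task_T - needed) %/% (n_blocks + 1L)
  lab <- rep("interval", cfg$task_T)
  onsets <- numeric(n_blocks)
  pos <- gap
  for (b in seq_len(n_blocks)) {
    lab[(pos + 1L):(pos + block_len)] <- order[b]
    onsets[b] <- pos * cfg$tr
    pos <- pos + block_len + gap
  }
  list(labels = lab,
       events = data.frame(onset = onsets,
                           duration = block_len * cfg$tr,
                           trial_type = order))
}

#' Synthesize a full rest + task session
#'
#' Simulates the generative model end to end: resting runs under zero input
#' and block-design task runs under the box-car design, each as a noise-driven
#' trajectory (1000-step warm-up) convolved with the canonical HRF and
#' corrupted by observation noise at the configured signal-to-noise ratio.
#'
#' @param params ground-truth [mindyx_params()] (e.g. [make_ground_truth()]).
#' @param cfg the [synth_config()] describing the session layout.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return A list with parallel lists `bold` (`bold_run`s), `neural`
#'   (ground-truth `neural_run`s), `designs` ([build_design()]s) and `events`
#'   (one events data frame per run; `NULL` for rest).
#' @export
synthesize_session <- function(params, cfg = synth_config(), seed = cfg$seed) {
  hrf <- canonical_hrf(cfg$tr)
  noise <- noise_spec(process_sd = cfg$process_sd, obs_snr = cfg$obs_snr)
  bold <- list(); neural <- list(); designs <- list(); events <- list()
  with_seed(seed, {
    ridx <- 0L
    add_run <- function(labels, run_id, modality, ev) {
      ridx <<- ridx + 1L
      design <- build_design(labels, cfg$conditions)
      traj <- simulate_noise_driven(params, design, noise, warmup = 1000)
      if (traj$diverged) stopf("simulation diverged in run '%s'", run_id)
      nr <- bold_run(traj$states, tr = cfg$tr, condition = labels,
                     run_id = run_id, modality = modality)
      bold[[ridx]] <<- generate_bold(traj, hrf, noise, condition = labels,
                                     run_id = run_id, modality = modality)
      neural[[ridx]] <<- as_neural_run(nr)
      designs[[ridx]] <<- design
      events[[ridx]] <<- ev
    }
    for (r in seq_len(cfg$n_rest_runs)) {
      add_run(rep("rest", cfg$rest_T), sprintf("rest_%d", r), "rest", NULL)
    }
    blk <- task_block_labels(cfg)
    for (r in seq_len(cfg$n_task_runs)) {
      add_run(blk$labels, sprintf("task_%d", r), "task", blk$events)
    }
  })
  list(bold = bold, neural = neural, designs = designs, events = events)
}

#' Deconvolve every run of a session
#'
#' Convenience wrapper applying [wiener_deconvolve()] run by run (synthetic
#' sessions are already on the model's standardized scale, so no
#' renormalization is applied here).
#'
#' @param runs list of `bold_run`s.
#' @param hrf optional shared [hrf_kernel()]; default canonical at each run's
#'   TR.
#' @param snr signal-to-noise prior of the Wiener filter.
#' @return List of `neural_run`s.
#' @export
deconvolve_session <- function(runs, hrf = NULL, snr = 50) {
  lapply(runs, function(r) {
    wiener_deconvolve(r, hrf = if (is.null(hrf)) canonical_hrf(r$tr) else hrf,
                      snr = snr)
  })
}
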