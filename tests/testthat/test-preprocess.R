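make_run <- function(data, tr = 0.72, ...) bold_run(data, tr = tr, ...)

test_that("normalization standardizes with own or reference statistics", {
  set.seed(1)
  r <- make_run(matrix(rnorm(3 * 50, mean = 4, sd = 3), 3))
  z <- normalize_run(r)
  expect_equal(rowMeans(z$data), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z$data, 1, sd), rep(1, 3), tolerance = 1e-12)
  # constant parcel series is degenerate
  bad <- make_run(rbind(rnorm(50), rep(2, 50)))
  expect_error(normalize_run(bad), "degenerate")
  # task run normalized by block-interval statistics: interval volumes get
  # mean 0 / sd 1, block volumes need not
  cond <- rep(c("interval", "cond_1"), each = 20)
  d <- rbind(c(rnorm(20), rnorm(20, 5)), c(rnorm(20, -1), rnorm(20, 3)))
  tr_run <- make_run(d, condition = cond, modality = "task")
  det <- normalize_run(tr_run, ref_mean = rep(0, 2), ref_sd = c(1, 1))  # detrend only
  st <- mindyx:::run_stats(det, volumes = det$condition == "interval")
  z2 <- normalize_run(tr_run, ref_mean = st$mean, ref_sd = st$sd)
  iv <- z2$condition == "interval"
  expect_equal(rowMeans(z2$data[, iv]), rep(0, 2), tolerance = 1e-8)
  expect_equal(apply(z2$data[, iv], 1, sd), rep(1, 2), tolerance = 1e-8)
  expect_gt(abs(mean(z2$data[1, !iv])), 0.5)
})

test_that("confound regression matches closed-form OLS", {
  set.seed(2)
  T <- 60
  conf <- matrix(rnorm(T), T, 1)
  # series orthogonal to the demeaned confound stays put
  y_orth <- residuals(lm(rnorm(T) ~ conf))
  r <- make_run(rbind(y_orth, conf[, 1]))
  out <- regress_confounds(r, conf)
  expect_equal(out$data[1, ], unname(y_orth), tolerance = 1e-10)
  # a series equal to the confound vanishes
  expect_equal(out$data[2, ], rep(0, T), tolerance = 1e-10)
  # hand simple-regression oracle: beta = cov/var on demeaned variables
  y <- rnorm(T, sd = 2) + 0.7 * conf[, 1]
  r2 <- make_run(matrix(y, 1))
  got <- regress_confounds(r2, conf)$data[1, ]
  xc <- conf[, 1] - mean(conf[, 1]); yc <- y - mean(y)
  beta <- sum(xc * yc) / sum(xc^2)
  expect_equal(got, yc - beta * xc, tolerance = 1e-10)
  # rank-deficient confounds fall back to pseudo-inverse with a warning
  expect_warning(regress_confounds(r2, cbind(conf, conf)), "rank-deficient")
})

test_that("scrubbing interpolates flagged volumes linearly", {
  d <- matrix(c(1, 2, 100, 4, 5), 1)
  r <- make_run(d)
  fd <- c(0, 0, 1, 0, 0)
  out <- scrub_interpolate(r, fd, threshold = 0.5)
  expect_equal(out$data[1, ], c(1, 2, 3, 4, 5))
  expect_equal(attr(out, "flagged_fraction"), 0.2)
  # untouched when nothing is flagged
  out0 <- scrub_interpolate(r, rep(0, 5), 0.5)
  expect_equal(out0$data, d)
  # boundary volumes copy the nearest unflagged value
  rb <- make_run(matrix(c(9, 2, 3, 4, 8), 1))
  outb <- scrub_interpolate(rb, c(1, 0, 0, 0, 1), 0.5)
  expect_equal(outb$data[1, ], c(2, 2, 3, 4, 4))
  # idempotent: scrubbing the scrubbed run changes nothing
  out2 <- scrub_interpolate(out, fd, threshold = 0.5)
  expect_equal(out2$data, out$data)
  expect_error(scrub_interpolate(r, rep(1, 5), 0.5), "all volumes")
})

test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.72)
  expect_s3_class(h, "hrf_kernel")
  expect_equal(h$h[1], 0)
  expect_equal(max(h$h), 1)
  # peak near 5 s for the 6/16 double gamma
  expect_equal((which.max(h$h) - 1) * 0.72, 5, tolerance = 0.5)
  # exactly one sign change: positive peak then undershoot
  s <- sign(h$h[abs(h$h) > 1e-12])
  expect_equal(sum(diff(s) != 0), 1)
  # finer sampling keeps the same shape
  h2 <- canonical_hrf(0.1)
  expect_equal((which.max(h2$h) - 1) * 0.1, 5, tolerance = 0.1)
})

test_that("wiener deconvolution implements the closed-form filter", {
  set.seed(3)
  T <- 128
  y <- matrix(rnorm(2 * T), 2)
  y <- y - rowMeans(y)  # zero-mean input isolates the pure filter gain
  impulse <- hrf_kernel(c(1, 0), 0.72)
  out <- wiener_deconvolve(make_run(y), impulse, snr = 50)
  # identity kernel: H == 1, so the filter is the scalar 1/(1 + 1/50)
  expect_equal(out$data, y * 50 / 51, tolerance = 1e-12)
  expect_s3_class(out, "neural_run")
  # linearity
  r1 <- wiener_deconvolve(make_run(y), canonical_hrf(0.72))
  r3 <- wiener_deconvolve(make_run(3 * y), canonical_hrf(0.72))
  expect_equal(3 * r1$data, r3$data, tolerance = 1e-10)
  expect_error(wiener_deconvolve(make_run(y), impulse, snr = -1), "positive")
})

test_that("convolve-then-deconvolve round trip is accurate in the passband", {
  hrf <- canonical_hrf(0.72)
  L <- length(hrf$h)
  T <- 600
  tt <- seq_len(T) * 0.72
  # band-limited signal well inside the hemodynamic passband (< 0.05 Hz)
  x <- rbind(sin(2 * pi * 0.02 * tt) + 0.5 * cos(2 * pi * 0.035 * tt),
             cos(2 * pi * 0.01 * tt) - 0.3 * sin(2 * pi * 0.04 * tt))
  bold <- generate_bold(x, hrf, noise_spec(0, obs_snr = Inf))
  dec <- wiener_deconvolve(bold, hrf, snr = 50)
  int <- (L + 1):(T - L)  # interior: the acausal filter lacks data at edges
  rel_rmse <- sqrt(mean((dec$data[, int] - x[, int])^2)) / sqrt(mean(x[, int]^2))
  expect_lt(rel_rmse, 0.05)
  # with snr -> infinity and an invertible kernel the filter is the inverse
  # (compared after centering: the mean-restoration convention leaves a tiny
  # DC offset from the truncated convolution tail)
  gain_kernel <- hrf_kernel(c(1, 0.4), 0.72)
  b2 <- generate_bold(x, gain_kernel, noise_spec(0, obs_snr = Inf))
  d2 <- wiener_deconvolve(b2, gain_kernel, snr = 1e12)
  ctr <- function(m) m - rowMeans(m)
  expect_equal(ctr(d2$data[, int]), ctr(x[, int]), tolerance = 1e-6)
  # shapes and labels survive the normalize -> deconvolve pipeline
  lab <- rep(c("rest"), T)
  run <- make_run(x + 5, condition = lab)
  piped <- wiener_deconvolve(normalize_run(run), hrf)
  expect_equal(dim(piped$data), dim(run$data))
  expect_equal(piped$condition, lab)
})

test_that("task designs one-hot encode conditions and zero rest/interval", {
  cond <- c("rest", "cond_1", "cond_2", "interval", "cond_1")
  d <- build_design(cond, c("cond_1", "cond_2"))
  expect_equal(dim(d$u), c(2, 5))
  expect_equal(d$u[, 1], c(cond_1 = 0, cond_2 = 0))
  expect_equal(d$u[, 2], c(cond_1 = 1, cond_2 = 0))
  expect_equal(d$u[, 3], c(cond_1 = 0, cond_2 = 1))
  expect_equal(d$u[, 4], c(cond_1 = 0, cond_2 = 0))
  expect_error(build_design(c("rest", "oops"), "cond_1"), "unknown")
})

test_that("events tables convert to per-volume labels", {
  ev <- data.frame(onset = c(2.16, 7.2), duration = c(2.16, 1.44),
                   trial_type = c("cond_1", "cond_2"))
  lab <- condition_from_events(ev, n_volumes = 15, tr = 0.72)
  expect_equal(lab[4:6], rep("cond_1", 3))
  expect_equal(lab[11:12], rep("cond_2", 2))
  expect_equal(lab[1:3], rep("interval", 3))
})
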