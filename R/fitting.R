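# System identification: minibatch NADAM on the regularized one-step loss,
# global rescaling, cross-validated one-step R^2, and linear baseline models.

#' Fitting configuration
#'
#' Hyperparameters of the minibatch gradient-descent fitter. Defaults mirror
#' the published training protocol (300 triplets per minibatch, 5000
#' minibatches, NADAM); the rank of the low-rank connectivity component
#' defaults to `min(72, n - 1)` so that small problems remain well posed.
#'
#' @param loss_cfg a [loss_config()].
#' @param rank_k rank of the low-rank component (`NULL` = `min(72, n - 1)`).
#' @param batch_size triplets per minibatch (default 300).
#' @param n_minibatches number of minibatch updates (default 5000).
#' @param learning_rate,beta1,beta2,epsilon NADAM hyperparameters.
#' @param seed integer seed making the fit fully reproducible.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(loss_cfg = loss_config(), rank_k = NULL,
                       batch_size = 300, n_minibatches = 5000,
                       learning_rate = 2e-3, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, seed = NULL) {
  if (batch_size < 1L || n_minibatches < 1L) {
    stopf("batch_size and n_minibatches must be >= 1")
  }
  structure(list(loss_cfg = loss_cfg, rank_k = rank_k,
                 batch_size = batch_size, n_minibatches = n_minibatches,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = seed),
            class = "fit_config")
}

# Concatenate all valid one-step transitions across runs: columns t of X pair
# with t+1 of the same run only. Returns matrices X, U, Xnext.
collect_triplets <- function(runs, designs) {
  Xs <- list(); Us <- list(); Xn <- list()
  for (i in seq_along(runs)) {
    d <- runs[[i]]$data
    T <- ncol(d)
    if (T < 2L) stopf("run %d has fewer than 2 volumes", i)
    Xs[[i]] <- d[, 1:(T - 1), drop = FALSE]
    Xn[[i]] <- d[, 2:T, drop = FALSE]
    Us[[i]] <- designs[[i]]$u[, 1:(T - 1), drop = FALSE]
  }
  list(X = do.call(cbind, Xs), U = do.call(cbind, Us),
       Xnext = do.call(cbind, Xn))
}

#' Sample a minibatch of one-step transition triplets
#'
#' Triplets `(x_t, u_t, x_{t+1})` are drawn uniformly over all valid
#' consecutive-volume pairs across all runs; a pair never spans a run
#' boundary.
#'
#' @param runs list of `neural_run` objects.
#' @param designs list of [build_design()] objects aligned with `runs`.
#' @param size number of triplets (default 300).
#' @param seed optional integer seed.
#' @return A list with matrices `x`, `u`, `x_next` (columns = triplets).
#' @export
sample_minibatch <- function(runs, designs, size = 300, seed = NULL) {
  tri <- collect_triplets(runs, designs)
  N <- ncol(tri$X)
  if (N < 1L) stopf("no valid transition pairs")
  idx <- with_seed(seed, sample.int(N, size, replace = TRUE))
  list(x = tri$X[, idx, drop = FALSE], u = tri$U[, idx, drop = FALSE],
       x_next = tri$Xnext[, idx, drop = FALSE])
}

#' Fit a MINDy-X model by minibatch NADAM
#'
#' Estimates `(Ws, W1, W2, alpha, D, B)` by stochastic gradient descent with
#' Nesterov-accelerated adaptive moments on the mean squared one-step
#' prediction error; the l1 penalties are applied by proximal soft
#' thresholding of `Ws`, `W1` and `W2` after each update (producing exact
#' zeros), and `alpha` and `D` are projected to be at least `1e-6`. Training
#' is followed by [global_rescale()] to compensate for regularization bias.
#'
#' @param runs list of `neural_run` objects (rest and/or task).
#' @param designs list of matching [build_design()] objects.
#' @param cfg a [fit_config()].
#' @return A list with elements `params` ([mindyx_params()]) and `report`
#'   (loss trace, per-parcel training noise estimate, rescale factors, seed).
#' @export
fit_mindyx <- function(runs, designs, cfg = fit_config()) {
  tri <- collect_triplets(runs, designs)
  n <- nrow(tri$X)
  m <- nrow(tri$U)
  N <- ncol(tri$X)
  k <- if (is.null(cfg$rank_k)) min(72L, n - 1L) else cfg$rank_k
  tr <- runs[[1]]$tr
  lcfg <- cfg$loss_cfg
  lr <- cfg$learning_rate; b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon

  with_seed(cfg$seed, {
    # initialization: small random weights, alpha near its typical fitted
    # value (~5), moderate decay
    th <- list(Ws = matrix(stats::rnorm(n * n, 0, 0.01), n, n),
               W1 = matrix(stats::rnorm(n * k, 0, 0.01), n, k),
               W2 = matrix(stats::rnorm(n * k, 0, 0.01), n, k),
               alpha = rep(5, n), D = rep(0.5, n),
               B = matrix(stats::rnorm(n * m, 0, 0.01), n, m))
    mom <- lapply(th, function(p) p * 0)
    vel <- lapply(th, function(p) p * 0)
    loss_trace <- numeric(cfg$n_minibatches)
    bsz <- cfg$batch_size

    for (it in seq_len(cfg$n_minibatches)) {
      idx <- sample.int(N, bsz, replace = TRUE)
      X <- tri$X[, idx, drop = FALSE]
      U <- tri$U[, idx, drop = FALSE]
      Xn <- tri$Xnext[, idx, drop = FALSE]

      W <- th$Ws + th$W1 %*% t(th$W2)
      Psi <- activation(X, th$alpha)
      E <- (X + W %*% Psi - th$D * X + th$B %*% U) - Xn  # n x bsz residuals
      loss_trace[it] <- 0.5 * sum(E^2) / bsz

      dW <- E %*% t(Psi) / bsz
      g <- list(Ws = dW,
                W1 = dW %*% th$W2,
                W2 = t(dW) %*% th$W1,
                alpha = rowMeans((t(W) %*% E) * activation_dalpha(X, th$alpha)),
                D = -rowMeans(E * X),
                B = E %*% t(U) / bsz)

      c1 <- 1 - b1^it; c2 <- 1 - b2^it
      for (nm in names(th)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
        upd <- (b1 * mom[[nm]] / c1 + (1 - b1) * g[[nm]] / c1) /
          (sqrt(vel[[nm]] / c2) + eps)
        th[[nm]] <- th[[nm]] - lr * upd
      }
      if (!all(is.finite(th$Ws))) stopf("non-finite loss/parameters at minibatch %d", it)

      # proximal l1 steps (exact zeros) and positivity projections
      th$Ws <- soft_threshold(th$Ws, lr * lcfg$lambda1)
      diag(th$Ws) <- soft_threshold(diag(th$Ws), lr * lcfg$lambda2)
      th$W1 <- soft_threshold(th$W1, lr * lcfg$lambda3)
      th$W2 <- soft_threshold(th$W2, lr * lcfg$lambda3)
      th$alpha <- pmax(th$alpha, 1e-6)
      th$D <- pmax(th$D, 1e-6)
    }

    params <- mindyx_params(th$Ws, th$W1, th$W2, th$alpha, th$D, th$B, tr = tr)
    rs <- global_rescale(params, runs, designs)
    params <- rs$params
    # per-parcel mean squared one-step prediction error (process-noise
    # estimate used for noise-driven simulation)
    pred <- mindyx_step(params, tri$X, tri$U)
    mspe <- rowMeans((tri$Xnext - pred)^2)
    list(params = params,
         report = list(loss_trace = loss_trace, rescale = rs$factors,
                       noise_sd = sqrt(mspe), seed = cfg$seed, rank_k = k))
  })
}

#' Global rescaling of fitted parameters
#'
#' Finds scalars `(pW, pD, pB)` minimizing the one-step squared error
#' `||x_{t+1} - (x_t + pW W psi(x_t) - pD D x_t + pB B u_t)||^2` over all
#' training transitions by ordinary least squares (no intercept), and factors
#' them into `W`, `D` and `B`. A term that is identically zero in the training
#' data (e.g. `B u` on all-rest data) keeps factor 1 and is flagged.
#'
#' @param params fitted [mindyx_params()].
#' @param runs,designs training data as in [fit_mindyx()].
#' @return A list with `params` (rescaled) and `factors`
#'   (`pW`, `pD`, `pB`, `flagged`).
#' @export
global_rescale <- function(params, runs, designs) {
  tri <- collect_triplets(runs, designs)
  W <- assemble_connectivity(params)
  r1 <- as.vector(W %*% activation(tri$X, params$alpha))
  r2 <- as.vector(-params$D * tri$X)
  r3 <- as.vector(params$B %*% tri$U)
  y <- as.vector(tri$Xnext - tri$X)
  Z <- cbind(pW = r1, pD = r2, pB = r3)
  active <- colSums(Z^2) > 1e-12 * length(y)
  p <- c(pW = 1, pD = 1, pB = 1)
  if (any(active)) {
    p[active] <- qr.solve(Z[, active, drop = FALSE], y)
  }
  params$Ws <- p["pW"] * params$Ws
  params$W1 <- p["pW"] * params$W1
  params$D <- p["pD"] * params$D
  params$B <- p["pB"] * params$B
  list(params = params,
       factors = list(pW = unname(p["pW"]), pD = unname(p["pD"]),
                      pB = unname(p["pB"]), flagged = names(p)[!active]))
}

# One-step prediction x_hat_{t+1} from states X (n x N) and inputs U (m x N),
# for a fitted MINDy-X model or a linear baseline.
predict_one_step <- function(model, X, U) {
  if (inherits(model, "mindyx_params")) return(mindyx_step(model, X, U))
  if (inherits(model, "baseline_params")) {
    switch(model$kind,
           brainwise_linear = model$A %*% X + model$B %*% U,
           decay_only = model$D * X + model$B %*% U,
           stopf("one-step prediction undefined for baseline kind '%s'",
                 model$kind))
  } else {
    stopf("unsupported model class")
  }
}

#' Cross-validated one-step R-squared
#'
#' Coefficient of determination `1 - SSE/SST` between the observed and
#' predicted next state on held-out runs, per parcel and pooled over all
#' parcels and volumes.
#'
#' @param model a [mindyx_params()] or a dynamical `baseline_params`
#'   (VARX/ARX).
#' @param runs,designs held-out test runs and their designs.
#' @return A list with `per_parcel` (length-n vector) and `overall` (scalar).
#' @export
crossval_r2 <- function(model, runs, designs) {
  tri <- collect_triplets(runs, designs)
  pred <- predict_one_step(model, tri$X, tri$U)
  res <- tri$Xnext - pred
  ctr <- tri$Xnext - rowMeans(tri$Xnext)
  sst <- rowSums(ctr^2)
  if (any(sst < 1e-12)) stopf("constant target series: R^2 undefined")
  list(per_parcel = 1 - rowSums(res^2) / sst,
       overall = 1 - sum(res^2) / sum(ctr^2))
}

#' Fit a linear baseline model
#'
#' Three baselines of decreasing complexity: `"brainwise_linear"` is the
#' vector autoregression VARX(1,1) `x_{t+1} = A x_t + B u_t + e` with an l1
#' penalty on `A` (fit by glmnet over a lambda grid); `"decay_only"` is the
#' scalar autoregression ARX(1,1) `x_{t+1} = D * x_t + B u_t + e` fit per
#' parcel; `"glm"` is the pure noise-process model `x_t = mu + beta u_t + e`.
#'
#' @param kind one of `"brainwise_linear"`, `"decay_only"`, `"glm"`.
#' @param runs,designs training data.
#' @param lambda_grid candidate l1 weights for the VARX fit.
#' @param lambda the l1 weight whose solution is returned (default 0.01).
#' @return An object of class `baseline_params`.
#' @export
fit_baseline <- function(kind = c("brainwise_linear", "decay_only", "glm"),
                         runs, designs,
                         lambda_grid = c(0, 0.001, 0.005, 0.01, 0.05),
                         lambda = 0.01) {
  kind <- match.arg(kind)
  tri <- collect_triplets(runs, designs)
  n <- nrow(tri$X); m <- nrow(tri$U)
  out <- switch(
    kind,
    brainwise_linear = {
      if (!length(lambda_grid)) stopf("empty lambda grid for VARX")
      Z <- t(rbind(tri$X, tri$U))
      grid <- sort(unique(c(lambda_grid, lambda)), decreasing = TRUE)
      A <- matrix(0, n, n); B <- matrix(0, n, m)
      pf <- c(rep(1, n), rep(0, m))  # task-input columns unpenalized
      for (i in seq_len(n)) {
        fit <- glmnet::glmnet(Z, tri$Xnext[i, ], family = "gaussian",
                              lambda = grid, intercept = FALSE,
                              standardize = FALSE, penalty.factor = pf)
        cf <- as.numeric(stats::coef(fit, s = lambda))[-1]  # drop intercept
        A[i, ] <- cf[1:n]
        B[i, ] <- cf[(n + 1):(n + m)]
      }
      list(A = A, B = B, lambda = lambda)
    },
    decay_only = {
      D <- numeric(n); B <- matrix(0, n, m)
      for (i in seq_len(n)) {
        Z <- cbind(tri$X[i, ], t(tri$U))
        cf <- unname(qr.solve(Z, tri$Xnext[i, ]))
        D[i] <- cf[1]
        B[i, ] <- cf[-1]
      }
      list(D = D, B = B)
    },
    glm = {
      # GLM models the state itself: use every volume with its own input
      Uall <- do.call(cbind, lapply(designs, function(d) d$u))
      Xfull <- do.call(cbind, lapply(runs, function(r) r$data))
      Z <- cbind(1, t(Uall))
      cf <- unname(qr.solve(Z, t(Xfull)))
      list(mu = as.numeric(cf[1, ]), beta = t(cf[-1, , drop = FALSE]))
    })
  structure(c(list(kind = kind), out), class = "baseline_params")
}
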