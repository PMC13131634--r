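# Model core: parameterization, activation function, one-step dynamics map and
# the regularized training loss of the nonlinear neural-mass network model.

#' Construct a MINDy-X parameter set
#'
#' Bundles all parameters of the discrete-time neural-mass network model
#' \deqn{x_{t+1} = x_t + W\psi_\alpha(x_t) - D \odot x_t + B u_t,}
#' where the effective connectivity decomposes as `W = Ws + W1 %*% t(W2)`
#' (sparse plus low-rank), `alpha` controls the curvature of the sigmoidal
#' activation of each region, `D` is the per-region decay rate and `B` couples
#' task regressors to regional activation. The activation scale `b = 20/3` is
#' fixed.
#'
#' @param Ws n x n sparse component of the effective connectivity.
#' @param W1,W2 n x k low-rank factors of the effective connectivity.
#' @param alpha length-n nonnegative activation curvature parameters.
#' @param D length-n nonnegative decay rates.
#' @param B n x m task-input weight matrix (m = number of task regressors).
#' @param tr repetition time in seconds associated with one model step.
#' @return An object of class `mindyx_params`.
#' @export
mindyx_params <- function(Ws, W1, W2, alpha, D, B, tr = 0.72) {
  Ws <- as.matrix(Ws); W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  B <- as.matrix(B)
  n <- nrow(Ws)
  if (ncol(Ws) != n) stopf("Ws must be square, got %d x %d", nrow(Ws), ncol(Ws))
  if (nrow(W1) != n || nrow(W2) != n) stopf("W1/W2 must have %d rows", n)
  if (ncol(W1) != ncol(W2)) stopf("W1 and W2 must share the rank dimension")
  if (length(alpha) != n || length(D) != n) {
    stopf("alpha and D must have length n = %d", n)
  }
  if (any(alpha < 0)) stopf("alpha must be nonnegative")
  if (any(D < 0)) stopf("D must be nonnegative")
  if (nrow(B) != n) stopf("B must have %d rows", n)
  structure(
    list(Ws = Ws, W1 = W1, W2 = W2,
         alpha = as.numeric(alpha), D = as.numeric(D), B = B,
         b = 20 / 3, n = n, k = ncol(W1), m = ncol(B), tr = tr),
    class = "mindyx_params")
}

#' @export
print.mindyx_params <- function(x, ...) {
  cat(sprintf("<mindyx_params> n = %d parcels, rank k = %d, %d task regressor(s), TR = %g s\n",
              x$n, x$k, x$m, x$tr))
  W <- assemble_connectivity(x)
  cat(sprintf("  |W| mean %.4f, Ws sparsity %.1f%%, alpha in [%.2f, %.2f], D in [%.2f, %.2f]\n",
              mean(abs(W)), 100 * mean(x$Ws == 0),
              min(x$alpha), max(x$alpha), min(x$D), max(x$D)))
  invisible(x)
}

#' Sigmoidal activation function
#'
#' Elementwise activation
#' \eqn{\psi_\alpha(x) = \sqrt{\alpha^2+(bx+0.5)^2} - \sqrt{\alpha^2+(bx-0.5)^2}}
#' with fixed scale `b = 20/3`. The function is odd, strictly increasing and
#' bounded in (-1, 1); small `alpha` gives a step-like response, large `alpha`
#' a flat one.
#'
#' @param x numeric vector (length n) or n x N matrix of states.
#' @param alpha length-n nonnegative curvature vector (recycled across columns
#'   when `x` is a matrix).
#' @param b activation scale; fixed default 20/3.
#' @return Activation values, same shape as `x`.
#' @export
activation <- function(x, alpha, b = 20 / 3) {
  if (any(alpha < 0)) stopf("alpha must be nonnegative")
  assert_finite(x, "x")
  a2 <- alpha^2  # recycles down rows for matrix x
  sqrt(a2 + (b * x + 0.5)^2) - sqrt(a2 + (b * x - 0.5)^2)
}

#' Slope of the activation function at the origin
#'
#' Closed form \eqn{\psi'_\alpha(0) = b/\sqrt{\alpha^2 + 0.25}}, strictly
#' decreasing in `alpha`; equals `2b` at `alpha = 0`.
#'
#' @inheritParams activation
#' @return Positive slopes, one per element of `alpha`.
#' @export
activation_slope_at_zero <- function(alpha, b = 20 / 3) {
  if (any(alpha < 0)) stopf("alpha must be nonnegative")
  b / sqrt(alpha^2 + 0.25)
}

# Derivative of psi with respect to alpha, used by the fitter.
activation_dalpha <- function(x, alpha, b = 20 / 3) {
  a2 <- alpha^2
  alpha * (1 / sqrt(a2 + (b * x + 0.5)^2) - 1 / sqrt(a2 + (b * x - 0.5)^2))
}

# Derivative of psi with respect to x (diagnostics / Jacobian checks).
activation_dx <- function(x, alpha, b = 20 / 3) {
  a2 <- alpha^2
  b * ((b * x + 0.5) / sqrt(a2 + (b * x + 0.5)^2) -
         (b * x - 0.5) / sqrt(a2 + (b * x - 0.5)^2))
}

#' Assemble the effective connectivity matrix
#'
#' @param params a [mindyx_params()] object.
#' @return The n x n effective connectivity `W = Ws + W1 %*% t(W2)`.
#' @export
assemble_connectivity <- function(params) {
  params$Ws + params$W1 %*% t(params$W2)
}

#' One-step dynamics map
#'
#' Applies the noise-free difference equation
#' `x + W psi_alpha(x) - D * x + B u` to one state or to a batch of states.
#'
#' @param params a [mindyx_params()] object.
#' @param x state vector (length n) or n x N matrix of states (one per column).
#' @param u task-input vector of length m, or m x N matrix aligned with the
#'   columns of `x`; `NULL` means zero input.
#' @param W optional precomputed effective connectivity (avoids reassembly in
#'   tight loops).
#' @return The next state(s), same shape as `x`.
#' @export
mindyx_step <- function(params, x, u = NULL, W = NULL) {
  assert_finite(x, "state")
  if (is.null(W)) W <- assemble_connectivity(params)
  psi <- activation(x, params$alpha, params$b)
  out <- x + W %*% psi - params$D * x
  if (!is.null(u)) {
    bu <- params$B %*% u
    if (is.matrix(x) && !is.matrix(u)) bu <- matrix(bu, params$n, ncol(x))
    out <- out + bu
  }
  if (is.matrix(x)) out else drop(out)
}

#' Regularization configuration for the training loss
#'
#' `lambda1` weights the l1 norm of `Ws`, `lambda2` an extra l1 penalty on the
#' diagonal of `Ws` (suppressing redundancy with the decay term), and `lambda3`
#' the l1 norms of the low-rank factors `W1` and `W2`. Defaults follow the
#' published calibration (0.075, 0.2, 0.05).
#'
#' @param lambda1,lambda2,lambda3 nonnegative penalty weights.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda1 = 0.075, lambda2 = 0.2, lambda3 = 0.05) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) stopf("penalty weights must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_config")
}

#' Training loss on a batch of one-step transitions
#'
#' Mean over the batch of `0.5 * ||x_next - step(params, x, u)||^2`, plus the
#' l1 penalties of [loss_config()] added once per batch. The squared-error term
#' is averaged (not summed) over triplets so the loss scale is stable across
#' batch sizes.
#'
#' @param params a [mindyx_params()] object.
#' @param batch a list with matrices `x` (n x N), `u` (m x N or NULL) and
#'   `x_next` (n x N) holding N one-step transition triplets.
#' @param cfg a [loss_config()].
#' @return Nonnegative scalar loss.
#' @export
mindyx_loss <- function(params, batch, cfg = loss_config()) {
  X <- as.matrix(batch$x); Xn <- as.matrix(batch$x_next)
  N <- ncol(X)
  if (N < 1L) stopf("empty batch")
  U <- if (is.null(batch$u)) NULL else as.matrix(batch$u)
  pred <- mindyx_step(params, X, U)
  err <- 0.5 * sum((Xn - pred)^2) / N
  pen <- cfg$lambda1 * sum(abs(params$Ws)) +
    cfg$lambda2 * sum(abs(diag(params$Ws))) +
    cfg$lambda3 * (sum(abs(params$W1)) + sum(abs(params$W2)))
  err + pen
}
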