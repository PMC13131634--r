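# Shared fixtures: small hand-built models and independent oracles.

b_scale <- 20 / 3

# Minimal parameter set with explicit matrices (rank-1 zero low-rank part).
toy_params <- function(W, alpha, D, B = NULL, tr = 0.72) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (is.null(B)) B <- matrix(0, n, 1)
  mindyx_params(W, matrix(0, n, 1), matrix(0, n, 1), alpha, D, as.matrix(B),
                tr = tr)
}

# 1D model with a bistable input-output curve: w * psi_5(x) = d * x has two
# stable nonzero roots for w * psi'(0) > d.
bistable_1d <- function(w = 0.6, d = 0.5, alpha = 5, B = 1) {
  toy_params(matrix(w, 1, 1), alpha, d, matrix(B, 1, 1))
}

# 2D rotational model: linearization at origin is an unstable spiral with
# rotation `theta` per step and radial growth `r`; activation saturation
# bounds the orbit into a limit cycle.
rotational_2d <- function(theta = 2 * pi / 40, r = 1.15, d = 0.5, alpha = 5) {
  g <- activation_slope_at_zero(alpha)
  A <- (r * cos(theta) - (1 - d)) / g
  C <- r * sin(theta) / g
  toy_params(matrix(c(A, C, -C, A), 2, 2), c(alpha, alpha), c(d, d))
}

# Globally contractive random model (weak coupling, strong decay).
contractive_model <- function(n = 5, seed = 1) {
  set.seed(seed)
  W <- matrix(rnorm(n * n, 0, 0.02 / n), n, n)
  toy_params(W, runif(n, 4, 6), runif(n, 0.4, 0.8), matrix(0, n, 1))
}

# Independent 1D oracle: all roots of w*psi_alpha(x) - d*x + B*u on a dense
# grid with uniroot refinement, split by slope-based stability of the map
# x -> x + w psi(x) - d x + B u.
roots_1d <- function(w, d, alpha, Bu = 0, lim = 10) {
  g <- function(x) w * activation(x, alpha) - d * x + Bu
  xs <- seq(-lim, lim, by = 1e-3)
  v <- g(xs)
  sgn <- sign(v)
  hits <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(hits, function(i) {
    uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-13)$root
  }, numeric(1))
  exact <- xs[v == 0]
  roots <- sort(unique(c(roots, exact)))
  dpsi <- function(x, h = 1e-7) (activation(x + h, alpha) - activation(x - h, alpha)) / (2 * h)
  stable <- abs(1 + w * dpsi(roots) - d) < 1
  list(all = roots, stable = roots[stable], unstable = roots[!stable])
}

# Small synthetic session at reduced length for fast tests.
quick_cfg <- function(seed, regime = "multistable", ...) {
  synth_config(regime = regime, rest_T = 400, task_T = 300,
               n_blocks_per_condition = 3, seed = seed, ...)
}
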