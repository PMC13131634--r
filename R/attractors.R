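# Attractor-landscape identification: equilibrium and limit-cycle detection
# from multi-start noise-free simulation, deduplication, topology taxonomy and
# rest-to-task bifurcation flagging.

#' Detect a stable equilibrium at the end of a trajectory
#'
#' A trajectory is considered converged to a fixed point if every per-parcel
#' step change over the last `window` steps is below `tol`.
#'
#' @param traj a `trajectory`.
#' @param tol convergence tolerance on per-parcel step changes (default 1e-6).
#' @param window number of trailing steps checked (default 10).
#' @return The final state (length-n vector) or `NULL` if not converged.
#' @export
detect_equilibrium <- function(traj, tol = 1e-6, window = 10) {
  S <- traj$states
  T <- ncol(S)
  if (T <= window) stopf("trajectory shorter than the detection window")
  tail_diff <- abs(S[, (T - window + 1):T, drop = FALSE] -
                     S[, (T - window):(T - 1), drop = FALSE])
  if (all(tail_diff < tol)) S[, T] else NULL
}

#' Detect a limit cycle at the end of a trajectory
#'
#' A non-equilibrium trajectory is classified as a limit cycle if it entered
#' and later left the Euclidean ball of the given radius around its final
#' state at least once. The period is measured as the interval between the
#' last two entries into that neighborhood (for a closed orbit this is
#' exactly one revolution) and the orbit is the corresponding state segment.
#'
#' @param traj a `trajectory` (that failed the equilibrium criterion).
#' @param radius detection neighborhood radius (default 0.5).
#' @return A list with `orbit` (n x P matrix) and `period` (P), or `NULL`.
#' @export
detect_limit_cycle <- function(traj, radius = 0.5) {
  S <- traj$states
  T <- ncol(S)
  d <- sqrt(colSums((S - S[, T])^2))
  inside <- d < radius
  # was the neighborhood of the final state entered and then left?
  exited <- any(!inside[which(inside)[1]:T])
  if (!any(inside[-T]) || is.na(exited) || !exited) return(NULL)
  entries <- which(inside & !c(FALSE, inside[-T]))  # first index of each visit
  if (length(entries) < 2L) return(NULL)
  s_prev <- entries[length(entries) - 1L]
  s_last <- entries[length(entries)]
  period <- s_last - s_prev
  if (period < 2L) return(NULL)
  list(orbit = S[, s_prev:(s_last - 1L), drop = FALSE], period = period)
}

#' Group equilibria by single-linkage clustering
#'
#' Transitive grouping at a Euclidean distance threshold; each group is
#' represented by its centroid, with `basin_count` the number of grouped
#' trajectories.
#'
#' @param points list of equilibrium state vectors (or a matrix with one row
#'   per equilibrium).
#' @param threshold linkage distance threshold (default 0.1).
#' @return List of equilibria, each a list with `x_star` and `basin_count`.
#' @export
cluster_equilibria <- function(points, threshold = 0.1) {
  P <- if (is.matrix(points)) points else do.call(rbind, points)
  if (is.null(P) || nrow(P) == 0L) stopf("no equilibria to cluster")
  if (nrow(P) == 1L) {
    return(list(list(x_star = as.numeric(P[1, ]), basin_count = 1L)))
  }
  hc <- stats::hclust(stats::dist(P), method = "single")
  grp <- stats::cutree(hc, h = threshold)
  lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    list(x_star = colMeans(P[sel, , drop = FALSE]), basin_count = sum(sel))
  })
}

# Symmetric mean minimum point-to-orbit Euclidean distance between two cycles.
orbit_distance <- function(o1, o2) {
  cross <- function(a, b) {
    mean(apply(a, 2, function(p) sqrt(min(colSums((b - p)^2)))))
  }
  (cross(o1, o2) + cross(o2, o1)) / 2
}

#' Identify the attractor set of a model under constant input
#'
#' Simulates the noise-free dynamics from `n_init` standard-normal initial
#' conditions for `steps` steps each. Each trajectory is classified as a
#' stable equilibrium, then (if not) as a limit cycle; unresolved trajectories
#' are extended by doubling the step count up to `max_steps`. Equilibria are
#' grouped at the Euclidean threshold 0.1 and limit cycles deduplicated by
#' symmetric mean minimum point-to-orbit distance below the detection radius.
#' If any trajectory is still unresolved (or diverged) at `max_steps`, the
#' result carries `unclassified_flag = TRUE` rather than being dropped.
#'
#' @param params a [mindyx_params()].
#' @param u_const constant input vector (`NULL` = rest, zero input).
#' @param n_init number of random initial conditions (default 120).
#' @param steps initial simulation length (default 1600).
#' @param max_steps upper bound after doublings (default 25600).
#' @param tol,window equilibrium criterion, see [detect_equilibrium()].
#' @param radius limit-cycle neighborhood radius, see [detect_limit_cycle()].
#' @param cluster_threshold equilibrium grouping threshold (default 0.1).
#' @param seed optional integer seed.
#' @return An object of class `attractor_set` with fields `equilibria`,
#'   `cycles`, `input`, `topology`, `unclassified_flag`, `n_diverged`.
#' @export
find_attractors <- function(params, u_const = NULL, n_init = 120,
                            steps = 1600, max_steps = 25600, tol = 1e-6,
                            window = 10, radius = 0.5,
                            cluster_threshold = 0.1, seed = NULL) {
  n <- params$n
  eq_states <- list()
  cycles <- list()
  unresolved <- 0L
  diverged <- 0L
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      x0 <- stats::rnorm(n)
      len <- steps
      traj <- simulate_noise_free(params, u_const, x0, len)
      repeat {
        if (traj$diverged) { diverged <- diverged + 1L; break }
        eq <- detect_equilibrium(traj, tol = tol, window = window)
        if (!is.null(eq)) { eq_states[[length(eq_states) + 1L]] <- eq; break }
        lc <- detect_limit_cycle(traj, radius = radius)
        if (!is.null(lc)) { cycles[[length(cycles) + 1L]] <- lc; break }
        if (2L * len > max_steps) { unresolved <- unresolved + 1L; break }
        # extend from the current endpoint, doubling the total length
        ext <- simulate_noise_free(params, u_const,
                                   traj$states[, ncol(traj$states)], len)
        traj <- new_trajectory(cbind(traj$states, ext$states[, -1L, drop = FALSE]),
                               traj$input, diverged = ext$diverged)
        len <- 2L * len
      }
    }
  })
  equilibria <- if (length(eq_states)) {
    cluster_equilibria(eq_states, threshold = cluster_threshold)
  } else list()
  # deduplicate limit cycles
  uniq <- list()
  for (lc in cycles) {
    dup <- FALSE
    for (u in uniq) {
      if (orbit_distance(lc$orbit, u$orbit) < radius) { dup <- TRUE; break }
    }
    if (!dup) uniq[[length(uniq) + 1L]] <- lc
  }
  aset <- structure(
    list(equilibria = equilibria, cycles = uniq,
         input = if (is.null(u_const)) rep(0, params$m) else u_const,
         topology = NA_character_,
         unclassified_flag = (unresolved + diverged) > 0L,
         n_diverged = diverged),
    class = "attractor_set")
  if (length(equilibria) + length(uniq) > 0L) {
    aset$topology <- classify_topology(aset)
  }
  aset
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor_set> %d FP, %d LC -> %s%s\n",
              length(x$equilibria), length(x$cycles),
              if (is.na(x$topology)) "unclassified" else x$topology,
              if (x$unclassified_flag) " [flagged]" else ""))
  invisible(x)
}

#' Classify the topology of an attractor set
#'
#' `"oscillatory"` if at least one stable limit cycle is present (regardless
#' of equilibria), else `"multistable"` with two or more stable equilibria,
#' else `"monostable"`.
#'
#' @param attrs an `attractor_set`.
#' @return One of `"monostable"`, `"multistable"`, `"oscillatory"`.
#' @export
classify_topology <- function(attrs) {
  n_eq <- length(attrs$equilibria)
  n_lc <- length(attrs$cycles)
  if (n_eq + n_lc == 0L) stopf("empty attractor set: no topology defined")
  if (n_lc >= 1L) "oscillatory" else if (n_eq >= 2L) "multistable" else "monostable"
}

#' Rest-to-task bifurcation flag
#'
#' `TRUE` iff the topology class differs between the two conditions of the
#' same model (e.g. multistable at rest, monostable under task input).
#'
#' @param type_rest,type_task topology labels from [classify_topology()].
#' @return Logical.
#' @export
bifurcation_flag <- function(type_rest, type_task) {
  valid <- c("monostable", "multistable", "oscillatory")
  if (!(type_rest %in% valid) || !(type_task %in% valid)) {
    stopf("topology labels must be one of: %s", paste(valid, collapse = ", "))
  }
  type_rest != type_task
}

#' Re-verify equilibria by one extra model step
#'
#' @param params a [mindyx_params()].
#' @param attrs an `attractor_set`.
#' @param tol residual tolerance.
#' @return Logical vector, one entry per equilibrium: does
#'   `||step(x*) - x*||_inf` fall below `tol`?
#' @export
verify_equilibria <- function(params, attrs, tol = 1e-4) {
  vapply(attrs$equilibria, function(eq) {
    x1 <- mindyx_step(params, eq$x_star, attrs$input)
    max(abs(x1 - eq$x_star)) < tol
  }, logical(1))
}
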