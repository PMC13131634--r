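# Population geometry: spherical K-means over pooled equilibria, selection of
# K by clustering instability, per-volume motif labeling, occupancy and
# distance features.

unit_rows <- function(P) {
  nrm <- sqrt(rowSums(P^2))
  if (any(nrm < 1e-12)) stopf("zero-norm point(s) cannot be clustered by cosine distance")
  P / nrm
}

# Assign unit rows of Pn to the nearest (highest cosine) unit centroid row;
# ties broken by lowest index.
cosine_assign <- function(Pn, Cn) {
  sim <- Pn %*% t(Cn)
  apply(sim, 1, which.max)
}

#' Spherical K-means (cosine distance)
#'
#' K-means on the unit sphere: points are unit-normalized, assignment is by
#' highest cosine similarity, and each centroid is the renormalized mean of
#' its cluster. The best of `restarts` random initializations (by total
#' within-cluster cosine dissimilarity) is returned. Assignments are
#' invariant to positive rescaling of any point.
#'
#' @param points P x n matrix, one point per row; no zero-norm rows.
#' @param K number of clusters (1 <= K <= P).
#' @param restarts number of random initializations (default 10).
#' @param iter_max maximum Lloyd iterations per restart.
#' @param seed optional integer seed.
#' @return A list with `assignments` (length P), `centroids` (K x n, unit
#'   rows) and `objective` (sum of 1 - cosine to own centroid).
#' @export
kmeans_cosine <- function(points, K, restarts = 10, iter_max = 100,
                          seed = NULL) {
  P <- as.matrix(points)
  if (K < 1L || K > nrow(P)) stopf("need 1 <= K <= number of points")
  Pn <- unit_rows(P)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      Cn <- Pn[sample.int(nrow(Pn), K), , drop = FALSE]
      asg <- rep(0L, nrow(Pn))
      for (it in seq_len(iter_max)) {
        new_asg <- cosine_assign(Pn, Cn)
        if (identical(new_asg, asg)) break
        asg <- new_asg
        for (kk in seq_len(K)) {
          sel <- asg == kk
          if (!any(sel)) {
            # re-seed an empty cluster at the point farthest from its centroid
            far <- which.min(rowSums(Pn * Cn[asg, , drop = FALSE]))
            Cn[kk, ] <- Pn[far, ]
          } else {
            v <- colMeans(Pn[sel, , drop = FALSE])
            Cn[kk, ] <- v / sqrt(sum(v^2))
          }
        }
      }
      obj <- sum(1 - rowSums(Pn * Cn[asg, , drop = FALSE]))
      if (is.null(best) || obj < best$objective) {
        best <- list(assignments = asg, centroids = Cn, objective = obj)
      }
    }
    best
  })
}

# Maximum achievable label agreement between two K-clusterings of the same
# points, over all one-to-one label permutations (assignment problem solved
# by dynamic programming over bitmasks; exact for K <= ~15).
max_label_agreement <- function(l1, l2, K) {
  Cmat <- unclass(table(factor(l1, levels = seq_len(K)),
                        factor(l2, levels = seq_len(K))))
  nmask <- bitwShiftL(1L, K)
  masks <- 0:(nmask - 1L)
  dp <- rep(-Inf, nmask)
  dp[1L] <- 0
  for (i in seq_len(K)) {
    ndp <- rep(-Inf, nmask)
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      free <- bitwAnd(masks, bit) == 0L
      cand <- dp[masks[free] + 1L] + Cmat[i, j]
      dst <- masks[free] + bit + 1L
      upd <- cand > ndp[dst]
      ndp[dst[upd]] <- cand[upd]
    }
    dp <- ndp
  }
  dp[nmask]
}

#' Select the number of motifs by clustering instability
#'
#' For each candidate K, the points are repeatedly split into random halves,
#' each half is clustered, all points are assigned to both centroid sets, the
#' two labelings are aligned by optimal (maximum-agreement) label matching,
#' and the instability is the mean disagreement. The selected K is the
#' smallest local minimum of the instability curve (falling back to the
#' global minimum when no interior local minimum exists).
#'
#' @param points P x n matrix of points (rows).
#' @param k_range candidate cluster counts (default 2:10).
#' @param n_resamples random half-splits per K (default 50).
#' @param restarts K-means restarts per half.
#' @param seed optional integer seed.
#' @return A list with `K_opt` and the named `instability` curve.
#' @export
select_k_by_instability <- function(points, k_range = 2:10, n_resamples = 50,
                                    restarts = 5, seed = NULL) {
  P <- as.matrix(points)
  np <- nrow(P)
  if (np < 2L * max(k_range)) stopf("too few points to split for K up to %d", max(k_range))
  Pn <- unit_rows(P)
  with_seed(seed, {
    curve <- vapply(k_range, function(K) {
      dis <- vapply(seq_len(n_resamples), function(r) {
        idx <- sample.int(np, np %/% 2L)
        f1 <- kmeans_cosine(Pn[idx, , drop = FALSE], K, restarts = restarts)
        f2 <- kmeans_cosine(Pn[-idx, , drop = FALSE], K, restarts = restarts)
        l1 <- cosine_assign(Pn, f1$centroids)
        l2 <- cosine_assign(Pn, f2$centroids)
        1 - max_label_agreement(l1, l2, K) / np
      }, numeric(1))
      mean(dis)
    }, numeric(1))
    names(curve) <- as.character(k_range)
    nk <- length(k_range)
    # non-strict on the left so that a tie plateau of equally stable
    # solutions resolves to its largest K (finer structure, same stability)
    local_min <- which(vapply(seq_len(nk), function(i) {
      i > 1L && i < nk && curve[i] <= curve[i - 1L] && curve[i] < curve[i + 1L]
    }, logical(1)))
    K_opt <- if (length(local_min)) k_range[local_min[1L]] else k_range[which.min(curve)]
    list(K_opt = K_opt, instability = curve)
  })
}

#' Construct a motif set
#'
#' @param centroids K x n matrix of motif centroids (one per row).
#' @param labels motif names; default `motif_1..K`. Supplying a parcel-to-
#'   network map via [name_motifs()] can replace these with network names.
#' @param condition condition tag (e.g. `"rest"`, `"cond_2"`).
#' @return An object of class `motif_set`.
#' @export
motif_set <- function(centroids, labels = NULL, condition = "rest") {
  centroids <- as.matrix(centroids)
  K <- nrow(centroids)
  if (is.null(labels)) labels <- paste0("motif_", seq_len(K))
  if (length(labels) != K) stopf("need one label per centroid")
  assert_finite(centroids, "centroids")
  structure(list(centroids = centroids, labels = labels,
                 condition = condition, K = K), class = "motif_set")
}

#' Name motifs by dominant network activation
#'
#' Renames each motif after the network with the largest mean absolute
#' centroid activation, given a parcel-to-network map.
#'
#' @param motifs a [motif_set()].
#' @param network_map character vector of length n assigning each parcel to a
#'   network name (e.g. DMN/FPN/TPN/VIS/SAL).
#' @return The motif set with updated labels (duplicates suffixed).
#' @export
name_motifs <- function(motifs, network_map) {
  if (length(network_map) != ncol(motifs$centroids)) {
    stopf("network_map must have one entry per parcel")
  }
  labs <- apply(motifs$centroids, 1, function(cen) {
    means <- tapply(abs(cen), network_map, mean)
    names(means)[which.max(means)]
  })
  motifs$labels <- make.unique(labs, sep = "_")
  motifs
}

#' Label volumes by nearest motif (cosine similarity)
#'
#' Each volume is assigned the motif with the highest cosine similarity; ties
#' break to the lowest motif index and zero-norm volumes get `NA`.
#'
#' @param states n x T matrix of neural states.
#' @param motifs a [motif_set()].
#' @return Integer vector of motif indices (length T, `NA` for zero volumes).
#' @export
label_volumes <- function(states, motifs) {
  X <- t(as.matrix(states))
  nrm <- sqrt(rowSums(X^2))
  lab <- rep(NA_integer_, nrow(X))
  ok <- nrm >= 1e-12
  if (any(ok)) {
    Cn <- unit_rows(motifs$centroids)
    lab[ok] <- cosine_assign(X[ok, , drop = FALSE] / nrm[ok], Cn)
  }
  lab
}

#' Motif occupancy and mean distances for one subject
#'
#' Occupancy is the fraction of (nonzero) volumes labeled by each motif;
#' `mean_dist[k]` is the mean Euclidean distance between every volume and
#' centroid k (all volumes, not only those assigned to k).
#'
#' @param states n x T matrix of neural states (e.g. deconvolved data during
#'   one condition).
#' @param motifs a [motif_set()].
#' @param volumes optional volume subset (e.g. in-block volumes only).
#' @return A list with named vectors `occupancy` (sums to 1) and `mean_dist`.
#' @export
occupancy_and_distances <- function(states, motifs, volumes = NULL) {
  X <- as.matrix(states)
  if (!is.null(volumes)) X <- X[, volumes, drop = FALSE]
  if (ncol(X) < 1L) stopf("need at least one volume")
  lab <- label_volumes(X, motifs)
  K <- motifs$K
  occ <- tabulate(lab[!is.na(lab)], nbins = K) / sum(!is.na(lab))
  md <- vapply(seq_len(K), function(kk) {
    mean(sqrt(colSums((X - motifs$centroids[kk, ])^2)))
  }, numeric(1))
  names(occ) <- names(md) <- motifs$labels
  list(occupancy = occ, mean_dist = md)
}

#' Build the per-subject dynamical feature table
#'
#' One row per subject: the rest-to-task bifurcation indicator, motif
#' occupancy during the task condition (one redundant occupancy column is
#' dropped since occupancies sum to one), and mean distances to all task
#' motifs; optionally the distances to rest-condition motifs as well.
#'
#' @param topology_rest,topology_task per-subject topology labels from
#'   [classify_topology()].
#' @param task_states list of n x T matrices (task-condition neural states,
#'   one per subject).
#' @param task_motifs the task-condition [motif_set()].
#' @param rest_states,rest_motifs optional rest-condition analogues; when
#'   given, rest-motif distance columns are appended.
#' @param drop_occupancy label of the occupancy column to drop (default the
#'   first motif).
#' @return A data frame with columns `Bifurc`, `occ_*` (K - 1 of them),
#'   `dist_*`, and optionally `rest_dist_*`.
#' @export
build_feature_table <- function(topology_rest, topology_task, task_states,
                                task_motifs, rest_states = NULL,
                                rest_motifs = NULL,
                                drop_occupancy = task_motifs$labels[1]) {
  S <- length(task_states)
  if (length(topology_rest) != S || length(topology_task) != S) {
    stopf("topology vectors must match the number of subjects")
  }
  bif <- as.integer(mapply(bifurcation_flag, topology_rest, topology_task))
  keep <- setdiff(task_motifs$labels, drop_occupancy)
  rows <- lapply(seq_len(S), function(i) {
    od <- occupancy_and_distances(task_states[[i]], task_motifs)
    row <- c(Bifurc = bif[i],
             stats::setNames(od$occupancy[keep], paste0("occ_", keep)),
             stats::setNames(od$mean_dist, paste0("dist_", task_motifs$labels)))
    if (!is.null(rest_states)) {
      if (is.null(rest_motifs)) stopf("rest_motifs required with rest_states")
      rd <- occupancy_and_distances(rest_states[[i]], rest_motifs)
      row <- c(row, stats::setNames(rd$mean_dist,
                                    paste0("rest_dist_", rest_motifs$labels)))
    }
    row
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
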