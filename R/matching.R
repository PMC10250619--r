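#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the
#' Jonker–Volgenant-style shortest augmenting path formulation with dual
#' potentials, O(n^2 m). Every row is assigned when `nrow(cost) <=
#' ncol(cost)`; otherwise every column.
#'
#' @param cost numeric cost matrix (finite).
#' @return Integer vector `a` of length `min(dim(cost))` mapping each row
#'   (resp. column, if columns are fewer) of the smaller dimension to its
#'   partner index, with attribute `"transposed"` indicating whether the
#'   matrix was transposed internally. Use [match_centroids()] for the
#'   point-set interface.
#' @keywords internal
solve_assignment <- function(cost) {
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(structure(integer(0), transposed = transposed))
  INF <- .Machine$double.xmax / 4
  # index 1 in p/v/way/minv/used stands for the virtual column 0
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(m + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in 2L:(m + 1L)) if (p[j] > 0L) a[p[j]] <- j - 1L
  structure(a, transposed = transposed)
}

#' Optimally match two point sets by Euclidean distance
#'
#' Computes the one-to-one assignment of size `min(|pred|, |truth|)` that
#' minimizes the total Euclidean distance between matched points (bipartite
#' graph matching), as used to map detected cell centroids onto ground-truth
#' annotations and to score vesicle detections.
#'
#' @param pred,truth [point_set()] objects.
#' @return A list with `pairs` (data.frame `pred_index`, `truth_index`,
#'   `distance`), `unmatched_pred`, `unmatched_truth` (integer indices) and
#'   `total_cost`.
#' @examples
#' p <- point_set(rbind(c(0, 0)))
#' t <- point_set(rbind(c(0, 1), c(5, 5)))
#' match_centroids(p, t)$pairs
#' @export
match_centroids <- function(pred, truth) {
  np <- n_points(pred); nt <- n_points(truth)
  empty <- data.frame(pred_index = integer(0), truth_index = integer(0),
                      distance = numeric(0))
  if (np == 0L || nt == 0L)
    return(list(pairs = empty, unmatched_pred = seq_len(np),
                unmatched_truth = seq_len(nt), total_cost = 0))
  d2 <- outer(pred$points[, 1L], truth$points[, 1L], "-")^2 +
        outer(pred$points[, 2L], truth$points[, 2L], "-")^2
  cost <- sqrt(d2)
  a <- solve_assignment(cost)
  if (attr(a, "transposed")) {
    truth_index <- seq_len(nt); pred_index <- as.integer(a)
  } else {
    pred_index <- seq_len(np); truth_index <- as.integer(a)
  }
  dist <- cost[cbind(pred_index, truth_index)]
  pairs <- data.frame(pred_index = pred_index, truth_index = truth_index,
                      distance = dist)
  list(pairs = pairs,
       unmatched_pred = setdiff(seq_len(np), pred_index),
       unmatched_truth = setdiff(seq_len(nt), truth_index),
       total_cost = sum(dist))
}
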