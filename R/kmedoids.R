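#' Partitioning around medoids for donor grouping
#'
#' k-medoids clustering with Euclidean distance on the z-scored selected
#' factors. Very small problems (n <= 10) are solved exactly by enumerating
#' every medoid subset (ties broken towards the lexicographically smallest
#' subset), which sidesteps the swap-neighbourhood local optima that any
#' descent heuristic can hit on adversarial tiny instances; larger problems
#' use classical deterministic PAM (BUILD + SWAP) via `cluster::pam`.
#' Assignments are recomputed as nearest-medoid with ties broken towards
#' the lowest medoid index, and the cost is the sum over donors of the
#' distance to their medoid, so the result is fully determined by the input
#' row order.
#'
#' @param x numeric matrix or data.frame, donors in rows (rownames used as
#'   donor ids).
#' @param k number of clusters, 1 <= k <= n.
#' @return object of class `pam_result`: `k`, `assignments` (named integer
#'   vector in 1..k), `medoids` (donor ids), `cost`, `metric`.
#' @export
pam_cluster <- function(x, k) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n")
  if (anyNA(x)) stop("no missing values allowed in clustering input")
  if (k == n) {
    med_idx <- seq_len(n)
  } else if (n <= 10) {                 # exact enumeration for tiny inputs
    d <- as.matrix(dist(x))
    combs <- utils::combn(n, k)
    costs <- apply(combs, 2L, function(m)
      sum(apply(d[, m, drop = FALSE], 1L, min)))
    med_idx <- combs[, which.min(costs)]
  } else {
    fit <- cluster::pam(x, k, metric = "euclidean", keep.diss = FALSE,
                        keep.data = FALSE, pamonce = FALSE)
    med_idx <- fit$id.med
  }
  dmat <- as.matrix(dist(x))[, med_idx, drop = FALSE]
  assignments <- apply(dmat, 1L, which.min)      # ties -> lowest medoid index
  cost <- sum(dmat[cbind(seq_len(n), assignments)])
  structure(list(k = as.integer(k),
                 assignments = setNames(as.integer(assignments), rownames(x)),
                 medoids = rownames(x)[med_idx], cost = cost,
                 metric = "euclidean"),
            class = "pam_result")
}

#' @export
print.pam_result <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, cost = %.4g, medoids: %s\n",
              x$k, x$cost, paste(x$medoids, collapse = ", ")))
  invisible(x)
}

#' Elbow selection of the cluster number
#'
#' Computes the PAM cost for k = 1..k_max and selects the k that maximises
#' the discrete second difference cost(k-1) - 2 cost(k) + cost(k+1), the
#' sharpest bend of the cost curve; ties go to the smallest k. The full
#' curve is returned for plotting. Identical points (zero-cost everywhere)
#' degenerate to k = 1 with a warning.
#'
#' @param x numeric matrix or data.frame, donors in rows.
#' @param k_max largest k evaluated (default 8; needs n > k_max, k_max >= 3).
#' @return list with `k` (selected), `curve` (data.frame k, cost).
#' @export
elbow_select <- function(x, k_max = 8L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k_max < 3) stop("k_max must be >= 3")
  if (n <= k_max) stop("need more donors than k_max")
  cost <- vapply(seq_len(k_max), function(k) pam_cluster(x, k)$cost, 0)
  curve <- data.frame(k = seq_len(k_max), cost = cost)
  if (cost[1] <= 1e-12) {
    warning("all points identical: no elbow, returning k = 1")
    return(list(k = 1L, curve = curve))
  }
  ks <- 2:(k_max - 1)
  d2 <- cost[ks - 1] - 2 * cost[ks] + cost[ks + 1]
  list(k = as.integer(ks[which.max(d2)]), curve = curve)
}
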