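# DBSCAN over strand-break positions, plus an independent brute-force oracle.

# Neighbor lists under strict distance < eps. The squared-distance matrix is
# evaluated in row blocks (bounded scratch memory) and thresholded, so the
# result is the exact full pairwise scan, vectorised.
eps_neighbors <- function(x, y, z, eps) {
  n <- length(x)
  if (n < 2) return(rep(list(integer(0)), n))
  p <- cbind(x, y, z)
  sq <- rowSums(p^2)
  eps2 <- eps^2
  block <- max(1L, as.integer(2e7 %/% n))
  is <- vector("list", 0)
  js <- vector("list", 0)
  for (start in seq.int(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(p[rows, , drop = FALSE], p)
    hits <- which(d2 < eps2)
    if (length(hits)) {
      ri <- rows[(hits - 1L) %% length(rows) + 1L]
      cj <- as.integer((hits - 1L) %/% length(rows) + 1L)
      keep <- ri != cj
      is <- c(is, list(ri[keep]))
      js <- c(js, list(cj[keep]))
    }
  }
  all_j <- as.integer(unlist(js))
  all_i <- as.integer(unlist(is))
  unname(split(all_j, factor(all_i, levels = seq_len(n))))
}

# DBSCAN partition. MinPts counts the point itself (a point is core when at
# least MinPts points, itself included, lie strictly within eps). With
# MinPts = 2 every non-noise point is core and clusters are exactly the
# connected components of the eps-proximity graph, so the partition does not
# depend on input order. Border points (possible only for MinPts > 2) are
# assigned to the candidate cluster containing the core neighbour with the
# smallest index, a deterministic tie-break.
dbscan_labels <- function(x, y, z, eps, min_pts = 2) {
  n <- length(x)
  labels <- integer(n)                 # 0 = noise
  if (n == 0) return(labels)
  nb <- eps_neighbors(x, y, z, eps)
  is_core <- vapply(nb, length, 0L) + 1L >= min_pts
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cluster
        if (is_core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster strand breaks with DBSCAN
#'
#' Groups strand breaks whose pairwise 3-D distance is strictly below `eps`
#' (default 3.4 nm, the ~10 base-pair span) using DBSCAN with `MinPts = 2`.
#' At `MinPts = 2` the clusters are exactly the connected components of the
#' eps-proximity graph and noise points are the isolated breaks; the partition
#' is independent of input order. Clusters are returned sorted by the minimum
#' member coordinate for determinism.
#'
#' @param breaks A strand-break tibble with `x_nm`, `y_nm`, `z_nm`, `strand`
#'   (0/1), as produced by [sample_breaks()].
#' @param params A [damage_parameters()].
#' @return List with `clusters` (tibble: `cluster_id`, `size`, `n_strand0`,
#'   `n_strand1`, `both_strands`, `max_span_nm`, `members` list-column of row
#'   indices into `breaks`), `isolated` (tibble of noise breaks), and
#'   `assignment` (integer vector, 0 for isolated).
#' @export
cluster_breaks <- function(breaks, params = damage_parameters()) {
  breaks <- as_tibble(breaks)
  labels <- dbscan_labels(breaks$x_nm, breaks$y_nm, breaks$z_nm,
                          eps = params$eps_nm, min_pts = params$min_pts)
  partition_from_labels(breaks, labels)
}

partition_from_labels <- function(breaks, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(k) which(labels == k))
  if (length(rows)) {
    # deterministic ordering by smallest member coordinate triple
    key <- vapply(rows, function(r) {
      r_ord <- r[order(breaks$x_nm[r], breaks$y_nm[r], breaks$z_nm[r])][1]
      sprintf("%.17g|%.17g|%.17g", breaks$x_nm[r_ord], breaks$y_nm[r_ord],
              breaks$z_nm[r_ord])
    }, "")
    ord <- order(key)
    rows <- rows[ord]
  }
  n0 <- vapply(rows, function(r) sum(breaks$strand[r] == 0), 0L)
  n1 <- vapply(rows, function(r) sum(breaks$strand[r] == 1), 0L)
  clusters <- tibble(
    cluster_id = seq_along(rows),
    size = vapply(rows, length, 0L),
    n_strand0 = n0,
    n_strand1 = n1,
    both_strands = n0 > 0L & n1 > 0L,
    max_span_nm = vapply(rows, function(r) {
      max_span(breaks$x_nm[r], breaks$y_nm[r], breaks$z_nm[r])
    }, 0),
    members = rows
  )
  assignment <- integer(nrow(breaks))
  for (k in seq_along(rows)) assignment[rows[[k]]] <- k
  list(clusters = clusters,
       isolated = breaks[assignment == 0L, , drop = FALSE],
       assignment = assignment)
}

max_span <- function(x, y, z) {
  if (length(x) < 2) return(0)
  best <- 0
  for (i in seq_len(length(x) - 1)) {
    j <- (i + 1):length(x)
    best <- max(best, max((x[j] - x[i])^2 + (y[j] - y[i])^2 + (z[j] - z[i])^2))
  }
  sqrt(best)
}

#' Brute-force clustering oracle
#'
#' Independent O(n^2) reference for [cluster_breaks()] at `MinPts = 2`: the
#' full pairwise distance matrix is thresholded at strictly-less-than `eps`
#' and labels are propagated to a fixed point (transitive closure), so each
#' final group is a connected component of the proximity relation. Singleton
#' components are isolated breaks. Intended for testing on at most a few
#' thousand points.
#'
#' @param breaks Strand-break tibble (`x_nm`, `y_nm`, `z_nm`, `strand`).
#' @param eps_nm Proximity radius (nm), strict.
#' @return Same structure as [cluster_breaks()].
#' @export
brute_force_cluster <- function(breaks, eps_nm = 3.4) {
  breaks <- as_tibble(breaks)
  n <- nrow(breaks)
  if (n > 5000) abort("brute_force_cluster is an oracle for <= 5000 breaks.")
  if (n == 0) return(partition_from_labels(breaks, integer(0)))
  p <- cbind(breaks$x_nm, breaks$y_nm, breaks$z_nm)
  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * tcrossprod(p)
  adj <- d2 < eps_nm^2
  diag(adj) <- TRUE
  labels <- seq_len(n)
  repeat {
    new_labels <- vapply(seq_len(n), function(i) min(labels[adj[i, ]]), 0L)
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  comp_size <- table(labels)
  keep <- labels %in% as.integer(names(comp_size)[comp_size >= 2])
  final <- integer(n)
  if (any(keep)) {
    final[keep] <- match(labels[keep], sort(unique(labels[keep])))
  }
  partition_from_labels(breaks, final)
}
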