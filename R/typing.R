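# Clustering species acoustic profiles into drumming types, with
# majority-rule selection of the number of clusters.

#' Euclidean distance matrix between species acoustic profiles
#'
#' @param profiles Numeric matrix (species x features), finite values.
#' @return Symmetric matrix with zero diagonal.
#' @export
acoustic_distance_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (any(!is.finite(profiles)))
    stop_("profiles contain non-finite values")
  D <- as.matrix(stats::dist(profiles, method = "euclidean"))
  dimnames(D) <- list(rownames(profiles), rownames(profiles))
  D
}

#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' @param distmat Symmetric distance matrix (or `dist`).
#' @return An `hclust` tree (merge heights are non-decreasing).
#' @export
ward_cluster <- function(distmat) {
  if (inherits(distmat, "dist")) distmat <- as.matrix(distmat)
  if (!is.matrix(distmat) || nrow(distmat) != ncol(distmat))
    stop_("distmat must be a square matrix")
  stats::hclust(stats::as.dist(distmat), method = "ward.D2")
}

# ---- internal cluster-validity indices ------------------------------------
# Each index returns a score; `maximize` says which direction is better.

.index_silhouette <- function(X, cl, D) {
  mean(cluster::silhouette(cl, stats::as.dist(D))[, 3])
}

.index_ch <- function(X, cl, D) {
  # Calinski-Harabasz variance-ratio criterion
  n <- nrow(X); k <- length(unique(cl))
  gm <- colMeans(X)
  B <- 0; W <- 0
  for (g in unique(cl)) {
    Xg <- X[cl == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((cg - gm)^2)
    W <- W + sum(sweep(Xg, 2, cg)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

.index_db <- function(X, cl, D) {
  # Davies-Bouldin (lower is better)
  gs <- sort(unique(cl)); k <- length(gs)
  cent <- t(sapply(gs, function(g) colMeans(X[cl == g, , drop = FALSE])))
  sig <- sapply(gs, function(g) {
    Xg <- X[cl == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xg, 2, colMeans(Xg))^2)))
  })
  r <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (dij == 0) return(Inf)
      best <- max(best, (sig[i] + sig[j]) / dij)
    }
    r[i] <- best
  }
  mean(r)
}

.index_dunn <- function(X, cl, D) {
  gs <- sort(unique(cl))
  diam <- max(sapply(gs, function(g) {
    d <- D[cl == g, cl == g, drop = FALSE]
    if (nrow(d) < 2) 0 else max(d)
  }))
  sep <- Inf
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i >= j) next
    sep <- min(sep, min(D[cl == gs[i], cl == gs[j], drop = FALSE]))
  }
  if (diam == 0) Inf else sep / diam
}

.index_cindex <- function(X, cl, D) {
  # C-index (lower is better)
  dv <- D[upper.tri(D)]
  same <- outer(cl, cl, "==")[upper.tri(D)]
  nw <- sum(same)
  if (nw == 0) return(Inf)
  sw <- sum(dv[same])
  sorted <- sort(dv)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq(length(sorted) - nw + 1, length(sorted))])
  if (smax == smin) return(0)
  (sw - smin) / (smax - smin)
}

.validity_panel <- function() {
  list(silhouette = list(fn = .index_silhouette, maximize = TRUE),
       calinski_harabasz = list(fn = .index_ch, maximize = TRUE),
       davies_bouldin = list(fn = .index_db, maximize = FALSE),
       dunn = list(fn = .index_dunn, maximize = TRUE),
       c_index = list(fn = .index_cindex, maximize = FALSE))
}

#' Majority-rule selection of the number of clusters
#'
#' Cuts the Ward.D2 dendrogram at every k in `k_range`, scores each partition
#' with a panel of internal validity indices (silhouette, Calinski-Harabasz,
#' Davies-Bouldin, Dunn, C-index by default), lets each index vote for its
#' best k and returns the modal k (ties broken by the smaller k). The result
#' is flagged low-confidence when no k collects a majority of the votes.
#'
#' @param profiles Species x features matrix.
#' @param k_range Candidate cluster counts (within 2..n-1).
#' @param indices Names of panel indices to use (default: all five).
#' @return List with `k`, `votes` (per-index best k), `vote_table`,
#'   `low_confidence`, the `hclust` tree and the per-k `labels` matrix.
#' @export
select_k_majority <- function(profiles, k_range = 2:10,
                              indices = names(.validity_panel())) {
  if (!length(k_range)) stop_("k_range is empty")
  n <- nrow(profiles)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop_("k_range must lie within [2, n_species - 1]")
  panel <- .validity_panel()[indices]
  if (any(vapply(panel, is.null, TRUE))) stop_("unknown validity index")
  D <- acoustic_distance_matrix(profiles)
  hc <- ward_cluster(D)
  labels <- sapply(k_range, function(k) stats::cutree(hc, k = k))
  colnames(labels) <- as.character(k_range)
  scores <- matrix(NA_real_, length(panel), length(k_range),
                   dimnames = list(names(panel), as.character(k_range)))
  for (i in seq_along(panel)) for (j in seq_along(k_range)) {
    scores[i, j] <- panel[[i]]$fn(profiles, labels[, j], D)
  }
  votes <- vapply(seq_along(panel), function(i) {
    s <- scores[i, ]
    if (!panel[[i]]$maximize) s <- -s
    k_range[which.max(s)]            # ties: earliest (smaller k)
  }, integer(1))
  names(votes) <- names(panel)
  tab <- table(factor(votes, levels = k_range))
  best <- k_range[which.max(tab)]    # modal k, ties -> smaller k
  list(k = best, votes = votes, vote_table = tab, scores = scores,
       low_confidence = max(tab) <= length(panel) / 2,
       hclust = hc, labels = labels)
}

#' Assign drumming-type clusters to species
#'
#' Ward.D2 partition of the species acoustic profiles at a given (or
#' majority-rule selected) number of clusters.
#'
#' @param profiles Species x features matrix with species rownames.
#' @param k Number of clusters; when `NULL` it is chosen by
#'   [select_k_majority()] over `k_range`.
#' @param k_range Candidate k values when `k` is NULL.
#' @return List of class `type_assignment`: `labels` (named integer vector in
#'   1..k), `k`, the `hclust` record and (when selected) the index votes.
#' @export
assign_types <- function(profiles, k = NULL, k_range = 2:10) {
  sel <- NULL
  if (is.null(k)) {
    sel <- select_k_majority(profiles, k_range)
    k <- sel$k
    hc <- sel$hclust
  } else {
    hc <- ward_cluster(acoustic_distance_matrix(profiles))
  }
  structure(list(labels = stats::cutree(hc, k = k), k = k,
                 hclust = hc, selection = sel),
            class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat(sprintf("type_assignment: %d species in %d clusters\n",
              length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}
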