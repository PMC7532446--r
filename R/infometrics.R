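# Leave-one-out discriminant classification, permutation null, and the
# information-theoretic layer: local/overall mutual information from the
# confusion matrix, its ceiling normalization, the MI <-> percent-correct
# relation under random misclassification, and the pairwise
# Classification Index.

#' Construct a confusion-matrix object
#'
#' Row-stochastic matrix of conditional classification probabilities
#' p(predicted | actual); the unconditional predicted distribution is
#' derived with a uniform prior over actual species.
#'
#' @param mat Square matrix, rows = actual species, columns = predicted;
#'   rows must sum to 1.
#' @param n_drums Optional per-species drum counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(mat, n_drums = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop_("confusion matrix must be square")
  if (any(mat < -1e-12 | mat > 1 + 1e-12))
    stop_("confusion-matrix entries must lie in [0, 1]")
  if (any(abs(rowSums(mat) - 1) > 1e-9))
    stop_("confusion-matrix rows must sum to 1")
  if (is.null(rownames(mat)))
    dimnames(mat) <- list(paste0("s", seq_len(nrow(mat))),
                          paste0("s", seq_len(nrow(mat))))
  structure(list(matrix = mat,
                 species = rownames(mat),
                 n_drums = n_drums,
                 p_predicted = colMeans(mat)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: %d species, mean diagonal %.3f\n",
              length(x$species), mean(diag(x$matrix))))
  invisible(x)
}

# Manual LOO linear-discriminant classification with covariance shrinkage,
# used when the pooled within-class covariance is ill-conditioned. Uniform
# class prior; ties broken by the first (alphabetically smallest) species.
.loo_lda_shrink <- function(X, g) {
  lev <- levels(g)
  k <- length(lev); n <- nrow(X); p <- ncol(X)
  mu <- t(sapply(lev, function(l) colMeans(X[g == l, , drop = FALSE])))
  ng <- as.integer(table(g))
  scat <- lapply(seq_len(k), function(j) {
    Xg <- sweep(X[g == lev[j], , drop = FALSE], 2, mu[j, ])
    crossprod(Xg)
  })
  S_tot <- Reduce(`+`, scat)
  shrunk <- FALSE
  pred <- character(n)
  for (i in seq_len(n)) {
    j <- match(g[i], lev)
    x <- X[i, ]
    mgi <- (ng[j] * mu[j, ] - x) / (ng[j] - 1)
    d <- x - mu[j, ]
    Sj_new <- scat[[j]] - (ng[j] / (ng[j] - 1)) * tcrossprod(d)
    Sig <- (S_tot - scat[[j]] + Sj_new) / (n - 1 - k)
    for (delta in c(0, 1e-4, 1e-3, 1e-2, 1e-1, 0.5)) {
      Ss <- (1 - delta) * Sig + delta * mean(diag(Sig)) * diag(p)
      ok <- tryCatch(Matrix::rcond(Matrix::Matrix(Ss)) > 1e-10,
                     error = function(e) FALSE)
      if (ok) break
    }
    if (delta > 0) shrunk <- TRUE
    mus <- mu; mus[j, ] <- mgi
    sc <- vapply(seq_len(k), function(l) {
      w <- solve(Ss, mus[l, ])
      sum(x * w) - 0.5 * sum(mus[l, ] * w)
    }, numeric(1))
    pred[i] <- lev[which.max(sc)]
  }
  if (shrunk)
    message("pooled within-class covariance ill-conditioned: ",
            "diagonal shrinkage applied")
  factor(pred, levels = lev)
}

#' Leave-one-out discriminant confusion matrix
#'
#' Linear discriminant classification of every drum in a leave-one-out
#' cross-validation, trained with a uniform class prior on the retained
#' principal-component scores. Each held-out drum contributes its hard
#' (argmax) classification; rows aggregate per actual species
#' (alphabetical order). With `method = "posterior"` the per-drum posterior
#' probabilities are averaged instead. Falls back to a documented
#' shrinkage-regularized LOO classifier when the pooled within-class
#' covariance is singular.
#'
#' @param scores Numeric matrix (drums x discriminant inputs).
#' @param labels Species label per drum; every species needs >= 2 drums.
#' @param method "hard" (default) or "posterior".
#' @return A `confusion_matrix`.
#' @export
loo_confusion <- function(scores, labels, method = c("hard", "posterior")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  g <- factor(labels, levels = sort(unique(as.character(labels))))
  if (nlevels(g) < 2) stop_("need at least 2 species")
  if (any(table(g) < 2))
    stop_("every species needs >= 2 drums for leave-one-out classification")
  k <- nlevels(g)
  fit <- tryCatch(
    withCallingHandlers(
      MASS::lda(scores, grouping = g, prior = rep(1 / k, k), CV = TRUE),
      warning = function(w) {
        # collinear inputs are routine on small subsets; the discriminant
        # rule itself remains defined
        if (grepl("collinear", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$class)) {
    pred <- .loo_lda_shrink(scores, g)
    post <- NULL
    if (method == "posterior")
      stop_("posterior method unavailable under the shrinkage fallback")
  } else {
    pred <- fit$class
    post <- fit$posterior
  }
  if (method == "hard") {
    tab <- table(actual = g, predicted = factor(pred, levels = levels(g)))
    M <- sweep(unclass(tab), 1, rowSums(tab), "/")
  } else {
    M <- rowsum(post, g) / as.vector(table(g))
  }
  dimnames(M) <- list(levels(g), levels(g))
  confusion_matrix(M, n_drums = as.integer(table(g)))
}

#' Permutation test of the discriminant classification (pDFA)
#'
#' Species labels are permuted across drums; the observed mean diagonal of
#' the LOO confusion matrix is compared with the permuted distribution.
#' The p-value uses the add-one convention and is never exactly 0.
#'
#' @param scores,labels As in [loo_confusion()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional RNG seed.
#' @return List with `p_value`, `observed` and `perm_stats`.
#' @export
permuted_dfa <- function(scores, labels, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop_("n_perm must be at least 99")
  observed <- mean(diag(loo_confusion(scores, labels)$matrix))
  with_seed(seed, {
    perm_stats <- vapply(seq_len(n_perm), function(b) {
      pl <- sample(labels)
      # a permutation can starve a species below 2 drums only if the
      # original labels were unbalanced across a shared pool; resample
      while (any(table(pl) < 2)) pl <- sample(labels)
      mean(diag(loo_confusion(scores, pl)$matrix))
    }, numeric(1))
    list(p_value = (1 + sum(perm_stats >= observed)) / (n_perm + 1),
         observed = observed, perm_stats = perm_stats)
  })
}

#' Local mutual information of one or all species (bits)
#'
#' MI_L(A) = sum_M p(M|A) log2( p(M|A) / p(M) ), with the 0 log 0 = 0
#' convention and p(M) the uniform-prior predicted distribution.
#'
#' @param cm A `confusion_matrix`.
#' @param species Optional species name(s); default all.
#' @return Named numeric vector of MI_L values in bits.
#' @export
local_mi <- function(cm, species = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (is.null(species)) species <- cm$species
  if (!all(species %in% cm$species)) stop_("unknown species")
  pm <- cm$p_predicted
  vapply(species, function(a) {
    row <- cm$matrix[a, ]
    nz <- row > 0
    stopifnot(all(pm[nz] > 0))  # impossible by construction
    sum(row[nz] * log2(row[nz] / pm[nz]))
  }, numeric(1))
}

#' Overall mutual information (bits)
#'
#' Average of the local mutual information over species (uniform species
#' prior).
#'
#' @param cm A `confusion_matrix`.
#' @return MI in bits.
#' @export
overall_mi <- function(cm) mean(local_mi(cm))

#' Information summary of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return List of class `info_result`: per-species `mi_local`, overall `mi`,
#'   ceiling `mi_ceil = log2(n_s)` and the ceiling-normalized values.
#' @export
info_summary <- function(cm) {
  mil <- local_mi(cm)
  n <- length(cm$species)
  ceil <- log2(n)
  structure(list(mi_local = mil, mi = mean(mil), mi_ceil = ceil,
                 mi_local_norm = mil / ceil, mi_norm = mean(mil) / ceil,
                 n_species = n),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("MI = %.3f bits (ceiling %.3f, normalized %.1f%%), n = %d species\n",
              x$mi, x$mi_ceil, 100 * x$mi_norm, x$n_species))
  invisible(x)
}

#' Mutual information implied by a correct-classification probability
#'
#' Assumes misclassifications spread evenly over the n_s - 1 wrong species:
#' MI = log2 n_s - (1 - p_c) log2(n_s - 1) + p_c log2 p_c +
#' (1 - p_c) log2(1 - p_c). Boundary values p_c = 1/n_s (chance, 0 bits) and
#' p_c = 1 (ceiling) are handled analytically.
#'
#' @param p_c Probability of correct classification, in [1/n_s, 1].
#' @param n_s Number of species (>= 2).
#' @return MI in bits (vectorized over `p_c`).
#' @export
mi_from_pc <- function(p_c, n_s) {
  stopifnot(n_s >= 2)
  if (any(p_c < 1 / n_s - 1e-12 | p_c > 1 + 1e-12))
    stop_("p_c must lie in [1/n_s, 1]")
  p_c <- pmin(pmax(p_c, 1 / n_s), 1)
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  log2(n_s) - (1 - p_c) * log2(n_s - 1) + xlx(p_c) + xlx(1 - p_c)
}

#' Correct-classification probability implied by a mutual information
#'
#' Numeric inversion of the random-misclassification relation (see
#' [mi_from_pc()]) by bracketed root-finding on [1/n_s, 1]; the relation is
#' strictly increasing on that interval.
#'
#' @param mi_bits MI in bits, in [0, log2(n_s)].
#' @param n_s Number of species (>= 2).
#' @return p_c in [1/n_s, 1].
#' @export
pc_from_mi <- function(mi_bits, n_s) {
  stopifnot(n_s >= 2, length(mi_bits) == 1)
  ceil <- log2(n_s)
  if (mi_bits < -1e-12 || mi_bits > ceil + 1e-12)
    stop_("mi_bits must lie in [0, log2(n_s)]")
  if (mi_bits <= 0) return(1 / n_s)
  if (mi_bits >= ceil) return(1)
  stats::uniroot(function(p) mi_from_pc(p, n_s) - mi_bits,
                 lower = 1 / n_s, upper = 1, tol = 1e-10)$root
}

#' Pairwise Classification Index
#'
#' CI(A, B) = ([p(A|A) - p(B|A)] + [p(B|B) - p(A|B)]) / 2 x 100, ranging
#' from -100 (the pair is fully swapped by the classifier) to 100 (perfect
#' mutual discrimination). Symmetric in (A, B).
#'
#' @param cm A `confusion_matrix`.
#' @param A,B Distinct species names.
#' @return CI value in [-100, 100].
#' @export
classification_index <- function(cm, A, B) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (identical(A, B)) stop_("A and B must be distinct species")
  if (!all(c(A, B) %in% cm$species)) stop_("unknown species")
  M <- cm$matrix
  ((M[A, A] - M[A, B]) + (M[B, B] - M[B, A])) / 2 * 100
}

#' Balanced per-type distribution of normalized local information
#'
#' Controls for unequal type sizes by repeatedly drawing `n_per_type`
#' species per drumming type, rebuilding the LOO confusion matrix on the
#' balanced subset and averaging the ceiling-normalized MI_L by type. Also
#' reports, on the full dataset, the Pearson correlation between a type's
#' species count and its mean normalized MI_L.
#'
#' @param dataset A dataset processed by [standardize_and_pca()].
#' @param types Named character vector species -> type; defaults to the
#'   generator's ground-truth types.
#' @param n_per_type Species drawn per type each iteration (default 5).
#' @param n_iter Number of iterations (default 100).
#' @param seed Optional RNG seed.
#' @return List of class `balanced_mi`: `per_iter` (iterations x types
#'   matrix of mean normalized MI_L), `type_means`, `full_mi_local_norm`,
#'   and `size_cor` (estimate + p-value).
#' @export
per_type_balanced_mi <- function(dataset, types = NULL, n_per_type = 5,
                                 n_iter = 100, seed = NULL) {
  stopifnot(!is.null(dataset$pca))
  if (is.null(types))
    types <- stats::setNames(dataset$species$drum_type,
                             dataset$species$species_id)
  sc <- pc_scores(dataset)
  tys <- sort(unique(types))
  counts <- table(types)
  short <- names(counts)[counts < n_per_type]
  if (length(short))
    stop_("type %s has fewer than %d species", short[1], n_per_type)

  cm_full <- loo_confusion(sc$scores, sc$labels)
  full_norm <- info_summary(cm_full)$mi_local_norm
  by_type_mean <- vapply(tys, function(ty)
    mean(full_norm[names(types)[types == ty]]), numeric(1))
  size_cor <- if (length(unique(as.numeric(counts[tys]))) < 2 ||
                  stats::sd(by_type_mean) == 0) {
    # correlation undefined for balanced type sizes
    list(estimate = NA_real_, p_value = NA_real_)
  } else {
    ct <- stats::cor.test(as.numeric(counts[tys]), by_type_mean,
                          method = "pearson")
    list(estimate = unname(ct$estimate), p_value = ct$p.value)
  }

  with_seed(seed, {
    per_iter <- matrix(NA_real_, n_iter, length(tys),
                       dimnames = list(NULL, tys))
    for (b in seq_len(n_iter)) {
      chosen <- unlist(lapply(tys, function(ty)
        sample(names(types)[types == ty], n_per_type)))
      idx <- sc$labels %in% chosen
      cm <- loo_confusion(sc$scores[idx, , drop = FALSE], sc$labels[idx])
      norm <- info_summary(cm)$mi_local_norm
      for (ty in tys)
        per_iter[b, ty] <- mean(norm[intersect(names(norm),
                                               names(types)[types == ty])])
    }
    structure(list(per_iter = per_iter,
                   type_means = colMeans(per_iter),
                   full_mi_local_norm = full_norm,
                   type_sizes = as.integer(counts[tys]),
                   size_cor = size_cor),
              class = "balanced_mi")
  })
}

#' @export
print.balanced_mi <- function(x, ...) {
  cat("balanced per-type normalized MI_L (mean over iterations):\n")
  print(round(x$type_means, 3))
  cat(sprintf("type size vs mean MI_L: Pearson r = %.2f (p = %.3g)\n",
              x$size_cor$estimate, x$size_cor$p_value))
  invisible(x)
}
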