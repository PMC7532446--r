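# 22-dimensional acoustic feature space: extraction, z-scoring, PCA and
# per-species acoustic profiles.

#' Names of the 22 acoustic features
#'
#' Fixed, ordered feature set: strike counts, duration, inter-pulse-interval
#' (IPI) statistics (temporal jitter = CV of IPIs), position/flags of the
#' maximum IPI, pulse rate, acceleration (least-squares slope of IPI against
#' strike index), amplitude statistics (amplitude jitter = CV of amplitudes,
#' all amplitudes normalized to the drum maximum), bout (pulse-sequence)
#' statistics and the per-drum peak frequency.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() {
  c("n_strikes", "duration",
    "ipi_mean", "ipi_sd", "ipi_cv", "ipi_min", "ipi_max",
    "ipi_max_pos", "ipi_max_first", "ipi_max_last",
    "pulse_rate", "accel_slope",
    "amp_mean", "amp_sd", "amp_cv", "amp_slope", "amp_last_first",
    "n_bouts", "bout_size_mean", "bout_size_cv", "inter_bout_ipi_mean",
    "peak_freq")
}

# Split strikes into bouts: IPIs larger than gap_factor x the median
# intra-bout IPI are inter-bout gaps. The intra-bout median is estimated
# robustly from the lower half of the IPIs (gaps can make up half of them,
# e.g. in double-knock drums) and refined once after classification.
segment_bouts <- function(ipis, gap_factor = 3) {
  med_low <- stats::median(ipis[ipis <= stats::median(ipis)])
  is_gap <- ipis > gap_factor * med_low
  if (any(!is_gap)) {
    thr <- gap_factor * stats::median(ipis[!is_gap])
    is_gap <- ipis > thr
  }
  bout_id <- c(1, 1 + cumsum(is_gap))
  list(bout_id = bout_id, sizes = as.integer(table(bout_id)),
       gap_ipis = ipis[is_gap])
}

#' Extract the 22 acoustic features from one drum
#'
#' Temporal and amplitude jitter are coefficients of variation; acceleration
#' is the least-squares slope of the IPI series against strike index;
#' `ipi_max_first`/`ipi_max_last` flag whether the maximum IPI appears in
#' first or last position. Drums with a single bout return inter-bout
#' statistics as 0 (documented convention; `bout_size_cv` is then 0 and
#' `bout_size_mean` equals the strike count).
#'
#' @param drum A `drum` (>= 2 strikes).
#' @param gap_factor Bout-segmentation threshold as a multiple of the median
#'   IPI (default 3).
#' @return Named numeric vector of length 22.
#' @export
extract_features <- function(drum, gap_factor = 3) {
  if (!inherits(drum, "drum")) stop_("expected a 'drum' object")
  tt <- drum$strike_times
  if (length(tt) < 2) stop_("a drum needs at least 2 strikes")
  aa <- drum$amplitudes
  d <- diff(tt)
  nd <- length(d)
  imax <- which.max(d)
  bouts <- segment_bouts(d, gap_factor)
  out <- c(
    n_strikes = length(tt),
    duration = tt[length(tt)] - tt[1],
    ipi_mean = mean(d),
    ipi_sd = sd0(d),
    ipi_cv = cv0(d),
    ipi_min = min(d),
    ipi_max = max(d),
    ipi_max_pos = if (nd == 1) 0.5 else (imax - 1) / (nd - 1),
    ipi_max_first = as.numeric(imax == 1),
    ipi_max_last = as.numeric(imax == nd),
    pulse_rate = length(tt) / (tt[length(tt)] - tt[1]),
    accel_slope = ls_slope(d),
    amp_mean = mean(aa),
    amp_sd = sd0(aa),
    amp_cv = cv0(aa),
    amp_slope = ls_slope(aa),
    amp_last_first = aa[length(aa)] / aa[1],
    n_bouts = length(bouts$sizes),
    bout_size_mean = mean(bouts$sizes),
    bout_size_cv = cv0(bouts$sizes),
    inter_bout_ipi_mean = if (length(bouts$gap_ipis)) mean(bouts$gap_ipis) else 0,
    peak_freq = drum$peak_freq
  )
  stats::setNames(out, feature_names())
}

#' Compute the drums x 22 feature matrix of a dataset
#'
#' @param dataset A `drum_dataset`.
#' @param gap_factor Bout segmentation threshold, see [extract_features()].
#' @return The dataset with `$features` (matrix) and `$drum_species`
#'   (per-row species labels) attached.
#' @export
feature_matrix <- function(dataset, gap_factor = 3) {
  stopifnot(inherits(dataset, "drum_dataset"))
  X <- t(vapply(dataset$drums, extract_features, numeric(22),
                gap_factor = gap_factor))
  rownames(X) <- NULL
  dataset$features <- X
  dataset$drum_species <- vapply(dataset$drums, `[[`, "", "species_id")
  dataset
}

#' Z-score the feature matrix and reduce it by PCA
#'
#' Columns are standardized to mean 0, SD 1 (the z-scoring parameters are
#' stored for reuse); principal components with eigenvalue > 1 are retained.
#' Loading signs are fixed so that each component's largest-magnitude loading
#' is positive. A warning is raised when the leading eigenvalue does not
#' exceed the Marchenko-Pastur noise edge, i.e. when the retained set is
#' unstable because the data carry no linear structure.
#'
#' @param dataset A `drum_dataset` with features (see [feature_matrix()]);
#'   needs more drums than features.
#' @param drop_constant Drop zero-variance features with a message instead
#'   of erroring (useful for degenerate datasets such as single-type
#'   clades, where e.g. every drum has one bout).
#' @return The dataset with `$z` (z-scoring parameters and standardized
#'   matrix) and `$pca` (loadings, eigenvalues, scores, variance explained,
#'   retained component indices) attached.
#' @export
standardize_and_pca <- function(dataset, drop_constant = FALSE) {
  stopifnot(inherits(dataset, "drum_dataset"))
  if (is.null(dataset$features)) dataset <- feature_matrix(dataset)
  X <- dataset$features
  if (nrow(X) <= ncol(X))
    stop_("need more drums (%d) than features (%d)", nrow(X), ncol(X))
  zero <- which(apply(X, 2, stats::sd) == 0)
  if (length(zero)) {
    if (!drop_constant)
      stop_("zero-variance feature: %s",
            paste(feature_names()[zero], collapse = ", "))
    message(sprintf("dropping %d zero-variance feature(s): %s",
                    length(zero),
                    paste(feature_names()[zero], collapse = ", ")))
    X <- X[, -zero, drop = FALSE]
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  Z <- scale(X, center = mu, scale = sdev)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  # fix sign: largest-magnitude loading positive
  for (j in seq_along(eig)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) {
      pc$rotation[, j] <- -l
      pc$x[, j] <- -pc$x[, j]
    }
  }
  retained <- which(eig > 1)
  mp_edge <- 1.05 * (1 + sqrt(ncol(X) / nrow(X)))^2
  if (max(eig) <= mp_edge)
    warning(sprintf(paste0("leading eigenvalue %.2f is below the noise edge ",
                           "%.2f: no reliable linear structure, retained ",
                           "components are unstable"), max(eig), mp_edge))
  dataset$z <- list(center = mu, scale = sdev, matrix = Z)
  dataset$pca <- list(loadings = pc$rotation, eigenvalues = eig,
                      scores = pc$x, var_explained = eig / sum(eig),
                      retained = retained)
  dataset
}

#' Apply stored z-scoring parameters to a feature matrix
#'
#' @param dataset A dataset processed by [standardize_and_pca()].
#' @param X Feature matrix (columns in [feature_names()] order).
#' @return Standardized matrix.
#' @export
apply_zscore <- function(dataset, X) {
  stopifnot(!is.null(dataset$z))
  scale(X, center = dataset$z$center, scale = dataset$z$scale)[, , drop = FALSE]
}

#' Per-species acoustic profiles
#'
#' Mean z-scored feature vector per species. Species with fewer than 3 drums
#' are excluded with a warning, mirroring the minimum-sample inclusion rule
#' of the clade-wide analysis.
#'
#' @param dataset A dataset processed by [standardize_and_pca()].
#' @param min_drums Minimum drums per species (default 3).
#' @return The dataset with `$profiles` (species x 22 matrix, rows sorted by
#'   species id) attached.
#' @export
species_profiles <- function(dataset, min_drums = 3) {
  stopifnot(inherits(dataset, "drum_dataset"), !is.null(dataset$z))
  sp <- dataset$drum_species
  counts <- table(sp)
  keep <- names(counts)[counts >= min_drums]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped))
    warning(sprintf("excluding %d species with < %d drums: %s",
                    length(dropped), min_drums,
                    paste(dropped, collapse = ", ")))
  keep <- sort(keep)
  P <- t(vapply(keep, function(s)
    colMeans(dataset$z$matrix[sp == s, , drop = FALSE]),
    numeric(ncol(dataset$z$matrix))))
  colnames(P) <- colnames(dataset$z$matrix)
  dataset$profiles <- P
  dataset
}

#' Retained principal-component scores and labels of a dataset
#'
#' Convenience accessor used by the discriminant and information layers.
#'
#' @param dataset A dataset processed by [standardize_and_pca()].
#' @return List with `scores` (drums x retained PCs) and `labels`.
#' @export
pc_scores <- function(dataset) {
  stopifnot(!is.null(dataset$pca))
  list(scores = dataset$pca$scores[, dataset$pca$retained, drop = FALSE],
       labels = dataset$drum_species)
}
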