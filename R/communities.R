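# Sympatry, community composition, pairwise discriminability profiles,
# virtual-community simulations and the character-displacement test.

#' Sympatric pairs and sympatry levels from species ranges
#'
#' Two species are sympatric as soon as their range rectangles overlap, even
#' if only at the range edge (closed boundaries: edge contact counts). The
#' sympatry level of a species is its degree in the overlap graph.
#'
#' @param ranges data.frame with species_id, xmin, xmax, ymin, ymax (see
#'   [generate_ranges()]).
#' @return Object of class `community_table`: `pairs` (one record per
#'   unordered pair with a `sympatric` flag), `sympatry_level`, and an
#'   empty `communities` slot fillable by [make_communities()].
#' @export
sympatric_pairs <- function(ranges) {
  stopifnot(all(c("species_id", "xmin", "xmax", "ymin", "ymax") %in%
                  names(ranges)))
  if (any(ranges$xmin >= ranges$xmax) || any(ranges$ymin >= ranges$ymax))
    stop_("degenerate range rectangle (min must be < max)")
  n <- nrow(ranges)
  ids <- ranges$species_id
  pr <- t(utils::combn(n, 2))
  i <- pr[, 1]; j <- pr[, 2]
  symp <- ranges$xmin[i] <= ranges$xmax[j] & ranges$xmin[j] <= ranges$xmax[i] &
          ranges$ymin[i] <= ranges$ymax[j] & ranges$ymin[j] <= ranges$ymax[i]
  pairs <- data.frame(species_a = ids[i], species_b = ids[j],
                      sympatric = symp, stringsAsFactors = FALSE)
  lev <- stats::setNames(integer(n), ids)
  tab <- table(c(pairs$species_a[symp], pairs$species_b[symp]))
  lev[names(tab)] <- as.integer(tab)
  structure(list(pairs = pairs, sympatry_level = lev, communities = NULL),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d pairs, %d sympatric; %d communities\n",
              nrow(x$pairs), sum(x$pairs$sympatric),
              length(x$communities %||% list())))
  invisible(x)
}

#' Assemble point-based communities from ranges
#'
#' Draws anchor locations (the centres of randomly chosen species ranges)
#' and defines each community as the set of species whose range contains
#' that location — a simple emulation of local species assemblages.
#'
#' @param ranges Range table, see [sympatric_pairs()].
#' @param n_communities Number of communities.
#' @param seed Optional RNG seed.
#' @return Named list community id -> character vector of species.
#' @export
make_communities <- function(ranges, n_communities = 5, seed = NULL) {
  with_seed(seed, {
    anchors <- sample(nrow(ranges), n_communities, replace = TRUE)
    out <- lapply(anchors, function(a) {
      px <- (ranges$xmin[a] + ranges$xmax[a]) / 2
      py <- (ranges$ymin[a] + ranges$ymax[a]) / 2
      ranges$species_id[ranges$xmin <= px & px <= ranges$xmax &
                        ranges$ymin <= py & py <= ranges$ymax]
    })
    stats::setNames(out, sprintf("comm%02d", seq_len(n_communities)))
  })
}

#' Pairwise acoustic distance and Classification Index within a community
#'
#' Per-pair Euclidean distance between the species' 22-dimensional acoustic
#' profiles and the pairwise Classification Index looked up in the
#' clade-wide confusion matrix.
#'
#' @param community Character vector of species ids.
#' @param dataset A dataset with `$profiles` (see [species_profiles()]).
#' @param cm A clade-wide `confusion_matrix` containing the species.
#' @return data.frame with one record per unordered pair (species_a,
#'   species_b, acoustic_dist, ci).
#' @export
community_profiles <- function(community, dataset, cm) {
  stopifnot(!is.null(dataset$profiles))
  community <- sort(unique(as.character(community)))
  if (!all(community %in% rownames(dataset$profiles)))
    stop_("community species missing from the dataset profiles")
  if (!all(community %in% cm$species))
    stop_("community species missing from the confusion matrix")
  if (length(community) < 2) stop_("a community needs at least 2 species")
  pr <- t(utils::combn(community, 2))
  P <- dataset$profiles
  data.frame(
    species_a = pr[, 1], species_b = pr[, 2],
    acoustic_dist = vapply(seq_len(nrow(pr)), function(r)
      sqrt(sum((P[pr[r, 1], ] - P[pr[r, 2], ])^2)), numeric(1)),
    ci = vapply(seq_len(nrow(pr)), function(r)
      classification_index(cm, pr[r, 1], pr[r, 2]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Virtual-community discriminability simulations
#'
#' Bootstraps communities of fixed size (balanced over `sizes`) assembled in
#' four ways — real communities subsampled, random species draws, all
#' species sharing one drumming type, or all types distinct — and summarizes
#' the per-community mean pairwise acoustic distance and Classification
#' Index as cumulative distribution curves with mean +/- 2 SD bootstrap
#' envelopes.
#'
#' @param dataset A dataset with `$profiles`.
#' @param types Named species -> type vector (default ground truth).
#' @param cm Clade-wide `confusion_matrix`.
#' @param mode One of "real", "random", "same_type", "different_type".
#' @param sizes Community sizes, balanced across draws (default c(5, 6)).
#' @param n_boot Bootstrap replicates (default 100).
#' @param communities Named list of real communities (required for
#'   `mode = "real"`).
#' @param n_comm_per_boot Communities drawn per bootstrap replicate.
#' @param grid_n Number of grid points of the cumulative curves.
#' @param seed Optional RNG seed.
#' @return Object of class `virtual_communities`: per-boot mean values and
#'   cumulative-distribution curves (grid, mean, sd) for both measures.
#' @export
simulate_virtual_communities <- function(dataset, types = NULL, cm, mode,
                                         sizes = c(5, 6), n_boot = 100,
                                         communities = NULL,
                                         n_comm_per_boot = 20,
                                         grid_n = 100, seed = NULL) {
  stopifnot(!is.null(dataset$profiles))
  mode <- match.arg(mode, c("real", "random", "same_type", "different_type"))
  if (is.null(types))
    types <- stats::setNames(dataset$species$drum_type,
                             dataset$species$species_id)
  pool <- intersect(rownames(dataset$profiles), cm$species)
  types <- types[pool]
  by_type <- split(names(types), types)
  for (size in sizes) {
    if (mode == "same_type" && !any(lengths(by_type) >= size))
      stop_("no drumming type has >= %d species for mode same_type", size)
    if (mode == "different_type" && length(by_type) < size)
      stop_("need >= %d distinct types for mode different_type", size)
    if (mode == "real") {
      if (is.null(communities)) stop_("mode real requires `communities`")
      if (!any(lengths(communities) >= size))
        stop_("no real community has >= %d species", size)
    }
  }
  draw <- function(size) {
    switch(mode,
      random = sample(pool, size),
      same_type = {
        ok <- names(by_type)[lengths(by_type) >= size]
        sample(by_type[[if (length(ok) == 1) ok else sample(ok, 1)]], size)
      },
      different_type = {
        tys <- sample(names(by_type), size)
        vapply(tys, function(ty) {
          s <- by_type[[ty]]
          if (length(s) == 1) s else sample(s, 1)
        }, character(1))
      },
      real = {
        ok <- which(lengths(communities) >= size)
        cc <- communities[[if (length(ok) == 1) ok else sample(ok, 1)]]
        sample(intersect(cc, pool), size)
      })
  }
  with_seed(seed, {
    vals_d <- vals_c <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      d <- c_ <- numeric(0)
      for (r in seq_len(n_comm_per_boot)) {
        size <- sizes[1 + (r - 1) %% length(sizes)]
        prof <- community_profiles(draw(size), dataset, cm)
        d <- c(d, mean(prof$acoustic_dist))
        c_ <- c(c_, mean(prof$ci))
      }
      vals_d[[b]] <- d; vals_c[[b]] <- c_
    }
    curve_of <- function(vals) {
      all <- unlist(vals)
      grid <- seq(min(all), max(all), length.out = grid_n)
      E <- sapply(vals, function(v) stats::ecdf(v)(grid))
      data.frame(grid = grid, mean = rowMeans(E),
                 sd = apply(E, 1, stats::sd))
    }
    structure(list(mode = mode, sizes = sizes, n_boot = n_boot,
                   boot_mean_dist = vapply(vals_d, mean, numeric(1)),
                   boot_mean_ci = vapply(vals_c, mean, numeric(1)),
                   curves = list(acoustic = curve_of(vals_d),
                                 ci = curve_of(vals_c))),
              class = "virtual_communities")
  })
}

#' @export
print.virtual_communities <- function(x, ...) {
  cat(sprintf(paste0("virtual_communities (%s, sizes %s, %d bootstraps): ",
                     "mean pairwise distance %.2f, mean CI %.1f\n"),
              x$mode, paste(x$sizes, collapse = "/"), x$n_boot,
              mean(x$boot_mean_dist), mean(x$boot_mean_ci)))
  invisible(x)
}

# interaction-model fit returning the t statistics of the sympatry terms
.cd_fit <- function(y, lx, s) {
  X <- cbind(1, lx, s, lx * s)
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXi <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXi))
  list(beta = beta, t = beta / se, se = se, df = df, XtXi = XtXi,
       sigma2 = sigma2)
}

#' Permutation test for character displacement under sympatry
#'
#' Fits the pairwise response (acoustic distance or Classification Index)
#' against log patristic distance, the sympatry flag and their interaction,
#' and assesses significance by permuting species identities over the range
#' data and re-deriving the pair flags — a species-level permutation that
#' respects the non-independence of pairs sharing a species. Displacement
#' concentrated among close relatives appears as a negative interaction
#' (the sympatry effect shrinks with phylogenetic distance); the sympatry
#' effect evaluated at the lower quartile of log distance is reported with
#' its own permutation p-value.
#'
#' @param pair_records data.frame with species_a, species_b, patristic,
#'   sympatric and the response column.
#' @param response Column name, "acoustic_dist" (default) or "ci".
#' @param n_perm Number of species-label permutations (default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `cd_test`: coefficient table, `p_interaction`,
#'   `p_low_distance`, and the observed effects.
#' @export
character_displacement_test <- function(pair_records,
                                        response = "acoustic_dist",
                                        n_perm = 999, seed = NULL) {
  pr <- pair_records
  need <- c("species_a", "species_b", "patristic", "sympatric", response)
  stopifnot(all(need %in% names(pr)))
  ns <- sum(pr$sympatric); nn <- sum(!pr$sympatric)
  if (ns == 0 || nn == 0)
    stop_("need both sympatric and non-sympatric pairs")
  if (min(ns, nn) < 20)
    stop_("need >= 20 pairs in each sympatry class (have %d / %d)", ns, nn)
  ids <- sort(unique(c(pr$species_a, pr$species_b)))
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(pr$species_a, pr$species_b)] <- pr$sympatric
  A[cbind(pr$species_b, pr$species_a)] <- pr$sympatric
  y <- pr[[response]]
  lx <- log(pr$patristic)
  q_low <- stats::quantile(lx, 0.25)
  obs <- .cd_fit(y, lx, as.numeric(pr$sympatric))
  # sympatry effect at low phylogenetic distance: beta_s + q_low * beta_int
  low_contrast <- c(0, 0, 1, q_low)
  eff_low <- sum(low_contrast * obs$beta)
  se_low <- sqrt(obs$sigma2 * drop(low_contrast %*% obs$XtXi %*% low_contrast))
  t_low_obs <- eff_low / se_low
  with_seed(seed, {
    t_int <- t_low <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(sample(ids), ids)
      s_perm <- as.numeric(A[cbind(perm[pr$species_a], perm[pr$species_b])])
      f <- .cd_fit(y, lx, s_perm)
      t_int[b] <- f$t[4]
      t_low[b] <- sum(low_contrast * f$beta) /
        sqrt(f$sigma2 * drop(low_contrast %*% f$XtXi %*% low_contrast))
    }
    coef_tab <- data.frame(term = c("intercept", "log_patristic",
                                    "sympatric", "interaction"),
                           estimate = as.numeric(obs$beta),
                           t = as.numeric(obs$t), row.names = NULL)
    structure(list(
      response = response,
      coefficients = coef_tab,
      effect_low_distance = eff_low,
      p_interaction = (1 + sum(abs(t_int) >= abs(obs$t[4]))) / (n_perm + 1),
      p_low_distance = (1 + sum(abs(t_low) >= abs(t_low_obs))) / (n_perm + 1),
      n_sympatric = ns, n_pairs = nrow(pr), n_perm = n_perm),
      class = "cd_test")
  })
}

#' @export
print.cd_test <- function(x, ...) {
  cat(sprintf("character displacement test on %s (%d pairs, %d sympatric)\n",
              x$response, x$n_pairs, x$n_sympatric))
  print(transform(x$coefficients, estimate = signif(estimate, 3),
                  t = round(t, 2)))
  cat(sprintf("interaction p = %.4g; sympatry effect at low distance = %.3g (p = %.4g)\n",
              x$p_interaction, x$effect_low_distance, x$p_low_distance))
  invisible(x)
}
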