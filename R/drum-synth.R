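# Synthetic drums, species, trees, trait histories and geographic ranges.
#
# The generator emulates the statistical shape of a clade-wide drumming
# dataset: ~92 species, 3-39 drums per species, six structural drumming
# types, and an ultrametric phylogeny with a crown age around 22.5 Myr.

#' The six drumming types
#'
#' Returns the drumming-type codes in their structural-complexity order
#' (the order used by the sequential transition models):
#' SF (steady fast), SS (steady slow), DK (double knock), AC (acceleration),
#' RS (regular sequences), IS (irregular sequences).
#'
#' @return Character vector of length 6.
#' @export
drum_types <- function() c("SF", "SS", "DK", "AC", "RS", "IS")

# Per-type generative prototypes at full separation. `rate` is the
# intra-bout pulse rate (strikes/s), `accel` the per-strike multiplicative
# change of the inter-pulse interval (<1 accelerates), `amp_decay` the
# per-strike amplitude factor, `bout_mean`/`bout_cv` the bout-size
# distribution (NA = single bout) and `gap` the inter-bout gap in seconds.
.type_prototypes <- function() {
  list(
    SF = list(rate = 28, n_strikes = 26, accel = 1,    amp_decay = 1,
              bout_mean = NA, bout_cv = 0,    gap = NA),
    SS = list(rate = 11, n_strikes = 14, accel = 1,    amp_decay = 1,
              bout_mean = NA, bout_cv = 0,    gap = NA),
    DK = list(rate = 14, n_strikes = 8,  accel = 1,    amp_decay = 1,
              bout_mean = 2,  bout_cv = 0,    gap = 0.8),
    AC = list(rate = 13, n_strikes = 20, accel = 0.94, amp_decay = 0.955,
              bout_mean = NA, bout_cv = 0,    gap = NA),
    RS = list(rate = 20, n_strikes = 25, accel = 1,    amp_decay = 1,
              bout_mean = 5,  bout_cv = 0.06, gap = 0.5),
    IS = list(rate = 20, n_strikes = 25, accel = 1,    amp_decay = 1,
              bout_mean = 5,  bout_cv = 0.55, gap = 0.5)
  )
}

# Structureless prototype every type collapses onto at separation = 0.
.neutral_prototype <- function() {
  list(rate = 16, n_strikes = 20, accel = 1, amp_decay = 1,
       bout_mean = NA, bout_cv = 0, gap = NA)
}

# Geometric interpolation between the neutral prototype and a type prototype.
.effective_prototype <- function(type, separation) {
  protos <- .type_prototypes()
  if (!type %in% names(protos))
    stop_("unknown drum_type '%s'; expected one of %s", type,
          paste(drum_types(), collapse = ", "))
  p <- protos[[type]]
  n <- .neutral_prototype()
  s <- separation
  gi <- function(a, b) exp((1 - s) * log(a) + s * log(b)) # geometric blend
  eff <- list(
    rate      = gi(n$rate, p$rate),
    n_strikes = gi(n$n_strikes, p$n_strikes),
    accel     = gi(n$accel, p$accel),
    amp_decay = gi(n$amp_decay, p$amp_decay),
    bout_cv   = s * p$bout_cv
  )
  ipi <- 1 / eff$rate
  if (is.na(p$bout_mean)) {
    eff$bout_mean <- Inf           # single bout
    eff$gap <- ipi
  } else {
    # at s = 0 the gap equals the intra-bout interval, so bout structure
    # vanishes smoothly
    eff$bout_mean <- gi(n$n_strikes, p$bout_mean)
    eff$gap <- ipi * (p$gap / ipi)^s
  }
  eff
}

#' Build a species-level drum generator model
#'
#' Draws species-specific generative parameters around the (separation-scaled)
#' prototype of a drumming type. `separation` dials how far the six type
#' prototypes sit from a common structureless prototype: at 0 all types
#' coincide (type labels carry no acoustic signal), at 1 (default) they are
#' fully distinct.
#'
#' @param species_id Species identifier.
#' @param drum_type One of [drum_types()].
#' @param separation Non-negative type-separability dial (default 1).
#' @param between_species_cv Lognormal coefficient of variation applied to the
#'   continuous parameters across species of the same type.
#' @param within_species_cv Coefficient of variation applied per drum.
#' @param seed Optional RNG seed.
#' @return An object of class `species_model`.
#' @export
species_model <- function(species_id, drum_type, separation = 1,
                          between_species_cv = 0.10,
                          within_species_cv = 0.06, seed = NULL) {
  stopifnot(within_species_cv >= 0, between_species_cv >= 0, separation >= 0)
  eff <- .effective_prototype(drum_type, separation)
  with_seed(seed, {
    jit <- function(x) x * exp(stats::rnorm(1, 0, between_species_cv))
    tp <- list(
      rate      = jit(eff$rate),
      n_strikes = max(4, jit(eff$n_strikes)),
      accel     = eff$accel,
      amp_decay = eff$amp_decay,
      bout_mean = if (is.finite(eff$bout_mean)) max(1.5, jit(eff$bout_mean)) else Inf,
      bout_cv   = eff$bout_cv,
      gap       = jit(eff$gap),
      peak_freq_mean = max(200, stats::rnorm(1, 1500, 300)),
      peak_freq_sd   = 60
    )
    # keep the defining pulse-rate property of the steady types whenever the
    # separation-scaled prototype itself satisfies it
    if (drum_type == "SF" && eff$rate > 20) tp$rate <- max(tp$rate, 20.2)
    if (drum_type == "SS" && eff$rate < 20) tp$rate <- min(tp$rate, 19.8)
    structure(list(species_id = as.character(species_id),
                   drum_type = drum_type,
                   type_params = tp,
                   within_species_cv = within_species_cv),
              class = "species_model")
  })
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("species_model '%s' (type %s): rate %.1f strikes/s, ~%.0f strikes\n",
              x$species_id, x$drum_type, x$type_params$rate,
              x$type_params$n_strikes))
  invisible(x)
}

# Drum constructor with invariant checks.
new_drum <- function(species_id, strike_times, amplitudes, peak_freq) {
  if (length(strike_times) < 2)
    stop_("a drum needs at least 2 strikes")
  if (any(diff(strike_times) <= 0))
    stop_("strike_times must be strictly increasing")
  if (length(amplitudes) != length(strike_times))
    stop_("amplitudes and strike_times lengths differ")
  amplitudes <- amplitudes / max(amplitudes)
  structure(list(species_id = as.character(species_id),
                 strike_times = strike_times - strike_times[1],
                 amplitudes = amplitudes,
                 peak_freq = peak_freq),
            class = "drum")
}

#' @export
print.drum <- function(x, ...) {
  cat(sprintf("drum of '%s': %d strikes over %.2f s, peak %.0f Hz\n",
              x$species_id, length(x$strike_times),
              max(x$strike_times), x$peak_freq))
  invisible(x)
}

#' Generate one drum from a species model
#'
#' Realizes the type's structural signature: steady types have constant-mean
#' inter-pulse intervals (SF above, SS below 20 strikes/s); AC shortens
#' intervals and attenuates amplitudes along the drum; RS/IS produce bouts
#' with low/high bout-size variance; DK produces repeated two-strike units.
#'
#' @param model A [species_model()].
#' @param seed Optional RNG seed.
#' @return A `drum`.
#' @export
generate_drum <- function(model, seed = NULL) {
  stopifnot(inherits(model, "species_model"))
  tp <- model$type_params
  cv <- model$within_species_cv
  with_seed(seed, {
    jit <- function(x) x * exp(stats::rnorm(1, 0, cv))
    rate <- jit(tp$rate)
    gap <- jit(tp$gap)
    n <- max(4, round(jit(tp$n_strikes)))
    # bout sizes
    if (is.finite(tp$bout_mean)) {
      sizes <- integer(0)
      while (sum(sizes) < n) {
        s <- round(stats::rnorm(1, tp$bout_mean, tp$bout_cv * tp$bout_mean))
        sizes <- c(sizes, max(1, s))
      }
      excess <- sum(sizes) - n
      if (excess > 0) {
        if (sizes[length(sizes)] > excess) {
          sizes[length(sizes)] <- sizes[length(sizes)] - excess
        } else sizes <- sizes[-length(sizes)]
      }
      n <- sum(sizes)
    } else sizes <- n
    if (n < 2) { sizes <- c(2); n <- 2 }
    bout_of <- rep(seq_along(sizes), sizes)
    ipi0 <- 1 / rate
    jitter_cv <- 0.04
    intervals <- numeric(n - 1)
    for (i in 2:n) {
      base <- if (bout_of[i] != bout_of[i - 1]) gap else ipi0 * tp$accel^(i - 2)
      intervals[i - 1] <- base * exp(stats::rnorm(1, 0, jitter_cv))
    }
    times <- c(0, cumsum(intervals))
    amps <- tp$amp_decay^(seq_len(n) - 1) * exp(stats::rnorm(n, 0, 0.05))
    pf <- max(100, stats::rnorm(1, tp$peak_freq_mean, tp$peak_freq_sd))
    new_drum(model$species_id, times, amps, pf)
  })
}

#' Generate a synthetic clade-wide drum dataset
#'
#' Every species is assigned one drumming type; species-level generator
#' parameters disperse around separation-scaled type prototypes, so the
#' ground-truth types are recoverable by clustering when `separation` is
#' high and carry no signal at `separation = 0`. Ground-truth labels and
#' models are kept for recovery experiments.
#'
#' @param n_species Number of species (>= 2).
#' @param drums_per_species Integer range (min, max) of drums per species.
#' @param type_proportions Named numeric vector over [drum_types()] summing
#'   to 1 (largest-remainder allocation of species counts).
#' @param separation Type-separability dial, see [species_model()].
#' @param within_species_cv,between_species_cv Generator dispersions.
#' @param seed Optional RNG seed.
#' @return A `drum_dataset`: drums, species table with ground-truth types,
#'   and the species models.
#' @export
generate_dataset <- function(n_species = 92,
                             drums_per_species = c(3, 39),
                             type_proportions = c(SF = 0.25, SS = 0.22,
                                                  DK = 0.10, AC = 0.27,
                                                  RS = 0.08, IS = 0.08),
                             separation = 1,
                             within_species_cv = 0.06,
                             between_species_cv = 0.10,
                             seed = NULL) {
  if (n_species < 2) stop_("n_species must be at least 2")
  stopifnot(length(drums_per_species) == 2,
            drums_per_species[1] >= 2,
            drums_per_species[1] <= drums_per_species[2])
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop_("type_proportions must sum to 1")
  bad <- setdiff(names(type_proportions), drum_types())
  if (length(bad)) stop_("unknown drum_type '%s'", bad[1])

  # largest-remainder allocation of species to types
  raw <- type_proportions * n_species
  counts <- floor(raw)
  rem <- n_species - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  types_pool <- rep(names(counts), counts)

  with_seed(seed, {
    ids <- sprintf("sp%03d", seq_len(n_species))
    types <- sample(types_pool)
    ndr <- sample(seq(drums_per_species[1], drums_per_species[2]),
                  n_species, replace = TRUE)
    models <- vector("list", n_species)
    drums <- list()
    for (i in seq_len(n_species)) {
      models[[i]] <- species_model(ids[i], types[i], separation,
                                   between_species_cv, within_species_cv)
      drums <- c(drums, lapply(seq_len(ndr[i]),
                               function(j) generate_drum(models[[i]])))
    }
    names(models) <- ids
    structure(list(
      drums = drums,
      species = data.frame(species_id = ids, drum_type = types,
                           n_drums = ndr, stringsAsFactors = FALSE),
      models = models,
      params = list(n_species = n_species,
                    drums_per_species = drums_per_species,
                    separation = separation,
                    within_species_cv = within_species_cv,
                    between_species_cv = between_species_cv)
    ), class = "drum_dataset")
  })
}

#' Build a dataset from a fixed species -> type assignment
#'
#' Like [generate_dataset()], but the drumming type of every species is
#' supplied (e.g. tip states evolved along a tree) rather than drawn from
#' proportions.
#'
#' @param types Named character vector species_id -> drum type.
#' @param drums_per_species Integer range (min, max) of drums per species.
#' @param separation,within_species_cv,between_species_cv See
#'   [generate_dataset()].
#' @param seed Optional RNG seed.
#' @return A `drum_dataset`.
#' @export
dataset_from_types <- function(types, drums_per_species = c(3, 39),
                               separation = 1, within_species_cv = 0.06,
                               between_species_cv = 0.10, seed = NULL) {
  if (is.null(names(types)) || length(types) < 2)
    stop_("types must be a named vector over >= 2 species")
  bad <- setdiff(unique(types), drum_types())
  if (length(bad)) stop_("unknown drum_type '%s'", bad[1])
  ids <- names(types)
  with_seed(seed, {
    ndr <- sample(seq(drums_per_species[1], drums_per_species[2]),
                  length(ids), replace = TRUE)
    models <- vector("list", length(ids))
    drums <- list()
    for (i in seq_along(ids)) {
      models[[i]] <- species_model(ids[i], types[[i]], separation,
                                   between_species_cv, within_species_cv)
      drums <- c(drums, lapply(seq_len(ndr[i]),
                               function(j) generate_drum(models[[i]])))
    }
    names(models) <- ids
    structure(list(
      drums = drums,
      species = data.frame(species_id = ids, drum_type = unname(types),
                           n_drums = ndr, stringsAsFactors = FALSE),
      models = models,
      params = list(n_species = length(ids),
                    drums_per_species = drums_per_species,
                    separation = separation,
                    within_species_cv = within_species_cv,
                    between_species_cv = between_species_cv)
    ), class = "drum_dataset")
  })
}

#' @export
print.drum_dataset <- function(x, ...) {
  cat(sprintf("drum_dataset: %d species, %d drums, %d ground-truth types\n",
              nrow(x$species), length(x$drums),
              length(unique(x$species$drum_type))))
  if (!is.null(x$pca))
    cat(sprintf("  features + PCA attached (%d PCs retained, %.0f%% variance)\n",
                length(x$pca$retained),
                100 * sum(x$pca$var_explained[x$pca$retained])))
  invisible(x)
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Constant-rate birth-death tree conditioned on the number of extant tips,
#' rescaled so that the crown (root) age equals `crown_age_myr`.
#'
#' @param n_tips Number of tips.
#' @param birth,death Speciation and extinction rates (birth > death >= 0).
#' @param crown_age_myr Crown age in Myr (default 22.5).
#' @param tip_labels Optional tip labels (default t1..tn).
#' @param seed Optional RNG seed.
#' @param max_tries Resampling cap when the process goes extinct.
#' @return An ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, birth = 0.2, death = 0,
                          crown_age_myr = 22.5, tip_labels = NULL,
                          seed = NULL, max_tries = 100) {
  stopifnot(n_tips >= 2, birth > death, death >= 0, crown_age_myr > 0)
  with_seed(seed, {
    tree <- NULL
    for (i in seq_len(max_tries)) {
      tree <- tryCatch(ape::rphylo(n_tips, birth, death),
                       error = function(e) NULL)
      if (!is.null(tree)) break
    }
    if (is.null(tree))
      stop_("birth-death simulation failed to reach %d tips after %d tries",
            n_tips, max_tries)
    tree$edge.length <- tree$edge.length *
      crown_age_myr / tree_root_age(tree)
    if (!is.null(tip_labels)) {
      stopifnot(length(tip_labels) == n_tips)
      tree$tip.label <- as.character(tip_labels)
    }
    assert_ultrametric(tree)
    tree
  })
}

# Validate a CTMC generator matrix; errors name the offending row.
validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop_("Q must be a square matrix")
  k <- nrow(Q)
  for (i in seq_len(k)) {
    off <- Q[i, -i]
    if (any(off < -1e-12))
      stop_("Q row %d has a negative off-diagonal rate", i)
    if (abs(sum(Q[i, ])) > 1e-8)
      stop_("Q row %d does not sum to 0 (sum = %g)", i, sum(Q[i, ]))
  }
  invisible(TRUE)
}

#' Simulate discrete character evolution on a tree
#'
#' Forward continuous-time Markov simulation with exponential waiting times
#' along branches; the full substitution history is retained.
#'
#' @param tree A `phylo`.
#' @param Q Generator matrix (rows sum to 0, off-diagonals >= 0); state names
#'   taken from `rownames(Q)` or 1..k.
#' @param root_state State (name or index) at the root.
#' @param seed Optional RNG seed.
#' @return List with `tip_states`, `node_states` (internal nodes, root first)
#'   and `history` (per-edge change records).
#' @export
evolve_discrete <- function(tree, Q, root_state, seed = NULL) {
  validate_q(Q)
  k <- nrow(Q)
  states <- rownames(Q) %||% as.character(seq_len(k))
  root_idx <- if (is.character(root_state)) match(root_state, states)
              else as.integer(root_state)
  if (is.na(root_idx) || root_idx < 1 || root_idx > k)
    stop_("root_state not in the state set")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  with_seed(seed, {
    st <- integer(ntip + tree$Nnode)
    st[root] <- root_idx
    history <- vector("list", nrow(tree_cw$edge))
    for (e in seq_len(nrow(tree_cw$edge))) {
      par <- tree_cw$edge[e, 1]; chi <- tree_cw$edge[e, 2]
      len <- tree_cw$edge.length[e]
      s <- st[par]; t0 <- 0
      changes <- NULL
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) break
        w <- stats::rexp(1, rate)
        if (t0 + w > len) break
        t0 <- t0 + w
        probs <- Q[s, ]; probs[s] <- 0
        s_new <- sample.int(k, 1, prob = probs)
        changes <- rbind(changes, c(time = t0, from = s, to = s_new))
        s <- s_new
      }
      st[chi] <- s
      history[[e]] <- changes
    }
    tip_states <- stats::setNames(states[st[seq_len(ntip)]], tree$tip.label)
    node_states <- stats::setNames(states[st[(ntip + 1):(ntip + tree$Nnode)]],
                                   as.character((ntip + 1):(ntip + tree$Nnode)))
    list(tip_states = tip_states, node_states = node_states,
         history = history, states = states)
  })
}

#' Pagel's lambda branch-length transform
#'
#' Scales internal node heights by `lambda` while keeping tip heights fixed;
#' defined for ultrametric trees when `lambda < 1`.
#'
#' @param tree An ultrametric `phylo`.
#' @param lambda Value in [0, 1].
#' @return Transformed `phylo`.
#' @export
lambda_transform <- function(tree, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (lambda == 1) return(tree)
  assert_ultrametric(tree)
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  newdepth <- depth
  internal <- (ntip + 1):(ntip + tree$Nnode)
  newdepth[internal] <- lambda * depth[internal]
  out <- tree
  out$edge.length <- newdepth[tree$edge[, 2]] - newdepth[tree$edge[, 1]]
  out
}

#' Simulate Brownian motion on a tree
#'
#' Gaussian increments with variance `sigma2 * branch length` on the
#' lambda-transformed tree.
#'
#' @param tree A `phylo` (ultrametric if `lambda < 1`).
#' @param sigma2 BM rate (> 0, or 0 for a degenerate constant trait).
#' @param root_value Trait value at the root.
#' @param lambda Pagel transform applied before simulation (default 1).
#' @param seed Optional RNG seed.
#' @return List with named `tip_values` and `node_values`.
#' @export
evolve_bm <- function(tree, sigma2, root_value = 0, lambda = 1, seed = NULL) {
  stopifnot(sigma2 >= 0)
  tr <- lambda_transform(tree, lambda)
  ntip <- ape::Ntip(tr)
  tr <- ape::reorder.phylo(tr, "cladewise")
  with_seed(seed, {
    val <- numeric(ntip + tr$Nnode)
    val[ntip + 1L] <- root_value
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
      val[chi] <- val[par] +
        stats::rnorm(1, 0, sqrt(sigma2 * tr$edge.length[e]))
    }
    list(tip_values = stats::setNames(val[seq_len(ntip)], tree$tip.label),
         node_values = stats::setNames(val[(ntip + 1):(ntip + tr$Nnode)],
                                       as.character((ntip + 1):(ntip + tr$Nnode))))
  })
}

#' Generate rectangular species ranges
#'
#' Axis-aligned rectangles in abstract map units, centred on a jittered
#' disjoint grid. `overlap_level` grows the rectangles from small disjoint
#' boxes (`overlap_level = 0`, no sympatric pairs) up to ranges spanning the
#' whole map (`overlap_level = 1`, every pair sympatric), so intermediate
#' values yield a graded mixture of sympatric and allopatric pairs.
#'
#' @param n_species Number of species.
#' @param overlap_level Value in [0, 1].
#' @param species_ids Optional identifiers (default sp001..).
#' @param box_size Nominal box side length.
#' @param seed Optional RNG seed.
#' @return data.frame with species_id, xmin/xmax/ymin/ymax and area.
#' @export
generate_ranges <- function(n_species, overlap_level, species_ids = NULL,
                            box_size = 1, seed = NULL) {
  stopifnot(overlap_level >= 0, overlap_level <= 1, n_species >= 1)
  if (is.null(species_ids)) species_ids <- sprintf("sp%03d", seq_len(n_species))
  stopifnot(length(species_ids) == n_species)
  m <- ceiling(sqrt(n_species))
  spacing <- 3 * box_size
  gx <- ((seq_len(n_species) - 1) %% m) * spacing
  gy <- ((seq_len(n_species) - 1) %/% m) * spacing
  extent <- spacing * (m - 1) + box_size
  with_seed(seed, {
    ord <- sample(n_species)
    gx <- gx[ord]; gy <- gy[ord]
    cx <- gx + stats::runif(n_species, -0.4, 0.4) * box_size
    cy <- gy + stats::runif(n_species, -0.4, 0.4) * box_size
    half <- box_size * stats::runif(n_species, 0.45, 0.55) +
      overlap_level * (extent / 2) * stats::runif(n_species, 1, 1.2)
    data.frame(species_id = species_ids,
               xmin = cx - half, xmax = cx + half,
               ymin = cy - half, ymax = cy + half,
               area = (2 * half)^2,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic species-pair records with optional character displacement
#'
#' Builds a full pairwise table (acoustic distance, classification-index-like
#' score, patristic distance, sympatry flag) from a simulated tree, simulated
#' Brownian acoustic traits and generated ranges. When `displacement > 0`,
#' sympatric pairs receive an extra acoustic divergence that decays with
#' phylogenetic distance (scale `pd_scale` Myr), i.e. displacement is
#' concentrated among close relatives, mirroring the pattern the
#' displacement test is designed to detect.
#'
#' @param n_species Number of species.
#' @param displacement Injected effect size in units of the baseline
#'   acoustic-distance SD at zero phylogenetic distance (0 = null model).
#' @param overlap_level Range overlap dial, see [generate_ranges()].
#' @param pd_scale Decay scale (Myr) of the displacement effect.
#' @param seed Optional RNG seed.
#' @return data.frame of pair records (class `pair_records`).
#' @export
simulate_displacement_data <- function(n_species = 50, displacement = 0,
                                       overlap_level = 0.2, pd_scale = 15,
                                       seed = NULL) {
  with_seed(seed, {
    ids <- sprintf("sp%03d", seq_len(n_species))
    tree <- simulate_tree(n_species, tip_labels = ids)
    pd <- phylo_distance_matrix(tree)
    traits <- sapply(1:5, function(j) evolve_bm(tree, sigma2 = 1)$tip_values)
    ad <- as.matrix(stats::dist(traits))
    ranges <- generate_ranges(n_species, overlap_level, species_ids = ids)
    ct <- sympatric_pairs(ranges)
    pr <- ct$pairs
    pr$patristic <- pd[cbind(pr$species_a, pr$species_b)]
    base_sd <- stats::sd(ad[upper.tri(ad)])
    pr$acoustic_dist <- ad[cbind(pr$species_a, pr$species_b)] +
      ifelse(pr$sympatric,
             displacement * base_sd * exp(-pr$patristic / pd_scale), 0)
    med <- stats::median(pr$acoustic_dist)
    pr$ci <- pmin(100, pmax(-100,
      100 * (1 - exp(-pr$acoustic_dist / med)) + stats::rnorm(nrow(pr), 0, 5)))
    class(pr) <- c("pair_records", class(pr))
    pr
  })
}
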