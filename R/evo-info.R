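# Information-through-time reconstruction and the analytic
# diversifying-selection scenarios.

#' Branches crossing a time slice
#'
#' @param tree A `phylo` (ultrametric interpretation: time measured in Myr
#'   before the present, 0 = tips).
#' @param t Time slice, 0 <= t <= root age.
#' @return Integer vector of edge indices (rows of `tree$edge`) whose child
#'   age <= t < parent age.
#' @export
lineages_at <- function(tree, t) {
  ra <- tree_root_age(tree)
  if (t < -1e-9 || t > ra + 1e-9)
    stop_("t = %g outside [0, root age = %g]", t, ra)
  age <- node_ages(tree)
  # tolerance matches the package-wide ultrametricity tolerance (1e-6 Myr)
  which(age[tree$edge[, 2]] <= t + 1e-6 & age[tree$edge[, 1]] > t + 1e-6)
}

#' Interpolated ancestral type distributions at a time slice
#'
#' For a lineage crossing time `t` on the branch between nodes u (older) and
#' v (younger), the distribution is the length-proportional linear blend of
#' u's and v's marginal distributions; tips contribute their (posterior)
#' state distributions, point masses for known states.
#'
#' @param tree A `phylo`.
#' @param asr An `asr_result` covering all internal nodes.
#' @param t Time slice (Myr before present), 0 <= t <= root age.
#' @return Matrix (crossing lineages x states); rownames are the younger
#'   node ids; each row sums to 1. The edge indices are in attribute
#'   `"edges"`.
#' @export
interpolate_type_distributions <- function(tree, asr, t) {
  stopifnot(inherits(asr, "asr_result"))
  edges <- lineages_at(tree, t)
  age <- node_ages(tree)
  allP <- rbind(asr$tip_probs, asr$node_probs)  # rows 1..(ntip+nnode)
  out <- matrix(NA_real_, length(edges), length(asr$states),
                dimnames = list(as.character(tree$edge[edges, 2]),
                                asr$states))
  for (i in seq_along(edges)) {
    e <- edges[i]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    span <- age[u] - age[v]
    w <- if (span <= 0) 1 else (age[u] - t) / span  # weight on the child
    w <- min(1, max(0, w))
    p <- pmax((1 - w) * allP[u, ] + w * allP[v, ], 0)
    out[i, ] <- p / sum(p)
  }
  attr(out, "edges") <- edges
  out
}

# Descendant tip indices per node, via one postorder sweep.
.descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  desc
}

#' Information-through-time bootstrap trajectory
#'
#' At each time slice (step `dt` Myr from the present), each reconstructed
#' lineage samples a drumming type from its interpolated ancestral
#' distribution and then an extant species of that type among the
#' descendants of the branch's younger node (falling back to any extant
#' species of the type when no descendant matches). The sampled
#' pseudo-species' drums rebuild the LOO confusion matrix, giving MI and
#' ceiling-normalized MI; means and SDs are taken over `n_boot` bootstrap
#' replicates. With `freeze_types = TRUE`, sampling is restricted to the
#' (modal) types already present at the oldest grid point — the "without
#' the onset of new drumming types" variant.
#'
#' @param tree Ultrametric `phylo` whose tips are dataset species.
#' @param asr An `asr_result` (typically the model-averaged one).
#' @param dataset A dataset processed by [standardize_and_pca()].
#' @param types Named species -> type vector; defaults to ground truth.
#' @param dt Time step in Myr (default 1).
#' @param n_boot Bootstrap replicates (default 30).
#' @param seed Optional RNG seed.
#' @param freeze_types Restrict to the types present at the oldest slice.
#' @return data.frame of class `info_trajectory`: time, n_lineages, mi_mean,
#'   mi_sd, nmi_mean, nmi_sd; attributes `n_boot`, `dt`, `variant`.
#' @export
info_through_time <- function(tree, asr, dataset, types = NULL, dt = 1,
                              n_boot = 30, seed = NULL,
                              freeze_types = FALSE) {
  stopifnot(!is.null(dataset$pca))
  if (is.null(types))
    types <- stats::setNames(dataset$species$drum_type,
                             dataset$species$species_id)
  labs <- tree$tip.label
  if (!all(labs %in% names(types)) ||
      !all(labs %in% dataset$drum_species))
    stop_("tree tips must all be dataset species with a type")
  sc <- pc_scores(dataset)
  states <- asr$states
  desc <- .descendant_tips(tree)
  by_type <- split(labs, types[labs])

  ra <- tree_root_age(tree)
  grid <- seq(0, ra - 1e-9, by = dt)
  keep <- vapply(grid, function(t) length(lineages_at(tree, t)) >= 2,
                 logical(1))
  if (any(!keep))
    warning("skipping time points with fewer than 2 lineages")
  grid <- grid[keep]

  # only types with extant representatives can be sampled
  allowed <- intersect(states, names(by_type))
  if (freeze_types) {
    oldest <- interpolate_type_distributions(tree, asr, max(grid))
    allowed <- intersect(unique(states[apply(oldest, 1, which.max)]),
                         allowed)
    if (!length(allowed)) allowed <- intersect(states, names(by_type))
  }

  with_seed(seed, {
    res <- lapply(grid, function(t) {
      P <- interpolate_type_distributions(tree, asr, t)
      edges <- attr(P, "edges")
      mi <- nmi <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        chosen <- character(length(edges))
        for (i in seq_along(edges)) {
          p <- P[i, ]
          p[!states %in% allowed] <- 0
          if (sum(p) <= 0) p[states %in% allowed] <- 1
          ty <- states[sample.int(length(states), 1, prob = p)]
          cand <- intersect(labs[desc[[tree$edge[edges[i], 2]]]],
                            by_type[[ty]] %||% character(0))
          if (!length(cand)) cand <- by_type[[ty]]
          chosen[i] <- if (length(cand) == 1) cand else sample(cand, 1)
        }
        spp <- unique(chosen)
        if (length(spp) < 2) { mi[b] <- NA; nmi[b] <- NA; next }
        idx <- sc$labels %in% spp
        cm <- loo_confusion(sc$scores[idx, , drop = FALSE], sc$labels[idx])
        mi[b] <- overall_mi(cm)
        nmi[b] <- mi[b] / log2(length(spp))
      }
      c(time = t, n_lineages = length(edges),
        mi_mean = mean(mi, na.rm = TRUE), mi_sd = sd0(mi[!is.na(mi)]),
        nmi_mean = mean(nmi, na.rm = TRUE), nmi_sd = sd0(nmi[!is.na(nmi)]))
    })
    out <- as.data.frame(do.call(rbind, res))
    attr(out, "n_boot") <- n_boot
    attr(out, "dt") <- dt
    attr(out, "variant") <- if (freeze_types) "frozen_types" else "full"
    class(out) <- c("info_trajectory", class(out))
    out
  })
}

#' Analytic diversifying-selection scenario trajectories
#'
#' Converts a species-count trajectory into (normalized) mutual information
#' under two extreme scenarios. With no diversifying selection, new species
#' are as similar to existing ones as the initial pair was to each other, so
#' the per-species probability of correct detection decays as
#' p_c = p2^(n_s - 1); with strong diversifying selection p_c stays at p2.
#' p_c is converted to MI via the random-misclassification relation and
#' normalized by log2(n_s).
#'
#' @param p2 Initial pairwise probability of correct detection (0.5 < p2 <= 1).
#' @param n_s Non-decreasing integer vector of species counts, starting >= 2.
#' @param mode "none" or "strong".
#' @return data.frame of class `scenario_trajectory`: n_s, p_c, mi, mi_norm,
#'   clamped (TRUE where p_c hit the chance floor under mode "none").
#' @export
scenario_trajectory <- function(p2, n_s, mode = c("none", "strong")) {
  mode <- match.arg(mode)
  stopifnot(p2 > 0.5, p2 <= 1, all(n_s >= 2), !is.unsorted(n_s))
  pc <- switch(mode, none = p2^(n_s - 1), strong = rep(p2, length(n_s)))
  floorp <- 1 / n_s
  clamped <- pc < floorp
  if (any(clamped)) {
    warning(sprintf("p_c below chance for n_s >= %d: clamped to 1/n_s (0 bits)",
                    min(n_s[clamped])))
    pc[clamped] <- floorp[clamped]
  }
  mi <- vapply(seq_along(n_s), function(i) mi_from_pc(pc[i], n_s[i]),
               numeric(1))
  mi[clamped] <- 0   # information floor at chance
  out <- data.frame(n_s = n_s, p_c = pc, mi = mi,
                    mi_norm = mi / log2(n_s), clamped = clamped)
  class(out) <- c("scenario_trajectory", class(out))
  out
}
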