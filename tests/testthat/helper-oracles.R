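# Independent oracles and shared fixtures for the test suite.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Exhaustive-summation likelihood over all internal-state assignments:
# the brute-force counterpart of the pruning algorithm (<= 5 tips).
enum_mk_loglik <- function(tree, tip_states, Q, states = rownames(Q)) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  k <- length(states)
  tipP <- matrix(0, ntip, k, dimnames = list(tree$tip.label, states))
  tipP[cbind(tree$tip.label, tip_states[tree$tip.label])] <- 1
  grids <- rep(list(seq_len(k)), nnode)
  combos <- as.matrix(expand.grid(grids))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign_int <- combos[r, ]
    prob <- 1 / k   # equiprobable root prior
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      P <- as.matrix(Matrix::expm(Q * tree$edge.length[e]))
      sp <- assign_int[par - ntip]
      if (chi <= ntip) {
        prob <- prob * sum(P[sp, ] * tipP[chi, ])
      } else {
        prob <- prob * P[sp, assign_int[chi - ntip]]
      }
    }
    total <- total + prob
  }
  log(total)
}

# Brute-force marginal ancestral distribution at one internal node.
enum_marginal <- function(tree, tip_states, Q, node, states = rownames(Q)) {
  ntip <- ape::Ntip(tree)
  k <- length(states)
  out <- numeric(k)
  for (s in seq_len(k)) {
    # joint probability of tips and node = s, by enumeration over the others
    tipP <- matrix(0, ntip, k, dimnames = list(tree$tip.label, states))
    tipP[cbind(tree$tip.label, tip_states[tree$tip.label])] <- 1
    combos <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
    combos <- combos[combos[, node - ntip] == s, , drop = FALSE]
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      assign_int <- combos[r, ]
      prob <- 1 / k
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
        P <- as.matrix(Matrix::expm(Q * tree$edge.length[e]))
        sp <- assign_int[par - ntip]
        prob <- prob * if (chi <= ntip) sum(P[sp, ] * tipP[chi, ])
                       else P[sp, assign_int[chi - ntip]]
      }
      tot <- tot + prob
    }
    out[s] <- tot
  }
  out / sum(out)
}

# Naive Lance-Williams Ward.D2 agglomeration: returns merge heights and the
# partition trace, independently of stats::hclust.
ward_lw <- function(D) {
  D <- as.matrix(D)^2          # work with squared distances
  n <- nrow(D)
  size <- rep(1, n)
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      i <- active[ii]; j <- active[jj]
      if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestd)
    # Lance-Williams update for Ward.D2 on squared distances
    for (l in setdiff(active, c(i, j))) {
      ai <- (size[i] + size[l]) / (size[i] + size[j] + size[l])
      aj <- (size[j] + size[l]) / (size[i] + size[j] + size[l])
      b <- -size[l] / (size[i] + size[j] + size[l])
      D[i, l] <- D[l, i] <- ai * D[i, l] + aj * D[j, l] + b * D[i, j]
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
    partitions[[step]] <- lapply(active, function(a) sort(members[[a]]))
  }
  list(heights = heights, partitions = partitions)
}

# Mutual information of a confusion matrix via the joint-entropy identity
# I(A; M) = H(A) + H(M) - H(A, M) with uniform p(A).
joint_entropy_mi <- function(M) {
  n <- nrow(M)
  J <- M / n                       # joint p(A, M)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  H(rep(1 / n, n)) + H(colSums(J)) - H(as.vector(J))
}

# Brute-force LOO nearest-centroid classifier with pooled within-class
# covariance and uniform prior (the linear-discriminant rule).
loo_centroid_oracle <- function(X, labels) {
  g <- factor(labels, levels = sort(unique(labels)))
  lev <- levels(g)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; gtr <- g[-i]
    mus <- t(sapply(lev, function(l) colMeans(Xtr[gtr == l, , drop = FALSE])))
    S <- Reduce(`+`, lapply(lev, function(l) {
      Xc <- sweep(Xtr[gtr == l, , drop = FALSE], 2,
                  colMeans(Xtr[gtr == l, , drop = FALSE]))
      crossprod(Xc)
    })) / (nrow(Xtr) - length(lev))
    Si <- solve(S)
    d2 <- apply(mus, 1, function(m) {
      v <- X[i, ] - m
      drop(v %*% Si %*% v)
    })
    pred[i] <- lev[which.min(d2)]
  }
  tab <- table(actual = g, predicted = factor(pred, levels = lev))
  sweep(unclass(tab), 1, rowSums(tab), "/")
}

# GLS/Laplacian oracle for BM ancestral states: ML node values minimize
# sum over edges (x_child - x_parent)^2 / length, tips fixed.
bm_asr_oracle <- function(tree, tip_values) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  A <- matrix(0, tree$Nnode, tree$Nnode)
  b <- numeric(tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    w <- 1 / tree$edge.length[e]
    pi_ <- par - ntip
    A[pi_, pi_] <- A[pi_, pi_] + w
    if (chi <= ntip) {
      b[pi_] <- b[pi_] + w * tip_values[tree$tip.label[chi]]
    } else {
      ci <- chi - ntip
      A[ci, ci] <- A[ci, ci] + w
      A[pi_, ci] <- A[pi_, ci] - w
      A[ci, pi_] <- A[ci, pi_] - w
    }
  }
  drop(solve(A, b))
}

# BM likelihood of a trait under the lambda transform, computed through the
# explicit multivariate-normal density (solve/determinant path).
lambda_loglik_oracle <- function(tree, x, lam) {
  C <- ape::vcv(tree)
  Cl <- C * lam; diag(Cl) <- diag(C)
  x <- x[rownames(Cl)]
  n <- length(x)
  Ci <- solve(Cl)
  one <- rep(1, n)
  mu <- drop(one %*% Ci %*% x) / drop(one %*% Ci %*% one)
  r <- x - mu
  s2 <- drop(r %*% Ci %*% r) / n
  -0.5 * (n * log(2 * pi * s2) + determinant(Cl)$modulus[1] + n)
}

# Shared 92-species dataset at default settings, built once per run.
.fixture_env <- new.env()
shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    ds <- generate_dataset(seed = 421)
    ds <- species_profiles(standardize_and_pca(feature_matrix(ds)))
    .fixture_env$ds <- ds
  }
  .fixture_env$ds
}

# Small clade with types evolved along the tree (so ancestral slices hold
# fewer types than the present), plus its fitted ASR.
evolved_clade <- function(seed, n_tips = 15) {
  ids <- sprintf("sp%03d", seq_len(n_tips))
  tree <- simulate_tree(n_tips, tip_labels = ids, seed = seed)
  Q <- build_q("ER", 0.01)$Q
  repeat {
    sim <- evolve_discrete(tree, Q, root_state = "AC", seed = seed)
    if (length(unique(sim$tip_states)) >= 3) break
    seed <- seed + 1000
  }
  types <- sim$tip_states
  ds <- dataset_from_types(types, drums_per_species = c(3, 6),
                           seed = seed + 7)
  ds <- suppressMessages(standardize_and_pca(feature_matrix(ds),
                                             drop_constant = TRUE))
  ds <- species_profiles(ds)
  fit <- fit_markov_model(tree, types,
                          "ER", states = drum_types(), n_restart = 2)
  list(tree = tree, types = types, dataset = ds,
       asr = marginal_asr(tree, types, fit))
}

random_stochastic_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  M <- M / rowSums(M)
  dimnames(M) <- list(letters[1:n], letters[1:n])
  M
}
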