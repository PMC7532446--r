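# Discrete (Mk-type) and continuous ancestral-state machinery: six rate
# parameterizations, pruning-algorithm likelihood with tip priors, marginal
# (empirical Bayes) reconstruction, AICc model averaging, Brownian-motion
# ancestral states, Pagel's lambda and patristic distances.

#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser with the contract checks used
#' throughout the package: labelled tips and branch lengths are required.
#'
#' @param path File path.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop_("Newick parse error in '%s': %s", path, conditionMessage(e)))
  if (is.null(tr)) stop_("Newick parse error in '%s'", path)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop_("tree in '%s' is missing branch lengths", path)
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop_("tree in '%s' has unlabeled tips", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Pairwise patristic distance matrix (Myr)
#'
#' Sum of branch lengths along the path between each pair of tips; for an
#' ultrametric tree this equals twice the age of the pair's most recent
#' common ancestor.
#'
#' @param tree A `phylo`.
#' @return Symmetric matrix with tip-label dimnames.
#' @export
phylo_distance_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[order(rownames(D)), order(colnames(D))]
}

# ---- rate models -----------------------------------------------------------

.mk_model_names <- function()
  c("ER", "SYM", "ARD", "SEQ_EQ", "SEQ_INC", "SEQ_REV")

#' Number of free rate parameters of a transition model
#'
#' @param model_name One of ER, SYM, ARD, SEQ_EQ, SEQ_INC, SEQ_REV.
#' @param k Number of states.
#' @return Integer parameter count.
#' @export
n_free_params <- function(model_name, k) {
  switch(model_name,
         ER = 1L,
         SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)),
         SEQ_EQ = 1L,
         SEQ_INC = 2L,
         SEQ_REV = as.integer(2 * (k - 1)),
         stop_("unknown transition model '%s'", model_name))
}

#' Build a transition-rate generator matrix
#'
#' Six parameterizations over an ordered state set (default the six drumming
#' types in their sequential order SF-SS-DK-AC-RS-IS): ER (one shared rate),
#' SYM (one rate per unordered pair), ARD (one per ordered pair, row-major
#' off-diagonal order), and three sequential models restricted to adjacent
#' moves along the state order: SEQ_EQ (one shared adjacent rate), SEQ_INC
#' (base rate and a geometric per-step multiplier along the order) and
#' SEQ_REV (each directed adjacent move free; parameters ordered forward,
#' backward per adjacency).
#'
#' @param model_name Model name, see [n_free_params()].
#' @param params Numeric parameter vector of the model's free length.
#' @param states Ordered state names (default [drum_types()]).
#' @return Object of class `transition_model` with the generator `Q`.
#' @export
build_q <- function(model_name, params, states = drum_types()) {
  k <- length(states)
  np <- n_free_params(model_name, k)
  if (length(params) != np)
    stop_("model %s with %d states expects %d parameters, got %d",
          model_name, k, np, length(params))
  if (any(params < 0) && model_name != "SEQ_INC")
    stop_("rates must be non-negative")
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (model_name == "ER") {
    Q[] <- params[1]
  } else if (model_name == "SYM") {
    idx <- 1
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- params[idx]; idx <- idx + 1
    }
  } else if (model_name == "ARD") {
    idx <- 1
    for (i in 1:k) for (j in 1:k) {
      if (i == j) next
      Q[i, j] <- params[idx]; idx <- idx + 1
    }
  } else if (model_name == "SEQ_EQ") {
    for (i in 1:(k - 1)) Q[i, i + 1] <- Q[i + 1, i] <- params[1]
  } else if (model_name == "SEQ_INC") {
    if (params[1] < 0 || params[2] < 0) stop_("rates must be non-negative")
    for (i in 1:(k - 1))
      Q[i, i + 1] <- Q[i + 1, i] <- params[1] * params[2]^(i - 1)
  } else if (model_name == "SEQ_REV") {
    for (i in 1:(k - 1)) {
      Q[i, i + 1] <- params[2 * i - 1]
      Q[i + 1, i] <- params[2 * i]
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(name = model_name, states = states, params = params,
                 Q = Q, n_free = np),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition_model %s: %d states, %d free parameter(s)\n",
              x$name, length(x$states), x$n_free))
  invisible(x)
}

# Factory returning P(t) = expm(Q t) via eigendecomposition, with a
# scaling-and-squaring fallback when Q is defective.
.q_expm_factory <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  usable <- !is.null(eg) && all(is.finite(Mod(eg$values)))
  Vi <- NULL
  if (usable) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    usable <- !is.null(Vi) && all(is.finite(Mod(Vi)))
  }
  function(t) {
    P <- if (usable) {
      Re(eg$vectors %*% (exp(eg$values * t) * Vi))
    } else {
      as.matrix(Matrix::expm(Q * t))
    }
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

# Normalize tip input (state vector or prior matrix) to an Ntip x k matrix
# of partial likelihoods ordered like tree$tip.label.
.tip_prior_matrix <- function(tree, tips, states) {
  labs <- tree$tip.label
  k <- length(states)
  if (is.matrix(tips) || is.data.frame(tips)) {
    tips <- as.matrix(tips)
    if (is.null(rownames(tips)) || !all(labs %in% rownames(tips)))
      stop_("tip prior matrix must have all tip labels as rownames")
    if (!all(states %in% colnames(tips)))
      stop_("tip prior matrix must have the states as colnames")
    P <- tips[labs, states, drop = FALSE]
    if (any(P < 0) || any(rowSums(P) <= 0))
      stop_("tip priors must be non-negative with positive row sums")
    return(P)
  }
  tips <- stats::setNames(as.character(tips), names(tips))
  if (is.null(names(tips)) || !all(labs %in% names(tips)))
    stop_("tip states must be named by tip label, covering every tip")
  bad <- setdiff(unique(tips[labs]), states)
  if (length(bad)) stop_("tip state '%s' not in the model's state set", bad[1])
  P <- matrix(0, length(labs), k, dimnames = list(labs, states))
  P[cbind(seq_along(labs), match(tips[labs], states))] <- 1
  P
}

# Pruning-algorithm log-likelihood with an equiprobable root prior.
.mk_loglik <- function(tree, tipP, Q, root_prior = NULL) {
  k <- ncol(tipP)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, ntip + tree$Nnode, k)
  L[seq_len(ntip), ] <- tipP
  Pfun <- .q_expm_factory(Q)
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    v <- as.vector(Pfun(po$edge.length[e]) %*% L[chi, ])
    s <- sum(v)
    if (s <= 0 || !is.finite(s)) return(-Inf)
    logscale <- logscale + log(s)
    L[par, ] <- L[par, ] * (v / s)
    s2 <- sum(L[par, ])
    if (s2 <= 0 || !is.finite(s2)) return(-Inf)
    logscale <- logscale + log(s2)
    L[par, ] <- L[par, ] / s2
  }
  root <- ntip + 1L
  logscale + log(sum(root_prior * L[root, ]))
}

#' Pruning-algorithm log-likelihood of tip data under a transition model
#'
#' Felsenstein's post-order algorithm with per-branch matrix exponentials
#' and an equiprobable root prior.
#'
#' @param tree A `phylo`.
#' @param tips Named character vector of tip states, or a tips x states
#'   prior matrix.
#' @param model A `transition_model` (see [build_q()]), or a generator
#'   matrix with state dimnames.
#' @return Log-likelihood (natural log).
#' @export
mk_loglik <- function(tree, tips, model) {
  Q <- if (inherits(model, "transition_model")) model$Q else as.matrix(model)
  if (is.null(rownames(Q))) stop_("Q needs state dimnames")
  validate_q(Q)
  tipP <- .tip_prior_matrix(tree, tips, rownames(Q))
  .mk_loglik(tree, tipP, Q)
}

#' Fit a continuous-time Markov model of discrete character evolution
#'
#' Maximum-likelihood rates via the pruning (post-order) algorithm with
#' per-branch matrix exponentials, an equiprobable root prior, bounded
#' optimization on the log-rate scale (bounds 1e-8 to 1e3 events/Myr) and
#' random multi-start restarts. Uncertain tips may be supplied as prior
#' probability vectors (e.g. 1/3 per state for an unknown drummer status).
#'
#' @param tree A `phylo`.
#' @param tips Named character vector of tip states, or a tips x states
#'   prior matrix.
#' @param model_name One of ER, SYM, ARD, SEQ_EQ, SEQ_INC, SEQ_REV.
#' @param states Ordered state set; default: the states present in `tips`
#'   arranged in [drum_types()] order when they are drumming types,
#'   alphabetically otherwise.
#' @param n_restart Number of random restarts (default 5).
#' @param seed RNG seed for the restarts (default 1).
#' @return Object of class `mk_fit`: fitted `transition_model`, `logLik`,
#'   `AICc`, and the normalized tip prior matrix.
#' @export
fit_markov_model <- function(tree, tips, model_name, states = NULL,
                             n_restart = 5, seed = 1) {
  if (is.null(states)) {
    obs <- if (is.matrix(tips) || is.data.frame(tips)) colnames(tips)
           else sort(unique(as.character(tips)))
    states <- if (all(obs %in% drum_types()))
      intersect(drum_types(), obs) else sort(obs)
  }
  k <- length(states)
  if (k < 2) stop_("need at least 2 states")
  tipP <- .tip_prior_matrix(tree, tips, states)
  np <- n_free_params(model_name, k)
  lb <- log(1e-8); ub <- log(1e3)
  negll <- function(logpar) {
    Q <- build_q(model_name, exp(logpar), states)$Q
    -.mk_loglik(tree, tipP, Q)
  }
  rate0 <- max(1e-6, k / sum(tree$edge.length))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      start <- log(rate0) + if (r == 1) rep(0, np) else
        stats::runif(np, -2, 2)
      start <- pmin(pmax(start, lb), ub)
      fit <- tryCatch(
        stats::optim(start, negll, method = "L-BFGS-B",
                     lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
  })
  if (is.null(best))
    stop_("optimization of the %s model failed after %d restarts",
          model_name, n_restart)
  ll <- -best$value
  n <- ape::Ntip(tree)
  aicc <- if (n - np - 1 > 0) {
    -2 * ll + 2 * np + 2 * np * (np + 1) / (n - np - 1)
  } else Inf
  structure(list(model = build_q(model_name, exp(best$par), states),
                 logLik = ll, AICc = aicc, n_free = np,
                 n_tips = n, tipP = tipP, convergence = best$convergence),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("mk_fit %s: logLik %.3f, AICc %.3f (%d parameters, %d tips)\n",
              x$model$name, x$logLik, x$AICc, x$n_free, x$n_tips))
  invisible(x)
}

#' Marginal (empirical Bayes) ancestral state reconstruction
#'
#' Per-node posterior state distributions from the standard two-pass
#' (inside-outside) computation under the fitted rate matrix, with an
#' equiprobable root prior. Tip rows are posteriors too, which resolves
#' uncertain tips supplied as priors.
#'
#' @param tree A `phylo`.
#' @param tips Tip states or prior matrix (as in [fit_markov_model()]).
#' @param fit A fitted `mk_fit` (its state set is used).
#' @return Object of class `asr_result`: `node_probs` (internal nodes x
#'   states, rownames are node ids), `tip_probs`, `states`.
#' @export
marginal_asr <- function(tree, tips, fit) {
  stopifnot(inherits(fit, "mk_fit"))
  states <- fit$model$states
  k <- length(states)
  Q <- fit$model$Q
  tipP <- .tip_prior_matrix(tree, tips, states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  Pfun <- .q_expm_factory(Q)
  Pe <- lapply(po$edge.length, Pfun)

  # inside pass: D[v] = conditional likelihood of the subtree below v;
  # C[[e]] = P_e %*% D[child_e], normalized
  D <- matrix(1, nn, k)
  D[seq_len(ntip), ] <- tipP
  Cl <- vector("list", nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    v <- as.vector(Pe[[e]] %*% D[chi, ])
    v <- v / sum(v)
    Cl[[e]] <- v
    D[par, ] <- D[par, ] * v
    D[par, ] <- D[par, ] / sum(D[par, ])
  }

  # outside pass in reverse postorder (parents before children)
  U <- matrix(0, nn, k)
  root <- ntip + 1L
  U[root, ] <- rep(1 / k, k)
  children_edges <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    sib <- setdiff(children_edges[[as.character(par)]], e)
    above <- U[par, ]
    for (b in sib) above <- above * Cl[[b]]
    u <- as.vector(t(Pe[[e]]) %*% above)
    s <- sum(u)
    U[chi, ] <- if (s > 0) u / s else rep(1 / k, k)
  }

  M <- D * U
  M <- M / rowSums(M)
  dimnames(M) <- list(as.character(seq_len(nn)), states)
  structure(list(node_probs = M[(ntip + 1):nn, , drop = FALSE],
                 tip_probs = M[seq_len(ntip), , drop = FALSE],
                 states = states),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("asr_result: %d internal nodes, states %s\n",
              nrow(x$node_probs), paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Akaike-weight model-averaged ancestral reconstruction
#'
#' Fits the requested rate models, converts their AICc values to Akaike
#' weights w_i proportional to exp(-dAICc_i / 2), and averages the marginal
#' node distributions with those weights.
#'
#' @param tree A `phylo`.
#' @param tips Tip states or prior matrix.
#' @param models Model names to fit (default all six).
#' @param states Ordered state set, see [fit_markov_model()].
#' @param n_restart,seed Passed to [fit_markov_model()].
#' @return List of class `model_average`: `asr` (averaged `asr_result`),
#'   `fits`, `table` (model, logLik, AICc, weight).
#' @export
model_average_asr <- function(tree, tips, models = .mk_model_names(),
                              states = NULL, n_restart = 5, seed = 1) {
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_markov_model(tree, tips, m, states = states,
                                   n_restart = n_restart, seed = seed),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) < 1) stop_("all model fits failed")
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  ok <- is.finite(aicc)
  if (!any(ok)) stop_("all model fits failed (non-finite AICc)")
  fits <- fits[ok]; aicc <- aicc[ok]
  w <- exp(-(aicc - min(aicc)) / 2)
  w <- w / sum(w)
  asrs <- lapply(fits, function(f) marginal_asr(tree, tips, f))
  avg <- asrs[[1]]
  avg$node_probs <- Reduce(`+`, Map(function(a, wi) wi * a$node_probs,
                                    asrs, as.list(w)))
  avg$tip_probs <- Reduce(`+`, Map(function(a, wi) wi * a$tip_probs,
                                   asrs, as.list(w)))
  tab <- data.frame(model = names(fits),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    n_free = vapply(fits, `[[`, numeric(1), "n_free"),
                    AICc = aicc, weight = w, row.names = NULL)
  structure(list(asr = avg, fits = fits, per_model_asr = asrs, table = tab),
            class = "model_average")
}

#' @export
print.model_average <- function(x, ...) {
  cat("Akaike-weight model-averaged ancestral reconstruction\n")
  print(transform(x$table, logLik = round(logLik, 2),
                  AICc = round(AICc, 2), weight = round(weight, 3)))
  invisible(x)
}

#' Brownian-motion ancestral states of a continuous trait
#'
#' Maximum-likelihood (GLS) ancestral values under Brownian motion; the root
#' estimate equals the phylogenetic mean.
#'
#' @param tree A `phylo` (>= 2 tips).
#' @param tip_values Named numeric vector, one value per tip.
#' @return List of class `bm_asr`: `node_values` and `node_vars` (named by
#'   node id).
#' @export
bm_asr <- function(tree, tip_values) {
  if (ape::Ntip(tree) < 2) stop_("tree must have at least 2 tips")
  if (is.null(names(tip_values)) ||
      !all(tree$tip.label %in% names(tip_values)))
    stop_("tip_values must be named, covering every tip")
  x <- tip_values[tree$tip.label]
  fa <- phytools::fastAnc(tree, x, vars = TRUE)
  structure(list(node_values = stats::setNames(as.numeric(fa$ace),
                                               names(fa$ace)),
                 node_vars = stats::setNames(as.numeric(fa$var),
                                             names(fa$var))),
            class = "bm_asr")
}

# BM log-likelihood of tip data under a trait covariance matrix C (up to the
# ML-profiled mean and rate).
.bm_profile_loglik <- function(C, x) {
  n <- length(x)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Ci_x <- backsolve(ch, forwardsolve(t(ch), x))
  Ci_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Ci_x) / sum(Ci_1)
  r <- x - mu
  Ci_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Ci_r) / n
  if (s2 <= 0) s2 <- 1e-12
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
}

#' Maximum-likelihood Pagel's lambda of a continuous trait
#'
#' Profiles the Brownian-motion likelihood over the lambda-transformed trait
#' covariance (off-diagonal entries scaled by lambda), lambda in [0, 1].
#'
#' @param tree A `phylo` with >= 4 tips.
#' @param tip_values Named numeric vector of tip trait values.
#' @param profile_step Grid step of the returned likelihood profile.
#' @return List of class `pagels_lambda`: `lambda`, `logLik`, and a
#'   `profile` data.frame (lambda, logLik).
#' @export
pagels_lambda <- function(tree, tip_values, profile_step = 0.05) {
  if (ape::Ntip(tree) < 4) stop_("need at least 4 tips")
  x <- tip_values[tree$tip.label]
  if (anyNA(x)) stop_("tip_values must cover every tip")
  C <- ape::vcv(tree)
  ll <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- diag(C)
    .bm_profile_loglik(Cl, x)
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll(0)), c(1, ll(1)))
  best <- cand[which.max(cand[, 2]), ]
  grid <- seq(0, 1, by = profile_step)
  structure(list(lambda = unname(best[1]), logLik = unname(best[2]),
                 profile = data.frame(lambda = grid,
                                      logLik = vapply(grid, ll, numeric(1)))),
            class = "pagels_lambda")
}

#' @export
print.pagels_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.3f (logLik %.3f)\n", x$lambda, x$logLik))
  invisible(x)
}
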