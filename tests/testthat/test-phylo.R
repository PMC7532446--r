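# Mk models, pruning likelihood, marginal ASR, model averaging, BM states,
# Pagel's lambda, tree I/O and distances.

test_that("rate-model parameter counts and structures are correct", {
  expect_equal(n_free_params("ER", 6), 1)
  expect_equal(n_free_params("SYM", 6), 15)   # C(6,2)
  expect_equal(n_free_params("ARD", 6), 30)   # ordered pairs
  expect_equal(n_free_params("SEQ_EQ", 6), 1)
  expect_equal(n_free_params("SEQ_INC", 6), 2)
  expect_equal(n_free_params("SEQ_REV", 6), 10)  # 5 adjacencies x 2

  tm <- build_q("ER", 0)
  expect_true(all(tm$Q == 0))
  expect_error(build_q("SYM", 1:3), "expects 15")
  expect_error(build_q("XXX", 1), "unknown")

  inc <- build_q("SEQ_INC", c(0.2, 2))
  st <- drum_types()
  for (i in 1:5) {
    expect_equal(inc$Q[st[i], st[i + 1]], 0.2 * 2^(i - 1))
    expect_equal(inc$Q[st[i + 1], st[i]], 0.2 * 2^(i - 1))
  }
  expect_equal(inc$Q[st[1], st[3]], 0)  # non-adjacent moves forbidden

  rev_ <- build_q("SEQ_REV", 1:10)
  expect_equal(rev_$Q[st[1], st[2]], 1)
  expect_equal(rev_$Q[st[2], st[1]], 2)
  expect_equal(unname(rowSums(rev_$Q)), rep(0, 6))
})

test_that("pruning likelihood matches the closed-form two-state case", {
  tr <- ape::read.tree(text = "(A:1.3,B:0.7);")
  r <- 0.4
  Q <- build_q("ER", r, states = c("x", "y"))
  psame <- function(t) (1 + exp(-2 * r * t)) / 2
  pdiff <- function(t) (1 - exp(-2 * r * t)) / 2
  # same tip states
  ll_same <- mk_loglik(tr, c(A = "x", B = "x"), Q)
  expect_equal(ll_same,
               log(0.5 * (psame(1.3) * psame(0.7) + pdiff(1.3) * pdiff(0.7))),
               tolerance = 1e-10)
  ll_diff <- mk_loglik(tr, c(A = "x", B = "y"), Q)
  expect_equal(ll_diff,
               log(0.5 * (psame(1.3) * pdiff(0.7) + pdiff(1.3) * psame(0.7))),
               tolerance = 1e-10)
})

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  set.seed(6)
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    tr <- ape::rcoal(n)
    k <- sample(2:3, 1)
    states <- letters[1:k]
    R <- matrix(runif(k * k, 0.1, 1.2), k, k)
    Q <- (R + t(R)) / 2
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    dimnames(Q) <- list(states, states)
    tips <- setNames(sample(states, n, TRUE), tr$tip.label)
    expect_equal(mk_loglik(tr, tips, Q),
                 enum_mk_loglik(tr, tips, Q), tolerance = 1e-8)
  }
})

test_that("fitted rates agree with an independent ER fit and edge cases", {
  set.seed(15)
  tr <- ape::rcoal(10)
  tips <- setNames(sample(c("a", "b"), 10, TRUE), tr$tip.label)
  a <- ape::ace(tips, tr, type = "discrete", model = "ER")
  # ace omits the 1/k root prior, an additive log(k) offset
  ll_at_ace_rate <- mk_loglik(tr, tips, build_q("ER", a$rates,
                                                states = c("a", "b")))
  expect_equal(ll_at_ace_rate + log(2), a$loglik, tolerance = 1e-4)
  fit <- fit_markov_model(tr, tips, "ER", states = c("a", "b"))
  expect_gte(fit$logLik + 1e-6, ll_at_ace_rate)

  # all tips in one state: the rate collapses and the likelihood approaches
  # the root prior mass log(1/k)
  same <- setNames(rep("a", 10), tr$tip.label)
  fs <- fit_markov_model(tr, same, "ER", states = c("a", "b"))
  expect_equal(fs$logLik, log(0.5), tolerance = 1e-3)

  # AICc: more parameters, bigger penalty at equal fit
  expect_equal(fit$AICc,
               -2 * fit$logLik + 2 + 4 / (10 - 2), tolerance = 1e-10)
})

test_that("marginal reconstruction matches brute-force marginalization", {
  tr <- ape::read.tree(text = "((A:0.6,B:0.9):0.5,(C:1.1,D:0.4):0.8);")
  states <- c("x", "y")
  Q <- build_q("ER", 0.7, states = states)
  tips <- c(A = "x", B = "x", C = "y", D = "x")
  fit <- list(model = Q, logLik = NA, AICc = NA)
  class(fit) <- "mk_fit"
  asr <- marginal_asr(tr, tips, fit)
  for (node in 5:7) {
    expect_equal(unname(asr$node_probs[as.character(node), ]),
                 enum_marginal(tr, tips, Q$Q, node, states),
                 tolerance = 1e-8)
  }
  # all tips in one state: modal state everywhere
  asr1 <- marginal_asr(tr, c(A = "y", B = "y", C = "y", D = "y"), fit)
  expect_true(all(asr1$node_probs[, "y"] > 0.5))

  # zero-length branches to identical tips pin the node
  tr0 <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  asr0 <- marginal_asr(tr0, c(A = "x", B = "x", C = "y"), fit)
  expect_equal(unname(asr0$node_probs["5", "x"]), 1, tolerance = 1e-9)

  # invariance to tip input order
  asr_perm <- marginal_asr(tr, tips[c("D", "B", "A", "C")], fit)
  expect_equal(asr$node_probs, asr_perm$node_probs, tolerance = 1e-12)
})

test_that("uncertain tips accept prior vectors", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c("drummer", "non_drummer", "occasional")
  prior <- matrix(1, 4, 3, dimnames = list(c("A", "B", "C", "D"), states))
  prior["A", ] <- c(1, 0, 0)
  prior["B", ] <- c(1, 0, 0)
  prior["C", ] <- rep(1 / 3, 3)   # unknown drummer status
  prior["D", ] <- c(0, 1, 0)
  fit <- fit_markov_model(tr, prior, "ER", states = states, n_restart = 2)
  asr <- marginal_asr(tr, prior, fit)
  expect_equal(rowSums(asr$node_probs), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
  # the root leans toward the majority drummer state
  expect_gt(asr$node_probs["5", "drummer"],
            asr$node_probs["5", "non_drummer"])
})

test_that("Akaike weights average the per-model reconstructions", {
  tr <- simulate_tree(12, seed = 30)
  Q <- build_q("ER", 0.05, states = c("a", "b"))$Q
  tips <- evolve_discrete(tr, Q, "a", seed = 31)$tip_states
  ma <- model_average_asr(tr, tips, models = c("ER", "ARD"),
                          states = c("a", "b"), n_restart = 2)
  expect_equal(sum(ma$table$weight), 1, tolerance = 1e-12)
  # independent weight arithmetic from the AICc column
  w <- exp(-(ma$table$AICc - min(ma$table$AICc)) / 2)
  expect_equal(ma$table$weight, w / sum(w), tolerance = 1e-12)
  # averaged distributions are the weighted sums of the per-model ones
  manual <- ma$table$weight[1] * ma$per_model_asr[[1]]$node_probs +
            ma$table$weight[2] * ma$per_model_asr[[2]]$node_probs
  expect_equal(ma$asr$node_probs, manual, tolerance = 1e-12)
  # ER and SEQ_EQ coincide for 2 states: equal AICc, weights 1/2 each
  ma2 <- model_average_asr(tr, tips, models = c("ER", "SEQ_EQ"),
                           states = c("a", "b"), n_restart = 2)
  expect_equal(ma2$table$weight, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("BM ancestral values solve the GLS system", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(bm_asr(tr, c(A = 0, B = 2))$node_values), 1)

  tr5 <- ape::rcoal(5)
  set.seed(40)
  x <- setNames(rnorm(5), tr5$tip.label)
  fit <- bm_asr(tr5, x)
  expect_equal(unname(fit$node_values), bm_asr_oracle(tr5, x),
               tolerance = 1e-6)

  const <- bm_asr(tr5, setNames(rep(3.2, 5), tr5$tip.label))
  expect_equal(unname(const$node_values), rep(3.2, 4), tolerance = 1e-9)
})

test_that("Pagel's lambda matches grid and phylosig oracles", {
  tr <- simulate_tree(30, seed = 50)
  x <- evolve_bm(tr, 1, lambda = 0.6, seed = 51)$tip_values
  pl <- pagels_lambda(tr, x)
  grid <- seq(0, 1, by = 0.001)
  oracle <- grid[which.max(vapply(grid, function(l)
    lambda_loglik_oracle(tr, x, max(l, 1e-9)), numeric(1)))]
  expect_equal(pl$lambda, oracle, tolerance = 2e-3)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(pl$lambda, ps$lambda, tolerance = 0.02)

  # shuffling the trait destroys the signal
  tr2 <- simulate_tree(60, seed = 53)
  x2 <- evolve_bm(tr2, 1, seed = 54)$tip_values
  set.seed(52)
  xs <- setNames(sample(x2), names(x2))
  expect_lt(pagels_lambda(tr2, xs)$lambda, 0.3)
  expect_error(pagels_lambda(ape::rcoal(3), setNames(1:3, ape::rcoal(3)$tip.label)),
               "4 tips")
})

test_that("patristic distances match hand values and pair counts", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- phylo_distance_matrix(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)

  tr8 <- ape::rcoal(8)
  D8 <- phylo_distance_matrix(tr8)
  expect_equal(sum(upper.tri(D8)), choose(8, 2))
  # path-sum oracle
  for (pair in list(c(1, 5), c(2, 8), c(3, 4))) {
    i <- tr8$tip.label[pair[1]]; j <- tr8$tip.label[pair[2]]
    path <- ape::nodepath(tr8, pair[1], pair[2])
    len <- 0
    for (s in seq_len(length(path) - 1)) {
      e <- which(tr8$edge[, 1] == path[s] & tr8$edge[, 2] == path[s + 1] |
                 tr8$edge[, 2] == path[s] & tr8$edge[, 1] == path[s + 1])
      len <- len + tr8$edge.length[e]
    }
    expect_equal(D8[i, j], len, tolerance = 1e-12)
  }
})

test_that("Newick round trips preserve topology and lengths", {
  tr <- simulate_tree(12, seed = 60)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_true(ape::all.equal.phylo(tr, tr2, tolerance = 1e-9))
  expect_equal(sort(ape::node.depth.edgelength(tr2)[1:12]),
               sort(ape::node.depth.edgelength(tr)[1:12]), tolerance = 1e-9)

  bad <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1", bad)
  expect_error(suppressWarnings(read_newick(bad)))
  nolen <- tempfile(fileext = ".nwk")
  writeLines("(A,B);", nolen)
  expect_error(read_newick(nolen), "branch lengths")
})
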