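# LOO discriminant confusion, permutation null and the information layer.

test_that("confusion-matrix construction enforces its invariants", {
  expect_error(confusion_matrix(matrix(1, 2, 3)), "square")
  expect_error(confusion_matrix(matrix(c(0.5, 0.5, 0.2, 0.9), 2, 2,
                                       byrow = TRUE)), "sum to 1")
  M <- random_stochastic_matrix(4, seed = 1)
  cm <- confusion_matrix(M)
  expect_equal(rowSums(cm$matrix), rep(1, 4), ignore_attr = TRUE)
  # p(M) is the column mean under a uniform species prior
  expect_equal(cm$p_predicted, colMeans(M))
})

test_that("LOO classification is near-perfect for separated species and at
           chance for exchangeable labels", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
             matrix(rnorm(20, 8, 0.2), 10, 2))
  lab <- rep(c("A", "B"), each = 10)
  cm <- loo_confusion(X, lab)
  expect_equal(unname(cm$matrix), diag(2))

  diags <- vapply(1:6, function(s) {
    set.seed(100 + s)
    Xs <- matrix(rnorm(240), 80, 3)
    mean(diag(loo_confusion(Xs, rep(letters[1:4], each = 20))$matrix))
  }, numeric(1))
  expect_equal(mean(diags), 0.25, tolerance = 0.08)
})

test_that("LOO confusion equals the pooled-covariance centroid oracle", {
  set.seed(11)
  centers <- rbind(c(0, 0), c(6, 0), c(3, 5), c(3.4, 5.2)) # last two overlap
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(16, sd = 1), 8, 2), 2, centers[i, ], "+")))
  lab <- rep(c("a", "b", "c", "d"), each = 8)
  cm <- loo_confusion(X, lab)
  expect_equal(unname(cm$matrix), unname(loo_centroid_oracle(X, lab)),
               tolerance = 1e-12)
  # off-diagonal mass sits inside the overlapping pair
  off <- cm$matrix; diag(off) <- 0
  expect_gte(off["c", "d"] + off["d", "c"],
             0.8 * sum(off))
})

test_that("permutation p-values hit the add-one floor and ceiling", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 9, 0.1), 10, 2))
  lab <- rep(c("A", "B"), each = 10)
  p <- permuted_dfa(X, lab, n_perm = 999, seed = 4)
  expect_equal(p$p_value, 1 / 1000)
  expect_equal(p$observed, 1)

  # adversarial interleaving: LOO pessimism sends the observed diagonal to 0,
  # below (or equal to) every permuted value
  Xa <- matrix(c(-1, 1, -0.9, 0.9), 4, 1)
  la <- c("A", "A", "B", "B")
  pa <- permuted_dfa(Xa, la, n_perm = 99, seed = 5)
  expect_equal(pa$observed, 0)
  expect_equal(pa$p_value, 1)
  expect_error(permuted_dfa(Xa, la, n_perm = 10), "99")
})

test_that("local MI evaluates the conditional-vs-marginal ratio in bits", {
  cm2 <- confusion_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
                                 dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(unname(local_mi(cm2)), c(0.531, 0.531), tolerance = 5e-4)

  id4 <- confusion_matrix(diag(4))
  expect_equal(unname(local_mi(id4, "s1")), 2)
  expect_equal(overall_mi(id4), 2)

  unif <- confusion_matrix(matrix(1 / 3, 3, 3))
  expect_equal(unname(local_mi(unif)), rep(0, 3))
  expect_equal(overall_mi(unif), 0)
  expect_error(local_mi(id4, "nope"), "unknown")
})

test_that("overall MI agrees with brute-force and joint-entropy oracles", {
  M3 <- matrix(c(0.7, 0.2, 0.1,
                 0.1, 0.6, 0.3,
                 0.2, 0.2, 0.6), 3, 3, byrow = TRUE)
  cm <- confusion_matrix(M3)
  # direct double sum of Eqs for MI with uniform p(A)
  pm <- colMeans(M3)
  brute <- 0
  for (a in 1:3) for (m in 1:3) {
    if (M3[a, m] > 0)
      brute <- brute + (1 / 3) * M3[a, m] * log2(M3[a, m] / pm[m])
  }
  expect_equal(overall_mi(cm), brute, tolerance = 1e-12)
  expect_equal(overall_mi(cm), joint_entropy_mi(M3), tolerance = 1e-12)

  for (s in 1:5) {
    M <- random_stochastic_matrix(5, seed = s)
    cmr <- confusion_matrix(M)
    expect_equal(overall_mi(cmr), joint_entropy_mi(M), tolerance = 1e-10)
    expect_lte(overall_mi(cmr), log2(5))
  }
  # equality with the ceiling holds for a permutation matrix
  perm <- diag(4)[c(2, 4, 1, 3), ]
  expect_equal(overall_mi(confusion_matrix(perm)), 2)
})

test_that("the MI <-> percent-correct relation inverts and is monotone", {
  expect_equal(mi_from_pc(1, 92), log2(92))
  expect_equal(round(mi_from_pc(1, 92), 2), 6.52)
  expect_equal(mi_from_pc(1 / 92, 92), 0)
  expect_gte(mi_from_pc(0.53, 92), 2.46)
  expect_lte(mi_from_pc(0.53, 92), 2.49)

  expect_equal(pc_from_mi(0, 92), 1 / 92)
  expect_equal(pc_from_mi(log2(92), 92), 1)
  expect_equal(round(pc_from_mi(2.48, 92), 2), 0.53)

  grid <- seq(1 / 92 + 1e-6, 1, length.out = 200)
  vals <- mi_from_pc(grid, 92)
  expect_true(all(diff(vals) > 0))
  for (p in seq(0.05, 0.95, by = 0.1)) {
    pc <- 1 / 10 + p * (1 - 1 / 10)
    expect_equal(pc_from_mi(mi_from_pc(pc, 10), 10), pc, tolerance = 1e-8)
  }
  expect_error(mi_from_pc(0.005, 92), "1/n_s")
  expect_error(pc_from_mi(7, 92), "log2")
})

test_that("the Classification Index spans [-100, 100] and is symmetric", {
  expect_equal(classification_index(confusion_matrix(diag(2)), "s1", "s2"),
               100)
  swapped <- confusion_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(classification_index(swapped, "s1", "s2"), -100)
  m <- confusion_matrix(matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE,
                               dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(classification_index(m, "A", "B"), 30)
  cmr <- confusion_matrix(random_stochastic_matrix(5, seed = 9))
  expect_identical(classification_index(cmr, "a", "c"),
                   classification_index(cmr, "c", "a"))
  expect_error(classification_index(cmr, "a", "a"), "distinct")
})

test_that("balanced per-type MI isolates a planted outlier type", {
  set.seed(21)
  mk_scores <- function(center, n_sp, sd_sp = 0.6) {
    do.call(rbind, lapply(seq_len(n_sp), function(i) {
      mu <- center + rnorm(3, sd = sd_sp)
      matrix(rnorm(12, sd = 0.3), 4, 3) + rep(mu, each = 4)
    }))
  }
  S <- rbind(mk_scores(c(0, 0, 0), 6), mk_scores(c(1, 0.5, 0), 6),
             mk_scores(c(10, 10, 10), 6))
  sp <- rep(sprintf("sp%02d", 1:18), each = 4)
  types <- setNames(rep(c("X", "Y", "Z"), each = 6), sprintf("sp%02d", 1:18))
  fake <- structure(list(
    pca = list(scores = S, retained = 1:3),
    drum_species = sp,
    species = data.frame(species_id = names(types), drum_type = types)
  ), class = "drum_dataset")
  bm <- per_type_balanced_mi(fake, types, n_per_type = 5, n_iter = 40,
                             seed = 2)
  # the far-away type Z is the most informative in nearly every iteration
  zwins <- mean(apply(bm$per_iter, 1, which.max) == 3)
  expect_gte(zwins, 0.95)
  expect_error(per_type_balanced_mi(fake, types, n_per_type = 7),
               "fewer than 7")
  bm2 <- per_type_balanced_mi(fake, types, n_per_type = 5, n_iter = 2,
                              seed = 77)
  bm3 <- per_type_balanced_mi(fake, types, n_per_type = 5, n_iter = 2,
                              seed = 77)
  expect_identical(bm2$per_iter, bm3$per_iter)
})
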