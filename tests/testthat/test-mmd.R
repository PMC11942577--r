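test_that("mmd2 matches the explicit-feature-map oracle for linear kernels", {
  # linear kernel: squared MMD is exactly ||mean(Xs) - mean(Xt)||^2
  expect_equal(mmd2(matrix(c(0, 0), 1), matrix(c(3, 4), 1), "linear"), 25,
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    Xs <- matrix(rnorm(50 * 7), 50, 7)
    Xt <- matrix(rnorm(30 * 7, mean = 0.3), 30, 7)
    oracle <- sum((colMeans(Xs) - colMeans(Xt))^2)
    expect_equal(mmd2(Xs, Xt, "linear"), oracle, tolerance = 1e-10)
  }
})

test_that("mmd2 is zero on identical samples, symmetric, and shape-checked", {
  set.seed(5)
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rnorm(24), 6, 4)
  expect_lt(abs(mmd2(X, X)), 1e-10)
  expect_lt(abs(mmd2(X, X, "linear")), 1e-10)
  expect_identical(mmd2(X, Y), mmd2(Y, X))
  expect_gte(mmd2(X, Y), -1e-12)
  expect_error(mmd2(X, Y[, 1:3]), "dimension")
})

test_that("rbf mmd2 is invariant to joint row permutation", {
  set.seed(6)
  X <- matrix(rnorm(60), 15, 4)
  Y <- matrix(rnorm(32), 8, 4)
  v1 <- mmd2(X, Y)
  v2 <- mmd2(X[sample(15), ], Y[sample(8), ])
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("mmd2 responds monotonically to a growing mean gap", {
  vals <- vapply(c(0, 1, 2), function(gap) {
    mean(vapply(1:5, function(s) {
      set.seed(s)
      Xs <- matrix(rnorm(200 * 3), 200, 3)
      Xt <- matrix(rnorm(200 * 3, mean = gap), 200, 3)
      mmd2(Xs, Xt, "linear")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the unbiased estimator is available and near the biased one", {
  set.seed(7)
  Xs <- matrix(rnorm(100), 25, 4)
  Xt <- matrix(rnorm(100, 0.5), 25, 4)
  b <- mmd2(Xs, Xt)
  u <- mmd2(Xs, Xt, estimator = "unbiased")
  expect_lt(abs(b - u), 0.2)
  expect_error(mmd2(Xs[1, , drop = FALSE], Xt, estimator = "unbiased"),
               "2 samples")
})

test_that("analytic mmd2 gradients match finite differences", {
  set.seed(8)
  Xs <- matrix(rnorm(12), 4, 3)
  Xt <- matrix(rnorm(9), 3, 3)
  for (kern in c("linear", "rbf")) {
    bw <- if (kern == "rbf") 2.5 else NA_real_  # fixed bandwidth: smooth obj
    g <- dadsp:::mmd2Grad(Xs, Xt, kern, bw)
    expect_equal(g$value, mmd2(Xs, Xt, kern, bandwidth = bw),
                 tolerance = 1e-10)
    h <- 1e-6
    for (probe in list(c(2, 1), c(4, 3))) {
      Ep <- Xs
      Ep[probe[1], probe[2]] <- Ep[probe[1], probe[2]] + h
      Em <- Xs
      Em[probe[1], probe[2]] <- Em[probe[1], probe[2]] - h
      fd <- (mmd2(Ep, Xt, kern, bandwidth = bw) -
               mmd2(Em, Xt, kern, bandwidth = bw)) / (2 * h)
      expect_equal(g$dXs[probe[1], probe[2]], fd, tolerance = 1e-5)
    }
    Ep <- Xt
    Ep[2, 3] <- Ep[2, 3] + h
    Em <- Xt
    Em[2, 3] <- Em[2, 3] - h
    fd <- (mmd2(Xs, Ep, kern, bandwidth = bw) -
             mmd2(Xs, Em, kern, bandwidth = bw)) / (2 * h)
    expect_equal(g$dXt[2, 3], fd, tolerance = 1e-5)
  }
})

test_that("the staged freezing protocol freezes what it promises", {
  pair <- generateDomainPair(tinySimConfig(seed = 13L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 13L))
  cfg <- tinyDadspConfig(seed = 2L, adversarial = FALSE, pretrain = FALSE,
                         learningRate = 1e-3)
  mc <- MMDConfig(stageEpochs = c(5L, 30L, 10L), seed = 2L)
  s1 <- trainStage1(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                    config = cfg, mmdConfig = mc)
  expect_identical(s1@variant, "stage1")
  # stage-1 training reduced the source loss from its first epoch
  expect_lt(tail(s1@history$L_MSE, 1), s1@history$L_MSE[1] + 1e-8)

  s2 <- trainStage2(s1, prep$targetGene, prep$sourceGene, mc)
  expect_identical(s2@regressor, s1@regressor)         # frozen bitwise
  expect_false(identical(s2@geneExtractor, s1@geneExtractor))

  s3 <- trainStage3(s2, prep$source$X_gene, prep$source$X_drug,
                    prep$source$y, config = cfg, mmdConfig = mc)
  expect_identical(s3@geneExtractor, s2@geneExtractor)  # frozen bitwise
  expect_identical(s3@drugExtractor, s2@drugExtractor)
  expect_false(identical(s3@regressor, s2@regressor))
  # stage-3 source loss not worse at the end than at the start
  l3 <- attr(s3@history, "stage3_loss")
  expect_lte(tail(l3, 1), l3[1])
})

test_that("stage 2 reduces the source/target code discrepancy under shift", {
  wins <- 0L
  for (seed in 1:6) {
    pair <- generateDomainPair(tinySimConfig(seed = seed, delta = 1))
    prep <- prepareDomainPair(pair, SplitSpec("standard", seed = seed))
    cfg <- tinyDadspConfig(seed = seed, adversarial = FALSE, pretrain = FALSE)
    mc <- MMDConfig(stageEpochs = c(2L, 40L, 5L), seed = seed)
    s1 <- trainStage1(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                      config = cfg, mmdConfig = mc)
    s2 <- trainStage2(s1, prep$targetGene, prep$sourceGene, mc)
    tr <- attr(s2@history, "stage2_mmd")
    wins <- wins + (tr$mmd_end[1] < tr$mmd_start[1])
  }
  expect_gte(wins, 5L)
})

test_that("stage 2 with zero MMD weight is plain target reconstruction", {
  pair <- generateDomainPair(tinySimConfig(seed = 14L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 14L))
  cfg <- tinyDadspConfig(seed = 3L, adversarial = FALSE, pretrain = FALSE)
  mc0 <- MMDConfig(mmdWeight = 0, stageEpochs = c(2L, 20L, 5L), seed = 3L)
  s1 <- trainStage1(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                    config = cfg, mmdConfig = mc0)
  s2 <- trainStage2(s1, prep$targetGene, prep$sourceGene, mc0)
  expect_s4_class(s2, "DadspModel")  # runs; discrepancy may stay large
  expect_identical(s2@regressor, s1@regressor)
})
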