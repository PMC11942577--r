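test_that("the gradient reversal layer is identity forward, -lambda back", {
  x <- c(1.5, -2)
  expect_identical(grlForward(x, 1), x)
  expect_identical(grlForward(x, 0), x)

  # lambda = 0 kills the upstream gradient exactly
  expect_identical(grlBackward(c(3, -4), 0), c(0, 0))

  # finite differences on the composed forward see +1 (identity), while the
  # backward contract returns -lambda: the flip exists only in the backward
  set.seed(1)
  x0 <- rnorm(3)
  f <- function(x) sum(grlForward(x, lambda = 2))
  fd <- vapply(1:3, function(i) {
    h <- 1e-6
    e <- numeric(3)
    e[i] <- h
    (f(x0 + e) - f(x0 - e)) / (2 * h)
  }, numeric(1))
  expect_equal(fd, rep(1, 3), tolerance = 1e-6)
  expect_equal(grlBackward(rep(1, 3), lambda = 2), rep(-2, 3))
})

test_that("the lambda schedule starts at 0, rises monotonically, caps below 1", {
  expect_identical(lambdaSchedule(0), 0)
  expect_equal(lambdaSchedule(1, gamma = 10), 2 / (1 + exp(-10)) - 1,
               tolerance = 1e-12)
  expect_equal(lambdaSchedule(1, gamma = 10), 0.999909, tolerance = 1e-6)
  expect_gt(lambdaSchedule(0.7, 10), lambdaSchedule(0.3, 10))
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(lambdaSchedule(p, 10)) > 0))
  expect_true(all(lambdaSchedule(p, 10) >= 0 & lambdaSchedule(p, 10) < 1))
  expect_error(lambdaSchedule(1.2), "\\[0, 1\\]")
})

test_that("the domain loss is mean BCE with the adversarial optimum at ln 2", {
  expect_lt(domainLoss(1, 1 - 1e-9), 1e-6)
  expect_equal(domainLoss(1, 0.5), log(2), tolerance = 1e-12)
  # chance-level output on a balanced batch
  expect_equal(domainLoss(c(0, 0, 1, 1), rep(0.5, 4)), log(2),
               tolerance = 1e-12)
  expect_error(domainLoss(c(0, 1), 0.5), "length")
})

test_that("forward wiring: shapes, sigmoid head, and late fusion", {
  cfg <- tinyDadspConfig()
  nets <- dadsp:::dadspInitNets(10L, 6L, cfg, NULL)
  model <- new("DadspModel", geneExtractor = nets$gene,
               drugExtractor = nets$drug, discriminator = nets$disc,
               regressor = nets$reg, norm = list(), history = data.frame(),
               config = cfg, variant = "wiring-test")
  set.seed(2)
  Xs <- matrix(runif(40), 4, 10)
  Xt <- matrix(runif(20), 2, 10)
  Xd <- matrix(rbinom(24, 1, 0.3), 4, 6)
  out <- dadspForward(model, Xs, Xt, Xd, lambda = 0.5)
  expect_length(out$yhat, 4)
  expect_identical(dim(out$domainProbs), c(6L, 2L))
  expect_equal(rowSums(out$domainProbs), rep(1, 6), tolerance = 1e-12)
  expect_true(all(out$yhat > 0 & out$yhat < 1))

  # all-zero final regressor weights: yhat is sigmoid(bias) everywhere
  m0 <- model
  k <- length(m0@regressor)
  m0@regressor[[k]]$W[] <- 0
  m0@regressor[[k]]$b <- 0.3
  out0 <- dadspForward(m0, Xs, Xt, Xd)
  expect_equal(out0$yhat, rep(1 / (1 + exp(-0.3)), 4), tolerance = 1e-12)

  # late fusion: permuting drug rows changes yhat but not domain probs
  perm <- c(2, 1, 4, 3)
  outp <- dadspForward(model, Xs, Xt, Xd[perm, ], lambda = 0.5)
  expect_false(isTRUE(all.equal(outp$yhat, out$yhat)))
  expect_identical(outp$domainProbs, out$domainProbs)
})

test_that("training records an exact loss decomposition and stops in budget", {
  pair <- generateDomainPair(tinySimConfig(seed = 3L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 3L))
  cfg <- tinyDadspConfig(seed = 3L, pretrain = FALSE)
  m <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                  targetGene = prep$targetGene, config = cfg,
                  norm = list(features = prep$norm$features,
                              labels = prep$norm$sourceLabels))
  h <- m@history
  expect_lte(nrow(h), cfg@epochs)
  expect_identical(h$L_Total, h$L_MSE + h$L_domain)  # exact, by construction
  expect_true(all(is.finite(h$L_Total)))
  expect_true(all(h$lambda >= 0 & h$lambda < 1))
})

test_that("with lambda forced to 0 training equals a GRL-free run bitwise", {
  pair <- generateDomainPair(tinySimConfig(seed = 8L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 8L))
  base <- list(features = prep$norm$features, labels = prep$norm$sourceLabels)
  cfgAdv <- tinyDadspConfig(seed = 5L, pretrain = FALSE, lambdaFix = 0)
  cfgOff <- tinyDadspConfig(seed = 5L, pretrain = FALSE, adversarial = FALSE)
  mAdv <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                     targetGene = prep$targetGene, config = cfgAdv, norm = base)
  mOff <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                     config = cfgOff, norm = base)
  expect_identical(mAdv@geneExtractor, mOff@geneExtractor)
  expect_identical(mAdv@drugExtractor, mOff@drugExtractor)
  expect_identical(mAdv@regressor, mOff@regressor)
})

test_that("training is deterministic given a seed and guards its inputs", {
  pair <- generateDomainPair(tinySimConfig(seed = 9L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 9L))
  cfg <- tinyDadspConfig(seed = 7L, pretrain = FALSE, epochs = 2L,
                         earlyStoppingPatience = 2L)
  args <- list(prep$source$X_gene, prep$source$X_drug, prep$source$y,
               targetGene = prep$targetGene, config = cfg)
  m1 <- do.call(trainDadsp, args)
  m2 <- do.call(trainDadsp, args)
  expect_identical(m1@geneExtractor, m2@geneExtractor)
  expect_identical(m1@regressor, m2@regressor)

  # adversarial training without target data is refused
  expect_error(trainDadsp(prep$source$X_gene, prep$source$X_drug,
                          prep$source$y, config = cfg),
               "target")
  # pretrain flag without a bundle is refused
  cfgP <- tinyDadspConfig(pretrain = TRUE)
  expect_error(trainDadsp(prep$source$X_gene, prep$source$X_drug,
                          prep$source$y, targetGene = prep$targetGene,
                          config = cfgP),
               "bundle")
})

test_that("prediction is pure and order-preserving under inverse transforms", {
  pair <- generateDomainPair(tinySimConfig(seed = 10L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 10L))
  cfg <- tinyDadspConfig(seed = 1L, pretrain = FALSE, adversarial = FALSE,
                         epochs = 2L, earlyStoppingPatience = 2L)
  m <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                  config = cfg,
                  norm = list(features = prep$norm$features,
                              labels = prep$norm$sourceLabels))
  Xg <- prep$targetTest$X_gene[c(1, 1, 2), , drop = FALSE]
  Xd <- prep$targetTest$X_drug[c(1, 1, 2), , drop = FALSE]
  pr <- predictDadsp(m, Xg, Xd)
  expect_identical(pr$normalized[1], pr$normalized[2])
  expect_identical(order(pr$normalized), order(pr$response))
  expect_error(predictDadsp(m, Xg[, 1:3], Xd), "features")
})

test_that("the model learns a noiseless low-dimensional response surface", {
  # sigma = 0, q = 2, ~2000 source triplets; oracle floor is exactly 0
  cfg <- SimulationConfig(nGenes = 60L, nCellsSource = 100L,
                          nCellsTarget = 30L, nDrugs = 20L, latentDim = 2L,
                          sigma = 0, delta = 0, seed = 12L)
  pair <- generateDomainPair(cfg)
  prep <- prepareDomainPair(pair)
  n <- length(prep$source$y)
  idx <- withr::with_seed(1, sample.int(n))
  tr <- idx[seq_len(1600)]
  te <- idx[-seq_len(1600)]
  dCfg <- DadspConfig(geneDims = c(32L, 16L), drugDims = c(32L, 16L),
                      regDims = c(32L, 16L, 8L), epochs = 60L,
                      earlyStoppingPatience = 60L, learningRate = 1e-3,
                      adversarial = FALSE, pretrain = FALSE, seed = 1L)
  m <- trainDadsp(prep$source$X_gene[tr, ], prep$source$X_drug[tr, ],
                  prep$source$y[tr], config = dCfg)
  pr <- predictDadsp(m, prep$source$X_gene[te, ], prep$source$X_drug[te, ])
  expect_lt(rmse(prep$source$y[te], pr$normalized), 0.15)
})
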