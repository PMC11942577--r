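test_that("the standard split partitions pairs exactly and reproducibly", {
  pair <- generateDomainPair(tinySimConfig(seed = 16L))
  rt <- pair$target$responses
  spec <- SplitSpec("standard", testFraction = 0.2, seed = 4L)
  sp <- standardSplit(rt, spec)
  expect_identical(nResponses(sp$train) + nResponses(sp$test), nResponses(rt))
  key <- function(x) {
    d <- responseData(x)
    sort(paste(d$cell_id, d$drug_id, d$y_raw))
  }
  expect_identical(sort(c(key(sp$train), key(sp$test))), key(rt))
  # no (cell, drug) pair on both sides
  pk <- function(x) {
    d <- responseData(x)
    unique(paste(d$cell_id, d$drug_id))
  }
  expect_length(intersect(pk(sp$train), pk(sp$test)), 0)
  # same seed, same split
  sp2 <- standardSplit(rt, spec)
  expect_identical(responseData(sp$test), responseData(sp2$test))
  expect_error(standardSplit(rt, SplitSpec("standard", testFraction = 1e-6)),
               "empty test")
})

test_that("the blind split holds out whole drugs and cell lines", {
  # full 3x3 grid, hold out 1 drug and 1 cell: train 4, test 5 by enumeration
  rt <- ResponseTable(rep(c("c1", "c2", "c3"), each = 3),
                      rep(c("d1", "d2", "d3"), 3),
                      rep(1, 9))
  spec <- SplitSpec("blind", drugFraction = 1 / 3, cellFraction = 1 / 3,
                    seed = 2L)
  sp <- blindSplit(rt, spec)
  expect_identical(nResponses(sp$train), 4L)
  expect_identical(nResponses(sp$test), 5L)
  heldD <- attr(sp, "heldDrugs")
  heldC <- attr(sp, "heldCells")
  tr <- responseData(sp$train)
  expect_false(any(tr$drug_id %in% heldD))
  expect_false(any(tr$cell_id %in% heldC))
  # union preserved
  expect_identical(nResponses(sp$train) + nResponses(sp$test), 9L)

  # larger random instance: defining property holds
  pair <- generateDomainPair(tinySimConfig(seed = 17L))
  spB <- blindSplit(pair$target$responses,
                    SplitSpec("blind", drugFraction = 0.25,
                              cellFraction = 0.1, seed = 3L))
  trB <- responseData(spB$train)
  expect_false(any(trB$drug_id %in% attr(spB, "heldDrugs")))
  expect_false(any(trB$cell_id %in% attr(spB, "heldCells")))
})

test_that("the domain-confusion probe calibrates to its two extremes", {
  set.seed(14)
  # identical distributions: accuracy near chance (binomial CI, n = 200)
  a <- matrix(rnorm(200 * 5), 200, 5)
  b <- matrix(rnorm(200 * 5), 200, 5)
  accSame <- as.numeric(domainConfusionProbe(a, b, seed = 1L))
  expect_lt(abs(accSame - 0.5), 1.96 * sqrt(0.25 / 200))
  # linearly separated clouds: near-perfect accuracy
  accSep <- as.numeric(domainConfusionProbe(a, b + 6, seed = 1L))
  expect_gte(accSep, 0.95)
  expect_error(domainConfusionProbe(a[1:5, ], b, seed = 1L), ">= 20")
})

test_that("the ablation harness returns its contract and audits variants", {
  pair <- generateDomainPair(tinySimConfig(seed = 18L))
  res <- runAblation(pair, variants = c("DeepDSC-1", "DeepDSC-2"),
                     seeds = c(1L, 2L),
                     dadspConfig = tinyDadspConfig(epochs = 2L,
                                                   earlyStoppingPatience = 2L),
                     saeConfig = tinySaeConfig(epochsPerLayer = 3L,
                                               finetuneEpochs = 3L))
  expect_identical(nrow(res), 4L)
  expect_true(all(c("variant", "seed", "rmse", "r2_conventional",
                    "r2_paper") %in% colnames(res)))
  expect_error(runAblation(pair, variants = "NoSuchModel", seeds = 1L),
               "unknown variant")
})

test_that("target-only variants never touch source-domain data", {
  # hand the harness a prep object with NO source data: any access by the
  # target-only variant would fail immediately
  pair <- generateDomainPair(tinySimConfig(seed = 19L))
  featNP <- fitMinMax(exprValues(pair$target$expr))
  labT <- fitMinMax(responseData(pair$target$responses)$y, "global")
  sp <- standardSplit(pair$target$responses, SplitSpec("standard", seed = 1L))
  tgtNorm <- list(features = featNP, labels = labT)
  prep <- list(
    source = NULL, sourceGene = NULL,
    targetGene = applyMinMax(exprValues(pair$target$expr), featNP),
    targetTrain = assembleDataset(pair$target$expr, pair$fingerprints,
                                  sp$train, tgtNorm),
    targetTest = assembleDataset(pair$target$expr, pair$fingerprints,
                                 sp$test, tgtNorm),
    norm = list(features = featNP, sourceLabels = NULL, targetLabels = labT))
  cfg <- tinyDadspConfig(epochs = 2L, earlyStoppingPatience = 2L)
  mc <- tinySaeConfig(epochsPerLayer = 2L, finetuneEpochs = 2L)
  m <- dadsp:::fitVariant("DeepDSC-1", prep, cfg, mc, MMDConfig(seed = 1L))
  expect_true(all(is.finite(unlist(lapply(m@regressor, `[[`, "W")))))
  pr <- predictDadsp(m, prep$targetTest$X_gene, prep$targetTest$X_drug)
  expect_true(all(is.finite(pr$normalized)))
})

test_that("missing-pair prediction enumerates and ranks unmeasured pairs", {
  pair <- generateDomainPair(tinySimConfig(seed = 20L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 20L))
  cfg <- tinyDadspConfig(seed = 1L, pretrain = FALSE, adversarial = FALSE,
                         epochs = 2L, earlyStoppingPatience = 2L)
  m <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                  config = cfg,
                  norm = list(features = prep$norm$features,
                              labels = prep$norm$sourceLabels))
  missing <- predictMissing(m, pair$target$expr, pair$fingerprints,
                            pair$target$responses)
  cfgS <- pair$truth@config
  nAll <- cfgS@nCellsTarget * cfgS@nDrugs
  expect_identical(nrow(missing), nAll - nResponses(pair$target$responses))
  expect_true(all(diff(missing$pred_normalized) <= 0))
  have <- responseData(pair$target$responses)
  expect_length(intersect(paste(missing$cell_id, missing$drug_id),
                          paste(have$cell_id, have$drug_id)), 0)
})
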