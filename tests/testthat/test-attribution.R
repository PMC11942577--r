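test_that("integrated gradients are exact for a linear prediction head", {
  w <- c(0.5, -1.2, 2, 0)
  model <- linearDadspModel(w)
  x <- c(1, 0.5, -1, 3)
  b <- c(0.2, 0, 0.1, 0)
  for (steps in c(2L, 7L, 64L)) {
    res <- integratedGradients(model, x, rep(0, 4), baseline = b,
                               nSteps = steps)
    expect_equal(unname(res@scores), w * (x - b), tolerance = 1e-12)
    expect_lt(res@completenessGap, 1e-12)
  }
})

test_that("attribution at the baseline itself is identically zero", {
  model <- linearDadspModel(c(1, 2, 3))
  res <- integratedGradients(model, c(0.4, 0.1, 0.9), rep(0, 4),
                             baseline = c(0.4, 0.1, 0.9))
  expect_identical(unname(res@scores), c(0, 0, 0))
  expect_identical(res@completenessGap, 0)
})

test_that("the completeness gap shrinks as the path is refined", {
  pair <- generateDomainPair(tinySimConfig(seed = 15L))
  prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 15L))
  cfg <- tinyDadspConfig(seed = 4L, pretrain = FALSE, adversarial = FALSE,
                         epochs = 15L, learningRate = 1e-3)
  m <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                  config = cfg)
  # attribute the row with the least degenerate prediction difference so
  # the relative completeness bound is meaningful
  deltaF <- vapply(1:20, function(r) {
    d <- prep$source$X_drug[r, ]
    ends <- dadsp:::dadspInputGradient(
      m, rbind(numeric(ncol(prep$source$X_gene)), prep$source$X_gene[r, ]),
      as.numeric(dadsp:::nnForward(m@drugExtractor, matrix(d, 1),
                                   cache = FALSE)$out))$F
    abs(ends[2] - ends[1])
  }, numeric(1))
  r <- which.max(deltaF)
  x <- prep$source$X_gene[r, ]
  d <- prep$source$X_drug[r, ]
  g32 <- integratedGradients(m, x, d, nSteps = 32L)@completenessGap
  g512 <- integratedGradients(m, x, d, nSteps = 512L)@completenessGap
  expect_lt(g512, g32)
  expect_lt(g512, 1e-3 * deltaF[r])
})

test_that("attribution mass concentrates on truly active genes", {
  # truth loads the response only on latent dims read out by a known gene
  # set; attribution should put more mass there than on random genes
  wins <- 0L
  for (seed in 1:6) {
    cfg <- tinySimConfig(seed = seed, sigma = 0.02, delta = 0)
    pair <- generateDomainPair(cfg)
    truth <- pair$truth
    # genes ranked by their loading on the response-relevant direction
    relevance <- abs(truth@W %*% truth@u)
    active <- order(-relevance)[1:8]
    inert <- order(relevance)[1:8]
    prep <- prepareDomainPair(pair)
    dCfg <- DadspConfig(geneDims = c(24L, 8L), drugDims = c(16L, 8L),
                        regDims = c(16L, 8L, 4L), epochs = 30L,
                        earlyStoppingPatience = 30L, learningRate = 1e-3,
                        adversarial = FALSE, pretrain = FALSE, seed = seed)
    m <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                    config = dCfg)
    rows <- seq_len(10)
    mass <- function(idx) {
      tot <- 0
      for (r in rows) {
        res <- integratedGradients(m, prep$source$X_gene[r, ],
                                   prep$source$X_drug[r, ], nSteps = 32L)
        tot <- tot + sum(abs(res@scores[idx]))
      }
      tot
    }
    wins <- wins + (mass(active) > mass(inert))
  }
  expect_gte(wins, 5L)
})

test_that("gene ranking sorts, breaks ties lexicographically, and warns", {
  mk <- function(scores, ids) {
    new("AttributionResult", cellId = "c", drugId = "d",
        scores = setNames(scores, ids), baseline = "zero", nSteps = 8L,
        completenessGap = 0)
  }
  r <- mk(c(0.3, 0.1, 0.2), c("g1", "g2", "g3"))
  top2 <- rankGenes(r, topN = 2L)
  expect_identical(top2$gene_id, c("g1", "g3"))
  expect_identical(top2$score, c(0.3, 0.2))

  tie <- mk(c(0.2, 0.2, 0.1), c("gb", "ga", "gc"))
  expect_identical(rankGenes(tie, topN = 2L)$gene_id, c("ga", "gb"))

  expect_warning(all3 <- rankGenes(r, topN = 10L), "exceeds")
  expect_identical(nrow(all3), 3L)

  # averaging across cell lines, ten-row report shape
  set.seed(13)
  rs <- lapply(1:3, function(i) mk(rnorm(20), sprintf("g%02d", 1:20)))
  rep10 <- rankGenes(rs, topN = 10L)
  expect_identical(dim(rep10), c(10L, 2L))
  expect_true(all(diff(rep10$score) <= 0))

  bad <- mk(1:3, c("x", "y", "z"))
  expect_error(rankGenes(list(r, bad)), "share")
})
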