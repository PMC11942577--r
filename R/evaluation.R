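# Evaluation protocols: pair-level and blind splits, the ablation harness,
# the domain-confusion probe, and missing-pair prediction.

responsesFromRows <- function(responses, rows) {
  d <- responseData(responses)[rows, , drop = FALSE]
  ResponseTable(d$cell_id, d$drug_id, d$y_raw)
}

#' Pair-level (standard) response split
#'
#' Random partition at the (cell, drug) pair level: a drug or cell line may
#' appear on both sides, but no pair does; duplicate measurements of one
#' pair travel together.
#'
#' @param responses a [ResponseTable-class].
#' @param spec a [SplitSpec-class] with `mode = "standard"`.
#' @return list with `train` and `test` [ResponseTable-class] objects whose
#'   union is exactly the input.
#' @export
standardSplit <- function(responses, spec) {
  stopifnot(is(spec, "SplitSpec"))
  if (spec@mode != "standard") stopf("spec mode must be 'standard'")
  d <- responseData(responses)
  pair <- paste(d$cell_id, d$drug_id, sep = "\r")
  pairs <- unique(pair)
  nTest <- round(spec@testFraction * length(pairs))
  if (nTest < 1L) stopf("test fraction leaves an empty test set")
  if (nTest >= length(pairs)) stopf("test fraction leaves an empty training set")
  testPairs <- withSeed(deriveSeed(spec@seed, "standard_split"),
                        sample(pairs, nTest))
  isTest <- pair %in% testPairs
  list(train = responsesFromRows(responses, which(!isTest)),
       test = responsesFromRows(responses, which(isTest)))
}

#' Blind (leave-drug-and-cell-line-out) response split
#'
#' Samples a held-out drug set D and cell-line set C simultaneously; every
#' triplet touching a held-out drug OR a held-out cell line goes to the
#' test side, so no held-out entity appears in training in any pairing.
#'
#' @param responses a [ResponseTable-class].
#' @param spec a [SplitSpec-class] with `mode = "blind"`.
#' @return list with `train` and `test` [ResponseTable-class] objects and
#'   attributes `heldDrugs` / `heldCells` on the list.
#' @export
blindSplit <- function(responses, spec) {
  stopifnot(is(spec, "SplitSpec"))
  if (spec@mode != "blind") stopf("spec mode must be 'blind'")
  d <- responseData(responses)
  drugs <- unique(d$drug_id)
  cells <- unique(d$cell_id)
  nD <- max(1L, round(spec@drugFraction * length(drugs)))
  nC <- max(1L, round(spec@cellFraction * length(cells)))
  heldD <- withSeed(deriveSeed(spec@seed, "blind_drugs"), sample(drugs, nD))
  heldC <- withSeed(deriveSeed(spec@seed, "blind_cells"), sample(cells, nC))
  isTest <- d$drug_id %in% heldD | d$cell_id %in% heldC
  if (all(isTest)) stopf("blind fractions leave an empty training set")
  if (!any(isTest)) stopf("blind fractions leave an empty test set")
  out <- list(train = responsesFromRows(responses, which(!isTest)),
              test = responsesFromRows(responses, which(isTest)))
  attr(out, "heldDrugs") <- heldD
  attr(out, "heldCells") <- heldC
  out
}

#' Normalize and assemble a source/target domain pair for training
#'
#' Applies the transfer pipeline's conventions: genes are intersected
#' (lexicographic order), per-gene min-max scaling is fit on the pooled
#' source + target expression (both domains enter the shared extractor),
#' and labels are min-max scaled per domain separately (the two domains'
#' IC50 scales need not agree).
#'
#' @param pair output of [generateDomainPair()], or any list with the same
#'   structure built from real data.
#' @param splitSpec optional [SplitSpec-class] applied to the target
#'   responses.
#' @return list with assembled arrays (`source`, `targetTrain`,
#'   `targetTest` or `target`), the normalized full gene matrices
#'   (`sourceGene`, `targetGene`), and the [NormalizationParams-class]
#'   objects used.
#' @export
prepareDomainPair <- function(pair, splitSpec = NULL) {
  ig <- intersectGenes(pair$source$expr, pair$target$expr)
  vS <- exprValues(ig$source)
  vT <- exprValues(ig$target)
  featNP <- fitMinMax(rbind(vS, vT), "per_feature", fitOn = "source+target")
  labS <- fitMinMax(responseData(pair$source$responses)$y, "global",
                    fitOn = "source labels")
  labT <- fitMinMax(responseData(pair$target$responses)$y, "global",
                    fitOn = "target labels")
  srcNorm <- list(features = featNP, labels = labS)
  tgtNorm <- list(features = featNP, labels = labT)
  out <- list(
    source = assembleDataset(ig$source, pair$fingerprints,
                             pair$source$responses, srcNorm),
    sourceGene = applyMinMax(vS, featNP),
    targetGene = applyMinMax(vT, featNP),
    norm = list(features = featNP, sourceLabels = labS, targetLabels = labT))
  if (is.null(splitSpec)) {
    out$target <- assembleDataset(ig$target, pair$fingerprints,
                                  pair$target$responses, tgtNorm)
  } else {
    sp <- if (splitSpec@mode == "standard") {
      standardSplit(pair$target$responses, splitSpec)
    } else {
      blindSplit(pair$target$responses, splitSpec)
    }
    out$targetTrain <- assembleDataset(ig$target, pair$fingerprints,
                                       sp$train, tgtNorm)
    out$targetTest <- assembleDataset(ig$target, pair$fingerprints,
                                      sp$test, tgtNorm)
  }
  out
}

#' Domain-confusion probe
#'
#' Trains fresh ridge-penalized logistic classifiers on balanced, random
#' half/half splits of labeled feature rows and reports the mean held-out
#' domain-classification accuracy over `nRepeats` independent splits
#' (repeated subsampling validation; one split is a noisy estimate at
#' small sample sizes). Accuracy near 0.5 means the domains are
#' indistinguishable in the probed representation (well adapted); accuracy
#' near 1 means clearly separated.
#'
#' @param featSrc,featTgt feature matrices (rows = samples) from a frozen
#'   extractor, or raw inputs for the unadapted reference.
#' @param seed integer controlling balancing and the splits.
#' @param nRepeats number of independent balanced splits averaged.
#' @return mean held-out accuracy in `[0, 1]`, with attributes `nTest` (the
#'   total number of held-out classifications across repeats) and
#'   `nTestDistinct` (held-out classifications per split — the conservative
#'   sample size for binomial uncertainty, since repeats reuse the data).
#' @export
domainConfusionProbe <- function(featSrc, featTgt, seed = 1L,
                                 nRepeats = 10L) {
  featSrc <- as.matrix(featSrc)
  featTgt <- as.matrix(featTgt)
  if (nrow(featSrc) < 20L || nrow(featTgt) < 20L) {
    stopf("probe needs >= 20 samples per domain")
  }
  m <- min(nrow(featSrc), nrow(featTgt))
  half <- floor(m / 2)
  accs <- vapply(seq_len(nRepeats), function(rep) {
    iS <- withSeed(deriveSeed(seed, "probe_balance_src", rep),
                   sample.int(nrow(featSrc), m))
    iT <- withSeed(deriveSeed(seed, "probe_balance_tgt", rep),
                   sample.int(nrow(featTgt), m))
    trS <- withSeed(deriveSeed(seed, "probe_split_src", rep),
                    sample.int(m, half))
    trT <- withSeed(deriveSeed(seed, "probe_split_tgt", rep),
                    sample.int(m, half))
    xTrain <- rbind(featSrc[iS[trS], , drop = FALSE],
                    featTgt[iT[trT], , drop = FALSE])
    xTest <- rbind(featSrc[iS[-trS], , drop = FALSE],
                   featTgt[iT[-trT], , drop = FALSE])
    yTrain <- c(rep(0L, half), rep(1L, half))
    yTest <- c(rep(0L, m - half), rep(1L, m - half))
    fit <- glmnet::glmnet(xTrain, factor(yTrain, levels = c(0, 1)),
                          family = "binomial", alpha = 0, lambda = 0.01,
                          standardize = TRUE)
    p <- as.numeric(predict(fit, xTest, type = "response"))
    mean(as.integer(p > 0.5) == yTest)
  }, numeric(1))
  structure(mean(accs), nTest = nRepeats * 2L * (m - half),
            nTestDistinct = 2L * (m - half))
}

dadspVariants <- c("DADSP-A", "DADSPA-", "DADSP-B", "DADSP-B-stage1",
                   "DeepDSC-1", "DeepDSC-2", "SourceOnly")

#' Ablation harness over model variants and seeds
#'
#' Reproduces the published comparison structure on synthetic data. For
#' each seed the domain pair is regenerated (when `x` is a
#' [SimulationConfig-class]) or reused (when `x` is an existing pair), the
#' target responses are split, each requested variant is trained, and
#' target-domain test metrics are recorded.
#'
#' Variants: `"DADSP-A"` (adversarial, pretrained), `"DADSPA-"`
#' (adversarial, no pretraining), `"DADSP-B"` (three-stage MMD transfer),
#' `"DADSP-B-stage1"` (its stage-1 model applied directly to the target),
#' `"DeepDSC-1"` (target-only feedforward model with a target-trained
#' autoencoder), `"DeepDSC-2"` (target-trained regressor with an
#' autoencoder pretrained on both domains), `"SourceOnly"` (source-trained,
#' no adversary: the no-adaptation reference).
#'
#' @param x a [SimulationConfig-class] or a domain pair from
#'   [generateDomainPair()].
#' @param variants subset of the variant names above.
#' @param seeds integer vector; one run per seed.
#' @param dadspConfig,saeConfig,mmdConfig,splitSpec configuration objects;
#'   their seeds are re-derived per run.
#' @return data.frame with one row per (variant, seed) and metric columns
#'   from [evaluatePredictions()].
#' @export
runAblation <- function(x, variants = c("DADSP-A", "DeepDSC-1"),
                        seeds = 1:3, dadspConfig = DadspConfig(),
                        saeConfig = SAEConfig(), mmdConfig = MMDConfig(),
                        splitSpec = SplitSpec("standard")) {
  bad <- setdiff(variants, dadspVariants)
  if (length(bad)) {
    stopf("unknown variant(s): %s", paste(bad, collapse = ", "))
  }
  rows <- list()
  for (seed in seeds) {
    pair <- if (is(x, "SimulationConfig")) {
      cfg <- x
      cfg@seed <- as.integer(seed)
      generateDomainPair(cfg)
    } else {
      x
    }
    sSpec <- splitSpec
    sSpec@seed <- deriveSeed(seed, "split")
    prep <- prepareDomainPair(pair, sSpec)
    dCfg <- dadspConfig
    dCfg@seed <- deriveSeed(seed, "train")
    aCfg <- saeConfig
    aCfg@seed <- deriveSeed(seed, "sae")
    mCfg <- mmdConfig
    mCfg@seed <- deriveSeed(seed, "mmd")
    cache <- new.env(parent = emptyenv())
    for (variant in variants) {
      model <- fitVariant(variant, prep, dCfg, aCfg, mCfg, cache)
      pr <- predictDadsp(model, prep$targetTest$X_gene, prep$targetTest$X_drug)
      met <- evaluatePredictions(prep$targetTest$y, pr$normalized)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(variant = variant, seed = seed), met)
    }
  }
  do.call(rbind, rows)
}

# Train one ablation variant; heavyweight intermediates (autoencoders, the
# three-stage run) are cached per seed so requesting related variants does
# not retrain them.
fitVariant <- function(variant, prep, dCfg, aCfg, mCfg, cache = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  saeOn <- function(key, X) {
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, pretrainLayerwise(X, aCfg), envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
  srcNorm <- list(features = prep$norm$features, labels = prep$norm$sourceLabels)
  tgtNorm <- list(features = prep$norm$features, labels = prep$norm$targetLabels)
  tgtTrain <- prep$targetTrain %||% prep$target
  switch(variant,
    "DADSP-A" = {
      cfg <- dCfg; cfg@adversarial <- TRUE; cfg@pretrain <- TRUE
      enc <- exportEncoder(saeOn("sae_src", prep$sourceGene))
      trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                 targetGene = prep$targetGene, config = cfg,
                 encoderInit = enc, norm = srcNorm, variant = "DADSP-A")
    },
    "DADSPA-" = {
      cfg <- dCfg; cfg@adversarial <- TRUE; cfg@pretrain <- FALSE
      trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                 targetGene = prep$targetGene, config = cfg,
                 norm = srcNorm, variant = "DADSPA-")
    },
    "DADSP-B" = ,
    "DADSP-B-stage1" = {
      if (is.null(cache$dadspB)) {
        cfg <- dCfg; cfg@adversarial <- FALSE; cfg@pretrain <- TRUE
        enc <- exportEncoder(saeOn("sae_src", prep$sourceGene))
        cache$dadspB <- trainDadspB(prep$source$X_gene, prep$source$X_drug,
                                    prep$source$y, prep$targetGene,
                                    config = cfg, mmdConfig = mCfg,
                                    encoderInit = enc, norm = srcNorm,
                                    sourceGene = prep$sourceGene)
      }
      if (variant == "DADSP-B") cache$dadspB$final else cache$dadspB$stage1
    },
    "DeepDSC-1" = {
      cfg <- dCfg; cfg@adversarial <- FALSE; cfg@pretrain <- TRUE
      enc <- exportEncoder(saeOn("sae_tgt", prep$targetGene))
      trainDadsp(tgtTrain$X_gene, tgtTrain$X_drug, tgtTrain$y,
                 config = cfg, encoderInit = enc, norm = tgtNorm,
                 variant = "DeepDSC-1")
    },
    "DeepDSC-2" = {
      cfg <- dCfg; cfg@adversarial <- FALSE; cfg@pretrain <- TRUE
      enc <- exportEncoder(saeOn("sae_both",
                                 rbind(prep$sourceGene, prep$targetGene)))
      trainDadsp(tgtTrain$X_gene, tgtTrain$X_drug, tgtTrain$y,
                 config = cfg, encoderInit = enc, norm = tgtNorm,
                 variant = "DeepDSC-2")
    },
    "SourceOnly" = {
      cfg <- dCfg; cfg@adversarial <- FALSE; cfg@pretrain <- TRUE
      enc <- exportEncoder(saeOn("sae_src", prep$sourceGene))
      trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                 config = cfg, encoderInit = enc, norm = srcNorm,
                 variant = "SourceOnly")
    },
    stopf("unknown variant '%s'", variant))
}

#' Predict and rank unmeasured (cell line, drug) pairs
#'
#' Enumerates pairs absent from the response table, predicts their response
#' with a trained model, and returns them ranked by predicted sensitivity
#' (highest predicted -log10 IC50, i.e. lowest IC50, first).
#'
#' @param model a trained [DadspModel-class] (with stored normalization).
#' @param expr an [ExpressionMatrix-class] of the domain to predict in.
#' @param fps a [FingerprintSet-class].
#' @param responses the measured [ResponseTable-class].
#' @return data.frame `(cell_id, drug_id, pred_normalized, pred_response)`
#'   sorted most-sensitive first.
#' @export
predictMissing <- function(model, expr, fps, responses) {
  d <- responseData(responses)
  have <- paste(d$cell_id, d$drug_id, sep = "\r")
  grid <- expand.grid(cell_id = cellIds(expr), drug_id = drugIds(fps),
                      stringsAsFactors = FALSE)
  key <- paste(grid$cell_id, grid$drug_id, sep = "\r")
  missing <- grid[!key %in% have, , drop = FALSE]
  if (!nrow(missing)) {
    return(data.frame(cell_id = character(), drug_id = character(),
                      pred_normalized = numeric(), pred_response = numeric()))
  }
  v <- exprValues(expr)[missing$cell_id, , drop = FALSE]
  if (!is.null(model@norm$features)) v <- applyMinMax(v, model@norm$features)
  Xd <- fingerprintBits(fps)[missing$drug_id, , drop = FALSE]
  pr <- predictDadsp(model, v, Xd)
  out <- data.frame(cell_id = missing$cell_id, drug_id = missing$drug_id,
                    pred_normalized = pr$normalized,
                    pred_response = pr$response %||% NA_real_)
  out[order(-out$pred_normalized), , drop = FALSE]
}

#' Two-dimensional view of the source/target feature space
#'
#' Principal-component scatter of pooled feature rows, colored by domain —
#' a quick visual companion to [domainConfusionProbe()], which is the
#' quantitative diagnostic.
#'
#' @param featSrc,featTgt feature matrices (rows = samples).
#' @param main plot title.
#' @return the PCA scores, invisibly.
#' @export
plotFeatureSpace <- function(featSrc, featTgt, main = "feature space") {
  Z <- rbind(as.matrix(featSrc), as.matrix(featTgt))
  keep <- apply(Z, 2, sd) > 0
  pc <- stats::prcomp(Z[, keep, drop = FALSE], scale. = TRUE)
  lab <- c(rep(1L, nrow(featSrc)), rep(2L, nrow(featTgt)))
  graphics::plot(pc$x[, 1:2], col = c("#1f77b4", "#d62728")[lab],
                 pch = c(1, 3)[lab], main = main,
                 xlab = "PC1", ylab = "PC2")
  graphics::legend("topright", legend = c("source", "target"),
                   col = c("#1f77b4", "#d62728"), pch = c(1, 3), bty = "n")
  invisible(pc$x[, 1:2])
}
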