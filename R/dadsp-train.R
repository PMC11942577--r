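# DADSP-A: adversarial domain-adaptive training.
#
# Four sub-networks: gene feature extractor (optionally initialized from a
# pretrained stacked-autoencoder encoder), drug feature extractor (two
# hidden layers on the fingerprint bits), domain discriminator (three
# layers, 2-unit softmax) behind a gradient reversal layer, and regression
# predictor (four layers, sigmoid head so predictions live in [0, 1]).
#
# Each training step draws a labeled source batch and an equally sized
# unlabeled target batch (resampled with replacement — the target domain is
# roughly an order of magnitude smaller), concatenates them along the batch
# dimension through the gene extractor, splits the features again so the
# regressor sees only source features joined with drug features, and feeds
# all features through the GRL into the discriminator.

dadspInitNets <- function(nGenes, nDrugBits, config, encoderInit = NULL) {
  if (!is.null(encoderInit)) {
    if (encoderInit$inputDim != nGenes) {
      stopf("encoder bundle expects %d genes but the data has %d",
            encoderInit$inputDim, nGenes)
    }
    gene <- encoderInit$layers
  } else {
    gd <- config@geneDims
    gene <- nnInit(c(nGenes, gd), rep("relu", length(gd)),
                   seed = deriveSeed(config@seed, "init_gene"))
  }
  geneOut <- ncol(gene[[length(gene)]]$W)
  dd <- config@drugDims
  drug <- nnInit(c(nDrugBits, dd), rep("relu", length(dd)),
                 seed = deriveSeed(config@seed, "init_drug"))
  drugOut <- dd[length(dd)]
  disc <- nnInit(c(geneOut, config@discDims, 2L),
                 c(rep("relu", length(config@discDims)), "softmax"),
                 seed = deriveSeed(config@seed, "init_disc"))
  reg <- nnInit(c(geneOut + drugOut, config@regDims, 1L),
                c(rep("relu", length(config@regDims)), "sigmoid"),
                seed = deriveSeed(config@seed, "init_reg"))
  list(gene = gene, drug = drug, disc = disc, reg = reg)
}

#' Train the adversarial transfer model (DADSP-A)
#'
#' Minimizes `L_Total = L_MSE + L_domain`: the regression loss is the batch
#' mean squared error on min-max scaled labels, the domain loss is the mean
#' cross-entropy of the 2-unit softmax discriminator. The gradient reversal
#' layer between the gene features and the discriminator multiplies the
#' discriminator's feature gradient by `-lambda`, so minimizing the
#' discriminator simultaneously pushes the extractor toward
#' domain-confusable features. `lambda` follows [lambdaSchedule()] over the
#' planned iterations. Training stops early when the epoch loss fails to
#' decrease for `earlyStoppingPatience` consecutive epochs.
#'
#' @param XGene source-domain gene inputs (triplets x genes), min-max scaled.
#' @param XDrug source-domain drug fingerprints aligned with `XGene` rows.
#' @param y source labels scaled to `[0, 1]`.
#' @param targetGene unlabeled target-domain expression (cells x genes),
#'   same gene columns and scaling; required when `config@adversarial`.
#' @param config a [DadspConfig-class].
#' @param encoderInit optional encoder bundle from [exportEncoder()];
#'   required when `config@pretrain` is `TRUE`.
#' @param norm optional list of [NormalizationParams-class] (`features`,
#'   `labels`) stored in the model for later inverse transforms.
#' @param variant free-text tag recorded on the model.
#' @return a trained [DadspModel-class] with per-epoch loss history.
#' @export
trainDadsp <- function(XGene, XDrug, y, targetGene = NULL,
                       config = DadspConfig(), encoderInit = NULL,
                       norm = list(), variant = NULL) {
  validObject(config)
  XGene <- unname(as.matrix(XGene))
  XDrug <- unname(as.matrix(XDrug))
  y <- as.numeric(y)
  n <- nrow(XGene)
  if (nrow(XDrug) != n || length(y) != n) {
    stopf("gene inputs, drug inputs and labels must align row-wise")
  }
  if (!all(is.finite(XGene)) || !all(is.finite(y))) {
    stopf("non-finite training inputs")
  }
  if (config@adversarial &&
      (is.null(targetGene) || nrow(as.matrix(targetGene)) == 0L)) {
    stopf("adversarial training requires target-domain expression")
  }
  if (config@pretrain && is.null(encoderInit)) {
    stopf(paste("config requests pretraining but no encoder bundle was",
                "supplied; pass exportEncoder(...) or set pretrain = FALSE"))
  }
  if (!config@pretrain) encoderInit <- NULL
  if (!is.null(targetGene)) {
    targetGene <- unname(as.matrix(targetGene))
    if (ncol(targetGene) != ncol(XGene)) {
      stopf("source and target gene inputs must share columns")
    }
  }

  nets <- dadspInitNets(ncol(XGene), ncol(XDrug), config, encoderInit)
  states <- lapply(nets, adamInit)
  bs <- config@batchSize
  stepsPerEpoch <- ceiling(n / bs)
  totalSteps <- config@epochs * stepsPerEpoch
  nTgt <- if (is.null(targetGene)) 0L else nrow(targetGene)

  hist <- data.frame(epoch = integer(), L_MSE = double(),
                     L_domain = double(), L_Total = double(),
                     lambda = double())
  best <- Inf
  bad <- 0L
  t <- 0L

  for (epoch in seq_len(config@epochs)) {
    perm <- withSeed(deriveSeed(config@seed, "shuffle", epoch), sample.int(n))
    if (config@adversarial) {
      tgtIdxAll <- withSeed(deriveSeed(config@seed, "target_sample", epoch),
                            sample.int(nTgt, stepsPerEpoch * bs, replace = TRUE))
    }
    sumMse <- 0
    sumDom <- 0
    lambda <- 0
    for (step in seq_len(stepsPerEpoch)) {
      idx <- perm[((step - 1L) * bs + 1L):min(step * bs, n)]
      m <- length(idx)
      p <- t / totalSteps
      lambda <- if (is.na(config@lambdaFix)) {
        lambdaSchedule(p, config@gamma)
      } else {
        config@lambdaFix
      }

      Xb <- XGene[idx, , drop = FALSE]
      if (config@adversarial) {
        tidx <- tgtIdxAll[((step - 1L) * bs + 1L):((step - 1L) * bs + m)]
        Xall <- rbind(Xb, targetGene[tidx, , drop = FALSE])
      } else {
        Xall <- Xb
      }
      fwG <- nnForward(nets$gene, Xall)
      feat <- fwG$out
      fs <- feat[seq_len(m), , drop = FALSE]
      fwD <- nnForward(nets$drug, XDrug[idx, , drop = FALSE])
      regIn <- cbind(fs, fwD$out)
      fwR <- nnForward(nets$reg, regIn)
      yhat <- as.numeric(fwR$out)
      resid <- yhat - y[idx]
      lMse <- mean(resid^2)

      lDom <- 0
      discBw <- NULL
      if (config@adversarial) {
        # GRL forward: identity on the features
        fwC <- nnForward(nets$disc, grlForward(feat, lambda))
        probs <- fwC$out
        lab <- c(rep(0L, m), rep(1L, m))  # source = 0, target = 1
        lDom <- domainLoss(lab, probs[, 2])
        onehot <- cbind(1 - lab, lab)
        dLogits <- (probs - onehot) / nrow(probs)
        discBw <- nnBackward(nets$disc, fwC$cache, dLogits)
      }
      lTot <- lMse + lDom
      if (!is.finite(lTot)) stopf("non-finite training loss at epoch %d", epoch)

      regBw <- nnBackward(nets$reg, fwR$cache, matrix(2 * resid / m, ncol = 1))
      gd <- ncol(fs)
      dFs <- regBw$gradIn[, seq_len(gd), drop = FALSE]
      dDrugFeat <- regBw$gradIn[, -seq_len(gd), drop = FALSE]
      drugBw <- nnBackward(nets$drug, fwD$cache, dDrugFeat)

      dFeat <- matrix(0, nrow(feat), gd)
      dFeat[seq_len(m), ] <- dFs
      if (config@adversarial) {
        # GRL backward: reversed, scaled gradient into the extractor
        dFeat <- dFeat + grlBackward(discBw$gradIn, lambda)
      }
      geneBw <- nnBackward(nets$gene, fwG$cache, dFeat)

      t <- t + 1L
      up <- adamStep(nets$gene, geneBw$grads, states$gene, config@learningRate, t)
      nets$gene <- up$net; states$gene <- up$state
      up <- adamStep(nets$drug, drugBw$grads, states$drug, config@learningRate, t)
      nets$drug <- up$net; states$drug <- up$state
      up <- adamStep(nets$reg, regBw$grads, states$reg, config@learningRate, t)
      nets$reg <- up$net; states$reg <- up$state
      if (config@adversarial) {
        up <- adamStep(nets$disc, discBw$grads, states$disc, config@learningRate, t)
        nets$disc <- up$net; states$disc <- up$state
      }
      sumMse <- sumMse + lMse
      sumDom <- sumDom + lDom
    }
    epMse <- sumMse / stepsPerEpoch
    epDom <- sumDom / stepsPerEpoch
    epTot <- epMse + epDom
    hist <- rbind(hist, data.frame(epoch = epoch, L_MSE = epMse,
                                   L_domain = epDom, L_Total = epTot,
                                   lambda = lambda))
    # Early stopping monitors the regression loss: the domain loss rises by
    # construction as lambda grows (the extractor is winning the adversarial
    # game), so the total would mis-signal divergence in adversarial runs.
    if (epMse < best) {
      best <- epMse
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config@earlyStoppingPatience) break
    }
  }

  if (is.null(variant)) {
    variant <- if (config@adversarial) {
      if (config@pretrain) "DADSP-A" else "DADSPA-"
    } else "feedforward"
  }
  new("DadspModel", geneExtractor = nets$gene, drugExtractor = nets$drug,
      discriminator = if (config@adversarial) nets$disc else list(),
      regressor = nets$reg, norm = norm, history = hist, config = config,
      variant = variant)
}

#' Forward pass of a DADSP model (inspection/testing aid)
#'
#' Runs the split-then-concatenate wiring once: source and target gene
#' inputs are concatenated along the batch dimension through the gene
#' extractor; the regressor sees only source gene features joined with drug
#' features; the discriminator (if present) sees all features through the
#' gradient reversal layer.
#'
#' @param model a [DadspModel-class].
#' @param XGeneSrc source gene inputs (rows align with `XDrugSrc`).
#' @param XGeneTgt optional target gene inputs.
#' @param XDrugSrc source drug fingerprints.
#' @param lambda GRL strength for the forward pass (identity regardless).
#' @return list with `yhat` (length = source rows) and `domainProbs`
#'   (all rows x 2, or NULL for non-adversarial models).
#' @export
dadspForward <- function(model, XGeneSrc, XGeneTgt = NULL, XDrugSrc,
                         lambda = 0) {
  XGeneSrc <- as.matrix(XGeneSrc)
  XDrugSrc <- as.matrix(XDrugSrc)
  stopifnot(nrow(XGeneSrc) == nrow(XDrugSrc))
  Xall <- if (is.null(XGeneTgt)) XGeneSrc else rbind(XGeneSrc, as.matrix(XGeneTgt))
  feat <- nnForward(model@geneExtractor, Xall, cache = FALSE)$out
  fs <- feat[seq_len(nrow(XGeneSrc)), , drop = FALSE]
  df <- nnForward(model@drugExtractor, XDrugSrc, cache = FALSE)$out
  yhat <- as.numeric(nnForward(model@regressor, cbind(fs, df), cache = FALSE)$out)
  probs <- NULL
  if (length(model@discriminator)) {
    probs <- nnForward(model@discriminator, grlForward(feat, lambda),
                       cache = FALSE)$out
  }
  list(yhat = yhat, domainProbs = probs)
}

#' Predict drug response with a trained model
#'
#' @param model a trained [DadspModel-class].
#' @param XGene gene inputs (rows x genes), min-max scaled like training.
#' @param XDrug drug fingerprints aligned with `XGene` rows.
#' @return list with `normalized` (sigmoid-scale predictions in `(0, 1)`)
#'   and `response` (inverse min-max transform to the -log10 IC50 label
#'   scale, or NULL when the model stores no label normalization).
#' @export
predictDadsp <- function(model, XGene, XDrug) {
  XGene <- as.matrix(XGene)
  XDrug <- as.matrix(XDrug)
  if (nrow(XGene) != nrow(XDrug)) stopf("gene and drug inputs must align")
  if (ncol(XGene) != nrow(model@geneExtractor[[1]]$W)) {
    stopf("gene input has %d features; model expects %d",
          ncol(XGene), nrow(model@geneExtractor[[1]]$W))
  }
  feat <- nnForward(model@geneExtractor, XGene, cache = FALSE)$out
  df <- nnForward(model@drugExtractor, XDrug, cache = FALSE)$out
  yhat <- as.numeric(nnForward(model@regressor, cbind(feat, df),
                               cache = FALSE)$out)
  resp <- if (!is.null(model@norm$labels)) {
    invertMinMax(yhat, model@norm$labels)
  }
  list(normalized = yhat, response = resp)
}

#' Gene features from a trained extractor
#'
#' @param model a [DadspModel-class].
#' @param XGene gene inputs (rows x genes), scaled like training.
#' @return feature matrix (rows x bottleneck width).
#' @export
geneFeatures <- function(model, XGene) {
  nnForward(model@geneExtractor, as.matrix(XGene), cache = FALSE)$out
}
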