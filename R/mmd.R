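# DADSP-B: MMD-regularized stacked-autoencoder transfer with staged
# parameter freezing.
#
# Stage 1 trains the gene extractor (SAE-initialized), drug branch and
# regressor on source data alone.  Stage 2 adapts the shared encoder layer
# by layer on target data: each layer minimizes the target reconstruction
# loss plus the squared maximum mean discrepancy between source and target
# codes at that layer, with the regressor frozen.  Stage 3 freezes all
# feature-extraction layers and fine-tunes the regressor on source data
# with the MSE loss only.

pairwiseSqDist <- function(X, Y) {
  xx <- rowSums(X^2)
  yy <- rowSums(Y^2)
  d <- outer(xx, yy, "+") - 2 * tcrossprod(X, Y)
  pmax(d, 0)
}

medianGamma <- function(Xs, Xt) {
  Z <- rbind(Xs, Xt)
  d <- pairwiseSqDist(Z, Z)
  med <- median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) 1 else 1 / med
}

#' Squared maximum mean discrepancy between two samples
#'
#' Kernel-expansion estimator of the squared RKHS distance between the mean
#' embeddings of two samples:
#' `mean k(s,s') + mean k(t,t') - 2 mean k(s,t)`. The default is the biased
#' V-statistic (diagonal terms included), which is non-negative; an
#' unbiased U-statistic is available and may be slightly negative. For the
#' RBF kernel the bandwidth follows the median heuristic on pooled pairwise
#' squared distances unless fixed.
#'
#' @param Xs,Xt numeric matrices (samples x features) with equal feature
#'   dimension.
#' @param kernel `"rbf"` or `"linear"`.
#' @param bandwidth fixed RBF bandwidth `h` (kernel `exp(-d2 / h)` with `d2`
#'   the squared distance); NA uses the median heuristic.
#' @param estimator `"biased"` (V-statistic) or `"unbiased"` (U-statistic).
#' @return scalar squared MMD (>= 0 for the biased estimator).
#' @export
mmd2 <- function(Xs, Xt, kernel = c("rbf", "linear"), bandwidth = NA_real_,
                 estimator = c("biased", "unbiased")) {
  kernel <- match.arg(kernel)
  estimator <- match.arg(estimator)
  Xs <- as.matrix(Xs)
  Xt <- as.matrix(Xt)
  if (ncol(Xs) != ncol(Xt)) {
    stopf("samples must share feature dimension (%d vs %d)",
          ncol(Xs), ncol(Xt))
  }
  ns <- nrow(Xs)
  nt <- nrow(Xt)
  stopifnot(ns >= 1, nt >= 1)
  if (kernel == "linear") {
    Kss <- tcrossprod(Xs)
    Ktt <- tcrossprod(Xt)
    Kst <- tcrossprod(Xs, Xt)
  } else {
    gamma <- if (is.na(bandwidth)) medianGamma(Xs, Xt) else 1 / bandwidth
    Kss <- exp(-gamma * pairwiseSqDist(Xs, Xs))
    Ktt <- exp(-gamma * pairwiseSqDist(Xt, Xt))
    Kst <- exp(-gamma * pairwiseSqDist(Xs, Xt))
  }
  if (estimator == "biased") {
    mean(Kss) + mean(Ktt) - 2 * mean(Kst)
  } else {
    if (ns < 2 || nt < 2) stopf("unbiased estimator needs >= 2 samples per side")
    (sum(Kss) - sum(diag(Kss))) / (ns * (ns - 1)) +
      (sum(Ktt) - sum(diag(Ktt))) / (nt * (nt - 1)) -
      2 * mean(Kst)
  }
}

# Gradient of the biased squared-MMD estimator w.r.t. both code matrices.
# The RBF bandwidth is treated as a constant at the current step (the
# median heuristic is recomputed each step but not differentiated).
mmd2Grad <- function(Xs, Xt, kernel, bandwidth = NA_real_) {
  ns <- nrow(Xs)
  nt <- nrow(Xt)
  if (kernel == "linear") {
    mus <- colMeans(Xs)
    mut <- colMeans(Xt)
    diff <- mus - mut
    list(dXs = matrix(2 * diff / ns, ns, length(diff), byrow = TRUE),
         dXt = matrix(-2 * diff / nt, nt, length(diff), byrow = TRUE),
         value = sum(diff^2))
  } else {
    gamma <- if (is.na(bandwidth)) medianGamma(Xs, Xt) else 1 / bandwidth
    Kss <- exp(-gamma * pairwiseSqDist(Xs, Xs))
    Ktt <- exp(-gamma * pairwiseSqDist(Xt, Xt))
    Kst <- exp(-gamma * pairwiseSqDist(Xs, Xt))
    val <- mean(Kss) + mean(Ktt) - 2 * mean(Kst)
    # d/dXs of mean(Kss): sum_j 2 * k(si,sj) * -2gamma (si - sj) / ns^2
    gKss <- (-4 * gamma / ns^2) * (Xs * rowSums(Kss) - Kss %*% Xs)
    gKtt <- (-4 * gamma / nt^2) * (Xt * rowSums(Ktt) - Ktt %*% Xt)
    cst <- -2 / (ns * nt)
    gKstS <- cst * (-2 * gamma) * (Xs * rowSums(Kst) - Kst %*% Xt)
    gKstT <- cst * (-2 * gamma) * (Xt * rowSums(t(Kst)) - t(Kst) %*% Xs)
    list(dXs = gKss + gKstS, dXt = gKtt + gKstT, value = val)
  }
}

#' Stage 1 of the MMD transfer protocol: supervised source training
#'
#' Trains the gene extractor (SAE-initialized when a bundle is given), drug
#' branch and regressor on source data only, with the plain MSE objective
#' (no adversary). No target data is touched.
#'
#' @inheritParams trainDadsp
#' @param mmdConfig an [MMDConfig-class] (stage-1 epochs come from
#'   `stageEpochs[1]`).
#' @return a [DadspModel-class] tagged `"stage1"`.
#' @export
trainStage1 <- function(XGene, XDrug, y, config = DadspConfig(),
                        mmdConfig = MMDConfig(), encoderInit = NULL,
                        norm = list()) {
  cfg <- config
  cfg@adversarial <- FALSE
  cfg@epochs <- mmdConfig@stageEpochs[1]
  cfg@earlyStoppingPatience <- min(cfg@earlyStoppingPatience, cfg@epochs)
  trainDadsp(XGene, XDrug, y, targetGene = NULL, config = cfg,
             encoderInit = encoderInit, norm = norm, variant = "stage1")
}

#' Stage 2: layer-wise encoder adaptation with reconstruction + MMD loss
#'
#' Shares the stage-1 encoder with the target domain and adapts it layer by
#' layer: each encoder layer (plus a fresh decoder head) minimizes the
#' target-domain reconstruction MSE plus `mmdWeight` times the squared MMD
#' between source and target codes at that layer. The regressor (and drug
#' branch) are frozen bitwise. Full-batch Adam; both domains' codes flow
#' through the shared layer, so the MMD gradient also shapes the source
#' representation.
#'
#' @param stage1 the [DadspModel-class] from [trainStage1()].
#' @param targetGene target-domain expression (cells x genes), scaled like
#'   training data.
#' @param sourceGene source-domain expression used for the MMD reference.
#' @param mmdConfig an [MMDConfig-class].
#' @return a [DadspModel-class] tagged `"stage2"` with the adapted encoder;
#'   `metadata` in its history records per-layer start/end MMD.
#' @export
trainStage2 <- function(stage1, targetGene, sourceGene,
                        mmdConfig = MMDConfig()) {
  stopifnot(is(stage1, "DadspModel"))
  regHash <- serialize(stage1@regressor, NULL)
  targetGene <- unname(as.matrix(targetGene))
  sourceGene <- unname(as.matrix(sourceGene))
  enc <- stage1@geneExtractor
  codesT <- targetGene
  codesS <- sourceGene
  epochs <- mmdConfig@stageEpochs[2]
  mmdTrace <- data.frame(layer = integer(), mmd_start = double(),
                         mmd_end = double())

  for (l in seq_along(enc)) {
    nIn <- nrow(enc[[l]]$W)
    decAct <- if (l == 1L) "sigmoid" else "relu"
    dec <- nnInit(c(ncol(enc[[l]]$W), nIn), decAct,
                  seed = deriveSeed(mmdConfig@seed, "stage2_dec", l))
    layer <- list(enc[[l]], dec[[1]])
    st <- adamInit(layer)
    m0 <- NA_real_
    for (ep in seq_len(epochs)) {
      fwT <- nnForward(layer, codesT)          # encode + reconstruct target
      encT <- fwT$cache[[1]]$out
      fwS <- nnForward(layer[1], codesS)       # source codes, shared encoder
      encS <- fwS$out
      resid <- fwT$out - codesT
      recon <- mean(resid^2)
      mg <- mmd2Grad(encS, encT, mmdConfig@kernel, mmdConfig@bandwidth)
      if (ep == 1L) m0 <- mg$value
      loss <- recon + mmdConfig@mmdWeight * mg$value
      if (!is.finite(loss)) stopf("non-finite stage-2 loss at layer %d", l)

      bwT <- nnBackward(layer, fwT$cache, 2 * resid / length(resid))
      gradsEnc <- bwT$grads[[1]]
      gradsDec <- bwT$grads[[2]]
      # MMD contribution through the shared encoder, both domains
      w <- mmdConfig@mmdWeight
      bwMmdT <- nnBackward(layer[1], fwT$cache[1], w * mg$dXt)
      bwMmdS <- nnBackward(layer[1], fwS$cache, w * mg$dXs)
      gradsEnc$dW <- gradsEnc$dW + bwMmdT$grads[[1]]$dW + bwMmdS$grads[[1]]$dW
      gradsEnc$db <- gradsEnc$db + bwMmdT$grads[[1]]$db + bwMmdS$grads[[1]]$db
      up <- adamStep(layer, list(gradsEnc, gradsDec), st,
                     mmdConfig@learningRate, ep)
      layer <- up$net
      st <- up$state
    }
    enc[[l]] <- layer[[1]]
    encS_f <- nnForward(layer[1], codesS, cache = FALSE)$out
    encT_f <- nnForward(layer[1], codesT, cache = FALSE)$out
    mEnd <- mmd2(encS_f, encT_f, mmdConfig@kernel, mmdConfig@bandwidth)
    mmdTrace <- rbind(mmdTrace, data.frame(layer = l, mmd_start = m0,
                                           mmd_end = mEnd))
    codesS <- encS_f
    codesT <- encT_f
  }

  if (!identical(serialize(stage1@regressor, NULL), regHash)) {
    stopf("invariant breach: regressor parameters drifted during stage 2")
  }
  out <- stage1
  out@geneExtractor <- enc
  out@variant <- "stage2"
  attr(out@history, "stage2_mmd") <- mmdTrace
  out
}

#' Stage 3: regressor fine-tuning with frozen feature extractors
#'
#' Freezes every feature-extraction layer (adapted gene encoder and drug
#' branch) and retrains the regressor on source data with the MSE loss
#' only. Because the extractors are frozen, their codes are precomputed
#' once.
#'
#' @param stage2 the [DadspModel-class] from [trainStage2()].
#' @param XGene,XDrug,y assembled source arrays (as in [trainDadsp()]).
#' @param config a [DadspConfig-class] (batch size reused).
#' @param mmdConfig an [MMDConfig-class] (`stageEpochs[3]`, learning rate).
#' @return the final [DadspModel-class], tagged `"DADSP-B"`.
#' @export
trainStage3 <- function(stage2, XGene, XDrug, y, config = DadspConfig(),
                        mmdConfig = MMDConfig()) {
  stopifnot(is(stage2, "DadspModel"))
  extractorHash <- serialize(list(stage2@geneExtractor, stage2@drugExtractor),
                             NULL)
  XGene <- unname(as.matrix(XGene))
  XDrug <- unname(as.matrix(XDrug))
  y <- as.numeric(y)
  feat <- nnForward(stage2@geneExtractor, XGene, cache = FALSE)$out
  df <- nnForward(stage2@drugExtractor, XDrug, cache = FALSE)$out
  Z <- cbind(feat, df)
  reg <- stage2@regressor
  st <- adamInit(reg)
  n <- nrow(Z)
  bs <- config@batchSize
  t <- 0L
  losses <- numeric(mmdConfig@stageEpochs[3])
  for (ep in seq_len(mmdConfig@stageEpochs[3])) {
    perm <- withSeed(deriveSeed(mmdConfig@seed, "stage3_shuffle", ep),
                     sample.int(n))
    epLoss <- 0
    nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      fw <- nnForward(reg, Z[idx, , drop = FALSE])
      resid <- as.numeric(fw$out) - y[idx]
      loss <- mean(resid^2)
      if (!is.finite(loss)) stopf("non-finite stage-3 loss")
      bw <- nnBackward(reg, fw$cache, matrix(2 * resid / length(idx), ncol = 1))
      t <- t + 1L
      up <- adamStep(reg, bw$grads, st, mmdConfig@learningRate, t)
      reg <- up$net
      st <- up$state
      epLoss <- epLoss + loss
      nb <- nb + 1L
    }
    losses[ep] <- epLoss / nb
  }
  if (!identical(serialize(list(stage2@geneExtractor, stage2@drugExtractor),
                           NULL), extractorHash)) {
    stopf("invariant breach: feature extractor drifted during stage 3")
  }
  out <- stage2
  out@regressor <- reg
  out@variant <- "DADSP-B"
  attr(out@history, "stage3_loss") <- losses
  out
}

#' Full three-stage MMD transfer training (DADSP-B)
#'
#' @inheritParams trainStage1
#' @param targetGene target-domain expression (cells x genes), scaled.
#' @param sourceGene source-domain expression (cells x genes) used as the
#'   stage-2 MMD reference; defaults to the unique rows of `XGene`. Passing
#'   the per-cell expression matrix directly avoids weighting cells by
#'   their number of response triplets.
#' @return list with `stage1` and `final` [DadspModel-class] objects.
#' @export
trainDadspB <- function(XGene, XDrug, y, targetGene, config = DadspConfig(),
                        mmdConfig = MMDConfig(), encoderInit = NULL,
                        norm = list(), sourceGene = NULL) {
  if (is.null(sourceGene)) sourceGene <- unique(as.matrix(XGene))
  s1 <- trainStage1(XGene, XDrug, y, config = config, mmdConfig = mmdConfig,
                    encoderInit = encoderInit, norm = norm)
  s2 <- trainStage2(s1, targetGene, sourceGene, mmdConfig = mmdConfig)
  s3 <- trainStage3(s2, XGene, XDrug, y, config = config,
                    mmdConfig = mmdConfig)
  list(stage1 = s1, final = s3)
}
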