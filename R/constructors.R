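#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, cell lines as rows, genes as columns.
#' @param cellIds,geneIds identifiers; default to the dimnames of `values`.
#' @param domainTag `"source"` or `"target"`.
#' @return an [ExpressionMatrix-class].
#' @examples
#' m <- matrix(runif(12, 3, 10), 3, 4,
#'             dimnames = list(paste0("C", 1:3), paste0("G", 1:4)))
#' ExpressionMatrix(m, domainTag = "source")
#' @export
ExpressionMatrix <- function(values, cellIds = rownames(values),
                             geneIds = colnames(values),
                             domainTag = c("source", "target")) {
  domainTag <- match.arg(domainTag)
  values <- as.matrix(values)
  if (is.null(cellIds)) cellIds <- paste0("cell", seq_len(nrow(values)))
  if (is.null(geneIds)) stopf("gene IDs are required")
  storage.mode(values) <- "double"
  a <- t(values)  # genes x cells, Bioconductor orientation
  dimnames(a) <- list(as.character(geneIds), as.character(cellIds))
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(exprs = a))
  new("ExpressionMatrix", se, domainTag = domainTag)
}

#' @describeIn ExpressionMatrix expression values in cell-by-gene orientation.
#' @param x an `ExpressionMatrix`.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  t(SummarizedExperiment::assay(x, "exprs"))
}

#' @describeIn ExpressionMatrix cell-line identifiers.
#' @export
cellIds <- function(x) colnames(x)

#' @describeIn ExpressionMatrix gene identifiers.
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn ExpressionMatrix domain tag ("source" or "target").
#' @export
domainTag <- function(x) x@domainTag

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s domain]: %d cell lines x %d genes\n",
              object@domainTag, ncol(object), nrow(object)))
  v <- SummarizedExperiment::assay(object)
  cat(sprintf("  value range: [%.3g, %.3g]\n", min(v), max(v)))
})

#' Construct a FingerprintSet
#'
#' @param bits binary matrix, drugs (rows, named by drug ID) x bits.
#' @return a [FingerprintSet-class].
#' @export
FingerprintSet <- function(bits) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "double"
  new("FingerprintSet", bits = bits)
}

#' @describeIn FingerprintSet drug identifiers.
#' @param x a `FingerprintSet`.
#' @export
drugIds <- function(x) rownames(x@bits)

#' @describeIn FingerprintSet the drugs-by-bits binary matrix.
#' @export
fingerprintBits <- function(x) x@bits

#' @describeIn FingerprintSet fingerprint length.
#' @export
nBits <- function(x) ncol(x@bits)

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d drugs x %d bits (mean popcount %.1f)\n",
              nrow(object@bits), ncol(object@bits), mean(rowSums(object@bits))))
})

#' Construct a ResponseTable from (cell, drug, IC50) triplets
#'
#' IC50 values are stored raw and as the modeling response
#' `y = -log10(IC50)`.
#'
#' @param cellId,drugId character vectors.
#' @param ic50 positive IC50 values on the original scale.
#' @return a [ResponseTable-class].
#' @export
ResponseTable <- function(cellId, drugId, ic50) {
  stopifnot(length(cellId) == length(drugId), length(drugId) == length(ic50))
  y <- negLog10Ic50(ic50)
  new("ResponseTable", data = S4Vectors::DataFrame(
    cell_id = as.character(cellId), drug_id = as.character(drugId),
    y_raw = as.numeric(ic50), y = y))
}

#' @describeIn ResponseTable triplets as a plain data.frame.
#' @param x a `ResponseTable`.
#' @export
responseData <- function(x) as.data.frame(x@data)

#' @describeIn ResponseTable number of triplets.
#' @export
nResponses <- function(x) nrow(x@data)

setMethod("show", "ResponseTable", function(object) {
  d <- object@data
  cat(sprintf(
    "ResponseTable: %d triplets, %d cell lines, %d drugs; -log10 IC50 in [%.3g, %.3g]\n",
    nrow(d), length(unique(d$cell_id)), length(unique(d$drug_id)),
    if (nrow(d)) min(d$y) else NA, if (nrow(d)) max(d$y) else NA))
})

#' Construct a SimulationConfig
#'
#' @param nGenes,nCellsSource,nCellsTarget,nDrugs,latentDim problem sizes.
#' @param delta latent covariate-shift strength.
#' @param sigma noise standard deviation (expression and response).
#' @param fingerprintDensity Bernoulli rate of fingerprint bits.
#' @param targetResponseDensity fraction of target (cell, drug) pairs with a
#'   measured response; the default keeps the labeled source set about ten
#'   times the labeled target set, the regime of the motivating databases.
#' @param nBits fingerprint length.
#' @param seed master seed; every random component draws from a named
#'   substream derived from it.
#' @return a [SimulationConfig-class].
#' @export
SimulationConfig <- function(nGenes = 500L, nCellsSource = 200L,
                             nCellsTarget = 60L, nDrugs = 30L,
                             latentDim = 10L, delta = 1.0, sigma = 0.1,
                             fingerprintDensity = 0.1,
                             targetResponseDensity = 1 / 3, nBits = 256L,
                             seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nCellsSource = as.integer(nCellsSource),
      nCellsTarget = as.integer(nCellsTarget), nDrugs = as.integer(nDrugs),
      latentDim = as.integer(latentDim), delta = as.numeric(delta),
      sigma = as.numeric(sigma),
      fingerprintDensity = as.numeric(fingerprintDensity),
      targetResponseDensity = as.numeric(targetResponseDensity),
      nBits = as.integer(nBits), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d genes, %d source / %d target cells, %d drugs (q=%d, delta=%.2g, sigma=%.2g, seed=%d)\n",
    object@nGenes, object@nCellsSource, object@nCellsTarget, object@nDrugs,
    object@latentDim, object@delta, object@sigma, object@seed))
})

#' Construct an SAEConfig
#'
#' @param layerDims strictly decreasing encoder widths.
#' @param epochsPerLayer,finetuneEpochs training lengths.
#' @param learningRate,batchSize Adam settings.
#' @param seed integer.
#' @return a [SAEConfig-class].
#' @export
SAEConfig <- function(layerDims = c(256L, 64L, 32L), epochsPerLayer = 30L,
                      finetuneEpochs = 30L, learningRate = 1e-3,
                      batchSize = 32L, seed = 1L) {
  new("SAEConfig", layerDims = as.integer(layerDims),
      epochsPerLayer = as.integer(epochsPerLayer),
      finetuneEpochs = as.integer(finetuneEpochs),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Construct a DadspConfig
#'
#' @param learningRate,batchSize,epochs,earlyStoppingPatience,gamma training
#'   recipe (defaults: 1e-4, 128, 15, 3, 10).
#' @param geneDims encoder widths used when no pretrained encoder is given.
#' @param drugDims,discDims,regDims hidden widths of drug branch,
#'   discriminator and regressor.
#' @param adversarial enable the discriminator/GRL path.
#' @param pretrain initialize the gene extractor from a stacked autoencoder.
#' @param lambdaFix optional fixed lambda (NA = schedule).
#' @param seed integer.
#' @return a [DadspConfig-class].
#' @export
DadspConfig <- function(learningRate = 1e-4, batchSize = 128L, epochs = 15L,
                        earlyStoppingPatience = 3L, gamma = 10,
                        geneDims = c(256L, 64L, 32L),
                        drugDims = c(128L, 64L),
                        discDims = c(256L, 128L),
                        regDims = c(128L, 64L, 16L),
                        adversarial = TRUE, pretrain = TRUE,
                        lambdaFix = NA_real_, seed = 1L) {
  new("DadspConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      earlyStoppingPatience = as.integer(earlyStoppingPatience),
      gamma = as.numeric(gamma), geneDims = as.integer(geneDims),
      drugDims = as.integer(drugDims), discDims = as.integer(discDims),
      regDims = as.integer(regDims), adversarial = isTRUE(adversarial),
      pretrain = isTRUE(pretrain), lambdaFix = as.numeric(lambdaFix),
      seed = as.integer(seed))
}

setMethod("show", "DadspModel", function(object) {
  cat(sprintf("DadspModel [%s]: %d-gene input, %d epochs trained\n",
              object@variant,
              if (length(object@geneExtractor)) nrow(object@geneExtractor[[1]]$W) else NA,
              nrow(object@history)))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final losses: L_MSE=%.5f  L_domain=%.5f  L_Total=%.5f\n",
                last$L_MSE, last$L_domain, last$L_Total))
  }
})

#' Construct an MMDConfig
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param bandwidth fixed RBF bandwidth; NA uses the median heuristic.
#' @param mmdWeight weight of the MMD penalty (default 1: the discrepancy
#'   enters the reconstruction objective unweighted).
#' @param stageEpochs integer triple (stage-1, stage-2 per layer, stage-3).
#' @param learningRate Adam rate for stages 2-3.
#' @param seed integer.
#' @return an [MMDConfig-class].
#' @export
MMDConfig <- function(kernel = c("rbf", "linear"), bandwidth = NA_real_,
                      mmdWeight = 1.0, stageEpochs = c(15L, 100L, 100L),
                      learningRate = 1e-3, seed = 1L) {
  kernel <- match.arg(kernel)
  new("MMDConfig", kernel = kernel, bandwidth = as.numeric(bandwidth),
      mmdWeight = as.numeric(mmdWeight), stageEpochs = as.integer(stageEpochs),
      learningRate = as.numeric(learningRate), seed = as.integer(seed))
}

#' Construct a SplitSpec
#'
#' @param mode `"standard"` or `"blind"`.
#' @param testFraction pair fraction held out in standard mode.
#' @param drugFraction,cellFraction entity fractions held out in blind mode.
#' @param seed integer.
#' @return a [SplitSpec-class].
#' @export
SplitSpec <- function(mode = c("standard", "blind"), testFraction = 0.2,
                      drugFraction = 0.1, cellFraction = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  new("SplitSpec", mode = mode, testFraction = as.numeric(testFraction),
      drugFraction = as.numeric(drugFraction),
      cellFraction = as.numeric(cellFraction), seed = as.integer(seed))
}

setMethod("show", "AttributionResult", function(object) {
  cat(sprintf(
    "AttributionResult: cell %s, drug %s, %d genes (baseline: %s, %d steps)\n",
    object@cellId, object@drugId, length(object@scores), object@baseline,
    object@nSteps))
  cat(sprintf("  completeness gap: %.3g\n", object@completenessGap))
})
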