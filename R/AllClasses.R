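#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

#' ExpressionMatrix: cell-line by gene expression with a domain tag
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one expression matrix (genes as rows, cell lines as columns, following
#' Bioconductor convention) together with a `domainTag` marking it as the
#' labeled source domain or the differently distributed target domain.
#' User-facing accessors present the matrix in cell-by-gene orientation,
#' the layout used by the model input pipeline.
#'
#' @slot domainTag `"source"` or `"target"`.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(domainTag = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@domainTag) != 1L ||
      !object@domainTag %in% c("source", "target")) {
    msg <- c(msg, "domainTag must be one of 'source', 'target'")
  }
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a)) msg <- c(msg, "expression values contain missing entries")
  if (!is.numeric(a)) msg <- c(msg, "expression values must be numeric")
  gid <- rownames(object)
  if (is.null(gid) || anyDuplicated(gid)) {
    msg <- c(msg, "gene IDs must be present and unique")
  }
  if (is.null(colnames(object))) msg <- c(msg, "cell IDs must be present")
  if (length(msg)) msg else TRUE
})

#' FingerprintSet: drug-ID to fixed-length bit vector map
#'
#' @slot bits binary matrix, drugs (rows, named by drug ID) by fingerprint
#'   bits (columns); every entry 0 or 1.
#' @exportClass FingerprintSet
setClass("FingerprintSet", representation(bits = "matrix"))

setValidity("FingerprintSet", function(object) {
  b <- object@bits
  msg <- character()
  if (is.null(rownames(b)) || anyDuplicated(rownames(b))) {
    msg <- c(msg, "drug IDs (rownames) must be present and unique")
  }
  if (!all(b %in% c(0, 1))) msg <- c(msg, "all fingerprint entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' ResponseTable: (cell line, drug, IC50) response triplets
#'
#' Stores the raw IC50 alongside the transformed response
#' `y = -log10(IC50)` used for modeling.
#'
#' @slot data a [S4Vectors::DataFrame] with columns `cell_id`, `drug_id`,
#'   `y_raw` (IC50, original scale) and `y` (-log10 IC50).
#' @exportClass ResponseTable
setClass("ResponseTable", representation(data = "DataFrame"))

setValidity("ResponseTable", function(object) {
  d <- object@data
  need <- c("cell_id", "drug_id", "y_raw", "y")
  if (!all(need %in% colnames(d))) {
    return(paste("response table needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(d) && !all(is.finite(d$y))) return("transformed responses must be finite")
  TRUE
})

#' NormalizationParams: min-max scaling state
#'
#' Captures the per-feature (or global, for labels) minima and maxima of the
#' data the scaling was fit on, so that `applyMinMax()` and `invertMinMax()`
#' form an identity on the fit data.  Constant features are mapped to 0
#' rather than dropped.
#'
#' @slot mode `"per_feature"` or `"global"`.
#' @slot lo,hi numeric minima / maxima (length = number of features, or 1).
#' @slot fitOn free-text note of what the parameters were fit on.
#' @exportClass NormalizationParams
setClass("NormalizationParams",
  representation(mode = "character", lo = "numeric", hi = "numeric",
                 fitOn = "character")
)

setValidity("NormalizationParams", function(object) {
  if (!object@mode %in% c("per_feature", "global")) {
    return("mode must be 'per_feature' or 'global'")
  }
  if (length(object@lo) != length(object@hi)) return("lo/hi length mismatch")
  if (any(object@hi < object@lo)) return("max must be >= min for every feature")
  TRUE
})

#' SimulationConfig: parameters of the synthetic domain-pair generator
#'
#' Defaults emulate the study regime: a labeled source domain roughly 3x the
#' target in cell lines (order-of-magnitude more response triplets), a shared
#' gene set, shared drugs as sparse bit fingerprints, latent covariate shift
#' of strength `delta`, and expression values mapped to the 3-10 range typical
#' of RMA-normalized arrays.
#'
#' @slot nGenes,nCellsSource,nCellsTarget,nDrugs,latentDim positive integers.
#' @slot delta shift strength (>= 0) applied to target latent factors.
#' @slot sigma noise s.d. (>= 0) for expression and response noise.
#' @slot fingerprintDensity Bernoulli rate of fingerprint bits, in (0,1).
#' @slot targetResponseDensity fraction of the target cell-by-drug grid with
#'   measured responses, in (0,1]; the default keeps the source response
#'   table roughly an order of magnitude larger than the target one.
#' @slot nBits fingerprint length.
#' @slot seed integer master seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nGenes = "integer", nCellsSource = "integer",
                 nCellsTarget = "integer", nDrugs = "integer",
                 latentDim = "integer", delta = "numeric", sigma = "numeric",
                 fingerprintDensity = "numeric",
                 targetResponseDensity = "numeric", nBits = "integer",
                 seed = "integer")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (nm in c("nGenes", "nCellsSource", "nCellsTarget", "nDrugs",
               "latentDim", "nBits")) {
    if (slot(object, nm) < 1L) msg <- c(msg, paste(nm, "must be positive"))
  }
  if (object@latentDim > object@nGenes) msg <- c(msg, "latentDim must be <= nGenes")
  if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@fingerprintDensity <= 0 || object@fingerprintDensity >= 1) {
    msg <- c(msg, "fingerprintDensity must be in (0,1)")
  }
  if (object@targetResponseDensity <= 0 || object@targetResponseDensity > 1) {
    msg <- c(msg, "targetResponseDensity must be in (0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth behind one synthetic domain pair
#'
#' @slot W gene loading matrix (genes x latentDim).
#' @slot u latent effect vector; @slot v drug-bit effect vector;
#'   @slot U latent-by-bit interaction weights.
#' @slot A,b latent-space shift (target latents are `z A' + delta b`).
#' @slot zSource latent factors per source cell line.
#' @slot zTargetBase biological latent factors per target cell line (drive
#'   the response surface).
#' @slot zTarget shifted latent factors (drive the target expression
#'   readout; equal to `zTargetBase` when `delta = 0`).
#' @slot config the generating [SimulationConfig-class].
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(W = "matrix", u = "numeric", v = "numeric", U = "matrix",
                 A = "matrix", b = "numeric", zSource = "matrix",
                 zTargetBase = "matrix", zTarget = "matrix",
                 config = "SimulationConfig")
)

#' SAEConfig: stacked-autoencoder pretraining settings
#'
#' @slot layerDims strictly decreasing hidden sizes of the encoder stack.
#' @slot epochsPerLayer,finetuneEpochs training lengths.
#' @slot learningRate,batchSize optimizer settings.
#' @slot seed integer.
#' @exportClass SAEConfig
setClass("SAEConfig",
  representation(layerDims = "integer", epochsPerLayer = "integer",
                 finetuneEpochs = "integer", learningRate = "numeric",
                 batchSize = "integer", seed = "integer")
)

setValidity("SAEConfig", function(object) {
  d <- object@layerDims
  msg <- character()
  if (any(d < 1L)) msg <- c(msg, "layer dims must be positive")
  if (length(d) > 1 && any(diff(d) >= 0)) {
    msg <- c(msg, "layer dims must be strictly decreasing")
  }
  if (object@epochsPerLayer < 1 || object@finetuneEpochs < 0) {
    msg <- c(msg, "epoch counts must be positive")
  }
  if (object@learningRate <= 0 || object@batchSize < 1) {
    msg <- c(msg, "learning rate and batch size must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' SAEModel: a trained stacked autoencoder
#'
#' @slot encoder dense layers, input to bottleneck.
#' @slot decoder dense layers in decoding order, bottleneck back to input.
#' @slot inputDim integer.
#' @slot lossHistory per-layer and fine-tuning reconstruction loss traces.
#' @exportClass SAEModel
setClass("SAEModel",
  representation(encoder = "list", decoder = "list", inputDim = "integer",
                 lossHistory = "list")
)

setValidity("SAEModel", function(object) {
  if (length(object@encoder) != length(object@decoder)) {
    return("encoder and decoder must have the same number of layers")
  }
  dim_in <- object@inputDim
  for (ly in object@encoder) {
    if (nrow(ly$W) != dim_in) return("encoder layer shapes do not chain")
    dim_in <- ncol(ly$W)
  }
  TRUE
})

#' DadspConfig: training hyperparameters of the adversarial model
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 1e-4, batch size 128, 15 epochs, early stopping after 3 non-improving
#' epochs, and gradient-reversal schedule constant `gamma = 10`.  Hidden
#' widths of the four sub-networks are configurable (the recipe fixes only
#' their depths: two-layer drug branch, three-layer discriminator,
#' four-layer regressor).
#'
#' @slot learningRate,batchSize,epochs,earlyStoppingPatience,gamma numerics.
#' @slot geneDims encoder widths used when no pretrained encoder is supplied.
#' @slot drugDims,discDims,regDims hidden widths of the other branches.
#' @slot adversarial logical; FALSE disables the discriminator/GRL path.
#' @slot pretrain logical; FALSE is the no-pretraining ablation.
#' @slot lambdaFix optional fixed lambda overriding the schedule (NA = use
#'   the schedule).
#' @slot seed integer.
#' @exportClass DadspConfig
setClass("DadspConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", earlyStoppingPatience = "integer",
                 gamma = "numeric", geneDims = "integer",
                 drugDims = "integer", discDims = "integer",
                 regDims = "integer", adversarial = "logical",
                 pretrain = "logical", lambdaFix = "numeric",
                 seed = "integer")
)

setValidity("DadspConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be positive")
  if (object@epochs < 1) msg <- c(msg, "epochs must be positive")
  if (object@earlyStoppingPatience < 1 ||
      object@earlyStoppingPatience > object@epochs) {
    msg <- c(msg, "earlyStoppingPatience must be in [1, epochs]")
  }
  if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
  if (length(msg)) msg else TRUE
})

#' DadspModel: trained model state of the four sub-networks
#'
#' @slot geneExtractor,drugExtractor,discriminator,regressor lists of dense
#'   layers (`W`, `b`, `act`); the discriminator list may be empty for
#'   non-adversarial variants.
#' @slot norm list with `features` and `labels` [NormalizationParams-class].
#' @slot history per-epoch data.frame with columns `epoch`, `L_MSE`,
#'   `L_domain`, `L_Total`, `lambda`.
#' @slot config the [DadspConfig-class] used.
#' @slot variant free-text tag ("DADSP-A", "source-only", "stage1", ...).
#' @exportClass DadspModel
setClass("DadspModel",
  representation(geneExtractor = "list", drugExtractor = "list",
                 discriminator = "list", regressor = "list",
                 norm = "list", history = "data.frame",
                 config = "DadspConfig", variant = "character")
)

setValidity("DadspModel", function(object) {
  if (nrow(object@history) > object@config@epochs) {
    return("history cannot be longer than the configured epochs")
  }
  TRUE
})

#' MMDConfig: settings of the MMD-regularized transfer variant
#'
#' @slot kernel `"rbf"` (median-heuristic bandwidth unless fixed) or
#'   `"linear"`.
#' @slot bandwidth fixed RBF bandwidth (NA = median heuristic per step).
#' @slot mmdWeight weight of the MMD term on the reconstruction objective.
#' @slot stageEpochs integer triple: stage-1 supervised epochs, stage-2
#'   per-layer adaptation epochs (full batch), stage-3 regressor epochs.
#' @slot learningRate Adam rate for stages 2-3.
#' @slot seed integer.
#' @exportClass MMDConfig
setClass("MMDConfig",
  representation(kernel = "character", bandwidth = "numeric",
                 mmdWeight = "numeric", stageEpochs = "integer",
                 learningRate = "numeric", seed = "integer")
)

setValidity("MMDConfig", function(object) {
  msg <- character()
  if (!object@kernel %in% c("rbf", "linear")) {
    msg <- c(msg, "kernel must be 'rbf' or 'linear'")
  }
  if (!is.na(object@bandwidth) && object@bandwidth <= 0) {
    msg <- c(msg, "fixed bandwidth must be positive")
  }
  if (object@mmdWeight < 0) msg <- c(msg, "mmdWeight must be >= 0")
  if (length(object@stageEpochs) != 3L || any(object@stageEpochs < 1L)) {
    msg <- c(msg, "stageEpochs must be three positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' SplitSpec: response-table splitting protocol
#'
#' @slot mode `"standard"` (pair-level holdout; a drug or cell line may
#'   appear on both sides but no (cell, drug) pair does) or `"blind"`
#'   (held-out drugs AND cell lines are removed from training entirely).
#' @slot testFraction fraction of pairs held out in standard mode.
#' @slot drugFraction,cellFraction fractions of drugs / cell lines held out
#'   in blind mode.
#' @slot seed integer.
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(mode = "character", testFraction = "numeric",
                 drugFraction = "numeric", cellFraction = "numeric",
                 seed = "integer")
)

setValidity("SplitSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("standard", "blind")) {
    msg <- c(msg, "mode must be 'standard' or 'blind'")
  }
  for (nm in c("testFraction", "drugFraction", "cellFraction")) {
    f <- slot(object, nm)
    if (f <= 0 || f >= 1) msg <- c(msg, paste(nm, "must be in (0,1)"))
  }
  if (length(msg)) msg else TRUE
})

#' AttributionResult: per-gene integrated-gradients scores for one pair
#'
#' @slot cellId,drugId identifiers of the attributed prediction.
#' @slot scores named numeric vector, one score per gene.
#' @slot baseline description of the attribution baseline.
#' @slot nSteps Riemann steps used.
#' @slot completenessGap |sum(scores) - (F(x) - F(baseline))|; reported, not
#'   hidden.
#' @exportClass AttributionResult
setClass("AttributionResult",
  representation(cellId = "character", drugId = "character",
                 scores = "numeric", baseline = "character",
                 nSteps = "integer", completenessGap = "numeric")
)

setValidity("AttributionResult", function(object) {
  if (is.null(names(object@scores))) return("scores must be named by gene ID")
  TRUE
})
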