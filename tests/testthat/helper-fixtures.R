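# Shared fixtures: everything is generated in code at test time.

# A small, fast domain pair for unit tests (not the study-scale default).
tinySimConfig <- function(seed = 1L, ...) {
  SimulationConfig(nGenes = 40L, nCellsSource = 60L, nCellsTarget = 30L,
                   nDrugs = 8L, latentDim = 4L, nBits = 32L, seed = seed, ...)
}

tinySaeConfig <- function(seed = 1L, epochsPerLayer = 10L,
                          finetuneEpochs = 10L, ...) {
  SAEConfig(layerDims = c(16L, 8L), epochsPerLayer = epochsPerLayer,
            finetuneEpochs = finetuneEpochs, seed = seed, ...)
}

tinyDadspConfig <- function(seed = 1L, epochs = 4L,
                            earlyStoppingPatience = epochs, ...) {
  DadspConfig(geneDims = c(16L, 8L), drugDims = c(16L, 8L),
              discDims = c(16L, 8L), regDims = c(16L, 8L, 4L),
              epochs = epochs,
              earlyStoppingPatience = earlyStoppingPatience,
              seed = seed, ...)
}

tinyExpression <- function(nCells = 5, nGenes = 6, seed = 1,
                           domain = "source", prefix = "C") {
  withr_seed <- function(code) { set.seed(seed); code }
  m <- withr_seed(matrix(runif(nCells * nGenes, 3, 10), nCells, nGenes))
  dimnames(m) <- list(paste0(prefix, seq_len(nCells)),
                      paste0("g", seq_len(nGenes)))
  ExpressionMatrix(m, domainTag = domain)
}

# Hand-built model with purely linear layers: F(x) = w . x + c, with the
# drug branch contributing only through its (known) output.  Used to check
# attribution and wiring against closed forms.
linearDadspModel <- function(w, drugBits = 4L) {
  g <- length(w)
  geneLayer <- list(W = diag(g), b = numeric(g), act = "linear")
  drugLayer <- list(W = matrix(0, drugBits, 2L), b = c(0, 0), act = "linear")
  regLayer <- list(W = matrix(c(w, 0, 0), ncol = 1), b = 0, act = "linear")
  new("DadspModel", geneExtractor = list(geneLayer),
      drugExtractor = list(drugLayer), discriminator = list(),
      regressor = list(regLayer), norm = list(),
      history = data.frame(), config = DadspConfig(), variant = "linear-test")
}
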