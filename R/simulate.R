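# Synthetic paired source/target pharmacogenomic domains.
#
# Source cell lines draw latent factors z ~ N(0, I_q); target cell lines
# draw biological latents z the same way, but their expression READOUT is
# covariate-shifted: the readout latents are z' = A z + delta * b with
# A = I + delta * E (E a small random perturbation).  Expression is a
# shared linear map x = z W' + noise (z' for the target) mapped affinely
# into the 3-10 range typical of RMA arrays.  The response surface is
# shared and driven by the BIOLOGICAL latents in both domains: the shift
# emulates platform/batch distortion of the measurement, not altered
# biology, mirroring two databases that assay the same processes under
# different distributions.  A shared encoder that undoes the readout
# distortion therefore recovers the transferable signal exactly.
# Drug fingerprints are i.i.d. Bernoulli bits.  The IC50-scale response is
#   y_raw = exp(-(u.z + v.d + z' U d + sigma * eta)),
# positive by construction, so -log10 IC50 is linear in the latent factors
# and drug bits with one bilinear interaction.  Effect vectors are scaled
# so the three signal terms contribute comparably (unit variance each).

#' Generate a paired source/target synthetic dataset
#'
#' @param config a [SimulationConfig-class]; every random component draws
#'   from a named substream of `config@seed`, so regeneration is bitwise
#'   reproducible and enlarging one component does not perturb the others.
#' @return list with `source` and `target` (each `list(expr, responses)`),
#'   `fingerprints` (a [FingerprintSet-class]) and `truth`
#'   (a [SyntheticTruth-class]).
#' @export
generateDomainPair <- function(config = SimulationConfig()) {
  validObject(config)
  q <- config@latentDim
  g <- config@nGenes
  seed <- config@seed

  W <- withSeed(deriveSeed(seed, "loadings"),
                matrix(rnorm(g * q), g, q))
  u <- withSeed(deriveSeed(seed, "cell_effect"), rnorm(q, sd = 1 / sqrt(q)))
  pv <- config@fingerprintDensity * config@nBits
  v <- withSeed(deriveSeed(seed, "drug_effect"),
                rnorm(config@nBits, sd = 1 / sqrt(pv)))
  U <- withSeed(deriveSeed(seed, "interaction"),
                matrix(rnorm(q * config@nBits, sd = 1 / sqrt(q * pv)),
                       q, config@nBits))
  E <- withSeed(deriveSeed(seed, "shift_perturb"),
                matrix(rnorm(q * q, sd = 0.3), q, q))
  b <- withSeed(deriveSeed(seed, "shift_offset"), rnorm(q))
  A <- diag(q) + config@delta * E

  zS <- withSeed(deriveSeed(seed, "latents_source"),
                 matrix(rnorm(config@nCellsSource * q), ncol = q))
  z0 <- withSeed(deriveSeed(seed, "latents_target"),
                 matrix(rnorm(config@nCellsTarget * q), ncol = q))
  zT <- z0 %*% t(A) + matrix(config@delta * b, nrow(z0), q, byrow = TRUE)

  epsS <- withSeed(deriveSeed(seed, "noise_source"),
                   matrix(rnorm(config@nCellsSource * g, sd = config@sigma),
                          ncol = g))
  epsT <- withSeed(deriveSeed(seed, "noise_target"),
                   matrix(rnorm(config@nCellsTarget * g, sd = config@sigma),
                          ncol = g))
  XS <- zS %*% t(W) + epsS
  XT <- zT %*% t(W) + epsT

  # pooled affine map into the 3-10 RMA-like range
  lo <- min(XS, XT)
  hi <- max(XS, XT)
  scale <- if (hi > lo) 7 / (hi - lo) else 0
  XS <- 3 + (XS - lo) * scale
  XT <- 3 + (XT - lo) * scale

  geneNames <- sprintf("G%04d", seq_len(g))
  srcCells <- sprintf("S%03d", seq_len(config@nCellsSource))
  tgtCells <- sprintf("T%03d", seq_len(config@nCellsTarget))
  dimnames(XS) <- list(srcCells, geneNames)
  dimnames(XT) <- list(tgtCells, geneNames)

  drugNames <- sprintf("D%02d", seq_len(config@nDrugs))
  bits <- withSeed(deriveSeed(seed, "fingerprint_bits"),
                   matrix(as.numeric(runif(config@nDrugs * config@nBits) <
                                     config@fingerprintDensity),
                          config@nDrugs, config@nBits))
  rownames(bits) <- drugNames
  fps <- FingerprintSet(bits)

  makeResponses <- function(z, cells, stream, density = 1) {
    grid <- expand.grid(cell = seq_along(cells), drug = seq_len(config@nDrugs))
    eta <- withSeed(deriveSeed(seed, stream), rnorm(nrow(grid)))
    if (density < 1) {
      keep <- withSeed(deriveSeed(seed, stream, "subsample"),
                       sort(sample.int(nrow(grid),
                                       max(1L, round(density * nrow(grid))))))
      grid <- grid[keep, , drop = FALSE]
      eta <- eta[keep]
    }
    ZU <- z %*% U                       # cells x nBits
    bil <- rowSums(ZU[grid$cell, , drop = FALSE] *
                     bits[grid$drug, , drop = FALSE])
    score <- as.numeric(z %*% u)[grid$cell] +
      as.numeric(bits %*% v)[grid$drug] + bil + config@sigma * eta
    ic50 <- exp(-score)
    ResponseTable(cells[grid$cell], drugNames[grid$drug], ic50)
  }
  # responses follow the biological latents (z0), expression the shifted ones
  respS <- makeResponses(zS, srcCells, "response_noise_source")
  respT <- makeResponses(z0, tgtCells, "response_noise_target",
                         density = config@targetResponseDensity)

  truth <- new("SyntheticTruth", W = W, u = u, v = v, U = U, A = A, b = b,
               zSource = zS, zTargetBase = z0, zTarget = zT, config = config)
  list(source = list(expr = ExpressionMatrix(XS, domainTag = "source"),
                     responses = respS),
       target = list(expr = ExpressionMatrix(XT, domainTag = "target"),
                     responses = respT),
       fingerprints = fps, truth = truth)
}

#' Noiseless-oracle RMSE lower bound
#'
#' Evaluates the noiseless ground-truth response surface against the
#' observed (noisy) labels of one domain, on the same normalized `[0, 1]`
#' label scale the models train on. This is the RMSE floor a perfect model
#' would attain; trained models should approach but not systematically beat
#' it. Exactly 0 when `sigma = 0`.
#'
#' @param truth a [SyntheticTruth-class].
#' @param pair the dataset returned by [generateDomainPair()]; its seed must
#'   match the truth.
#' @param domain `"target"` or `"source"`.
#' @return scalar RMSE on the normalized label scale.
#' @export
oracleBestRmse <- function(truth, pair, domain = c("target", "source")) {
  domain <- match.arg(domain)
  cfg <- truth@config
  if (cfg@seed != pair$truth@config@seed) {
    stopf("truth seed (%d) does not match dataset seed (%d)",
          cfg@seed, pair$truth@config@seed)
  }
  z <- if (domain == "target") truth@zTargetBase else truth@zSource
  resp <- responseData(pair[[domain]]$responses)
  bits <- fingerprintBits(pair$fingerprints)
  cells <- cellIds(pair[[domain]]$expr)
  ci <- match(resp$cell_id, cells)
  di <- match(resp$drug_id, rownames(bits))
  ZU <- z %*% truth@U
  score0 <- as.numeric(z %*% truth@u)[ci] +
    as.numeric(bits %*% truth@v)[di] +
    rowSums(ZU[ci, , drop = FALSE] * bits[di, , drop = FALSE])
  yTrue0 <- score0 / log(10)          # noiseless -log10 IC50
  np <- fitMinMax(resp$y, "global", fitOn = paste(domain, "labels"))
  rmse(applyMinMax(resp$y, np), applyMinMax(yTrue0, np))
}

#' Write a generated domain pair as the delimited files the readers accept
#'
#' Emits `source_expr.tsv`, `target_expr.tsv`, `source_responses.tsv`,
#' `target_responses.tsv` and `fingerprints.tsv` under `dir`, making
#' synthetic and real data interchangeable at the command line.
#'
#' @param pair result of [generateDomainPair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDomainPair <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeExpressionMatrix(pair$source$expr, file.path(dir, "source_expr.tsv"))
  writeExpressionMatrix(pair$target$expr, file.path(dir, "target_expr.tsv"))
  writeResponseTable(pair$source$responses,
                     file.path(dir, "source_responses.tsv"))
  writeResponseTable(pair$target$responses,
                     file.path(dir, "target_responses.tsv"))
  bits <- fingerprintBits(pair$fingerprints)
  d <- data.frame(drug_id = rownames(bits), bits, check.names = FALSE)
  write.table(d, file.path(dir, "fingerprints.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
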