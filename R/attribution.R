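# Integrated-gradients attribution of the regressor's prediction to genes.
#
# score_i = (x_i - baseline_i) * mean over path steps of dF/dx_i, with the
# path a straight line from the baseline to the input in normalized
# expression space and the drug fingerprint held fixed.  The Riemann sum
# uses right endpoints; the completeness axiom |sum(scores) - (F(x) -
# F(baseline))| is reported as a gap, never hidden.

# Gradient of the scalar prediction w.r.t. the gene input, batched over
# rows; drug features are precomputed and recycled.
dadspInputGradient <- function(model, XGene, drugFeatRow) {
  fwG <- nnForward(model@geneExtractor, XGene)
  df <- matrix(drugFeatRow, nrow(XGene), length(drugFeatRow), byrow = TRUE)
  regIn <- cbind(fwG$out, df)
  fwR <- nnForward(model@regressor, regIn)
  gd <- ncol(fwG$out)
  bwR <- nnBackward(model@regressor, fwR$cache,
                    matrix(1, nrow(XGene), 1))
  dFeat <- bwR$gradIn[, seq_len(gd), drop = FALSE]
  bwG <- nnBackward(model@geneExtractor, fwG$cache, dFeat)
  list(grad = bwG$gradIn, F = as.numeric(fwR$out))
}

#' Integrated-gradients gene attribution for one (cell line, drug) pair
#'
#' @param model a trained [DadspModel-class].
#' @param xGene one gene-input row (normalized scale), named by gene ID or
#'   accompanied by `geneIds`.
#' @param xDrug the drug fingerprint bit vector.
#' @param baseline reference gene input; default all zeros in normalized
#'   space, i.e. each gene at its minimum observed expression.
#' @param nSteps Riemann steps (default 128, minimum 2).
#' @param cellId,drugId identifiers recorded on the result.
#' @param geneIds gene names when `xGene` is unnamed.
#' @return an [AttributionResult-class]; the completeness gap
#'   `|sum(scores) - (F(x) - F(baseline))|` is stored alongside the scores.
#' @export
integratedGradients <- function(model, xGene, xDrug, baseline = NULL,
                                nSteps = 128L, cellId = "cell",
                                drugId = "drug", geneIds = NULL) {
  stopifnot(is(model, "DadspModel"))
  if (!length(model@geneExtractor)) stopf("model has no trained extractor")
  if (nSteps < 2L) stopf("integrated gradients needs nSteps >= 2")
  x <- as.numeric(xGene)
  gid <- geneIds %||% names(xGene) %||% sprintf("g%d", seq_along(x))
  if (is.null(baseline)) baseline <- numeric(length(x))
  baseline <- as.numeric(baseline)
  if (length(baseline) != length(x)) {
    stopf("baseline must match the gene input length")
  }
  alphas <- seq_len(nSteps) / nSteps
  path <- outer(alphas, x - baseline) +
    matrix(baseline, nSteps, length(x), byrow = TRUE)
  dfRow <- as.numeric(nnForward(model@drugExtractor,
                                matrix(as.numeric(xDrug), 1), cache = FALSE)$out)
  ig <- dadspInputGradient(model, path, dfRow)
  scores <- (x - baseline) * colMeans(ig$grad)
  ends <- dadspInputGradient(model, rbind(baseline, x), dfRow)$F
  gap <- abs(sum(scores) - (ends[2] - ends[1]))
  names(scores) <- gid
  new("AttributionResult", cellId = as.character(cellId),
      drugId = as.character(drugId), scores = scores,
      baseline = if (all(baseline == 0)) "zero (per-gene minimum expression)"
                 else "user-supplied",
      nSteps = as.integer(nSteps), completenessGap = gap)
}

#' Rank genes by attribution score
#'
#' Averages the (signed, by default) scores across one or more attribution
#' results and returns the `topN` genes in descending order, ties broken
#' lexicographically by gene ID.
#'
#' @param results an [AttributionResult-class] or list of them sharing gene
#'   IDs.
#' @param topN number of genes to report (default 10).
#' @param absolute rank by absolute score instead of signed score.
#' @return data.frame with columns `gene_id` and `score`.
#' @export
rankGenes <- function(results, topN = 10L, absolute = FALSE) {
  if (is(results, "AttributionResult")) results <- list(results)
  gid <- names(results[[1]]@scores)
  for (r in results) {
    if (!identical(names(r@scores), gid)) {
      stopf("attribution results must share gene IDs")
    }
  }
  score <- rowMeans(vapply(results, function(r) r@scores,
                           numeric(length(gid))))
  key <- if (absolute) abs(score) else score
  ord <- order(-key, gid)
  if (topN > length(gid)) {
    warning(sprintf("topN = %d exceeds the %d available genes; returning all",
                    topN, length(gid)), call. = FALSE)
    topN <- length(gid)
  }
  out <- data.frame(gene_id = gid[ord], score = score[ord],
                    row.names = NULL)[seq_len(topN), ]
  rownames(out) <- NULL
  out
}
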