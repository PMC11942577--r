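#' Read an expression matrix from a delimited table
#'
#' Expects a header row of gene IDs and a first column of cell-line IDs;
#' TSV or CSV is chosen by file extension (`.csv` = comma, anything else =
#' tab).
#'
#' @param path file path.
#' @param domainTag `"source"` or `"target"`.
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, domainTag = c("source", "target")) {
  domainTag <- match.arg(domainTag)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("expression table '%s' needs >= 2 columns", path)
  genes <- colnames(d)[-1]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stopf("duplicated gene ID(s) in '%s': %s", path,
          paste(head(dup, 5), collapse = ", "))
  }
  cells <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!sapply(d[-1], is.numeric))[1]
    row <- which(is.na(suppressWarnings(as.numeric(d[[bad + 1]]))))[1]
    stopf("non-numeric expression value at row %s, column '%s' of '%s'",
          ifelse(is.na(row), "?", row), genes[bad], path)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("missing expression value at row %d, column '%s' of '%s'",
          idx[1], genes[idx[2]], path)
  }
  rownames(m) <- cells
  ExpressionMatrix(m, cellIds = cells, geneIds = genes, domainTag = domainTag)
}

#' Write an expression matrix in the format `readExpressionMatrix()` reads
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path (`.csv` writes comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- exprValues(x)
  d <- data.frame(cell_id = rownames(v), v, check.names = FALSE)
  write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two expression matrices to their shared genes
#'
#' The intersection is ordered lexicographically so results do not depend on
#' file column order. Cell lines are unchanged.
#'
#' @param source,target [ExpressionMatrix-class] objects.
#' @return list with elements `source` and `target` on identical gene sets.
#' @export
intersectGenes <- function(source, target) {
  shared <- sort(intersect(geneIds(source), geneIds(target)))
  if (!length(shared)) stopf("no shared genes between the two matrices")
  list(source = source[shared, ], target = target[shared, ])
}

#' Transform IC50 to the modeling scale
#'
#' @param ic50 positive IC50 values.
#' @return `-log10(ic50)`.
#' @export
negLog10Ic50 <- function(ic50) {
  if (length(ic50) && (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0))) {
    stopf("IC50 values must be positive and finite for the -log10 transform")
  }
  -log10(ic50)
}

#' Fit min-max normalization parameters
#'
#' @param values numeric matrix (samples x features) or vector.
#' @param axisMode `"per_feature"` (per column; used for gene expression) or
#'   `"global"` (one min/max; used for response labels).
#' @param fitOn optional note recording what the fit was computed on.
#' @return a [NormalizationParams-class].
#' @export
fitMinMax <- function(values, axisMode = c("per_feature", "global"),
                      fitOn = "unspecified") {
  axisMode <- match.arg(axisMode)
  if (axisMode == "per_feature") {
    values <- as.matrix(values)
    lo <- apply(values, 2, min)
    hi <- apply(values, 2, max)
  } else {
    lo <- min(values)
    hi <- max(values)
  }
  new("NormalizationParams", mode = axisMode, lo = as.numeric(lo),
      hi = as.numeric(hi), fitOn = fitOn)
}

#' Apply min-max scaling
#'
#' Maps the fit data into `[0, 1]`. Constant features map to 0. Values
#' outside the fit range (e.g. target-domain data exceeding source extremes)
#' map outside `[0, 1]` and are deliberately not clipped, preserving order.
#'
#' @param values matrix or vector, matching the fit.
#' @param params a [NormalizationParams-class].
#' @return scaled values, same shape as the input.
#' @export
applyMinMax <- function(values, params) {
  rng <- params@hi - params@lo
  if (params@mode == "per_feature") {
    values <- as.matrix(values)
    if (ncol(values) != length(params@lo)) {
      stopf("feature count (%d) does not match normalization fit (%d)",
            ncol(values), length(params@lo))
    }
    scale <- ifelse(rng > 0, 1 / rng, 0)
    sweep(sweep(values, 2, params@lo, "-"), 2, scale, "*")
  } else {
    if (rng > 0) (values - params@lo) / rng else values * 0
  }
}

#' Invert min-max scaling
#'
#' `invertMinMax(applyMinMax(x, p), p)` is the identity on the fit data
#' (within floating tolerance; exactly `lo` for constant features).
#'
#' @inheritParams applyMinMax
#' @return values on the original scale.
#' @export
invertMinMax <- function(values, params) {
  rng <- params@hi - params@lo
  if (params@mode == "per_feature") {
    values <- as.matrix(values)
    if (ncol(values) != length(params@lo)) {
      stopf("feature count (%d) does not match normalization fit (%d)",
            ncol(values), length(params@lo))
    }
    sweep(sweep(values, 2, rng, "*"), 2, params@lo, "+")
  } else {
    values * rng + params@lo
  }
}

#' Hashed circular (Morgan) fingerprint of one molecule
#'
#' Computes an extended-connectivity fingerprint of the given radius via
#' OpenBabel (ChemmineOB) and folds it to `nBits` by OR-ing bit `i` into
#' position `i mod nBits` — the conventional hashed/folded Morgan scheme.
#'
#' @param smiles a single SMILES string.
#' @param radius circular neighborhood radius (default 2, i.e. ECFP4).
#' @param nBits folded fingerprint length (default 256).
#' @param drugId optional identifier used in error messages.
#' @return integer vector of 0/1 of length `nBits`.
#' @export
smilesToFingerprint <- function(smiles, radius = 2L, nBits = 256L,
                                drugId = NULL) {
  stopifnot(length(smiles) == 1L)
  if (!radius %in% 0:5) stopf("fingerprint radius must be an integer in 0..5")
  name <- paste0("ECFP", 2L * as.integer(radius))
  id <- drugId %||% smiles
  fp <- tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", as.character(smiles), identity)
    ChemmineOB::fingerprint_OB(mol, name)
  }, error = function(e) {
    stopf("cannot parse SMILES for drug '%s': %s", id, conditionMessage(e))
  })
  fp <- as.numeric(fp)
  if (!length(fp) || !any(is.finite(fp))) {
    stopf("fingerprint computation failed for drug '%s'", id)
  }
  folded <- integer(nBits)
  on_bits <- which(fp != 0)
  folded[unique((on_bits - 1L) %% as.integer(nBits)) + 1L] <- 1L
  folded
}

#' Build a FingerprintSet from drug IDs and SMILES
#'
#' @param ids drug identifiers.
#' @param smiles SMILES strings, one per drug.
#' @inheritParams smilesToFingerprint
#' @return a [FingerprintSet-class].
#' @export
fingerprintSetFromSmiles <- function(ids, smiles, radius = 2L, nBits = 256L) {
  stopifnot(length(ids) == length(smiles))
  bits <- t(vapply(seq_along(ids), function(i) {
    smilesToFingerprint(smiles[i], radius = radius, nBits = nBits,
                        drugId = ids[i])
  }, integer(nBits)))
  rownames(bits) <- as.character(ids)
  FingerprintSet(bits)
}

#' Read a 2-column drug table (drug_id, SMILES) and fingerprint it
#'
#' @param path delimited file with columns `drug_id` and `smiles`.
#' @inheritParams smilesToFingerprint
#' @return a [FingerprintSet-class].
#' @export
readDrugTable <- function(path, radius = 2L, nBits = 256L) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("drug table '%s' needs columns (drug_id, smiles)", path)
  fingerprintSetFromSmiles(d[[1]], d[[2]], radius = radius, nBits = nBits)
}

#' Read a precomputed fingerprint bit table
#'
#' Reads the format [writeDomainPair()] emits: a delimited table with a
#' `drug_id` column followed by one 0/1 column per fingerprint bit.
#'
#' @param path delimited file.
#' @return a [FingerprintSet-class].
#' @export
readFingerprintTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.csv(path, sep = sep, check.names = FALSE,
                stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("fingerprint table '%s' needs bit columns", path)
  bits <- as.matrix(d[, -1, drop = FALSE])
  dimnames(bits) <- list(as.character(d[[1]]), NULL)
  FingerprintSet(bits)
}

#' Read a 3-column response table (cell_id, drug_id, ic50)
#'
#' @param path delimited file.
#' @return a [ResponseTable-class] (IC50 transformed to -log10 internally).
#' @export
readResponseTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(d) < 3) {
    stopf("response table '%s' needs columns (cell_id, drug_id, ic50)", path)
  }
  ResponseTable(d[[1]], d[[2]], d[[3]])
}

#' Write a ResponseTable in the format `readResponseTable()` reads
#'
#' @param x a [ResponseTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResponseTable <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- responseData(x)
  out <- data.frame(cell_id = d$cell_id, drug_id = d$drug_id, ic50 = d$y_raw)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble aligned model input arrays from a response table
#'
#' Row `i` of each output corresponds to triplet `i` of the response table;
#' duplicate (cell, drug) pairs are preserved as separate rows.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param fps a [FingerprintSet-class].
#' @param responses a [ResponseTable-class].
#' @param norm optional list with elements `features` and/or `labels`
#'   ([NormalizationParams-class]); when present, gene inputs and labels are
#'   min-max scaled.
#' @return list with `X_gene` (triplets x genes), `X_drug` (triplets x bits),
#'   `y` (labels, scaled to `[0,1]` if `norm$labels` given), and the aligned
#'   `cell_id` / `drug_id` vectors.
#' @export
assembleDataset <- function(expr, fps, responses, norm = NULL) {
  d <- responseData(responses)
  v <- exprValues(expr)
  badc <- setdiff(unique(d$cell_id), rownames(v))
  if (length(badc)) {
    stopf("cell ID(s) not in expression matrix: %s",
          paste(head(badc, 5), collapse = ", "))
  }
  badd <- setdiff(unique(d$drug_id), drugIds(fps))
  if (length(badd)) {
    stopf("drug ID(s) not in fingerprint set: %s",
          paste(head(badd, 5), collapse = ", "))
  }
  Xg <- v[d$cell_id, , drop = FALSE]
  Xd <- fingerprintBits(fps)[d$drug_id, , drop = FALSE]
  y <- d$y
  if (!is.null(norm$features)) Xg <- applyMinMax(Xg, norm$features)
  if (!is.null(norm$labels)) y <- applyMinMax(y, norm$labels)
  list(X_gene = unname(Xg), X_drug = unname(Xd), y = as.numeric(y),
       cell_id = d$cell_id, drug_id = d$drug_id)
}
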