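# Single-cell QC filters, library-size normalization, and the
# bin-matched-control signature (notch activity) score.

#' Default notch target signature
#'
#' Canonical downstream notch targets whose per-cell average, normalized
#' against bin-matched control genes, defines the notch activity score.
#' @export
notchSignature <- c("HES1", "CD3D", "HES4", "DTX1", "BCL11B", "HEY2")

#' Assemble a single-cell count matrix
#'
#' Wraps a genes x cells integer count matrix into a
#' `SingleCellExperiment` with per-cell condition labels.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse),
#'   nonnegative integers.
#' @param geneNames unique gene names (default `rownames(counts)`).
#' @param cellIds unique cell identifiers (default `colnames(counts)`).
#' @param condition per-cell condition label.
#' @return a `SingleCellExperiment` with a `counts` assay and a
#'   `condition` column in `colData`.
#' @export
makeCountMatrix <- function(counts, geneNames = rownames(counts),
                            cellIds = colnames(counts), condition) {
  if (is.null(geneNames) || is.null(cellIds)) {
    stop("gene names and cell ids are required")
  }
  if (anyDuplicated(geneNames)) stop("gene names must be unique")
  if (anyDuplicated(cellIds)) stop("cell ids must be unique")
  if (length(condition) != ncol(counts)) {
    stop("condition must have one label per cell")
  }
  rownames(counts) <- geneNames
  colnames(counts) <- cellIds
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = cellIds))
}

#' Quality-control thresholds
#'
#' Defaults follow the standard droplet scRNA-seq doublet/dead-cell
#' screen: cells with more than 36,000 total counts or more than 6000
#' detected genes are treated as likely doublets, cells with more than
#' 18% mitochondrial reads as dying, and genes detected in fewer than 3
#' remaining cells are dropped.
#'
#' @param maxCounts cell removed when total counts exceed this (strict).
#' @param maxGenes cell removed when detected genes exceed this (strict).
#' @param maxMitoFrac cell removed when the mitochondrial read fraction
#'   exceeds this (strict).
#' @param minCellsPerGene gene kept only when detected in at least this
#'   many remaining cells.
#' @param mitoPrefix gene-name prefix identifying mitochondrial genes.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(maxCounts = 36000, maxGenes = 6000,
                         maxMitoFrac = 0.18, minCellsPerGene = 3L,
                         mitoPrefix = "MT-") {
  stopifnot(maxCounts > 0, maxGenes > 0, maxMitoFrac > 0,
            minCellsPerGene > 0)
  list(maxCounts = maxCounts, maxGenes = maxGenes,
       maxMitoFrac = maxMitoFrac,
       minCellsPerGene = as.integer(minCellsPerGene),
       mitoPrefix = mitoPrefix)
}

perCellMetrics <- function(counts, mitoPrefix) {
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), mitoPrefix)
  mitoFrac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, ncol(counts))
  data.frame(total = as.numeric(total), detected = as.numeric(detected),
             mitoFrac = as.numeric(mitoFrac), row.names = colnames(counts))
}

#' Apply single-cell quality-control filters
#'
#' Removes cells exceeding any of the count / detected-gene /
#' mitochondrial-fraction thresholds (strict inequalities), then removes
#' genes detected in fewer than `minCellsPerGene` of the remaining cells.
#' The filter is idempotent. The itemized report is stored in
#' `metadata(.)$qcReport` (see [qcReport()]); a cell violating several
#' rules is listed under each.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param thresholds from [qcThresholds()].
#' @return the filtered `SingleCellExperiment`.
#' @export
applyQC <- function(sce, thresholds = qcThresholds()) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  m <- perCellMetrics(counts, thresholds$mitoPrefix)
  highCount <- m$total > thresholds$maxCounts
  highGene <- m$detected > thresholds$maxGenes
  highMito <- m$mitoFrac > thresholds$maxMitoFrac
  drop <- highCount | highGene | highMito
  if (all(drop)) stop("all cells filtered")
  kept <- sce[, !drop]
  detectedIn <- Matrix::rowSums(
    SummarizedExperiment::assay(kept, "counts") > 0)
  geneDrop <- detectedIn < thresholds$minCellsPerGene
  report <- list(
    nCellsIn = ncol(sce),
    nCellsRemoved = sum(drop),
    removedHighCount = colnames(sce)[highCount],
    removedHighGenes = colnames(sce)[highGene],
    removedHighMito = colnames(sce)[highMito],
    nGenesIn = nrow(sce),
    nGenesRemoved = sum(geneDrop),
    removedGenes = rownames(kept)[geneDrop],
    thresholds = thresholds)
  out <- kept[!geneDrop, ]
  S4Vectors::metadata(out)$qcReport <- report
  out
}

#' QC report of a filtered experiment
#' @param sce a `SingleCellExperiment` returned by [applyQC()].
#' @return the itemized removal report (list), or `NULL`.
#' @export
qcReport <- function(sce) S4Vectors::metadata(sce)$qcReport

#' Library-size normalization and log transform
#'
#' Scales each cell to `target` total counts (default \eqn{10^4}) and
#' applies the natural-log `log(1 + x)` transform, storing the result in
#' the `logcounts` assay. Zeros map to zero.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param target per-cell total after scaling, default 1e4.
#' @return the experiment with a `logcounts` assay added.
#' @export
normalizeLog <- function(sce, target = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    stop("all-zero cell(s): ",
         paste(colnames(counts)[total == 0], collapse = ", "))
  }
  scaled <- sweep(as.matrix(counts), 2L, target / total, `*`)
  SummarizedExperiment::assay(sce, "logcounts") <- log1p(scaled)
  sce
}

#' Per-cell signature score with bin-matched control genes
#'
#' Genes are ranked by mean normalized expression and cut into `nBins`
#' equal-size bins; for each signature gene, `nCtrl` control genes are
#' drawn without replacement from its bin (signature genes excluded).
#' The per-cell score is the mean normalized expression of the signature
#' genes minus the mean over the pooled control genes (`mode =
#' "subtract"`, the default; `"ratio"` divides instead). When a bin is
#' smaller than `nCtrl` after exclusions, controls are drawn with
#' replacement and the result is flagged. Sampling is seed-deterministic
#' and invariant to the storage order of genes (bins and candidate lists
#' are resolved by value and name).
#'
#' @param sce a normalized `SingleCellExperiment` (see [normalizeLog()]).
#' @param signatureGenes signature gene names; genes absent from the
#'   matrix are dropped with a warning (at least one must remain).
#' @param nBins number of expression bins, default 25.
#' @param nCtrl control genes per signature gene, default 50.
#' @param seed RNG seed for control sampling.
#' @param mode `"subtract"` or `"ratio"`.
#' @return a [SignatureScoreResult-class]; when exactly two conditions
#'   are present the fold change and Mann-Whitney p are filled in.
#' @export
scoreSignature <- function(sce, signatureGenes = notchSignature,
                           nBins = 25L, nCtrl = 50L, seed = 0L,
                           mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    stop("no 'logcounts' assay; run normalizeLog() first")
  }
  logc <- SummarizedExperiment::assay(sce, "logcounts")
  present <- intersect(signatureGenes, rownames(logc))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(present) < length(signatureGenes)) {
    warning("signature genes absent from matrix: ",
            paste(setdiff(signatureGenes, present), collapse = ", "))
  }
  nBins <- as.integer(nBins)
  if (nBins < 1L || nBins > nrow(logc)) stop("invalid nBins")

  means <- Matrix::rowMeans(logc)
  ord <- order(means, rownames(logc))       # name tie-break: deterministic
  binOfSorted <- ceiling(seq_along(ord) * nBins / length(ord))
  bin <- integer(length(ord))
  bin[ord] <- binOfSorted
  names(bin) <- rownames(logc)

  sig <- sort(present)
  withRepl <- FALSE
  ctrl <- withSeed(seed, {
    unlist(lapply(sig, function(g) {
      cand <- names(bin)[bin == bin[g]]
      cand <- sort(setdiff(cand, signatureGenes))
      if (!length(cand)) stop("no control candidates in bin of '", g, "'")
      if (length(cand) < nCtrl) {
        withRepl <<- TRUE
        sample(cand, nCtrl, replace = TRUE)
      } else sample(cand, nCtrl)
    }), use.names = FALSE)
  })

  sigMean <- Matrix::colMeans(logc[sig, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(logc[match(ctrl, rownames(logc)), ,
                                    drop = FALSE])
  scores <- if (mode == "subtract") sigMean - ctrlMean else sigMean / ctrlMean
  cond <- factor(SummarizedExperiment::colData(sce)$condition)
  perCond <- tapply(scores, cond, mean)

  fc <- NA_real_; mwP <- NA_real_
  if (nlevels(cond) == 2L) {
    g <- levels(cond)
    cmp <- mwCompare(scores[cond == g[1]], scores[cond == g[2]])
    fc <- cmp$foldChange; mwP <- cmp$p
  }
  new("SignatureScoreResult",
      scores = stats::setNames(as.numeric(scores), colnames(logc)),
      condition = cond, signatureGenes = sig, controlGenes = ctrl,
      nCtrlPerGene = as.integer(nCtrl), nBins = nBins,
      seed = as.integer(seed), sampledWithReplacement = withRepl,
      perConditionMean = stats::setNames(as.numeric(perCond),
                                         names(perCond)),
      foldChange = fc, mwP = mwP)
}

mwCompare <- function(s1, s2) {
  # ties are routine in discrete scores; the normal approximation is used
  p <- suppressWarnings(
    stats::wilcox.test(s1, s2, alternative = "two.sided")$p.value)
  m1 <- mean(s1); m2 <- mean(s2)
  fc <- if (m1 > 0 && m2 > 0) m2 / m1 else NA_real_
  list(foldChange = fc, p = p,
       flag = if (is.na(fc)) "fold change undefined: a group mean <= 0"
              else "")
}

#' Compare signature scores between two conditions
#'
#' Fold change of mean scores (group 2 over group 1; defined only when
#' both means are positive) and the two-sided Mann-Whitney rank-sum p
#' value (exact for small samples without ties, normal approximation
#' otherwise, as in [stats::wilcox.test()]).
#'
#' @param result a [SignatureScoreResult-class].
#' @param groups character vector of two condition labels (reference
#'   first).
#' @return list with `foldChange`, `p`, and a `flag` (non-empty when the
#'   fold change is undefined).
#' @export
compareConditions <- function(result, groups) {
  stopifnot(length(groups) == 2L)
  cond <- as.character(result@condition)
  miss <- setdiff(groups, unique(cond))
  if (length(miss)) stop("condition group(s) absent: ",
                         paste(miss, collapse = ", "))
  s1 <- result@scores[cond == groups[1]]
  s2 <- result@scores[cond == groups[2]]
  if (length(s1) < 2L || length(s2) < 2L) stop("each group needs >= 2 cells")
  mwCompare(s1, s2)
}
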