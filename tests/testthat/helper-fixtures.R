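# Shared fixtures: small designs and exactly-specified models.

sixFactorDesign <- function(nCenter = 8L, alpha = 2.366) {
  fx <- do.call(rbind, lapply(paste0("F", 1:6),
                              function(n) factorSpec(n, 1, 10)))
  makeCCD(fx, alpha = alpha, nCenter = nCenter)
}

twoFactorDesign <- function(alpha = 1.414, nCenter = 3L) {
  makeCCD(rbind(factorSpec("F1", 1, 10), factorSpec("F2", 1, 10)),
          alpha = alpha, nCenter = nCenter)
}

# design with integer axial distance so integer-coefficient identity
# surfaces take integer values at every run (rounding is then exact)
integerDesign <- function(k = 3L, nCenter = 3L) {
  fx <- do.call(rbind, lapply(paste0("F", seq_len(k)),
                              function(n) factorSpec(n, 1, 100)))
  makeCCD(fx, alpha = 2, nCenter = nCenter)
}

# ResponseModel with exactly the stated coefficients (no fitting)
exactModel <- function(factorNames, coefs, transform = "identity",
                       response = "y", thirdOrder = list()) {
  terms <- buildTerms(factorNames, thirdOrder = thirdOrder)
  lbl <- vapply(terms, termLabel, character(1))
  beta <- stats::setNames(numeric(length(terms)), lbl)
  stopifnot(all(names(coefs) %in% lbl))
  beta[names(coefs)] <- coefs
  new("ResponseModel", responseName = response, transform = transform,
      terms = terms, coefficients = as.numeric(beta),
      factorNames = factorNames, fitStats = list())
}

# 4-cell QC fixture: one violator per rule plus one clean cell
# (7000 genes so a >6000-detected-genes cell is constructible)
qcFixture <- function() {
  nG <- 7000L
  genes <- c("MT-1", sprintf("G%04d", seq_len(nG - 1L)))
  counts <- matrix(0L, nG, 4L,
                   dimnames = list(genes, paste0("cell", 1:4)))
  counts[2, 1] <- 40000L                    # high total counts
  counts[2:6501, 2] <- 1L                   # 6500 detected genes
  counts[1, 3] <- 20L; counts[2, 3] <- 80L  # 20% mitochondrial
  counts[2:6, 4] <- 5L                      # clean cell
  makeCountMatrix(counts, condition = rep("A", 4))
}

# SingleCellExperiment with a directly specified logcounts assay
sceFromLogcounts <- function(logc, condition = rep("A", ncol(logc))) {
  sce <- makeCountMatrix(matrix(1L, nrow(logc), ncol(logc),
                                dimnames = dimnames(logc)),
                         condition = condition)
  SummarizedExperiment::assay(sce, "logcounts") <- logc
  sce
}
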