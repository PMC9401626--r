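# Seed-deterministic synthetic data generators with known ground truth
# for every pipeline stage.

#' Ground-truth dose-response surface
#'
#' @param response response (phenotype) name.
#' @param coefficients named numeric of true coefficients on the
#'   transformed scale; names are term labels (see [termLabel()]), e.g.
#'   `c(Intercept = 5, IL7 = 0.4, "IL7^2" = -0.2)`.
#' @param transform `"log1p"` or `"identity"`.
#' @param noiseSd additive Gaussian noise SD on the transformed scale
#'   (>= 0).
#' @return truth spec list for [genDoseResponse()].
#' @export
responseSurfaceTruth <- function(response, coefficients,
                                 transform = c("log1p", "identity"),
                                 noiseSd = 0) {
  transform <- match.arg(transform)
  stopifnot(noiseSd >= 0, !is.null(names(coefficients)))
  list(response = response, coefficients = coefficients,
       transform = transform, noiseSd = noiseSd)
}

#' Generate a synthetic response table over a design
#'
#' Evaluates each truth polynomial at every coded design point, adds
#' Gaussian noise on the transformed scale, back-transforms, clips at 0
#' and rounds to integer counts — emulating the per-run absolute cell
#' counts a flow-cytometry readout would produce. Noise is on the
#' transformed scale so that least-squares fitting on that scale is the
#' exact maximum-likelihood estimator of the truth.
#'
#' @param truths list of [responseSurfaceTruth()] specs.
#' @param design a [CCDesign-class].
#' @param seed RNG seed; fully determines the output.
#' @return `data.frame` with columns `run_id`, `response`, `count`.
#' @export
genDoseResponse <- function(truths, design, seed = 1L) {
  if (!length(truths)) stop("need at least one truth surface")
  if (nrow(codedMatrix(design)) == 0L) stop("design is empty")
  fn <- factorNames(design)
  withSeed(seed, {
    do.call(rbind, lapply(truths, function(tr) {
      terms <- lapply(names(tr$coefficients), parseTermLabel,
                      factorNames = fn)
      M <- designModelMatrix(design, terms)
      eta <- as.numeric(M %*% tr$coefficients)
      yt <- eta + stats::rnorm(length(eta), sd = tr$noiseSd)
      data.frame(run_id = rownames(codedMatrix(design)),
                 response = tr$response,
                 count = round(backTransform(yt, tr$transform)),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
}

#' Generate limiting-dilution well data
#'
#' Each well seeded with `n` cells is negative iff every cell
#' independently fails to engraft, i.e. with probability
#' \eqn{(1-p)^n} — the exact Bernoulli-per-cell model, deliberately
#' finer than the Poisson approximation \eqn{e^{-pn}} used by the
#' estimator so the approximation is stress-tested.
#'
#' @param hitProbability per-cell probability `p` in [0, 1] that a
#'   seeded cell yields a positive readout.
#' @param doses cells per well, positive integers.
#' @param wellsPerDose wells tested at each dose.
#' @param seed RNG seed.
#' @return `data.frame` with columns `dose`, `tested`, `negative`.
#' @export
genLDAWells <- function(hitProbability, doses, wellsPerDose, seed = 1L) {
  stopifnot(hitProbability >= 0, hitProbability <= 1, all(doses > 0),
            wellsPerDose > 0)
  withSeed(seed, {
    qNeg <- (1 - hitProbability)^doses
    data.frame(
      dose = as.integer(doses),
      tested = as.integer(rep(wellsPerDose, length(doses))),
      negative = stats::rbinom(length(doses), wellsPerDose, qNeg))
  })
}

#' Ground truth for a synthetic expression dataset
#'
#' @param nCellsPerCondition named integer, cells per condition.
#' @param nGenes total genes (>= signature + mito genes).
#' @param baselineMean per-gene mean counts: a scalar (recycled) or a
#'   vector of length `nGenes`.
#' @param signatureGenes signature gene names; these names are assigned
#'   to dedicated genes in the matrix (default [notchSignature]).
#' @param signatureEffect named nonnegative multiplier of signature-gene
#'   means per condition (default 1 everywhere: null construction).
#' @param mitoFraction expected fraction of counts from mitochondrial
#'   genes in clean cells, in [0, 1).
#' @param nMitoGenes number of mitochondrial genes (named with
#'   `mitoPrefix`).
#' @param qcViolators named counts `c(highCount=, highGene=, highMito=)`
#'   of QC-violating cells to inject.
#' @param dispersion negative-binomial dispersion (variance
#'   \eqn{\mu + \phi\mu^2}); 0 gives Poisson counts.
#' @param mitoPrefix mitochondrial gene-name prefix, default `"MT-"`.
#' @return truth spec list for [genExpression()].
#' @export
expressionTruth <- function(nCellsPerCondition = c(A = 200L, B = 200L),
                            nGenes = 2000L, baselineMean = 2,
                            signatureGenes = notchSignature,
                            signatureEffect = NULL,
                            mitoFraction = 0.05, nMitoGenes = 10L,
                            qcViolators = c(highCount = 0L, highGene = 0L,
                                            highMito = 0L),
                            dispersion = 0.1, mitoPrefix = "MT-") {
  stopifnot(!is.null(names(nCellsPerCondition)),
            mitoFraction >= 0, mitoFraction < 1, dispersion >= 0)
  if (is.null(signatureEffect)) {
    signatureEffect <- stats::setNames(rep(1, length(nCellsPerCondition)),
                                       names(nCellsPerCondition))
  }
  if (!all(names(nCellsPerCondition) %in% names(signatureEffect))) {
    stop("signatureEffect must name every condition")
  }
  if (any(signatureEffect < 0)) stop("signature effects must be >= 0")
  if (nGenes < length(signatureGenes) + nMitoGenes) {
    stop("nGenes too small for the signature and mito genes")
  }
  viol <- c(highCount = 0L, highGene = 0L, highMito = 0L)
  viol[names(qcViolators)] <- as.integer(qcViolators)
  list(nCellsPerCondition = nCellsPerCondition, nGenes = as.integer(nGenes),
       baselineMean = baselineMean, signatureGenes = signatureGenes,
       signatureEffect = signatureEffect, mitoFraction = mitoFraction,
       nMitoGenes = as.integer(nMitoGenes), qcViolators = viol,
       dispersion = dispersion, mitoPrefix = mitoPrefix)
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  else stats::rpois(n, mu)
}

#' Generate a synthetic single-cell count matrix
#'
#' Draws negative-binomial counts per gene per cell around per-gene
#' baseline means, with mitochondrial genes scaled to carry
#' `mitoFraction` of the expected counts and signature-gene means
#' multiplied by the condition's effect. Requested numbers of
#' QC-violating cells (total counts above 36,000; detected genes above
#' 6000; mitochondrial fraction above 0.18) are appended and flagged in
#' `colData(.)$qcViolation`.
#'
#' @param truth from [expressionTruth()].
#' @param seed RNG seed.
#' @return a `SingleCellExperiment` with `counts`, `condition` and
#'   `qcViolation` columns.
#' @export
genExpression <- function(truth, seed = 1L) {
  nG <- truth$nGenes
  if (truth$qcViolators[["highGene"]] > 0L && nG <= 6000L) {
    stop("cannot inject high-gene violators: nGenes must exceed 6000")
  }
  sigN <- truth$signatureGenes
  mitoN <- paste0(truth$mitoPrefix, seq_len(truth$nMitoGenes))
  otherN <- sprintf("G%05d", seq_len(nG - length(sigN) - length(mitoN)))
  genes <- c(mitoN, sigN, otherN)
  mu <- rep_len(truth$baselineMean, nG)
  names(mu) <- genes
  # scale mito means so their expected share of counts is mitoFraction
  isMito <- startsWith(genes, truth$mitoPrefix)
  if (any(isMito) && truth$mitoFraction > 0) {
    sm <- sum(mu[isMito]); so <- sum(mu[!isMito])
    mu[isMito] <- mu[isMito] *
      truth$mitoFraction * so / ((1 - truth$mitoFraction) * sm)
  } else mu[isMito] <- 0

  conds <- truth$nCellsPerCondition
  withSeed(seed, {
    blocks <- lapply(names(conds), function(cd) {
      nc <- conds[[cd]]
      muC <- mu
      muC[sigN] <- muC[sigN] * truth$signatureEffect[[cd]]
      matrix(rcounts(nG * nc, rep(muC, nc), truth$dispersion),
             nrow = nG, ncol = nc)
    })
    counts <- do.call(cbind, blocks)
    condition <- rep(names(conds), times = unlist(conds))
    violation <- rep("", ncol(counts))

    addViolators <- function(kind, n) {
      if (n == 0L) return(NULL)
      cells <- vapply(seq_len(n), function(i) {
        muV <- mu
        if (kind == "highCount") muV <- muV * (2 * 36001 / sum(muV))
        if (kind == "highMito") {
          muV[isMito] <- if (sum(muV[isMito]) > 0) {
            muV[isMito] * (sum(muV[!isMito]) / sum(muV[isMito]))
          } else sum(muV[!isMito]) / sum(isMito)  # ~50% mito share
        }
        x <- rcounts(nG, muV, truth$dispersion)
        if (kind == "highGene") x[seq_len(6001L)] <- x[seq_len(6001L)] + 1L
        if (kind == "highCount" && sum(x) <= 36000) {
          x[1L] <- x[1L] + (36001L - sum(x))
        }
        if (kind == "highMito") {
          tot <- sum(x); mt <- sum(x[isMito])
          if (mt / max(tot, 1) <= 0.18) {
            x[which(isMito)[1L]] <- x[which(isMito)[1L]] +
              ceiling(0.3 * tot) + 1L
          }
        }
        as.integer(x)
      }, integer(nG))
      cells
    }
    for (kind in c("highCount", "highGene", "highMito")) {
      extra <- addViolators(kind, truth$qcViolators[[kind]])
      if (!is.null(extra)) {
        counts <- cbind(counts, extra)
        condition <- c(condition, rep(names(conds)[1], ncol(extra)))
        violation <- c(violation, rep(kind, ncol(extra)))
      }
    }
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
    sce <- makeCountMatrix(counts, condition = condition)
    SummarizedExperiment::colData(sce)$qcViolation <- violation
    sce
  })
}
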