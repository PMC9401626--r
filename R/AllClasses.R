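#' @import methods
NULL

#' Central composite design
#'
#' An orthogonal central composite design (CCD) over coded cytokine
#' concentrations. The coded matrix holds one row per experimental run:
#' a two-level factorial core at coded \eqn{\pm 1}, axial (star) runs at
#' \eqn{\pm\alpha} on one axis, and replicated center runs at 0. Factor
#' metadata maps coded levels to concentrations on a logarithmic scale
#' (see [codedToConc()]).
#'
#' @slot factors `data.frame` with columns `name`, `low`, `high`, `units`:
#'   concentrations at coded -1 and +1 for each factor (both strictly
#'   positive; the log mapping cannot represent zero).
#' @slot coded numeric matrix, runs x factors, of coded levels.
#' @slot pointType character vector, per run, one of `"factorial"`,
#'   `"axial"`, `"center"`.
#' @slot alpha positive numeric, the axial distance (default 2.366, the
#'   orthogonality-preserving value for the six-factor design).
#' @slot nCenter integer, number of center replicates.
#'
#' @seealso [makeCCD()], [codedToConc()], [designModelMatrix()]
#' @export
setClass("CCDesign",
  slots = c(
    factors   = "data.frame",
    coded     = "matrix",
    pointType = "character",
    alpha     = "numeric",
    nCenter   = "integer"
  )
)

setValidity("CCDesign", function(object) {
  msg <- character()
  fc <- object@factors
  need <- c("name", "low", "high")
  if (!all(need %in% names(fc))) {
    msg <- c(msg, "factors must have columns name, low, high")
  } else {
    if (anyDuplicated(fc$name)) msg <- c(msg, "factor names must be unique")
    if (any(fc$low <= 0)) msg <- c(msg, "factor low concentrations must be > 0")
    if (any(fc$high <= fc$low)) msg <- c(msg, "factor high must exceed low")
  }
  if (ncol(object@coded) != nrow(fc)) {
    msg <- c(msg, "coded matrix must have one column per factor")
  }
  if (length(object@pointType) != nrow(object@coded)) {
    msg <- c(msg, "pointType must have one entry per run")
  }
  if (!all(object@pointType %in% c("factorial", "axial", "center"))) {
    msg <- c(msg, "pointType entries must be factorial/axial/center")
  }
  if (length(object@alpha) != 1L || object@alpha <= 0) {
    msg <- c(msg, "alpha must be a single positive number")
  }
  cm <- object@coded
  pt <- object@pointType
  if (nrow(cm) > 0 && length(pt) == nrow(cm) && length(msg) == 0L) {
    fac <- cm[pt == "factorial", , drop = FALSE]
    if (length(fac) && !all(fac %in% c(-1, 1))) {
      msg <- c(msg, "factorial rows must contain only -1/+1")
    }
    ax <- cm[pt == "axial", , drop = FALSE]
    if (nrow(ax)) {
      ok <- apply(ax, 1L, function(r) {
        sum(r != 0) == 1L && all(abs(r[r != 0]) == object@alpha)
      })
      if (!all(ok)) msg <- c(msg, "axial rows must be +/-alpha on one axis, 0 elsewhere")
    }
    ce <- cm[pt == "center", , drop = FALSE]
    if (length(ce) && any(ce != 0)) msg <- c(msg, "center rows must be all zero")
  }
  if (length(msg)) msg else TRUE
})

#' Polynomial dose-response model for one phenotype
#'
#' Least-squares fit of a polynomial surface over coded cytokine
#' concentrations, predicting (a transform of) the absolute cell count of
#' one phenotype. Terms are exponent vectors over the design factors
#' (degree at most 3); the response is modelled on the `identity` or
#' `log1p` scale.
#'
#' @slot responseName character, phenotype name (e.g. `"proT"`).
#' @slot transform `"identity"` or `"log1p"` (natural log of count + 1).
#' @slot terms list of named integer exponent vectors, intercept first.
#' @slot coefficients numeric, aligned with `terms`.
#' @slot factorNames character, the design factor names the terms refer to.
#' @slot fitStats list with `r.squared`, `adj.r.squared`, `sigma`, `n`, `p`
#'   (empty for models loaded from a coefficient table).
#'
#' @seealso [fitResponse()], [predictResponse()], [readCoefCsv()]
#' @export
setClass("ResponseModel",
  slots = c(
    responseName = "character",
    transform    = "character",
    terms        = "list",
    coefficients = "numeric",
    factorNames  = "character",
    fitStats     = "list"
  )
)

setValidity("ResponseModel", function(object) {
  msg <- character()
  if (!object@transform %in% c("identity", "log1p")) {
    msg <- c(msg, "transform must be 'identity' or 'log1p'")
  }
  if (length(object@terms) != length(object@coefficients)) {
    msg <- c(msg, "coefficients must align with terms")
  }
  k <- length(object@factorNames)
  degs <- vapply(object@terms, function(e) {
    if (length(e) != k) return(-1L)
    sum(e)
  }, integer(1))
  if (any(degs < 0L)) msg <- c(msg, "each term needs one exponent per factor")
  else if (any(degs > 3L)) msg <- c(msg, "term degree must be <= 3")
  if (length(msg)) msg else TRUE
})

#' Desirability optimization result
#'
#' Result of the constrained basin-hopping search over coded cytokine
#' space: all restart solutions ranked by overall desirability, the mean
#' of the top-k coded vectors, and that average mapped back to
#' concentration units.
#'
#' @slot solutions `data.frame`: one row per restart, columns `D` plus one
#'   coded coordinate per factor, sorted by `D` decreasing.
#' @slot averagedCoded numeric, arithmetic mean of the top-k coded vectors.
#' @slot averagedConc named numeric, the averaged optimum in concentration
#'   units.
#' @slot predictedAtOptimum named numeric, predicted count-scale response
#'   of each model at the averaged optimum.
#' @slot radius positive numeric feasibility-hypersphere radius.
#' @slot topK integer, number of solutions averaged.
#' @slot seed integer seed used for the search.
#' @slot degenerate logical, `TRUE` when every restart ended with overall
#'   desirability 0 (objective flat at zero).
#'
#' @seealso [optimizeDesirability()]
#' @export
setClass("OptimizationResult",
  slots = c(
    solutions          = "data.frame",
    averagedCoded      = "numeric",
    averagedConc       = "numeric",
    predictedAtOptimum = "numeric",
    radius             = "numeric",
    topK               = "integer",
    seed               = "integer",
    degenerate         = "logical"
  )
)

setValidity("OptimizationResult", function(object) {
  msg <- character()
  cn <- setdiff(names(object@solutions), "D")
  if (nrow(object@solutions)) {
    X <- as.matrix(object@solutions[, cn, drop = FALSE])
    if (any(sqrt(rowSums(X^2)) > object@radius + 1e-6)) {
      msg <- c(msg, "solutions must satisfy ||x|| <= radius + 1e-6")
    }
    if (is.unsorted(rev(object@solutions$D))) {
      msg <- c(msg, "solutions must be sorted by D decreasing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Single-hit Poisson frequency estimate
#'
#' Maximum-likelihood estimate of progenitor frequency from
#' limiting-dilution well data under \eqn{P(\mathrm{negative} \mid n) =
#' e^{-f n}}. The reciprocal `1/f` is the cell dose at which the model's
#' failure (negative-well) rate is \eqn{e^{-1} \approx 0.37}.
#'
#' @slot f per-cell frequency estimate in (0, 1).
#' @slot reciprocal cells per progenitor, `1/f`.
#' @slot ci95 numeric length-2, 95% confidence interval on the reciprocal
#'   scale (low, high).
#' @slot loglik log-likelihood at the maximum.
#' @slot converged logical; `FALSE` when the estimate sits on a boundary
#'   (all wells negative, or all positive).
#' @slot flag character, `""` or a boundary explanation.
#' @slot data the input `data.frame` (dose, tested, negative).
#'
#' @seealso [estimateFrequency()], [predictedFailureRate()]
#' @export
setClass("FrequencyEstimate",
  slots = c(
    f          = "numeric",
    reciprocal = "numeric",
    ci95       = "numeric",
    loglik     = "numeric",
    converged  = "logical",
    flag       = "character",
    data       = "data.frame"
  )
)

setValidity("FrequencyEstimate", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@reciprocal, 1 / object@f))) {
    msg <- c(msg, "reciprocal must equal 1/f")
  }
  if (length(object@ci95) != 2L) msg <- c(msg, "ci95 must have length 2")
  else if (object@converged &&
           !(object@ci95[1] <= object@reciprocal &&
             object@reciprocal <= object@ci95[2])) {
    msg <- c(msg, "ci95 must bracket the reciprocal")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell signature score with bin-matched controls
#'
#' Result of scoring a gene signature (by default the notch targets HES1,
#' CD3D, HES4, DTX1, BCL11B, HEY2) against control genes drawn from the
#' same mean-expression bins, plus the between-condition comparison.
#'
#' @slot scores named numeric, one score per cell.
#' @slot condition factor, per-cell condition label aligned with `scores`.
#' @slot signatureGenes character, signature genes actually used.
#' @slot controlGenes character, pooled control genes (with multiplicity).
#' @slot nCtrlPerGene integer, control genes drawn per signature gene.
#' @slot nBins integer, number of mean-expression bins.
#' @slot seed integer, RNG seed used for control sampling.
#' @slot sampledWithReplacement logical, `TRUE` when some bin was smaller
#'   than the requested number of controls after exclusions.
#' @slot perConditionMean named numeric mean score per condition.
#' @slot foldChange numeric, mean(group 2)/mean(group 1) for two-condition
#'   data; `NA` when undefined (a mean <= 0) or with != 2 conditions.
#' @slot mwP numeric, two-sided Mann-Whitney p for two-condition data.
#'
#' @seealso [scoreSignature()], [compareConditions()]
#' @export
setClass("SignatureScoreResult",
  slots = c(
    scores                 = "numeric",
    condition              = "factor",
    signatureGenes         = "character",
    controlGenes           = "character",
    nCtrlPerGene           = "integer",
    nBins                  = "integer",
    seed                   = "integer",
    sampledWithReplacement = "logical",
    perConditionMean       = "numeric",
    foldChange             = "numeric",
    mwP                    = "numeric"
  )
)

setValidity("SignatureScoreResult", function(object) {
  if (length(object@condition) != length(object@scores)) {
    return("condition must align with scores")
  }
  TRUE
})
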