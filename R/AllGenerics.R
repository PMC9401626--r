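# Accessor generics and show methods for the package classes.

#' @describeIn CCDesign-class coded design matrix (runs x factors)
#' @param object,x a `CCDesign`
#' @export
setGeneric("codedMatrix", function(x) standardGeneric("codedMatrix"))

#' @export
setMethod("codedMatrix", "CCDesign", function(x) x@coded)

#' @rdname CCDesign-class
#' @export
setGeneric("pointType", function(x) standardGeneric("pointType"))

#' @export
setMethod("pointType", "CCDesign", function(x) x@pointType)

#' @rdname CCDesign-class
#' @export
setGeneric("designAlpha", function(x) standardGeneric("designAlpha"))

#' @export
setMethod("designAlpha", "CCDesign", function(x) x@alpha)

#' @rdname CCDesign-class
#' @export
setGeneric("designFactors", function(x) standardGeneric("designFactors"))

#' @export
setMethod("designFactors", "CCDesign", function(x) x@factors)

#' @rdname CCDesign-class
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @export
setMethod("factorNames", "CCDesign", function(x) x@factors$name)

#' @export
setMethod("factorNames", "ResponseModel", function(x) x@factorNames)

#' Number of runs in a design
#' @param x a `CCDesign`
#' @export
setMethod("nrow", "CCDesign", function(x) base::nrow(x@coded))

setMethod("show", "CCDesign", function(object) {
  k <- base::nrow(object@factors)
  pt <- table(factor(object@pointType,
                     levels = c("factorial", "axial", "center")))
  cat(sprintf(
    "CCDesign: %d factors, %d runs (%d factorial + %d axial + %d center), alpha = %g\n",
    k, base::nrow(object@coded), pt[["factorial"]], pt[["axial"]],
    pt[["center"]], object@alpha))
  cat("factors: ", paste(object@factors$name, collapse = ", "), "\n", sep = "")
})

#' @describeIn ResponseModel-class phenotype (response) name
#' @param x,object a `ResponseModel`
#' @export
setGeneric("responseName", function(x) standardGeneric("responseName"))

#' @export
setMethod("responseName", "ResponseModel", function(x) x@responseName)

#' @rdname ResponseModel-class
#' @export
setGeneric("responseTransform", function(x) standardGeneric("responseTransform"))

#' @export
setMethod("responseTransform", "ResponseModel", function(x) x@transform)

#' @rdname ResponseModel-class
#' @export
setGeneric("modelTerms", function(x) standardGeneric("modelTerms"))

#' @export
setMethod("modelTerms", "ResponseModel", function(x) x@terms)

#' @rdname ResponseModel-class
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))

#' @export
setMethod("fitStats", "ResponseModel", function(x) x@fitStats)

#' Model coefficients
#' @param object a `ResponseModel`
#' @param ... ignored
#' @export
setMethod("coef", "ResponseModel", function(object, ...) {
  stats::setNames(object@coefficients,
                  vapply(object@terms, termLabel, character(1)))
})

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf("ResponseModel '%s' (%s scale): %d terms over %d factors\n",
              object@responseName, object@transform, length(object@terms),
              length(object@factorNames)))
  fs <- object@fitStats
  if (length(fs)) {
    cat(sprintf("  R^2 = %.4f, adj R^2 = %.4f, sigma = %.4g, n = %d\n",
                fs$r.squared, fs$adj.r.squared, fs$sigma, fs$n))
  }
})

#' @describeIn OptimizationResult-class restart solutions ranked by D
#' @param x,object an `OptimizationResult`
#' @export
setGeneric("solutions", function(x) standardGeneric("solutions"))

#' @export
setMethod("solutions", "OptimizationResult", function(x) x@solutions)

#' @rdname OptimizationResult-class
#' @export
setGeneric("optimumCoded", function(x) standardGeneric("optimumCoded"))

#' @export
setMethod("optimumCoded", "OptimizationResult", function(x) x@averagedCoded)

#' @rdname OptimizationResult-class
#' @export
setGeneric("optimumConc", function(x) standardGeneric("optimumConc"))

#' @export
setMethod("optimumConc", "OptimizationResult", function(x) x@averagedConc)

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf(
    "OptimizationResult: %d restarts, top %d averaged, radius %g%s\n",
    base::nrow(object@solutions), object@topK, object@radius,
    if (object@degenerate) " [degenerate: objective flat at zero]" else ""))
  cat(sprintf("  best D = %.4f\n", object@solutions$D[1]))
  cat("  averaged optimum (concentration units):\n")
  print(signif(object@averagedConc, 4))
})

#' @describeIn FrequencyEstimate-class estimated per-cell frequency
#' @param x,object a `FrequencyEstimate`
#' @export
setGeneric("hitFrequency", function(x) standardGeneric("hitFrequency"))

#' @export
setMethod("hitFrequency", "FrequencyEstimate", function(x) x@f)

#' @rdname FrequencyEstimate-class
#' @export
setGeneric("reciprocalFrequency", function(x) standardGeneric("reciprocalFrequency"))

#' @export
setMethod("reciprocalFrequency", "FrequencyEstimate", function(x) x@reciprocal)

#' @rdname FrequencyEstimate-class
#' @export
setGeneric("confint95", function(x) standardGeneric("confint95"))

#' @export
setMethod("confint95", "FrequencyEstimate", function(x) x@ci95)

setMethod("show", "FrequencyEstimate", function(object) {
  cat(sprintf(
    "FrequencyEstimate: f = %.6g (1 in %.1f cells), 95%% CI 1/%.1f-1/%.1f\n",
    object@f, object@reciprocal, object@ci95[1], object@ci95[2]))
  if (nzchar(object@flag)) cat("  flag: ", object@flag, "\n", sep = "")
})

#' @describeIn SignatureScoreResult-class per-cell scores
#' @param x,object a `SignatureScoreResult`
#' @export
setGeneric("cellScores", function(x) standardGeneric("cellScores"))

#' @export
setMethod("cellScores", "SignatureScoreResult", function(x) x@scores)

setMethod("show", "SignatureScoreResult", function(object) {
  cat(sprintf(
    "SignatureScoreResult: %d cells, %d signature genes, %d bins, %d controls/gene\n",
    length(object@scores), length(object@signatureGenes), object@nBins,
    object@nCtrlPerGene))
  if (length(object@perConditionMean)) {
    cat("  mean score by condition:\n")
    print(signif(object@perConditionMean, 4))
  }
  if (!is.na(object@foldChange)) {
    cat(sprintf("  fold change = %.3f, Mann-Whitney p = %.3g\n",
                object@foldChange, object@mwP))
  }
})
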