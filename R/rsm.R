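# Polynomial response-surface terms and least-squares dose-response fits.

#' Label of a polynomial term
#'
#' Terms are named integer exponent vectors over the design factors. The
#' label convention matches coefficient tables: `"Intercept"`, `"IL7"`,
#' `"IL7^2"`, `"IL7*TNFa"`, `"IL7^2*IL3"`.
#'
#' @param e named integer vector of per-factor exponents.
#' @return character label.
#' @export
termLabel <- function(e) {
  nz <- which(e > 0)
  if (!length(nz)) return("Intercept")
  paste(ifelse(e[nz] == 1L, names(e)[nz],
               paste0(names(e)[nz], "^", e[nz])), collapse = "*")
}

#' Parse a term label
#'
#' Inverse of [termLabel()]. Unknown factor names or exponents above 3
#' raise an error naming the offending token.
#'
#' @param label character term label.
#' @param factorNames the design's factor names.
#' @return named integer exponent vector.
#' @export
parseTermLabel <- function(label, factorNames) {
  e <- stats::setNames(integer(length(factorNames)), factorNames)
  lab <- trimws(label)
  if (lab %in% c("Intercept", "(Intercept)", "1")) return(e)
  for (tok in strsplit(lab, "*", fixed = TRUE)[[1]]) {
    parts <- strsplit(tok, "^", fixed = TRUE)[[1]]
    nm <- parts[1]
    ex <- if (length(parts) == 1L) 1L else suppressWarnings(as.integer(parts[2]))
    if (length(parts) > 2L || is.na(ex) || ex < 1L) {
      stop("cannot parse term token '", tok, "' in '", label, "'")
    }
    if (!nm %in% factorNames) {
      stop("unknown factor '", nm, "' in term token '", tok, "'")
    }
    e[nm] <- e[nm] + ex
  }
  if (sum(e) > 3L) stop("term '", label, "' has degree ", sum(e), " (> 3)")
  e
}

# canonical sort key: degree first, then lexicographic in factor indices
# repeated by exponent (so for factors A,B: A^2 < A*B < B^2 within degree 2)
termKey <- function(e) {
  idx <- rep(seq_along(e), times = e)
  sprintf("%d|%s", sum(e), paste(sprintf("%02d", idx), collapse = ""))
}

#' Build the standard response-surface term set
#'
#' Returns the full second-order basis estimable from a central composite
#' design — intercept, all linear and quadratic terms, and all two-factor
#' interactions — plus any explicitly supplied third-order terms,
#' deduplicated and in canonical order (by degree, then lexicographic).
#'
#' @param factorNames character vector of factor names (or a single
#'   integer `k`, in which case names `X1..Xk` are used).
#' @param thirdOrder optional list of degree-3 exponent vectors (or term
#'   labels) to append; supplying a term of degree > 3 is an error.
#' @return list of named integer exponent vectors.
#' @examples
#' length(buildTerms(6))  # 28 = 1 + 6 + 6 + 15
#' @export
buildTerms <- function(factorNames, thirdOrder = list()) {
  if (is.numeric(factorNames) && length(factorNames) == 1L) {
    factorNames <- paste0("X", seq_len(factorNames))
  }
  k <- length(factorNames)
  if (k < 1L) stop("need at least one factor")
  zero <- stats::setNames(integer(k), factorNames)
  terms <- list(zero)
  for (i in seq_len(k)) {
    e <- zero; e[i] <- 1L; terms <- c(terms, list(e))
    e <- zero; e[i] <- 2L; terms <- c(terms, list(e))
  }
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      e <- zero; e[i] <- 1L; e[j] <- 1L; terms <- c(terms, list(e))
    }
  }
  extra <- lapply(thirdOrder, function(t) {
    if (is.character(t)) t <- parseTermLabel(t, factorNames)
    t <- stats::setNames(as.integer(t), factorNames)
    if (sum(t) > 3L) stop("third-order term of degree ", sum(t), " (> 3)")
    t
  })
  terms <- c(terms, extra)
  keys <- vapply(terms, termKey, character(1))
  terms <- terms[!duplicated(keys)]
  terms[order(vapply(terms, termKey, character(1)))]
}

#' Model matrix of a term set over coded points
#'
#' @param design a [CCDesign-class], or a coded numeric matrix.
#' @param terms list of exponent vectors (default: [buildTerms()] for the
#'   design's factors).
#' @return numeric matrix, one column per term, labelled by [termLabel()].
#' @export
designModelMatrix <- function(design, terms = NULL) {
  X <- if (is(design, "CCDesign")) codedMatrix(design) else as.matrix(design)
  if (is.null(terms)) terms <- buildTerms(colnames(X))
  M <- vapply(terms, function(e) {
    col <- rep(1, nrow(X))
    for (j in which(e > 0)) col <- col * X[, j]^e[j]
    col
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) M <- matrix(M, nrow = 1L)
  colnames(M) <- vapply(terms, termLabel, character(1))
  M
}

applyTransform <- function(y, transform) {
  switch(transform, identity = y, log1p = log1p(y),
         stop("unknown transform '", transform, "'"))
}

# counts are nonnegative: negative predictions clip to 0 on either scale
backTransform <- function(y, transform) {
  switch(transform, identity = pmax(y, 0), log1p = pmax(expm1(y), 0))
}

#' Fit a polynomial dose-response model
#'
#' Ordinary least squares of the transformed phenotype count on the
#' polynomial terms evaluated at the coded design points. Counts are
#' modelled as `X` (`identity`) or `log(X + 1)` (`log1p`, the default for
#' counts). The model matrix must be full rank; aliased terms are named
#' in the error otherwise.
#'
#' @param design a [CCDesign-class].
#' @param table response table `data.frame` with columns `run_id`,
#'   `response`, `count` (see [genDoseResponse()] / [readResponseTable()]).
#' @param response which response (phenotype) to fit.
#' @param transform `"log1p"` (default) or `"identity"`.
#' @param terms term list; default the full second-order basis.
#' @return a [ResponseModel-class] with populated fit statistics.
#' @export
fitResponse <- function(design, table, response,
                        transform = c("log1p", "identity"), terms = NULL) {
  transform <- match.arg(transform)
  if (is.null(terms)) terms <- buildTerms(factorNames(design))
  tab <- table[table$response == response, , drop = FALSE]
  runs <- rownames(codedMatrix(design))
  idx <- match(runs, tab$run_id)
  if (anyNA(idx)) {
    stop("missing counts for response '", response, "' at runs: ",
         paste(runs[is.na(idx)], collapse = ", "))
  }
  y <- applyTransform(as.numeric(tab$count[idx]), transform)
  X <- designModelMatrix(design, terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient model matrix; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  n <- length(y); p <- ncol(X)
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  adj <- if (sst > 0 && n > p) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  sigma <- if (n > p) sqrt(ssr / (n - p)) else NA_real_
  new("ResponseModel",
      responseName = response, transform = transform, terms = terms,
      coefficients = as.numeric(fit$coefficients),
      factorNames = factorNames(design),
      fitStats = list(r.squared = r2, adj.r.squared = adj, sigma = sigma,
                      n = n, p = p))
}

#' Greedy forward selection of third-order terms
#'
#' Starting from `baseTerms`, repeatedly adds the candidate degree-3 term
#' that most increases adjusted R-squared, stopping when no candidate
#' improves it by more than `threshold`. Ties are broken toward the
#' candidate earliest in canonical order.
#'
#' @inheritParams fitResponse
#' @param baseTerms term list to start from.
#' @param candidates list of degree-3 exponent vectors (or labels).
#' @param threshold minimum adjusted-R-squared gain to accept a term,
#'   default 0.
#' @return the selected term list (base plus accepted candidates, in
#'   canonical order).
#' @export
selectThirdOrder <- function(design, table, response,
                             transform = c("log1p", "identity"),
                             baseTerms = NULL, candidates = list(),
                             threshold = 0) {
  transform <- match.arg(transform)
  if (is.null(baseTerms)) baseTerms <- buildTerms(factorNames(design))
  cand <- lapply(candidates, function(t) {
    if (is.character(t)) t <- parseTermLabel(t, factorNames(design))
    if (sum(t) != 3L) stop("candidate term '", termLabel(t), "' is not degree 3")
    t
  })
  cand <- cand[order(vapply(cand, termKey, character(1)))]
  current <- baseTerms
  adjOf <- function(tl) fitStats(fitResponse(design, table, response,
                                             transform, tl))$adj.r.squared
  best <- adjOf(current)
  repeat {
    if (!length(cand)) break
    gains <- vapply(cand, function(t) {
      tl <- c(current, list(t))
      keys <- vapply(tl, termKey, character(1))
      tl <- tl[!duplicated(keys)]
      # a candidate aliased with the current terms cannot improve the fit
      tryCatch(adjOf(tl[order(vapply(tl, termKey, character(1)))]),
               error = function(e) -Inf)
    }, numeric(1))
    i <- which.max(gains)           # which.max takes the first maximum:
    if (gains[i] - best <= threshold) break  # canonical-order tie-break
    t <- cand[[i]]
    current <- c(current, list(t))
    keys <- vapply(current, termKey, character(1))
    current <- current[!duplicated(keys)]
    current <- current[order(vapply(current, termKey, character(1)))]
    best <- gains[i]
    cand <- cand[-i]
  }
  current
}

#' Predict from a dose-response model
#'
#' Evaluates the polynomial at coded point(s) and back-transforms to the
#' count scale (negative back-transformed predictions are clipped to 0,
#' since counts are nonnegative).
#'
#' @param model a [ResponseModel-class].
#' @param x coded point: numeric vector of length n-factors, or a matrix
#'   with one row per point.
#' @return list with `transformed` (linear-predictor scale) and `count`
#'   (count scale, >= 0), each of length `nrow(x)`.
#' @export
predictResponse <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@factorNames)) {
    stop("coded point must have ", length(model@factorNames), " coordinates")
  }
  colnames(x) <- model@factorNames
  M <- designModelMatrix(x, model@terms)
  eta <- as.numeric(M %*% model@coefficients)
  list(transformed = eta, count = backTransform(eta, model@transform))
}

#' @describeIn predictResponse `predict` method for `ResponseModel`
#' @param object a `ResponseModel`
#' @param newdata coded point(s)
#' @param ... ignored
#' @export
setMethod("predict", "ResponseModel", function(object, newdata, ...) {
  predictResponse(object, newdata)
})
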