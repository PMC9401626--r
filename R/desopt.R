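# Derringer-style desirability functions and constrained basin-hopping
# optimization of the overall (geometric-mean) desirability.

#' Desirability specification for one response
#'
#' Maximize-type desirability: predicted counts at or below `L` score 0,
#' at or above `U` score 1, with a power ramp of exponent `w` between.
#' `L`/`U` left as `NA` are anchored at fit time to the minimum and
#' maximum predicted count over the experimental design points (the
#' least-arbitrary scaling of predictions into [0,1]); both are
#' overridable.
#'
#' @param response response (phenotype) name.
#' @param L lower anchor on the count scale (`NA` = design minimum).
#' @param U upper anchor (`NA` = design maximum); must exceed `L`.
#' @param w positive ramp weight, default 1 (linear).
#' @return one-row `data.frame` spec; `rbind()` several for multiple
#'   responses.
#' @export
desirabilitySpec <- function(response, L = NA_real_, U = NA_real_, w = 1) {
  if (!is.na(L) && !is.na(U) && L >= U) stop("need L < U")
  if (w <= 0) stop("weight w must be > 0")
  data.frame(response = response, L = L, U = U, w = w,
             stringsAsFactors = FALSE)
}

#' Individual desirability of a predicted value
#'
#' @param value predicted response on the count scale.
#' @param L,U lower/upper anchors (L < U).
#' @param w positive ramp weight.
#' @return desirability in [0, 1]; monotone nondecreasing in `value`.
#' @examples
#' desirability(c(0, 5, 10), L = 0, U = 10)  # 0, 0.5, 1
#' @export
desirability <- function(value, L, U, w = 1) {
  stopifnot(L < U, w > 0)
  d <- ((value - L) / (U - L))
  d <- pmin(pmax(d, 0), 1)
  d^w
}

#' Overall desirability (geometric mean)
#'
#' Combines individual desirabilities into a single objective as their
#' geometric mean; any individual score of 0 annihilates the overall
#' score.
#'
#' @param d numeric vector of individual desirabilities in [0, 1].
#' @return geometric mean in [0, 1].
#' @examples
#' overallDesirability(c(0.25, 1))  # 0.5
#' @export
overallDesirability <- function(d) {
  if (!length(d)) stop("need at least one desirability score")
  if (any(d <= 0)) return(0)
  exp(mean(log(d)))
}

#' Optimization settings for the desirability search
#'
#' @param radius feasibility hypersphere radius in coded units; default
#'   2.366, the design's axial distance, so optima are never
#'   extrapolations beyond the tested concentration range.
#' @param nRestarts number of random initializations, default 25.
#' @param topK number of best restart solutions averaged, default 5.
#' @param seed RNG seed.
#' @param nHops perturbation/local-minimization hops per restart.
#' @param stepSize Gaussian hop step size in coded units.
#' @param maxit iteration cap for each local Nelder-Mead polish.
#' @return list of settings for [optimizeDesirability()].
#' @export
optimizationConfig <- function(radius = 2.366, nRestarts = 25L, topK = 5L,
                               seed = 1L, nHops = 5L, stepSize = 0.5,
                               maxit = 400L) {
  stopifnot(radius > 0, topK <= nRestarts)
  list(radius = radius, nRestarts = as.integer(nRestarts),
       topK = as.integer(topK), seed = as.integer(seed),
       nHops = as.integer(nHops), stepSize = stepSize,
       maxit = as.integer(maxit))
}

# radial projection onto the closed ball of given radius
projectBall <- function(x, radius) {
  nx <- sqrt(sum(x^2))
  if (nx > radius) x * (radius / nx) else x
}

# uniform draw inside a k-ball: normalized Gaussian direction x radius*u^(1/k)
runifBall <- function(k, radius) {
  g <- stats::rnorm(k)
  g / sqrt(sum(g^2)) * radius * stats::runif(1)^(1 / k)
}

# anchor NA desirability limits at the design-point prediction range
resolveSpecs <- function(models, specs, design) {
  for (i in seq_len(nrow(specs))) {
    if (is.na(specs$L[i]) || is.na(specs$U[i])) {
      if (is.null(design)) {
        stop("desirability spec for '", specs$response[i],
             "' has NA anchors and no design was supplied")
      }
      m <- models[[match(specs$response[i],
                         vapply(models, responseName, character(1)))]]
      pr <- predictResponse(m, codedMatrix(design))$count
      if (is.na(specs$L[i])) specs$L[i] <- min(pr)
      if (is.na(specs$U[i])) specs$U[i] <- max(pr)
      if (specs$L[i] >= specs$U[i]) {
        stop("degenerate anchors for '", specs$response[i],
             "': design predictions are constant")
      }
    }
  }
  specs
}

#' Optimize cytokine concentrations by overall desirability
#'
#' Basin-hopping-style global search for the coded point maximizing the
#' geometric-mean desirability of the fitted dose-response models,
#' constrained to the hypersphere \eqn{\lVert x\rVert_2 \le} `radius`.
#' Each of `nRestarts` restarts starts uniformly inside the sphere and
#' alternates Nelder-Mead local polish with Gaussian perturbation hops;
#' candidates outside the sphere are radially projected onto it before
#' evaluation. The best point of every restart is ranked by overall
#' desirability and the top `topK` coded vectors are averaged to give the
#' reported optimum, which is mapped back to concentration units.
#'
#' Inside the search the geometric mean is computed on desirabilities
#' clipped to `[1e-12, 1]` so the objective stays informative where some
#' response scores 0; reported desirabilities are unclipped.
#'
#' @param models list of [ResponseModel-class] objects.
#' @param specs `data.frame` of [desirabilitySpec()] rows, one per model
#'   (any order).
#' @param design the [CCDesign-class] used for fitting; needed to anchor
#'   `NA` spec limits and to map the optimum to concentrations.
#' @param config settings from [optimizationConfig()].
#' @return an [OptimizationResult-class].
#' @export
optimizeDesirability <- function(models, specs, design,
                                 config = optimizationConfig()) {
  mnames <- vapply(models, responseName, character(1))
  if (!setequal(mnames, specs$response) ||
      length(mnames) != nrow(specs)) {
    stop("models and desirability specs must align by response name")
  }
  specs <- specs[order(specs$response), , drop = FALSE]
  models <- models[order(mnames)]
  specs <- resolveSpecs(models, specs, design)
  k <- length(factorNames(models[[1]]))
  radius <- config$radius

  dVector <- function(x) {
    vapply(seq_along(models), function(i) {
      v <- predictResponse(models[[i]], x)$count
      desirability(v, specs$L[i], specs$U[i], specs$w[i])
    }, numeric(1))
  }
  # optimizer objective: -geometric mean of clipped desirabilities,
  # evaluated after radial projection into the feasible ball
  fobj <- function(x) {
    d <- pmin(pmax(dVector(projectBall(x, radius)), 1e-12), 1)
    -exp(mean(log(d)))
  }

  res <- withSeed(config$seed, {
    sols <- matrix(NA_real_, config$nRestarts, k)
    for (r in seq_len(config$nRestarts)) {
      x <- runifBall(k, radius)
      best <- stats::optim(x, fobj, method = "Nelder-Mead",
                           control = list(maxit = config$maxit,
                                          reltol = 1e-12))
      for (h in seq_len(config$nHops)) {
        x2 <- projectBall(best$par + stats::rnorm(k, sd = config$stepSize),
                          radius)
        cand <- stats::optim(x2, fobj, method = "Nelder-Mead",
                             control = list(maxit = config$maxit,
                                            reltol = 1e-12))
        if (cand$value < best$value) best <- cand
      }
      sols[r, ] <- projectBall(best$par, radius)
    }
    sols
  })

  D <- apply(res, 1L, function(x) overallDesirability(dVector(x)))
  ord <- order(D, decreasing = TRUE)
  res <- res[ord, , drop = FALSE]
  D <- D[ord]
  sol <- as.data.frame(res)
  names(sol) <- factorNames(models[[1]])
  sol <- cbind(D = D, sol)
  avg <- colMeans(res[seq_len(config$topK), , drop = FALSE])
  names(avg) <- factorNames(models[[1]])
  fx <- designFactors(design)
  conc <- vapply(seq_len(k), function(j) {
    codedToConc(fx[match(names(avg)[j], fx$name), , drop = FALSE], avg[j])
  }, numeric(1))
  names(conc) <- names(avg)
  predAt <- vapply(models, function(m) predictResponse(m, avg)$count,
                   numeric(1))
  names(predAt) <- vapply(models, responseName, character(1))
  new("OptimizationResult",
      solutions = sol, averagedCoded = avg, averagedConc = conc,
      predictedAtOptimum = predAt, radius = radius, topK = config$topK,
      seed = config$seed, degenerate = all(D == 0))
}
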