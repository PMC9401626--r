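# Single-hit Poisson limiting-dilution frequency estimation.

#' Validate a limiting-dilution dataset
#'
#' @param data `data.frame` with columns `dose` (cells/well, > 0),
#'   `tested` (wells, > 0), `negative` (wells, 0..tested); doses must be
#'   distinct.
#' @return the validated `data.frame`.
#' @export
ldaDataset <- function(data) {
  need <- c("dose", "tested", "negative")
  if (!all(need %in% names(data))) {
    stop("LDA data needs columns: ", paste(need, collapse = ", "))
  }
  if (any(data$dose <= 0)) stop("doses must be positive")
  if (anyDuplicated(data$dose)) stop("doses must be distinct")
  if (any(data$tested <= 0)) stop("tested well counts must be positive")
  if (any(data$negative < 0 | data$negative > data$tested)) {
    stop("negative well counts must satisfy 0 <= negative <= tested")
  }
  data
}

# binomial log-likelihood of frequency f under P(negative | n) = exp(-f n);
# vectorized over f
ldaLogLik <- function(f, dose, negative, positive) {
  vapply(f, function(fi) {
    q <- exp(-fi * dose)
    sum(negative * (-fi * dose)) +
      sum(positive * log1p(-q))
  }, numeric(1))
}

# first derivative of the log-likelihood w.r.t. f
ldaScore <- function(f, dose, negative, positive) {
  q <- exp(-f * dose)
  sum(dose * (positive * q / (1 - q) - negative))
}

# expected (Fisher) information about f
ldaInfo <- function(f, dose, tested) {
  q <- exp(-f * dose)
  sum(tested * dose^2 * q / (1 - q))
}

#' Estimate progenitor frequency from limiting-dilution wells
#'
#' Maximum-likelihood fit of the single-hit Poisson model, under which a
#' well seeded with \eqn{n} cells stays negative with probability
#' \eqn{e^{-f n}}. The binomial log-likelihood
#' \deqn{\ell(f) = \sum_i \left[\mathrm{neg}_i (-f n_i) +
#'   (\mathrm{w}_i - \mathrm{neg}_i)\log(1 - e^{-f n_i})\right]}
#' is maximized over \eqn{\log f} by bracketed 1-D search followed by a
#' Newton polish. The reciprocal \eqn{1/\hat f} is the number of cells
#' per progenitor — exactly the dose at which the fitted failure rate is
#' \eqn{e^{-1} \approx 0.37}.
#'
#' Degenerate datasets (all wells negative, or all positive) pin the
#' estimate at a search boundary; these return `converged = FALSE` with
#' an explanatory flag instead of an infinite estimate.
#'
#' @param data limiting-dilution `data.frame` (see [ldaDataset()]).
#' @param ciMethod `"wald"` (default; Wald interval on log f,
#'   back-transformed) or `"profile"` (profile-likelihood interval).
#' @return a [FrequencyEstimate-class].
#' @examples
#' d <- data.frame(dose = 100, tested = 1000, negative = 368)
#' estimateFrequency(d)  # reciprocal close to 100
#' @export
estimateFrequency <- function(data, ciMethod = c("wald", "profile")) {
  ciMethod <- match.arg(ciMethod)
  data <- ldaDataset(data)
  dose <- as.numeric(data$dose)
  neg <- as.numeric(data$negative)
  pos <- as.numeric(data$tested) - neg

  uLo <- log(1e-12)
  uHi <- log(-log(1e-12) / min(dose))  # failure ~1e-12 at smallest dose
  mk <- function(f, loglik, converged, flag, ci) {
    new("FrequencyEstimate", f = f, reciprocal = 1 / f, ci95 = ci,
        loglik = loglik, converged = converged, flag = flag, data = data)
  }
  if (all(pos == 0)) {
    f <- exp(uLo)
    return(mk(f, ldaLogLik(f, dose, neg, pos), FALSE,
              "no positive wells: frequency at lower boundary",
              c(NA_real_, NA_real_)))
  }
  if (all(neg == 0)) {
    f <- exp(uHi)
    return(mk(f, ldaLogLik(f, dose, neg, pos), FALSE,
              "no negative wells: frequency at upper boundary",
              c(NA_real_, NA_real_)))
  }

  opt <- stats::optimize(function(u) ldaLogLik(exp(u), dose, neg, pos),
                         c(uLo, uHi), maximum = TRUE, tol = 1e-10)
  f <- exp(opt$maximum)
  # Newton polish on f using analytic score and a finite-difference slope
  for (i in 1:3) {
    s <- ldaScore(f, dose, neg, pos)
    h <- max(f * 1e-6, 1e-14)
    ds <- (ldaScore(f + h, dose, neg, pos) -
           ldaScore(f - h, dose, neg, pos)) / (2 * h)
    if (!is.finite(ds) || ds >= 0) break
    fNew <- f - s / ds
    if (!is.finite(fNew) || fNew <= 0) break
    f <- fNew
  }
  ll <- ldaLogLik(f, dose, neg, pos)

  if (ciMethod == "wald") {
    seLogF <- 1 / sqrt(f^2 * ldaInfo(f, dose, data$tested))
    fLo <- f * exp(-1.96 * seLogF)
    fHi <- f * exp(1.96 * seLogF)
  } else {
    cut <- ll - stats::qchisq(0.95, 1) / 2
    g <- function(u) ldaLogLik(exp(u), dose, neg, pos) - cut
    u <- log(f)
    fLo <- exp(stats::uniroot(g, c(uLo, u))$root)
    fHi <- exp(stats::uniroot(g, c(u, uHi))$root)
  }
  # CI on the reciprocal scale: high f -> low reciprocal
  mk(f, ll, TRUE, "", c(1 / fHi, 1 / fLo))
}

#' Predicted failure (negative-well) rate
#'
#' Under the single-hit Poisson model the probability that a well seeded
#' with `n` cells is negative is \eqn{e^{-f n}}; at `n = 1/f` this is
#' \eqn{e^{-1} \approx 0.37}, the defining property of the reciprocal
#' frequency.
#'
#' @param f per-cell frequency (> 0).
#' @param n cells per well (> 0).
#' @return failure rate in (0, 1).
#' @examples
#' predictedFailureRate(1 / 57, 57)  # 0.3679
#' @export
predictedFailureRate <- function(f, n) {
  stopifnot(all(f > 0), all(n > 0))
  exp(-f * n)
}
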