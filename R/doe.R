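#' Specify a cytokine factor
#'
#' One row of factor metadata: the concentrations mapped to coded -1 and
#' +1. Concentrations must be strictly positive because coded levels map
#' to concentration on a log scale.
#'
#' @param name factor (cytokine) name, e.g. `"IL7"`.
#' @param low concentration at coded -1 (> 0).
#' @param high concentration at coded +1 (> low).
#' @param units unit string, default `"ng/ml"`.
#' @return a one-row `data.frame`; rows from several calls can be bound
#'   with `rbind()` and passed to [makeCCD()].
#' @examples
#' rbind(factorSpec("IL7", 0.005, 0.02, "ug/ml"),
#'       factorSpec("SCF", 5, 50))
#' @export
factorSpec <- function(name, low, high, units = "ng/ml") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low) {
    stop("factorSpec: need 0 < low < high for factor '", name, "'")
  }
  data.frame(name = name, low = low, high = high, units = units,
             stringsAsFactors = FALSE)
}

# Two-level factorial core in standard (Yates) order: first factor varies
# fastest. For k >= 5 the half fraction with the last factor generated as
# the product of the others is used (for six factors this is the
# resolution-VI fraction I = ABCDEF, so all main effects, quadratics and
# two-factor interactions are estimable).
factorialCore <- function(k) {
  if (k <= 4L) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  } else {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), k - 1L)))
    m <- cbind(m, apply(m, 1L, prod))
  }
  dimnames(m) <- NULL
  m
}

#' Construct an orthogonal central composite design
#'
#' Builds the coded run matrix of a central composite design: a two-level
#' factorial core at \eqn{\pm 1} (the half fraction I = ABCDEF for six
#' factors), two axial runs per factor at \eqn{\pm\alpha}, and `nCenter`
#' replicated center runs. With \eqn{\alpha \notin \{0, 1\}} each factor
#' column takes exactly five distinct levels
#' \eqn{\{-\alpha, -1, 0, +1, +\alpha\}}. Run order is deterministic:
#' factorial core in standard order, then axial runs by factor (low then
#' high), then center runs; set `shuffle = TRUE` for a seeded permutation.
#'
#' @param factors `data.frame` of factor specs (see [factorSpec()]).
#' @param alpha axial distance; default 2.366, the value that keeps the
#'   six-factor design orthogonal.
#' @param nCenter number of center replicates (>= 1), default 8.
#' @param shuffle permute run order? Default `FALSE`.
#' @param seed RNG seed for the shuffle (only used when `shuffle = TRUE`).
#' @return a [CCDesign-class] object.
#' @examples
#' fx <- do.call(rbind, lapply(paste0("F", 1:6),
#'                             function(n) factorSpec(n, 1, 10)))
#' d <- makeCCD(fx)
#' nrow(codedMatrix(d))  # 32 + 12 + 8 = 52
#' @export
makeCCD <- function(factors, alpha = 2.366, nCenter = 8L,
                    shuffle = FALSE, seed = 1L) {
  k <- nrow(factors)
  if (is.null(k) || k < 2L || k > 8L) {
    stop("makeCCD supports 2 to 8 factors, got ", k)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  nCenter <- as.integer(nCenter)
  if (nCenter < 1L) stop("nCenter must be >= 1")

  fac <- factorialCore(k)
  ax <- matrix(0, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    ax[2L * j - 1L, j] <- -alpha
    ax[2L * j, j] <- alpha
  }
  ce <- matrix(0, nrow = nCenter, ncol = k)
  coded <- rbind(fac, ax, ce)
  colnames(coded) <- factors$name
  pt <- c(rep("factorial", nrow(fac)), rep("axial", nrow(ax)),
          rep("center", nCenter))
  if (shuffle) {
    ord <- withSeed(seed, sample.int(nrow(coded)))
    coded <- coded[ord, , drop = FALSE]
    pt <- pt[ord]
  }
  rownames(coded) <- sprintf("run%02d", seq_len(nrow(coded)))
  if (!"units" %in% names(factors)) factors$units <- "ng/ml"
  new("CCDesign", factors = factors, coded = coded, pointType = pt,
      alpha = alpha, nCenter = nCenter)
}

#' Map a coded level to a concentration
#'
#' Coded levels map to concentrations logarithmically:
#' \deqn{c(x) = 10^{\log_{10}\sqrt{c_\mathrm{low} c_\mathrm{high}} +
#'   x \cdot \log_{10}(c_\mathrm{high}/c_\mathrm{low})/2}}
#' so that coded -1 and +1 hit the stated low and high concentrations,
#' coded 0 is their geometric mean, and any real coded level (including
#' the axial \eqn{\pm\alpha}) maps to a positive concentration.
#'
#' @param factor a one-row factor spec (see [factorSpec()]).
#' @param x coded level(s), any real.
#' @return concentration(s) in the factor's units.
#' @examples
#' f <- factorSpec("IL7", 0.005, 0.02, "ug/ml")
#' codedToConc(f, c(-1, 0, 1))  # 0.005, 0.01, 0.02
#' @export
codedToConc <- function(factor, x) {
  mid <- log10(sqrt(factor$low * factor$high))
  half <- log10(factor$high / factor$low) / 2
  10^(mid + x * half)
}

#' Map a concentration back to its coded level
#'
#' Exact inverse of [codedToConc()]; defined for any positive
#' concentration.
#'
#' @param factor a one-row factor spec.
#' @param conc concentration(s), > 0.
#' @return coded level(s).
#' @export
concToCoded <- function(factor, conc) {
  if (any(conc <= 0)) stop("concentration must be > 0")
  mid <- log10(sqrt(factor$low * factor$high))
  half <- log10(factor$high / factor$low) / 2
  (log10(conc) - mid) / half
}

#' Concentration matrix of a design
#'
#' Applies [codedToConc()] column-wise to the coded matrix.
#'
#' @param design a [CCDesign-class].
#' @return numeric matrix, runs x factors, of concentrations.
#' @export
concMatrix <- function(design) {
  cm <- codedMatrix(design)
  fx <- designFactors(design)
  out <- vapply(seq_len(ncol(cm)), function(j) {
    codedToConc(fx[j, , drop = FALSE], cm[, j])
  }, numeric(nrow(cm)))
  dimnames(out) <- dimnames(cm)
  out
}
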