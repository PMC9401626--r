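# CSV / Matrix Market / YAML / JSON readers and writers. Numeric fields
# are serialized with 17 significant digits so write-then-read round
# trips are lossless at double precision.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a design to CSV
#'
#' Columns: `run_id`, `point_type`, one coded column (`coded_<factor>`)
#' and one concentration column (`conc_<factor>`) per factor. Factor
#' metadata (name, low, high, units) plus `alpha`/`nCenter` are written
#' to a companion `<path>.factors.yaml` so the design can be
#' reconstructed exactly.
#'
#' @param design a [CCDesign-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDesignCsv <- function(design, path) {
  cm <- codedMatrix(design)
  cc <- concMatrix(design)
  df <- data.frame(run_id = rownames(cm), point_type = pointType(design),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(cm))) {
    df[[paste0("coded_", colnames(cm)[j])]] <- fmtNum(cm[, j])
    df[[paste0("conc_", colnames(cm)[j])]] <- fmtNum(cc[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  fx <- designFactors(design)
  yaml::write_yaml(
    list(alpha = designAlpha(design), nCenter = design@nCenter,
         factors = lapply(seq_len(nrow(fx)), function(i) {
           list(name = fx$name[i], low = fx$low[i], high = fx$high[i],
                units = fx$units[i])
         })),
    paste0(path, ".factors.yaml"))
  invisible(path)
}

#' Read a design from CSV
#'
#' Reads a CSV written by [writeDesignCsv()]. If the companion
#' `.factors.yaml` is absent, factor ranges are reconstructed from the
#' concentrations printed at coded -1/+1 (15+ significant digits).
#'
#' @param path CSV path.
#' @return a [CCDesign-class].
#' @export
readDesignCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "point_type")
  if (!all(need %in% names(df))) {
    stop("design CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  codedCols <- grep("^coded_", names(df), value = TRUE)
  if (!length(codedCols)) stop("design CSV '", path, "': no coded_ columns")
  fnames <- sub("^coded_", "", codedCols)
  cm <- as.matrix(df[codedCols])
  colnames(cm) <- fnames
  rownames(cm) <- df$run_id
  side <- paste0(path, ".factors.yaml")
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    fx <- do.call(rbind, lapply(y$factors, function(f) {
      factorSpec(f$name, f$low, f$high, f$units)
    }))
    alpha <- y$alpha
    nCenter <- as.integer(y$nCenter)
  } else {
    fx <- do.call(rbind, lapply(seq_along(fnames), function(j) {
      conc <- df[[paste0("conc_", fnames[j])]]
      lo <- conc[match(-1, cm[, j])]
      hi <- conc[match(1, cm[, j])]
      if (is.na(lo) || is.na(hi)) {
        stop("design CSV '", path, "': cannot recover range for factor '",
             fnames[j], "' (no +/-1 runs)")
      }
      factorSpec(fnames[j], lo, hi)
    }))
    alpha <- max(abs(cm))
    nCenter <- sum(df$point_type == "center")
  }
  new("CCDesign", factors = fx, coded = cm, pointType = df$point_type,
      alpha = alpha, nCenter = nCenter)
}

#' Write / read a response table
#'
#' Columns `run_id`, `response`, `count` (nonnegative integers).
#'
#' @param table response `data.frame`.
#' @param path CSV path.
#' @return `path` / the validated `data.frame`.
#' @export
writeResponseTable <- function(table, path) {
  utils::write.csv(table[c("run_id", "response", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeResponseTable
#' @export
readResponseTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "response", "count")
  if (!all(need %in% names(df))) {
    stop("response CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$count < 0)) {
    stop("response CSV '", path, "': negative count at row(s) ",
         paste(which(df$count < 0), collapse = ", "))
  }
  df
}

#' Write models to a coefficient CSV
#'
#' Long-format table mirroring published regression-coefficient tables:
#' columns `response`, `transform`, `term`, `coefficient`, one row per
#' term, with term labels like `"IL7"`, `"IL7^2"`, `"IL7*TNFa"`.
#' Published coefficient tables in this shape can drive the optimizer
#' without any raw data.
#'
#' @param models list of [ResponseModel-class] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeCoefCsv <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(response = responseName(m),
               transform = responseTransform(m),
               term = vapply(modelTerms(m), termLabel, character(1)),
               coefficient = fmtNum(m@coefficients),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read models from a coefficient CSV
#'
#' @param path CSV path (see [writeCoefCsv()] for the schema).
#' @param factorNames the design factor names the term labels refer to.
#' @return named list of [ResponseModel-class] objects (no fit stats).
#' @export
readCoefCsv <- function(path, factorNames) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("response", "term", "coefficient")
  if (!all(need %in% names(df))) {
    stop("coefficient CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!"transform" %in% names(df)) df$transform <- "log1p"
  models <- lapply(split(df, df$response), function(d) {
    terms <- lapply(d$term, parseTermLabel, factorNames = factorNames)
    new("ResponseModel", responseName = d$response[1],
        transform = d$transform[1], terms = terms,
        coefficients = as.numeric(d$coefficient),
        factorNames = factorNames, fitStats = list())
  })
  models[order(names(models))]
}

#' Write / read limiting-dilution well data
#'
#' CSV with mandatory header `dose,tested,negative`; validation errors
#' name the file and offending field.
#'
#' @param data LDA `data.frame`.
#' @param path CSV path.
#' @return `path` / the validated `data.frame`.
#' @export
writeLDACsv <- function(data, path) {
  utils::write.csv(ldaDataset(data)[c("dose", "tested", "negative")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLDACsv
#' @export
readLDACsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "tested", "negative")
  if (!all(need %in% names(df))) {
    stop("LDA CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(df$negative < 0 | df$negative > df$tested)
  if (length(bad)) {
    stop("LDA CSV '", path, "': negative wells outside 0..tested at row(s) ",
         paste(bad, collapse = ", "))
  }
  ldaDataset(df)
}

#' Write a frequency estimate to JSON
#' @param est a [FrequencyEstimate-class].
#' @param path JSON path.
#' @export
writeFrequencyJson <- function(est, path) {
  jsonlite::write_json(
    list(f = est@f, reciprocal = est@reciprocal,
         ci95_reciprocal = est@ci95, loglik = est@loglik,
         converged = est@converged, flag = est@flag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a single-cell count matrix in Matrix Market form
#'
#' Writes `matrix.mtx` (1-based indices per the MTX standard),
#' `genes.tsv`, `barcodes.tsv` and `conditions.csv` (cell, condition)
#' into `dir`, plus `provenance.json` when truth parameters are given.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if needed).
#' @param provenance optional list (e.g. the [expressionTruth()] spec
#'   and seed) echoed to `provenance.json`.
#' @return `dir` / the reconstructed `SingleCellExperiment`.
#' @export
writeCounts10x <- function(sce, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(
    data.frame(cell = colnames(counts),
               condition = SummarizedExperiment::colData(sce)$condition),
    file.path(dir, "conditions.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' @rdname writeCounts10x
#' @export
readCounts10x <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  cond <- utils::read.csv(file.path(dir, "conditions.csv"),
                          stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- cells
  makeCountMatrix(counts, condition = cond$condition[match(cells, cond$cell)])
}

#' Write per-cell signature scores to CSV
#' @param result a [SignatureScoreResult-class].
#' @param path CSV path.
#' @export
writeScoresCsv <- function(result, path) {
  utils::write.csv(
    data.frame(cell = names(result@scores),
               condition = as.character(result@condition),
               score = fmtNum(result@scores)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
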