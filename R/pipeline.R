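# End-to-end pipeline: design -> (synthetic) response measurement ->
# least-squares fitting (+ optional third-order selection) ->
# desirability optimization, per differentiation stage.

#' Read a pipeline configuration
#'
#' YAML (or JSON) with top-level `seed`, `outDir`, and `stages`: each
#' stage has `name`, `factors` (list of name/low/high/units), optional
#' `alpha` (default 2.366) and `nCenter` (default 8), either `simulate`
#' (list of truth surfaces: response/transform/noiseSd/coefficients) or
#' `responseCsv`, a `responses` list (name, transform, optional
#' desirability L/U/w), optional `thirdOrderCandidates` (term labels)
#' and optional `optimization` overrides (radius/nRestarts/topK).
#'
#' @param path YAML or JSON file.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    stop("config: no stages defined")
  }
  for (st in cfg$stages) {
    nm <- st$name
    if (is.null(nm)) stop("config: every stage needs a name")
    if (is.null(st$factors) || length(st$factors) < 2L) {
      stop("config: stage '", nm, "' needs at least two factors")
    }
    if (is.null(st$responses) || !length(st$responses)) {
      stop("config: stage '", nm, "' has no responses")
    }
    for (r in st$responses) {
      if (is.null(r$name)) {
        stop("config: stage '", nm, "' has a response without a name")
      }
      if (is.null(r$desirability)) {
        stop("config: stage '", nm, "' response '", r$name,
             "' has no desirability spec")
      }
    }
    if (is.null(st$simulate) && is.null(st$responseCsv)) {
      stop("config: stage '", nm, "' needs 'simulate' truths or a responseCsv")
    }
    if (!is.null(st$responseCsv) && !file.exists(st$responseCsv)) {
      stop("config: stage '", nm, "' responseCsv not found: ", st$responseCsv)
    }
    if (!is.null(st$simulate)) {
      simNames <- vapply(st$simulate, `[[`, character(1), "response")
      respNames <- vapply(st$responses, `[[`, character(1), "name")
      miss <- setdiff(respNames, simNames)
      if (length(miss)) {
        stop("config: stage '", nm, "' simulate lacks truth for: ",
             paste(miss, collapse = ", "))
      }
    }
  }
  invisible(cfg)
}

stageFactors <- function(st) {
  do.call(rbind, lapply(st$factors, function(f) {
    factorSpec(f$name, f$low, f$high,
               if (is.null(f$units)) "ng/ml" else f$units)
  }))
}

runStage <- function(st, seed, stageDir, logLines) {
  dir.create(stageDir, showWarnings = FALSE, recursive = TRUE)
  fx <- stageFactors(st)
  alpha <- if (is.null(st$alpha)) 2.366 else st$alpha
  nCenter <- if (is.null(st$nCenter)) 8L else as.integer(st$nCenter)
  design <- makeCCD(fx, alpha = alpha, nCenter = nCenter)
  writeDesignCsv(design, file.path(stageDir, "design.csv"))

  if (!is.null(st$simulate)) {
    truths <- lapply(st$simulate, function(tr) {
      responseSurfaceTruth(tr$response, unlist(tr$coefficients),
                           transform = tr$transform,
                           noiseSd = if (is.null(tr$noiseSd)) 0 else tr$noiseSd)
    })
    table <- genDoseResponse(truths, design, seed = seed)
    logLines(sprintf("stage %s: simulated responses with seed %d",
                     st$name, seed))
  } else {
    table <- readResponseTable(st$responseCsv)
  }
  writeResponseTable(table, file.path(stageDir, "responses.csv"))

  models <- list(); specRows <- list()
  for (r in st$responses) {
    transform <- if (is.null(r$transform)) "log1p" else r$transform
    terms <- buildTerms(factorNames(design))
    if (!is.null(st$thirdOrderCandidates)) {
      terms <- selectThirdOrder(design, table, r$name, transform,
                                baseTerms = terms,
                                candidates = as.list(st$thirdOrderCandidates))
    }
    m <- fitResponse(design, table, r$name, transform, terms)
    models[[r$name]] <- m
    ds <- r$desirability
    specRows[[r$name]] <- desirabilitySpec(
      r$name,
      L = if (is.null(ds$L)) NA_real_ else ds$L,
      U = if (is.null(ds$U)) NA_real_ else ds$U,
      w = if (is.null(ds$w)) 1 else ds$w)
    logLines(sprintf("stage %s: fit '%s' (%s), adj R^2 = %.4f", st$name,
                     r$name, transform, fitStats(m)$adj.r.squared))
  }
  writeCoefCsv(models, file.path(stageDir, "coefficients.csv"))

  oc <- st$optimization
  config <- optimizationConfig(
    radius = if (is.null(oc$radius)) alpha else oc$radius,
    nRestarts = if (is.null(oc$nRestarts)) 25L else oc$nRestarts,
    topK = if (is.null(oc$topK)) 5L else oc$topK,
    seed = seed + 1L)
  opt <- optimizeDesirability(models, do.call(rbind, specRows), design,
                              config)
  jsonlite::write_json(
    list(solutions = solutions(opt),
         averaged_optimum_coded = as.list(optimumCoded(opt)),
         averaged_optimum_conc = as.list(optimumConc(opt)),
         predicted_at_optimum = as.list(opt@predictedAtOptimum),
         radius = opt@radius, topK = opt@topK, seed = opt@seed,
         degenerate = opt@degenerate),
    file.path(stageDir, "optimization.json"),
    auto_unbox = TRUE, digits = NA)
  logLines(sprintf("stage %s: best D = %.6f", st$name,
                   solutions(opt)$D[1]))
  list(design = design, table = table, models = models, optimum = opt)
}

#' Run the full optimization pipeline
#'
#' Executes, for each configured differentiation stage: design
#' generation, (optionally synthetic) response generation, polynomial
#' fitting with optional third-order term selection, and desirability
#' optimization. Writes per-stage `design.csv`, `responses.csv`,
#' `coefficients.csv` and `optimization.json`, a combined
#' `optima_table.csv` of per-stage optimal cytokine concentrations, and
#' `run_log.txt` carrying the config hash and every seed used. Running
#' twice with the same config and seed reproduces all outputs exactly.
#'
#' @param config config list or path to a YAML/JSON config (see
#'   [readPipelineConfig()]).
#' @param outDir output directory (overrides `config$outDir`).
#' @return named list of per-stage results (design, table, models,
#'   optimum), invisibly.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  outDir <- if (!is.null(outDir)) outDir else config$outDir
  if (is.null(outDir)) stop("config: outDir is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hash <- fnv1a64(canonicalJson(config))
  log <- c(sprintf("config_hash: %s", hash), sprintf("seed: %d", seed))
  logLines <- function(x) log <<- c(log, x)

  results <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    results[[st$name]] <- runStage(st, seed + 10L * i,
                                   file.path(outDir, st$name), logLines)
  }

  optima <- do.call(rbind, lapply(names(results), function(nm) {
    opt <- results[[nm]]$optimum
    fx <- designFactors(results[[nm]]$design)
    data.frame(stage = nm, factor = names(optimumConc(opt)),
               coded = fmtNum(optimumCoded(opt)),
               concentration = fmtNum(optimumConc(opt)),
               units = fx$units[match(names(optimumConc(opt)), fx$name)],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(optima, file.path(outDir, "optima_table.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(results)
}
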