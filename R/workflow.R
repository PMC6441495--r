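#' Read a workflow configuration
#'
#' YAML with blocks: `synthetic` (times, nReps, cv, seed, truthVariant),
#' `fit` (nStarts, seed, sigmaFloor, maxit, freeNames), `search` (nStarts,
#' candidates limit), `selection` (threshold), `output` (dir). Every field
#' has a default; [runStressWorkflow()] also accepts the equivalent plain
#' list.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

# polynomial rolling hash over the serialized configuration: a stable
# fingerprint stamped on every artifact so a report can be traced to its
# exact configuration
configHash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.cfgDefaults <- function(config) {
  def <- list(
    synthetic = list(truthVariant = "III", times = defaultTimes(),
                     nReps = 4, cv = 0.15, seed = 1, companions = TRUE),
    fit = list(nStarts = 10, seed = 1, sigmaFloor = 0.05, maxit = 150,
               freeNames = NULL),
    search = list(nStarts = NULL, candidates = NULL),
    selection = list(threshold = 0.05),
    output = list(dir = NULL))
  for (blk in names(def)) {
    if (is.null(config[[blk]])) config[[blk]] <- list()
    for (f in names(def[[blk]]))
      if (is.null(config[[blk]][[f]])) config[[blk]][[f]] <- def[[blk]][[f]]
  }
  config
}

#' Run the model-building workflow
#'
#' Executes the study's model progression end to end on a synthetic study:
#' generate data from the configured ground-truth variant; fit the
#' stress-input-free model I (expected poor); fit model II (stress on PI3K);
#' run the systematic second-input search; gate the best candidate with the
#' 5 percent AIC improvement rule; fit the two-input models III/IV and the
#' three-input model V; and compare information criteria. Every stage
#' failure is recorded and downstream stages are skipped. All seeds are
#' logged; identical configurations give identical reports.
#'
#' @param config Configuration list (see [readRunConfig()]).
#' @return A `mtorWorkflowReport` list: config, config hash, per-variant fit
#'   table, search table, selection decisions, stage log.
#' @export
runStressWorkflow <- function(config = list()) {
  config <- .cfgDefaults(config)
  stages <- list()
  report <- list(config = config, hash = configHash(config))
  failed <- FALSE
  run_stage <- function(name, expr) {
    if (failed) {
      stages[[name]] <<- "skipped"
      return(NULL)
    }
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      stages[[name]] <<- paste("failed:", conditionMessage(out))
      failed <<- TRUE
      NULL
    } else {
      stages[[name]] <<- "ok"
      out
    }
  }
  syn <- config$synthetic
  truth_model <- run_stage("build_truth_model",
                           buildModel(syn$truthVariant))
  data <- run_stage("generate_data", {
    syntheticStudy(truth_model, groundTruthParams(syn$truthVariant),
                   times = syn$times, nReps = syn$nReps, cv = syn$cv,
                   seed = syn$seed, companions = syn$companions)
  })
  fitcfg <- config$fit
  n_data <- if (!is.null(data)) nrow(tcData(data)) else NA_integer_
  # desk scale (freeNames restricted): anchor the non-fitted parameters at
  # the generating values so variant comparisons probe topology, not the
  # unfitted remainder
  anchor <- function(m) {
    if (is.null(fitcfg$freeNames)) return(m)
    truth <- groundTruthParams(syn$truthVariant)
    keep <- intersect(names(truth), m@parameters$name)
    setParameterValues(m, truth[keep])
  }
  fit_variant <- function(m) {
    m <- anchor(m)
    free <- fitcfg$freeNames
    if (is.null(free)) free <- freeParameterNames(m)
    free <- intersect(free, m@parameters$name)
    prob <- fitProblem(m, data, freeNames = free,
                       sigmaFloor = fitcfg$sigmaFloor)
    fit <- fitMultistart(prob, nStarts = fitcfg$nStarts, seed = fitcfg$seed,
                         maxit = fitcfg$maxit)
    best <- bestFit(fit)
    ic <- informationCriteria(best$chi2, length(free), n_data)
    list(variant = modelVariant(m), chi2 = best$chi2, k = length(free),
         AIC = ic$AIC, AICc = ic$AICc, BIC = ic$BIC, fit = fit)
  }
  fits <- list()
  for (v in c("I", "II")) {
    fits[[v]] <- run_stage(paste0("fit_", v), fit_variant(buildModel(v)))
  }
  search <- run_stage("input_search", {
    scfg <- config$search
    base <- anchor(buildModel("II"))
    free <- fitcfg$freeNames
    if (is.null(free)) free <- freeParameterNames(base)
    free <- intersect(free, base@parameters$name)
    nst <- if (is.null(scfg$nStarts)) fitcfg$nStarts else scfg$nStarts
    secondInputSearch(base, data, nStarts = nst, seed = fitcfg$seed,
                      freeNames = free, candidates = scfg$candidates,
                      maxit = fitcfg$maxit)
  })
  decision <- run_stage("improvement_gate", {
    stopifnot(!is.null(search), !is.null(fits$II))
    list(best_candidate = search[1, c("substrate", "product")],
         aic_II = fits$II$AIC, aic_candidate = search$AIC[1],
         accepted = isImprovement(fits$II$AIC, search$AIC[1],
                                  config$selection$threshold))
  })
  for (v in c("III", "IV", "V")) {
    fits[[v]] <- run_stage(paste0("fit_", v), fit_variant(buildModel(v)))
  }
  third_input <- run_stage("third_input_gate", {
    stopifnot(!is.null(fits$III), !is.null(fits$V))
    list(aic_III = fits$III$AIC, aic_V = fits$V$AIC,
         lower = fits$V$AIC < fits$III$AIC,
         accepted = isImprovement(fits$III$AIC, fits$V$AIC,
                                  config$selection$threshold))
  })
  tab <- do.call(rbind, lapply(fits[!vapply(fits, is.null, logical(1))],
                               function(f)
    data.frame(variant = f$variant, chi2 = f$chi2, k = f$k, AIC = f$AIC,
               AICc = f$AICc, BIC = f$BIC, stringsAsFactors = FALSE)))
  if (!is.null(tab)) rownames(tab) <- NULL
  report$models <- tab
  report$search <- search
  report$second_input <- decision
  report$third_input <- third_input
  report$stages <- stages
  report$seeds <- list(synthetic = syn$seed, fit = fitcfg$seed)
  class(report) <- "mtorWorkflowReport"
  if (!is.null(config$output$dir)) {
    dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
    writeWorkflowReport(report,
                        file.path(config$output$dir, "run_report.txt"))
    if (!is.null(search))
      writeSearchTable(search,
                       file.path(config$output$dir, "search_table.csv"))
  }
  report
}

#' @export
print.mtorWorkflowReport <- function(x, ...) {
  cat(sprintf("Stress-mTORC1 workflow report (config %s)\n", x$hash))
  cat("Stages:\n")
  for (s in names(x$stages)) cat(sprintf("  %-18s %s\n", s, x$stages[[s]]))
  if (!is.null(x$models)) {
    cat("Model comparison:\n")
    print(x$models)
  }
  if (!is.null(x$second_input)) {
    d <- x$second_input
    cat(sprintf("Second input: best candidate %s -> %s, AIC %.4g vs %.4g, accepted: %s\n",
                d$best_candidate$substrate, d$best_candidate$product,
                d$aic_candidate, d$aic_II, d$accepted))
  }
  if (!is.null(x$third_input)) {
    d <- x$third_input
    cat(sprintf("Third input (mTORC1): AIC %.4g vs %.4g; lower: %s; above 5%% gate: %s\n",
                d$aic_V, d$aic_III, d$lower, d$accepted))
  }
  invisible(x)
}

#' Write a plain-text workflow report
#' @param report A `mtorWorkflowReport`.
#' @param path Output path.
#' @export
writeWorkflowReport <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, path)
  invisible(path)
}
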