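## Batch pipeline: default-parameter calling -> consensus validation set
## -> grid optimization -> final calling with optimized parameters, with a
## MANIFEST of every artifact. Annotation of the final calls is exposed
## only as a hook (an annotation-ready BED), not performed here.

.RUN_KEYS <- c("target_bed", "coverage_tsv", "sample_sheet",
               "external_calls", "batch_mode", "nocall_policy",
               "roi_filter", "sample_filter", "correlation_filter",
               "grid_correlation", "grid_coverage", "grid_transition",
               "objective", "output_dir", "seed", "log_level")

#' Build or read a pipeline run configuration
#'
#' A configuration is a named list; it can be read from a plain-text
#' \code{key: value} file. Recognized keys: \code{target_bed},
#' \code{coverage_tsv}, \code{sample_sheet}, \code{external_calls}
#' (comma-separated call BED paths), \code{batch_mode}
#' (default/batch2/single), \code{nocall_policy} (as_normal/excluded),
#' \code{roi_filter}, \code{sample_filter}, \code{correlation_filter}
#' (true/false), \code{grid_correlation}, \code{grid_coverage},
#' \code{grid_transition} (comma-separated values; all three or none),
#' \code{objective}, \code{output_dir}, \code{seed}, \code{log_level}.
#' Unknown keys are rejected; referenced input paths must exist.
#'
#' @param x path to a config file, or a named list of settings.
#' @param ... individual settings overriding those in \code{x}.
#' @return validated config list.
#' @export
runConfig <- function(x = list(), ...) {
  cfg <- if (is.character(x)) .parseConfigFile(x) else x
  over <- list(...)
  cfg[names(over)] <- over
  unknown <- setdiff(names(cfg), .RUN_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  need <- c("target_bed", "coverage_tsv", "sample_sheet", "output_dir")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("missing required configuration key(s): ",
         paste(missing, collapse = ", "))
  for (k in c("target_bed", "coverage_tsv", "sample_sheet")) {
    if (!file.exists(cfg[[k]]))
      stop(sprintf("configured %s does not exist: %s", k, cfg[[k]]))
  }
  if (!is.null(cfg$external_calls)) {
    paths <- .asPaths(cfg$external_calls)
    bad <- paths[!file.exists(paths)]
    if (length(bad))
      stop("configured external call set(s) missing: ",
           paste(bad, collapse = ", "))
    cfg$external_calls <- paths
  }
  cfg$batch_mode <- cfg$batch_mode %||% "default"
  cfg$nocall_policy <- cfg$nocall_policy %||% "as_normal"
  cfg$objective <- cfg$objective %||% "sensitivity"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$log_level <- cfg$log_level %||% "info"
  for (k in c("roi_filter", "sample_filter", "correlation_filter"))
    cfg[[k]] <- .asFlag(cfg[[k]] %||% TRUE, k)
  gk <- c("grid_correlation", "grid_coverage", "grid_transition")
  hasG <- gk %in% names(cfg)
  if (any(hasG) && !all(hasG))
    stop("provide all three grid axes or none")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asPaths <- function(x)
  trimws(unlist(strsplit(paste(x, collapse = ","), ",")))

.asFlag <- function(x, key) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  if (v %in% c("true", "yes", "1")) return(TRUE)
  if (v %in% c("false", "no", "0")) return(FALSE)
  stop(sprintf("'%s' must be true or false", key))
}

.asNum <- function(x) as.numeric(.asPaths(x))

.parseConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed config line(s): ",
         paste(utils::head(lines[bad], 3), collapse = "; "))
  stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                  vapply(kv, function(m) m[2L], character(1)))
}

#' Run the full batch pipeline
#'
#' Executes: (1) cohort calling with default parameters; (2) consensus of
#' the internal default calls with any configured external call sets (at
#' least two non-empty sets are required) to build the in silico
#' validation set; (3) grid optimization of the caller parameters against
#' it; (4) a final calling pass with the optimized parameters. Artifacts
#' written to \code{output_dir}: default and final call BEDs (5- and
#' 7-column), validated-call BED, validation-state TSV, the full
#' optimization table, the selected parameters, a benchmark metrics TSV
#' (default vs optimized, scored on the validation set), a no-call TSV, an
#' annotation-ready BED of the final calls, a parameter-complete run log
#' and a \code{MANIFEST} with MD5 checksums. On a stage failure the
#' MANIFEST records the artifacts produced so far and is marked
#' incomplete.
#'
#' @param config a \code{\link{runConfig}} (or path / list coercible to
#'   one).
#' @return invisibly, a list with the final call set, the optimization
#'   result, the validation set and the manifest \code{data.frame}.
#' @export
runBatch <- function(config) {
  cfg <- runConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  logf <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    if (cfg$log_level != "quiet") message(line)
  }
  artifacts <- data.frame(file = character(), role = character())
  addArtifact <- function(path, role)
    artifacts <<- rbind(artifacts,
                        data.frame(file = basename(path), role = role))
  writeManifest <- function(complete) {
    md5 <- tools::md5sum(file.path(cfg$output_dir, artifacts$file))
    df <- data.frame(file = artifacts$file, role = artifacts$role,
                     md5 = unname(md5))
    path <- file.path(cfg$output_dir, "MANIFEST")
    header <- if (complete) "# complete" else
      "# INCOMPLETE: pipeline aborted before finishing"
    writeLines(c(header,
                 sprintf("%s\t%s\t%s", df$file, df$role, df$md5)), path)
    df
  }
  out <- file.path
  set.seed(cfg$seed)
  for (k in .RUN_KEYS)
    logf("config %s = %s", k,
         paste(format(cfg[[k]] %||% "<default>"), collapse = ","))
  stage <- "setup"
  result <- tryCatch({
    stage <- "input"
    rois <- readTargetBed(cfg$target_bed)
    samples <- readSampleSheet(cfg$sample_sheet)
    cov <- readCoverageMatrix(cfg$coverage_tsv, rois, samples)
    logf("loaded %d ROIs, %d samples", length(rois), nrow(samples))

    stage <- "call(default)"
    defPar <- CallerParams()
    logf("default parameters: correlation %g, coverage %g, transition %g",
         defPar@minCorrelation, defPar@minCoverage, defPar@transitionProb)
    defCalls <- suppressWarnings(
      callCohort(cov, defPar, cfg$batch_mode,
                 roiFilter = cfg$roi_filter,
                 sampleFilter = cfg$sample_filter,
                 correlationFilter = cfg$correlation_filter))
    writeCallsBed(defCalls, out(cfg$output_dir, "calls_default.bed"))
    addArtifact("calls_default.bed", "default-parameter calls (5-col BED)")
    logf("default calling: %d calls", length(defCalls))

    stage <- "consensus"
    callsets <- list(defCalls)
    for (p in cfg$external_calls)
      callsets[[length(callsets) + 1L]] <-
        readCallsetBed(p, tools::file_path_sans_ext(basename(p)))
    vs <- buildValidationSet(callsets, samples, rois)
    writeCallsBed(CNVCallSet("validated", validatedCalls(vs)),
                  out(cfg$output_dir, "validated_calls.bed"))
    addArtifact("validated_calls.bed", "in silico validated calls")
    writeValidationStates(vs, out(cfg$output_dir, "validation_states.tsv"))
    addArtifact("validation_states.tsv", "per-(sample,region) truth states")
    logf("consensus: %d validated calls over %d regions",
         length(validatedCalls(vs)), length(validatedRegions(vs)))

    stage <- "optimize"
    grid <- if (!is.null(cfg$grid_correlation))
      ParameterGrid(.asNum(cfg$grid_correlation),
                    .asNum(cfg$grid_coverage),
                    .asNum(cfg$grid_transition))
    else defaultGrid()
    opt <- optimizeParams(cov, vs, grid, cfg$objective,
                          mode = cfg$batch_mode,
                          nocallPolicy = cfg$nocall_policy)
    utils::write.table(optimizationTable(opt),
                       out(cfg$output_dir, "optimization_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    addArtifact("optimization_table.tsv", "per-combination grid results")
    best <- bestParams(opt)
    writeLines(sprintf("%s: %g",
                       c("min_correlation", "min_coverage",
                         "transition_prob"),
                       c(best@minCorrelation, best@minCoverage,
                         best@transitionProb)),
               out(cfg$output_dir, "best_params.txt"))
    addArtifact("best_params.txt", "optimized caller parameters")
    logf("optimized parameters: correlation %g, coverage %g, transition %g",
         best@minCorrelation, best@minCoverage, best@transitionProb)

    stage <- "call(optimized)"
    finalCalls <- suppressWarnings(
      callCohort(cov, best, cfg$batch_mode,
                 roiFilter = cfg$roi_filter,
                 sampleFilter = cfg$sample_filter,
                 correlationFilter = cfg$correlation_filter))
    writeFinalBed(finalCalls, out(cfg$output_dir, "calls_final.bed"))
    addArtifact("calls_final.bed", "final annotated calls (7-col BED)")
    writeCallsBed(finalCalls,
                  out(cfg$output_dir, "calls_final_annotation_input.bed"))
    addArtifact("calls_final_annotation_input.bed",
                "annotation hook input (5-col BED)")
    utils::write.table(nocallUnits(finalCalls),
                       out(cfg$output_dir, "nocall_units.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    addArtifact("nocall_units.tsv", "no-call units with reasons")
    logf("final calling: %d calls, %d no-call units",
         length(finalCalls), nrow(nocallUnits(finalCalls)))

    stage <- "benchmark"
    met <- rbind(
      .metricsRow("default", defPar, cov, vs, cfg),
      .metricsRow("optimized", best, cov, vs, cfg))
    utils::write.table(met, out(cfg$output_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    addArtifact("metrics.tsv", "benchmark metrics vs validation set")
    logf("benchmark: default sensitivity %.4f, optimized %.4f",
         met$Sensitivity[1], met$Sensitivity[2])

    writeLines(logLines, out(cfg$output_dir, "run.log"))
    addArtifact("run.log", "run log (parameters and stages)")
    manifest <- writeManifest(complete = TRUE)
    list(finalCalls = finalCalls, optimization = opt, validation = vs,
         manifest = manifest)
  }, error = function(e) {
    writeLines(c(logLines, paste("ERROR in stage", stage, ":",
                                 conditionMessage(e))),
               out(cfg$output_dir, "run.log"))
    addArtifact("run.log", "run log (parameters and stages)")
    writeManifest(complete = FALSE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

.metricsRow <- function(label, params, cov, vs, cfg) {
  ev <- evaluateParams(params, cov, vs, mode = cfg$batch_mode,
                       nocallPolicy = cfg$nocall_policy)
  data.frame(Method = label, TP = ev$counts$tp, TN = ev$counts$tn,
             FP = ev$counts$fp, FN = ev$counts$fn,
             Total = ev$counts$total,
             Sensitivity = ev$metrics$sensitivity,
             Specificity = ev$metrics$specificity,
             PPV = ev$metrics$ppv, NPV = ev$metrics$npv,
             Fscore = ev$metrics$f_score)
}

#' Write the artifacts of a simulated cohort to disk
#'
#' Convenience used by the command-line front-end: writes the target BED,
#' coverage TSV, sample sheet, truth call BED and optionally k surrogate
#' call BEDs for a simulated cohort.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory.
#' @param nSurrogates number of surrogate caller outputs to emit.
#' @param profile base \code{\link{callerErrorProfile}}; surrogate i uses
#'   \code{seed + i}.
#' @return invisibly, the directory.
#' @export
writeCohort <- function(sim, dir, nSurrogates = 0L,
                        profile = callerErrorProfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rois <- sim$rois
  writeLines(sprintf("%s\t%d\t%d\t%s", as.character(seqnames(rois)),
                     start(rois) - 1L, end(rois), mcols(rois)$name),
             file.path(dir, "target.bed"))
  cnt <- counts(sim$coverage)
  df <- data.frame(roi = rownames(cnt), cnt, check.names = FALSE)
  utils::write.table(df, file.path(dir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  writeCallsBed(sim$truth, file.path(dir, "truth.bed"))
  for (i in seq_len(nSurrogates)) {
    pr <- callerErrorProfile(profile$fnRate, profile$fpRate,
                             profile$boundaryJitter,
                             seed = profile$seed + i)
    cs <- perturbCalls(sim$truth, pr, rois, sim$samples,
                       callerName = sprintf("surrogate%d", i))
    writeCallsBed(cs, file.path(dir, sprintf("surrogate%d.bed", i)))
  }
  invisible(dir)
}
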