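## light-weight structured logging to stderr
.logStage <- function(stage, ...) {
  kv <- c(...)
  msg <- paste0("stage=", stage,
                if (length(kv)) paste0(" ", paste(names(kv), kv,
                                                  sep = "=",
                                                  collapse = " ")))
  message(msg)
}

## hash of the scientific configuration only: input/output paths are
## volatile and excluded, so reruns on the same settings hash identically
.configHash <- function(config) {
  config <- config[setdiff(names(config),
                           c("genotypes", "fitness", "schedules", "out"))]
  config <- config[order(names(config))]
  json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(json) * seq_len(nchar(json))) %%
            .Machine$integer.max)
}

#' Run the full inference pipeline
#'
#' QC -> haplotype construction -> tally -> minor-RWH grouping -> regime
#' pooling -> ensemble reaction-norm inference -> trajectory prediction,
#' with per-stage logging to stderr and all artifacts written into one run
#' directory. Deterministic given the configuration and seed.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'   \item{genotypes}{path to a genotype TSV, or an in-memory data.frame}
#'   \item{fitness}{path to a fitness TSV, or a data.frame}
#'   \item{schedules}{optional path to a schedule TSV; built-in regimes
#'     are used for any regime not covered}
#'   \item{out}{output directory}
#'   \item{form}{"linear" (default) or "quadratic"}
#'   \item{top_k, n_anc_samples, n_secondary, n_starts, horizon, seed,
#'     fitness_weight}{tuning knobs, with the package defaults}
#'   }
#' @return invisibly, a list with the pooled counts, the
#'   [EnsembleFit-class] and the paths of the written artifacts.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  ## n_secondary is intentionally absent: NULL lets fitEnsemble default to
  ## 2 secondary draws per genotyped replicate population
  defaults <- list(form = "linear", top_k = 3L, n_anc_samples = 20L,
                   n_starts = 10L, horizon = 100L,
                   seed = 1L, fitness_weight = 1,
                   epochs = c(0L, 10L, 35L, 50L))
  config <- modifyList(defaults, config)
  if (is.null(config$out)) stop("config$out (output directory) is required")
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  genotypes <- config$genotypes
  if (is.character(genotypes)) {
    .logStage("read", file = genotypes)
    genotypes <- readGenotypeTable(genotypes)
  } else genotypes <- validateGenotypeTable(genotypes)
  fitness <- config$fitness
  if (is.character(fitness)) {
    if (!file.exists(fitness)) stop("fitness file not found: ", fitness)
    fitness <- read.delim(fitness, stringsAsFactors = FALSE)
  }
  .logStage("qc", n_calls = nrow(genotypes))
  qc <- applyQC(genotypes)
  .logStage("qc", dropped_snps = qc$report$n_dropped_snps,
            dropped_individuals = qc$report$n_dropped_individuals)
  writeQcReport(qc$report, file.path(config$out, "qc_report.json"))

  .logStage("haplotypes")
  cwh <- callsToCwh(qc$calls)
  rwh <- cwhToRwh(cwh)
  counts <- tallyRwh(rwh)
  writeRwhCounts(counts, file.path(config$out, "rwh_counts.tsv"))
  .logStage("haplotypes",
            distinct_rwh_product = distinctRwhSummary(counts)$product)
  grouped <- groupMinor(counts, top_k = config$top_k)
  pooled <- poolToRegime(grouped)
  writeRwhCounts(pooled, file.path(config$out, "pooled_counts.tsv"))

  horizon <- max(config$horizon, max(config$epochs))
  ev <- setdiff(unique(pooled$regime), "ancestral")
  schedules <- setNames(lapply(ev, envSchedule, horizon = horizon), ev)
  if (!is.null(config$schedules)) {
    from_file <- readScheduleTable(config$schedules, horizon = horizon)
    schedules[names(from_file)] <- from_file
  }
  n_repl <- length(unique(paste(grouped$regime, grouped$replicate)[
    grouped$regime != "ancestral"]))
  data <- assembleInferenceData(pooled, fitness, schedules,
                                epochs = config$epochs,
                                n_replicates = n_repl)
  .logStage("infer", regimes = paste(ev, collapse = ","),
            n_anc_samples = config$n_anc_samples)
  ensemble <- fitEnsemble(data, form = config$form,
                          n_anc_samples = config$n_anc_samples,
                          n_secondary = config$n_secondary,
                          n_starts = config$n_starts, seed = config$seed,
                          horizon = config$horizon,
                          fitness_weight = config$fitness_weight)
  writeFitJson(ensemble, file.path(config$out, "fit.json"),
               config = c(config[setdiff(names(config),
                                         c("genotypes", "fitness"))],
                          list(config_hash = .configHash(config))))
  .logStage("predict", horizon = config$horizon)
  traj_path <- file.path(config$out, "trajectories.tsv")
  first <- TRUE
  for (cc in names(data$regimes)) {
    for (j in seq_along(ensembleDraws(ensemble))) {
      d <- ensembleDraws(ensemble)[[j]]
      traj <- predictTrajectories(d$ancestral, data$regimes[[cc]]$schedule,
                                  config$horizon, fitNorms(d$fit))
      writeTrajectoryTable(traj, cc, traj_path, sample_index = j,
                           append = !first)
      first <- FALSE
    }
  }
  makeReport(ensemble, data, file.path(config$out, "report.txt"))
  writeJson(list(package_version =
                   as.character(packageVersion("normsel")),
                 seed = config$seed,
                 config_hash = .configHash(config),
                 config = config[setdiff(names(config),
                                         c("genotypes", "fitness"))]),
            file.path(config$out, "run_info.json"))
  .logStage("done", out = config$out)
  invisible(list(pooled = pooled, ensemble = ensemble, data = data,
                 out = config$out))
}

#' Human-readable summary of an ensemble fit
#'
#' Tabulates, per regime, the lineages reaching the highest median
#' predicted frequencies, their trajectory quantiles at the genotyped
#' epochs, and the median crossing point of the two leading lineages'
#' fitted reaction norms. No quantity is recomputed: everything derives
#' from the ensemble object.
#'
#' @param ensemble an [EnsembleFit-class].
#' @param data the `"normselData"` the ensemble was fitted to.
#' @param path output text file.
#' @return invisibly, the report lines.
#' @export
makeReport <- function(ensemble, data, path) {
  if (!length(ensembleDraws(ensemble))) stop("empty ensemble")
  lines <- c("normsel ensemble report",
             paste0("draws: ", length(ensembleDraws(ensemble)),
                    "  master seed: ", ensemble@seed), "")
  for (cc in names(ensembleQuantiles(ensemble))) {
    q <- ensembleQuantiles(ensemble)[[cc]]
    med_max <- apply(q[, , "q50", drop = FALSE], 2, max)
    top <- order(med_max, decreasing = TRUE)[seq_len(min(3, length(med_max)))]
    lines <- c(lines, paste0("regime ", cc, ": top lineages by median ",
                             "frequency"))
    for (k in top) {
      key <- dimnames(q)$lineage_key[k]
      at_ep <- vapply(as.character(data$epochs), function(g)
        if (g %in% dimnames(q)$generation)
          q[g, k, "q50"] else NA_real_, 0)
      lines <- c(lines, paste0("  ", key, "  median freq at epochs [",
                               paste(data$epochs, collapse = ","), "]: ",
                               paste(sprintf("%.3f", at_ep),
                                     collapse = " ")))
    }
    ## median crossing of the two leading lineages over draws
    if (length(med_max) >= 2) {
      k1 <- dimnames(q)$lineage_key[top[1]]
      k2 <- dimnames(q)$lineage_key[top[2]]
      cross <- vapply(ensembleDraws(ensemble), function(d) {
        keys <- lineageKeys(d$ancestral@lineages)
        i1 <- match(k1, keys); i2 <- match(k2, keys)
        if (is.na(i1) || is.na(i2)) return(NA_real_)
        xx <- tryCatch(crossingPoints(
          lineageIds(d$ancestral@lineages)[i1],
          lineageIds(d$ancestral@lineages)[i2],
          d$ancestral@lineages, fitNorms(d$fit), c(0, 400)),
          error = function(e) numeric(0))
        if (length(xx)) xx[1] else NA_real_
      }, 0)
      if (any(!is.na(cross)))
        lines <- c(lines, sprintf(
          "  crossing of top-2 lineage norms: median %.1f mM (%d/%d draws)",
          median(cross, na.rm = TRUE), sum(!is.na(cross)), length(cross)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(lines)
}
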