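# CSV schemas are documented in inst/FORMATS.md. All times are seconds with
# a decimal point; every file carries a header row.

readCsvChecked <- function(path, required) {
  stopIfNot(file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  stopIfNot(!length(missing), "missing column(s) ", paste(missing, collapse = ", "),
            " in ", path)
  df
}

badRow <- function(path, df, which, what) {
  # +1 for the header: report the file line number
  stop(sprintf("%s: %s at line %d", path, what, which[1L] + 1L), call. = FALSE)
}

#' Read and write spike timestamp tables
#'
#' Spikes CSV schema: columns \code{unit_id}, \code{time_s} (seconds,
#' nondecreasing within each unit, nonnegative). A header-only file yields
#' an empty list, not an error. Malformed rows are rejected with their line
#' number.
#'
#' @param path CSV file path.
#' @param sessionDur recording duration in seconds, applied to every train.
#' @param spikesList list of [SpikeTrain-class] to write.
#' @return \code{readSpikes}: named list of [SpikeTrain-class];
#'   \code{writeSpikes}: the path, invisibly.
#' @export
readSpikes <- function(path, sessionDur) {
  df <- readCsvChecked(path, c("unit_id", "time_s"))
  if (any(bad <- !is.finite(df$time_s)))
    badRow(path, df, which(bad), "non-numeric time_s")
  if (any(bad <- df$time_s < 0))
    badRow(path, df, which(bad), "negative time_s")
  out <- list()
  for (uid in unique(df$unit_id)) {
    ts <- df$time_s[df$unit_id == uid]
    if (is.unsorted(ts))
      badRow(path, df, which(df$unit_id == uid)[which(diff(ts) < 0)[1L] + 1L],
             sprintf("unsorted timestamps for unit %s", uid))
    out[[as.character(uid)]] <- new("SpikeTrain", unitId = as.character(uid),
                                    timestamps = ts, sessionDur = sessionDur)
  }
  out
}

#' @rdname readSpikes
#' @export
writeSpikes <- function(spikesList, path) {
  if (is(spikesList, "SpikeTrain")) spikesList <- list(spikesList)
  df <- do.call(rbind, lapply(spikesList, function(st)
    if (length(st@timestamps))
      data.frame(unit_id = st@unitId, time_s = st@timestamps)
    else NULL))
  if (is.null(df)) df <- data.frame(unit_id = character(), time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write stimulus/behavior event tables
#'
#' Events CSV schema: columns \code{label}, \code{time_s} (seconds,
#' nonnegative).
#'
#' @param path CSV file path.
#' @param events data.frame with columns \code{label}, \code{time_s}.
#' @return \code{readEvents}: the events data.frame; \code{writeEvents}: the
#'   path, invisibly.
#' @export
readEvents <- function(path) {
  df <- readCsvChecked(path, c("label", "time_s"))
  if (any(bad <- !is.finite(df$time_s)))
    badRow(path, df, which(bad), "non-numeric time_s")
  if (any(bad <- df$time_s < 0))
    badRow(path, df, which(bad), "negative time_s")
  df
}

#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(events[, c("label", "time_s")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write freezing-bout tables
#'
#' Bouts CSV schema: columns \code{start_s}, \code{end_s} (half-open
#' \code{[start, end)} seconds, sorted, disjoint).
#'
#' @param path CSV file path.
#' @param sessionDur session duration, seconds.
#' @param trace a [BehaviorTrace-class] to write.
#' @return \code{readBouts}: a [BehaviorTrace-class]; \code{writeBouts}: the
#'   path, invisibly.
#' @export
readBouts <- function(path, sessionDur) {
  df <- readCsvChecked(path, c("start_s", "end_s"))
  if (any(bad <- !is.finite(df$start_s) | !is.finite(df$end_s)))
    badRow(path, df, which(bad), "non-numeric bout bound")
  if (any(bad <- df$start_s < 0))
    badRow(path, df, which(bad), "negative start_s")
  if (any(bad <- df$end_s <= df$start_s))
    badRow(path, df, which(bad), "end_s <= start_s")
  # tolerate last-digit overshoot of the session end from decimal round-trip
  end <- ifelse(df$end_s > sessionDur & df$end_s - sessionDur < 1e-6,
                sessionDur, df$end_s)
  BehaviorTrace(start = df$start_s, end = end, sessionDur = sessionDur)
}

#' @rdname readBouts
#' @export
writeBouts <- function(trace, path) {
  utils::write.csv(trace@bouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write session timelines
#'
#' A timeline is stored as an events CSV (\code{label}, \code{time_s}) plus
#' a YAML sidecar holding the generating protocol, so a written timeline
#' round-trips to an equal object.
#'
#' @param timeline a [SessionTimeline-class].
#' @param path events CSV path.
#' @param protocolPath YAML sidecar path (default: \code{path} with a
#'   \code{.protocol.yaml} suffix).
#' @return \code{readTimeline}: a [SessionTimeline-class];
#'   \code{writeTimeline}: the path, invisibly.
#' @export
writeTimeline <- function(timeline, path,
                          protocolPath = paste0(path, ".protocol.yaml")) {
  writeEvents(timeline@events, path)
  p <- timeline@protocol
  yaml::write_yaml(list(
    kind = p@kind, baseline_dur = p@baselineDur, cs_dur = p@csDur,
    cs_count = p@csCount, us_flags = as.logical(p@usFlags), us_dur = p@usDur,
    interval_min = p@intervalRange[1L], interval_max = p@intervalRange[2L],
    post_dur = p@postDur, us_amp_mA = p@usAmp_mA, cs_level_dB = p@csLevel_dB,
    total_dur = timeline@totalDur), protocolPath, precision = 15L)
  invisible(path)
}

#' @rdname writeTimeline
#' @export
readTimeline <- function(path, protocolPath = paste0(path, ".protocol.yaml")) {
  ev <- readEvents(path)
  y <- yaml::read_yaml(protocolPath)
  prot <- SessionProtocol(y$kind, baselineDur = y$baseline_dur,
                          csDur = y$cs_dur, csCount = y$cs_count,
                          usFlags = as.logical(unlist(y$us_flags)),
                          usDur = y$us_dur,
                          intervalRange = c(y$interval_min, y$interval_max),
                          postDur = y$post_dur, usAmp_mA = y$us_amp_mA,
                          csLevel_dB = y$cs_level_dB)
  new("SessionTimeline", protocol = prot, events = ev,
      totalDur = y$total_dur)
}

# ---- pipeline configuration ------------------------------------------------

checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  stopIfNot(!length(unknown), "unknown key(s) in ", where, ": ",
            paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline configuration
#'
#' The config is a YAML file with top-level keys \code{seed},
#' \code{protocol}, \code{classifier}, \code{simulation} and
#' \code{sampling}; unknown keys anywhere are rejected. See the bundled demo
#' config (\code{system.file("extdata", "demo_config.yaml", package =
#' "perifreeze")}) for the full schema.
#'
#' @param path YAML config path.
#' @return a validated list with elements \code{seed}, \code{protocol}
#'   ([SessionProtocol-class]), \code{classifier}
#'   ([ClassifierParams-class]), \code{design} ([CohortDesign-class]) and
#'   \code{sampleInterval}.
#' @export
readConfig <- function(path) {
  stopIfNot(file.exists(path), "config not found: ", path)
  y <- yaml::read_yaml(path)
  checkKeys(y, c("seed", "protocol", "classifier", "simulation", "sampling"),
            "config")
  stopIfNot(!is.null(y$seed), "config must set a seed")

  prot <- y$protocol %||% list()
  checkKeys(prot, c("kind", "baseline_dur", "cs_dur", "post_dur"), "protocol")
  protocol <- defaultProtocol(prot$kind %||% "RETRIEVAL")
  if (!is.null(prot$baseline_dur)) protocol@baselineDur <- prot$baseline_dur
  if (!is.null(prot$cs_dur)) protocol@csDur <- prot$cs_dur
  if (!is.null(prot$post_dur)) protocol@postDur <- prot$post_dur
  validObject(protocol)

  cl <- y$classifier %||% list()
  checkKeys(cl, c("bin_width", "response_window", "n_baseline_bins",
                  "z_threshold", "min_supra_bins", "sd_denominator"),
            "classifier")
  params <- ClassifierParams(
    binWidth = cl$bin_width %||% 0.1,
    responseWindow = cl$response_window %||% 0.5,
    nBaselineBins = cl$n_baseline_bins %||% 10L,
    zThreshold = cl$z_threshold %||% 1.96,
    minSupraBins = cl$min_supra_bins %||% 2L,
    sdDenominator = cl$sd_denominator %||% "n-1")

  sim <- y$simulation
  stopIfNot(!is.null(sim$groups), "simulation.groups is required")
  checkKeys(sim, c("groups", "behavior"), "simulation")
  gdf <- do.call(rbind, lapply(sim$groups, function(g) {
    checkKeys(g, c("group", "n_units", "rate_mean_hz", "rate_sdlog",
                   "frac_cs_on", "frac_freeze_off", "cs_multiplier",
                   "freeze_multiplier"), "simulation.groups entry")
    data.frame(group = g$group, n_units = g$n_units,
               rate_mean_hz = g$rate_mean_hz %||% 4,
               rate_sdlog = g$rate_sdlog %||% 0.5,
               frac_cs_on = g$frac_cs_on %||% 0,
               frac_freeze_off = g$frac_freeze_off %||% 0,
               cs_multiplier = g$cs_multiplier %||% 1,
               freeze_multiplier = g$freeze_multiplier %||% 1)
  }))
  bh <- sim$behavior %||% list()
  checkKeys(bh, c("move_to_freeze_cs", "freeze_to_move_cs",
                  "move_to_freeze_out", "freeze_to_move_out", "min_bout"),
            "simulation.behavior")
  bp <- BehaviorModelParams(
    moveToFreezeCS = bh$move_to_freeze_cs %||% 0.10,
    freezeToMoveCS = bh$freeze_to_move_cs %||% 0.02,
    moveToFreezeOut = bh$move_to_freeze_out %||% 0.02,
    freezeToMoveOut = bh$freeze_to_move_out %||% 0.10,
    minBout = bh$min_bout %||% 1)

  sa <- y$sampling %||% list()
  checkKeys(sa, "sample_interval", "sampling")

  list(seed = as.integer(y$seed), protocol = protocol, classifier = params,
       design = CohortDesign(gdf, bp, seed = y$seed),
       sampleInterval = sa$sample_interval %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pipeline stages -------------------------------------------------------

stageLog <- function(stage, t0, quiet) {
  if (!quiet)
    message(sprintf("[perifreeze] %-14s %.2fs", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run pipeline stages over an output directory
#'
#' \code{pipelineSimulate} generates the cohort and writes, per group, the
#' timeline (+ protocol sidecar), spikes CSV, per-unit bout CSVs and the
#' ground-truth CSV. \code{pipelineScoreFreezing} writes per-unit per-epoch
#' freezing percentages. \code{pipelineClassify} writes the per-unit
#' classification CSV and z-profile CSV. \code{pipelineCompare} writes the
#' group summary and pairwise exact-test comparison CSVs. \code{runAll}
#' chains all four and writes a run manifest; identical config + seed give
#' byte-identical outputs.
#'
#' @param config validated config list from [readConfig()].
#' @param outDir output directory (created if needed).
#' @param quiet suppress stage-timing messages.
#' @return \code{runAll}: the manifest list, invisibly; stage functions: the
#'   files written, invisibly.
#' @export
pipelineSimulate <- function(config, outDir, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(config$design, protocol = config$protocol)
  files <- character()
  for (grp in names(cohort$groups)) {
    gdir <- file.path(outDir, grp)
    dir.create(file.path(gdir, "behavior"), showWarnings = FALSE,
               recursive = TRUE)
    gd <- cohort$groups[[grp]]
    files <- c(files,
               writeTimeline(gd$timeline, file.path(gdir, "timeline.csv")),
               writeSpikes(gd$spikes, file.path(gdir, "spikes.csv")))
    for (uid in names(gd$behavior))
      files <- c(files, writeBouts(gd$behavior[[uid]],
                                   file.path(gdir, "behavior",
                                             paste0(uid, ".csv"))))
  }
  utils::write.csv(cohort$truth, file.path(outDir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, file.path(outDir, "truth.csv"))
  stageLog("simulate", t0, quiet)
  invisible(files)
}

#' @rdname pipelineSimulate
#' @export
pipelineScoreFreezing <- function(config, outDir, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  truth <- utils::read.csv(file.path(outDir, "truth.csv"))
  rows <- list()
  for (grp in unique(truth$group)) {
    gdir <- file.path(outDir, grp)
    tl <- readTimeline(file.path(gdir, "timeline.csv"))
    for (uid in unique(truth$unit_id[truth$group == grp])) {
      tr <- readBouts(file.path(gdir, "behavior", paste0(uid, ".csv")),
                      sessionDur = tl@totalDur)
      fs <- scoreFreezing(tr, tl, sampleInterval = config$sampleInterval)
      fs <- cbind(unit_id = uid, group = grp, fs)
      rows[[length(rows) + 1L]] <- fs
    }
  }
  out <- file.path(outDir, "freezing.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE, quote = FALSE)
  stageLog("score-freezing", t0, quiet)
  invisible(out)
}

#' @rdname pipelineSimulate
#' @export
pipelineClassify <- function(config, outDir, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  truth <- utils::read.csv(file.path(outDir, "truth.csv"))
  allCalls <- list()
  zrows <- list()
  for (grp in unique(truth$group)) {
    gdir <- file.path(outDir, grp)
    tl <- readTimeline(file.path(gdir, "timeline.csv"))
    spikes <- readSpikes(file.path(gdir, "spikes.csv"),
                         sessionDur = tl@totalDur)
    for (uid in unique(truth$unit_id[truth$group == grp])) {
      tr <- readBouts(file.path(gdir, "behavior", paste0(uid, ".csv")),
                      sessionDur = tl@totalDur)
      fe <- extractFreezeEvents(tr, tl, preWindow = 2)
      st <- spikes[[uid]]
      if (is.null(st))  # silent unit: no rows in spikes.csv
        st <- new("SpikeTrain", unitId = uid, timestamps = numeric(),
                  sessionDur = tl@totalDur)
      calls <- classifyAll(list(st), tl, fe, params = config$classifier)
      allCalls[[length(allCalls) + 1L]] <- calls
      for (lab in c("CS_ON", "FREEZE_ON", "FREEZE_OFF")) {
        times <- switch(lab, CS_ON = eventTimes(tl, "CS_ON"),
                        FREEZE_ON = fe@onsets, FREEZE_OFF = fe@cessations)
        if (!length(times)) next
        prm <- config$classifier
        if (lab != "CS_ON") prm@baselineOffset <- 1
        mat <- alignAndBin(st, times, prm)
        if (nrow(mat@counts) == 0L) next
        prof <- zscoreProfile(mat, prm)
        if (prof@degenerate) next
        nb <- length(prof@z)
        zrows[[length(zrows) + 1L]] <- data.frame(
          unit_id = uid, event_label = lab,
          bin_left_s = prof@binEdges[seq_len(nb)], z = prof@z)
      }
    }
  }
  calls <- do.call(rbind, allCalls)
  outc <- file.path(outDir, "classification.csv")
  utils::write.csv(calls, outc, row.names = FALSE)
  outz <- file.path(outDir, "zprofiles.csv")
  utils::write.csv(do.call(rbind, zrows), outz, row.names = FALSE,
                   quote = FALSE)
  stageLog("classify", t0, quiet)
  invisible(c(outc, outz))
}

#' @rdname pipelineSimulate
#' @export
pipelineCompare <- function(config, outDir, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  calls <- utils::read.csv(file.path(outDir, "classification.csv"))
  truth <- utils::read.csv(file.path(outDir, "truth.csv"))
  gm <- unique(truth[, c("unit_id", "group")])
  res <- summarizeGroups(calls, gm)
  outs <- file.path(outDir, "summary.csv")
  utils::write.csv(res$summary, outs, row.names = FALSE, quote = FALSE)
  files <- outs
  if (!is.null(res$comparisons)) {
    outc <- file.path(outDir, "comparisons.csv")
    utils::write.csv(res$comparisons, outc, row.names = FALSE, quote = FALSE)
    files <- c(files, outc)
  }
  stageLog("compare", t0, quiet)
  invisible(files)
}

#' @rdname pipelineSimulate
#' @param configPath path to the YAML config.
#' @export
runAll <- function(configPath, outDir, quiet = FALSE) {
  config <- readConfig(configPath)
  f1 <- pipelineSimulate(config, outDir, quiet)
  f2 <- pipelineScoreFreezing(config, outDir, quiet)
  f3 <- pipelineClassify(config, outDir, quiet)
  f4 <- pipelineCompare(config, outDir, quiet)
  manifest <- list(
    config_md5 = unname(tools::md5sum(configPath)),
    seed = readConfig(configPath)$seed,
    package_version = as.character(utils::packageVersion("perifreeze")),
    stages = list(simulate = basename(f1), score_freezing = basename(f2),
                  classify = basename(f3), compare = basename(f4)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
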