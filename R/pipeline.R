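## Scriptable pipeline runner: an ordered stage list with per-stage
## parameters, validated up front, executed with provenance logging.

stageRequires <- c(
  simulate = "none", input = "none", quality = "recording",
  od = "recording", motion = "od", filter = "od", ssc = "od",
  mbll = "od", epoch = "series", glm = "series")

#' Run an analysis pipeline from a configuration
#'
#' The configuration is a list (or a YAML/JSON file path) with elements
#' \code{seed}, \code{outdir} and \code{stages} -- an ordered list of
#' stages, each a list with a \code{name} (one of simulate, input,
#' quality, od, motion, filter, ssc, mbll, epoch, glm) plus stage
#' parameters. Stage order is validated before anything runs (e.g.
#' \code{mbll} requires a prior \code{od}). Every output file starts with
#' provenance comment lines (stage, parameters, seed).
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @return invisibly, a list of produced artifact paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configurations")
      yaml::read_yaml(config)
    }
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("no stages configured")
  names <- vapply(stages, function(s) s$name %||% "", character(1))
  unknown <- setdiff(names, names(stageRequires))
  if (length(unknown)) stop("unknown stage(s): ",
                            paste(unknown, collapse = ", "))

  ## validate ordering before executing anything
  have <- character(0)
  for (nm in names) {
    req <- stageRequires[[nm]]
    ok <- switch(req,
                 none = TRUE,
                 recording = "recording" %in% have,
                 od = "od" %in% have,
                 series = any(c("od", "hb") %in% have))
    if (!ok) stop("stage '", nm, "' requires a prior stage producing ",
                  req)
    have <- c(have, switch(nm, simulate = , input = "recording",
                           od = "od", mbll = "hb",
                           motion = , filter = , ssc = "od",
                           character(0)))
  }

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "pipeline.log.jsonl")
  unlink(logPath)
  logLine <- function(...) cat(jsonlite::toJSON(list(...),
                                                auto_unbox = TRUE),
                               "\n", file = logPath, append = TRUE)
  writeTsv <- function(df, path, stage, params) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# stage=%s seed=%d params=%s", stage, seed,
                       jsonlite::toJSON(params, auto_unbox = TRUE)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  state <- list()
  artifacts <- character(0)
  for (st in stages) {
    nm <- st$name
    p <- st[setdiff(names(st), "name")]
    logLine(stage = nm, params = p, seed = seed)
    if (nm == "simulate") {
      phantom <- makePhantom()
      fwd <- buildForwardModel(phantom$volume, phantom$surface,
                               phantom$probe)
      sim <- utils::modifyList(defaultSimulation(), p)
      so <- simulateRecording(phantom, fwd, sim, seed = seed)
      state$recording <- so$recording
      out <- file.path(outdir, "recording.snirf")
      writeSnirf(so$recording, out)
      artifacts <- c(artifacts, out)
    } else if (nm == "input") {
      state$recording <- if (grepl("[.]nirs$", p$path))
        readNirsMat(p$path) else readSnirf(p$path)
    } else if (nm == "quality") {
      rep <- do.call(channelQualityReport, c(list(state$recording), p))
      out <- file.path(outdir, "quality.tsv")
      writeTsv(rep, out, nm, p)
      state$recording <- do.call(pruneChannels, c(list(state$recording), p))
      artifacts <- c(artifacts, out)
    } else if (nm == "od") {
      state$od <- do.call(toOpticalDensity, c(list(state$recording), p))
    } else if (nm == "motion") {
      state$od <- if (identical(p$method, "spline"))
        splineMotionCorrect(state$od, p$windows)
      else tddrMotionCorrect(state$od)
    } else if (nm == "filter") {
      state$od <- do.call(bandpassFilter, c(list(state$od), p))
    } else if (nm == "ssc") {
      state$od <- do.call(shortChannelRegress, c(list(state$od), p))
    } else if (nm == "mbll") {
      state$hb <- do.call(mbll, c(list(state$od), p))
      out <- file.path(outdir, "hbo.tsv")
      writeTsv(as.data.frame(state$hb@hbo), out, nm, p)
      artifacts <- c(artifacts, out)
    } else if (nm == "epoch") {
      series <- state$hb %||% state$od
      ep <- do.call(epochAverage, c(list(series), p))
      out <- file.path(outdir, "epochs.tsv")
      writeTsv(do.call(rbind, lapply(names(ep), function(l)
        data.frame(condition = l, n = ep[[l]]$n,
                   dropped = ep[[l]]$dropped))), out, nm, p)
      artifacts <- c(artifacts, out)
    } else if (nm == "glm") {
      series <- state$hb %||% state$od
      des <- buildDesign(series@events, series@times,
                         confounds = p$confounds %||%
                           c("constant", "linear"))
      fit <- fitGlm(series, des, serial = p$serial %||% "prewhiten")
      ctr <- c(1, numeric(ncol(des$X) - 1))
      res <- testContrast(fit, ctr, correction = p$correction %||% "fdr")
      out <- file.path(outdir, "glm.tsv")
      writeTsv(res, out, nm, p)
      artifacts <- c(artifacts, out)
    }
  }
  invisible(list(artifacts = artifacts, log = logPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
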