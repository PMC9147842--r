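#' Validate an end-to-end run configuration
#'
#' Reads a YAML configuration, applies defaults (contact slack 0.25, score
#' bounds 3.23/4.63, sequence window 4, stride 1, verdict threshold 0.2) and
#' validates every field, reporting the complete list of violations in one
#' error rather than stopping at the first.
#'
#' Expected layout:
#' \preformatted{
#' conditions:
#'   APO:  [apo_rep1.pdb, apo_rep2.pdb]
#'   LIG:  [lig_rep1.pdb]
#' reference: APO        # optional; default: first condition
#' bw_map: m1.tsv        # optional; default: shipped M1 map
#' pairs: pathway.tsv    # optional; default: shipped pathway registry
#' rrcs: {r_min: 3.23, r_max: 4.63, near_sequence_threshold: 4}
#' contacts: {epsilon: 0.25, include_hydrogens: false}
#' stride: 1
#' threshold: 0.2
#' out_dir: results
#' seed: 1
#' figures: false
#' }
#'
#' @param path YAML file path
#' @return a validated \linkS4class{RunConfig}; on violations, an error
#'   whose message lists every problem
#' @export
validateConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  conditions <- cfg$conditions
  if (is.null(conditions) || !length(conditions) || is.null(names(conditions))) {
    note("conditions: must be a named mapping of condition -> trajectory paths")
    conditions <- list()
  } else {
    conditions <- lapply(conditions, function(p) as.character(unlist(p)))
    for (nm in names(conditions)) {
      if (!length(conditions[[nm]])) note(sprintf("conditions.%s: no paths", nm))
      miss <- conditions[[nm]][!file.exists(conditions[[nm]])]
      if (length(miss)) {
        note(sprintf("conditions.%s: missing file(s) %s", nm,
                     paste(miss, collapse = ", ")))
      }
    }
  }
  reference <- cfg$reference %||% names(conditions)[1] %||% NA_character_
  if (length(conditions) && !is.na(reference) &&
      !reference %in% names(conditions)) {
    note(sprintf("reference: '%s' is not a configured condition", reference))
  }

  bwMap <- NULL
  if (!is.null(cfg$bw_map)) {
    if (!file.exists(cfg$bw_map)) note(sprintf("bw_map: file not found: %s", cfg$bw_map))
    else bwMap <- tryCatch(loadBWMap(cfg$bw_map),
                           error = function(e) { note(paste("bw_map:", conditionMessage(e))); NULL })
  }
  if (is.null(bwMap)) bwMap <- defaultBWMap()

  pairs <- NULL
  if (!is.null(cfg$pairs)) {
    if (!file.exists(cfg$pairs)) note(sprintf("pairs: file not found: %s", cfg$pairs))
    else pairs <- tryCatch(loadPairSet(cfg$pairs),
                           error = function(e) { note(paste("pairs:", conditionMessage(e))); NULL })
  }
  if (is.null(pairs)) pairs <- defaultPathwayPairs()

  rr <- cfg$rrcs %||% list()
  rrcsParams <- tryCatch(
    RRCSParams(rMin = rr$r_min %||% 3.23, rMax = rr$r_max %||% 4.63,
               nearSequenceThreshold = rr$near_sequence_threshold %||% 4L),
    error = function(e) { note(paste("rrcs:", conditionMessage(e))); RRCSParams() })

  ct <- cfg$contacts %||% list()
  contactSpec <- tryCatch(
    ContactSpec(epsilon = ct$epsilon %||% 0.25,
                heavyOnly = !isTRUE(ct$include_hydrogens)),
    error = function(e) { note(paste("contacts:", conditionMessage(e))); ContactSpec() })

  stride <- as.integer(cfg$stride %||% 1L)
  if (is.na(stride) || stride < 1L) note("stride: must be a positive integer")
  threshold <- as.numeric(cfg$threshold %||% 0.2)
  if (is.na(threshold) || threshold < 0) note("threshold: must be >= 0")
  outDir <- as.character(cfg$out_dir %||% "results")
  seed <- as.integer(cfg$seed %||% 1L)

  if (length(errs)) {
    stop(sprintf("invalid configuration (%d problem%s):\n  - %s",
                 length(errs), if (length(errs) > 1) "s" else "",
                 paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  new("RunConfig", conditions = conditions, reference = reference,
      bwMap = bwMap, pairs = pairs, rrcsParams = rrcsParams,
      contactSpec = contactSpec, stride = stride, threshold = threshold,
      outDir = outDir, seed = seed,
      writeFigures = isTRUE(cfg$figures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full contact-analysis pipeline
#'
#' Ingests every configured condition (one trajectory file per replicate),
#' computes average contact fractions, global-effect metrics of each ligand
#' condition against the reference, per-frame contact-score series,
#' histograms and increase/decrease verdicts, and writes a machine-readable
#' report (JSON plus CSV mirrors) into the output directory. The run is
#' deterministic: rerunning the same configuration reproduces the report
#' byte-identically.
#'
#' @param config a \linkS4class{RunConfig} from \code{\link{validateConfig}},
#'   or a path to a YAML configuration
#' @return invisibly, the report as a nested list
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- validateConfig(config)
  stopifnot(is(config, "RunConfig"))
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  p <- config@pairs@pairs
  plusSet <- pairLabel(p$labelA[p$direction == "increase"],
                       p$labelB[p$direction == "increase"])
  minusSet <- pairLabel(p$labelA[p$direction == "decrease"],
                        p$labelB[p$direction == "decrease"])

  stage <- function(fmt, ...) message(sprintf(paste0("[microsw] ", fmt), ...))
  wrap <- function(stageName, pairCtx, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s'%s: %s", stageName,
                   if (nzchar(pairCtx)) paste0(" [", pairCtx, "]") else "",
                   conditionMessage(e)), call. = FALSE)
    })
  }

  trajs <- list()
  for (cond in names(config@conditions)) {
    paths <- config@conditions[[cond]]
    trajs[[cond]] <- wrap("read", cond, lapply(seq_along(paths), function(i) {
      tr <- readPDB(paths[i], replicateId = sprintf("%s-rep%d", cond, i))
      tr
    }))
    stage("condition %s: %d replicate(s), %s frames", cond, length(paths),
          paste(vapply(trajs[[cond]], nFrames, 1L), collapse = "+"))
  }

  acf <- list()
  series <- list()
  for (cond in names(trajs)) {
    t0 <- proc.time()[["elapsed"]]
    acf[[cond]] <- wrap("contacts", cond,
      acfTable(trajs[[cond]], config@pairs, config@bwMap,
               config@contactSpec, condition = cond))
    series[[cond]] <- wrap("rrcs", cond,
      rrcsSeries(trajs[[cond]], config@pairs, config@bwMap,
                 config@rrcsParams, stride = config@stride))
    stage("condition %s analysed in %.1f s", cond,
          proc.time()[["elapsed"]] - t0)
    writeTable(acfFractions(acf[[cond]]),
               file.path(config@outDir, sprintf("acf_%s.csv", cond)))
    writeTable(series[[cond]],
               file.path(config@outDir, sprintf("rrcs_%s.csv", cond)))
    hist <- rrcsHistogram(series[[cond]], condition = cond)
    writeTable(hist, file.path(config@outDir, sprintf("rrcs_hist_%s.csv", cond)))
    if (config@writeFigures) {
      .plotHistogram(hist, file.path(config@outDir,
                                     sprintf("rrcs_hist_%s.png", cond)), cond)
    }
  }

  ref <- config@reference
  ge <- list()
  verdicts <- list()
  for (cond in setdiff(names(trajs), ref)) {
    g <- wrap("ge", cond,
              geMetric(acf[[ref]], acf[[cond]], plusSet, minusSet))
    ge[[cond]] <- list(ge_plus = gePlus(g), ge_minus = geMinus(g),
                       variant = if (g@rooted) "rooted" else "sum_of_squares")
    v <- wrap("classify", cond,
              classifyPairs(series[[ref]], series[[cond]], config@threshold))
    verdicts[[cond]] <- v
    writeTable(v, file.path(config@outDir, sprintf("verdicts_%s.csv", cond)))
  }

  report <- list(
    provenance = list(
      package = "MicroswitchMD",
      version = as.character(utils::packageVersion("MicroswitchMD")),
      seed = config@seed,
      reference = ref,
      conditions = config@conditions,
      parameters = list(
        r_min = config@rrcsParams@rMin, r_max = config@rrcsParams@rMax,
        near_sequence_threshold = config@rrcsParams@nearSequenceThreshold,
        epsilon = config@contactSpec@epsilon,
        stride = config@stride, threshold = config@threshold)),
    acf = lapply(acf, acfFractions),
    ge = ge,
    verdicts = verdicts)
  jsonlite::write_json(report, file.path(config@outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("report written to %s", file.path(config@outDir, "report.json"))
  invisible(report)
}

.plotHistogram <- function(hist, path, condition) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::barplot(hist$count, names.arg = sprintf("%.2f", hist$binStart),
                    space = 0, las = 2, col = "grey60", border = NA,
                    xlab = "contact score (bin start)", ylab = "frames",
                    main = sprintf("Contact-score distribution: %s", condition))
}
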