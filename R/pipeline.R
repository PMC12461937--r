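# End-to-end orchestration: simulate -> segment -> features -> focus ->
# bpd, with stages communicating through on-disk artifacts (PNG frames,
# CSV tables, JSON report) so that each stage is independently re-runnable
# and testable.

.default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "segment", "features", "focus", "bpd"),
    scene = list(nFrames = 10L, nTargetsPerFrame = 10L, nBackground = 3L),
    segmenter = list(),
    focus = list(nPairs = 150L, blurRange = c(2, 5), threshold = 0.5),
    bpd = list())
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the image-processing pipeline
#'
#' Executes the enabled stages in order (simulate, segment, features,
#' focus, bpd), each reading the previous stage's on-disk artifacts from
#' `outDir`, and writes a machine-readable `report.json` with per-stage
#' particle counts, the configuration hash and the seed. The global seed
#' propagates to every stochastic stage, so re-running an identical
#' configuration reproduces the report.
#'
#' @param config configuration list, or path to a YAML file with blocks
#'   `scene`, `segmenter`, `focus`, `bpd`, plus `seed` and `stages`.
#' @param outDir run directory for artifacts.
#' @return the run report (list), invisibly; also written as JSON.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("fimrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_pipeline_config(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, config_hash = .config_hash(cfg),
                 stages = list())
  stages <- cfg$stages

  if ("simulate" %in% stages) {
    sc_args <- cfg$scene
    sc_args$seed <- cfg$seed
    scene <- renderSequence(do.call(SceneConfig, sc_args))
    writeScene(scene, file.path(outDir, "frames"))
    report$stages$simulate <- list(
      frames = length(frames(scene)),
      truth_records = nrow(groundTruth(scene)))
  }

  set <- NULL
  if ("segment" %in% stages) {
    frs <- readFrames(file.path(outDir, "frames"))
    if (!length(frs)) stop("stage segment: no frames in run directory")
    sp <- do.call(SegmenterParams, cfg$segmenter)
    set <- segmentFrames(frs, sp)
    write.csv(roiTable(set), file.path(outDir, "rois.csv"),
              row.names = FALSE)
    report$stages$segment <- list(particles = length(set))
  }

  feats <- NULL
  if ("features" %in% stages) {
    if (is.null(set)) stop("stage features: segment stage did not run")
    feats <- featureTable(set)
    write.csv(feats, file.path(outDir, "features.csv"), row.names = FALSE)
    report$stages$features <- list(particles = nrow(feats),
                                   n_features = length(fimFeatureCatalog()))
  }

  keep <- NULL
  if ("focus" %in% stages) {
    if (is.null(feats)) stop("stage focus: features stage did not run")
    pairs <- makeFocusPairs(cfg$focus$nPairs,
                            blurRange = unlist(cfg$focus$blurRange),
                            seed = cfg$seed)
    ft <- focusPairFeatures(pairs)
    model <- trainFocusClassifier(ft, ft$label, seed = cfg$seed,
                                  threshold = cfg$focus$threshold)
    flt <- filterInFocus(set, feats, model)
    keep <- flt$isInFocus
    out <- data.frame(roi_id = roiTable(set)$roi_id,
                      p_out_of_focus = flt$pOutOfFocus,
                      in_focus = keep)
    write.csv(out, file.path(outDir, "focus.csv"), row.names = FALSE)
    report$stages$focus <- list(particles_in = length(keep),
                                particles_out = sum(keep),
                                held_out_accuracy = model@metrics$overall)
  }

  if ("bpd" %in% stages) {
    if (is.null(set) || is.null(feats))
      stop("stage bpd: segment/features stages did not run")
    bp <- do.call(BpdParams, cfg$bpd)
    sel <- if (is.null(keep)) rep(TRUE, length(set)) else keep
    sub <- set[which(sel)]
    particles <- cbind(roiTable(sub)[, c("frame", "roi_id", "cx", "cy")],
                       feats[sel, bp@featureSubset, drop = FALSE])
    flags <- if (length(unique(particles$frame)) >= 3L)
      runBpd(particles, bp) else rep(FALSE, nrow(particles))
    out <- data.frame(roi_id = particles$roi_id, background = flags)
    write.csv(out, file.path(outDir, "bpd.csv"), row.names = FALSE)
    report$stages$bpd <- list(particles_in = nrow(particles),
                              particles_out = sum(!flags),
                              background_flagged = sum(flags))
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
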