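# End-to-end orchestration: generate -> (wedge, noise) -> segment ->
# measure -> classify -> count clusters -> summarize, per region preset,
# with one global seed spawning per-tomogram substreams.

#' Load a region preset
#'
#' Presets are YAML files bundling a region's sampling context (landmark,
#' representative distance, number of tomograms) with the generator
#' parameters calibrated to the published per-region vesicle statistics.
#' The shipped presets are `"region1"` (interior, 3-8 um from the NM),
#' `"region2"` (mid, 3-6 um from the PM) and `"region3"` (peripheral,
#' within 2 um of the PM).
#'
#' @param name preset name, or a path to a preset YAML file.
#' @param overrides named list of generator parameters replacing the
#'   preset's values (e.g. a smaller `grid_shape` for quick runs).
#' @param n_tomograms replaces the preset's tomogram count (e.g. for
#'   quick runs); `NULL` keeps it.
#' @return list with `name`, `landmark`, `distance_um`, `n_tomograms`, and
#'   `generator` (a [generator_config()]).
#' @export
load_region_preset <- function(name, overrides = list(),
                               n_tomograms = NULL) {
  path <- if (file.exists(name)) name
  else system.file("extdata", "presets", paste0(name, ".yaml"),
                   package = "vesiclehood")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown region preset: ", name)
  y <- yaml::read_yaml(path)
  gen_args <- modifyList(y$generator, overrides)
  list(name = y$name, landmark = y$landmark, distance_um = y$distance_um,
       n_tomograms = if (is.null(n_tomograms)) y$n_tomograms
       else as.integer(n_tomograms),
       generator = do.call(generator_config, gen_args))
}

#' Pipeline run configuration
#'
#' @param regions list of region presets (from [load_region_preset()]), or
#'   a character vector of preset names.
#' @param detection a [detection_config()].
#' @param maturity a [maturity_config()].
#' @param clusters a [cluster_config()].
#' @param region_specs list of [region_spec()]s used to bin tomograms.
#' @param seed global integer seed; per-tomogram generator seeds are
#'   derived from it, so changing one region's tomogram count does not
#'   perturb the draws of the others.
#' @param use_wedge,use_noise apply the missing wedge / the noise stage
#'   (disable both for noiseless control runs).
#' @param overrides generator parameter overrides applied to every preset
#'   (only used when `regions` is given as preset names).
#' @param n_tomograms per-preset tomogram count override (single value
#'   applied to every preset; `NULL` keeps the presets' counts).
#' @return An object of class `run_config`.
#' @export
run_config <- function(regions = c("region1", "region2", "region3"),
                       detection = detection_config(),
                       maturity = maturity_config(),
                       clusters = cluster_config(),
                       region_specs = default_region_specs(),
                       seed = 1L,
                       use_wedge = TRUE,
                       use_noise = TRUE,
                       overrides = list(),
                       n_tomograms = NULL) {
  if (is.character(regions))
    regions <- lapply(regions, load_region_preset, overrides = overrides,
                      n_tomograms = n_tomograms)
  structure(list(regions = regions, detection = detection,
                 maturity = maturity, clusters = clusters,
                 region_specs = region_specs, seed = as.integer(seed),
                 use_wedge = isTRUE(use_wedge),
                 use_noise = isTRUE(use_noise)),
            class = "run_config")
}

# deterministic per-(region, tomogram) substream seed, < 2^31
.derive_seed <- function(seed, region_i, tomo_i) {
  as.integer((as.double(seed) * 48271 + region_i * 100003 + tomo_i * 1009) %%
               2147483587)
}

#' Run the full synthetic-analysis pipeline
#'
#' For every region preset, generates `n_tomograms` synthetic tomograms,
#' corrupts them as configured, segments, measures, classifies maturity,
#' detects metal clusters, matches detections to ground truth, assigns the
#' tomogram to a region by its landmark distance, and aggregates per-region
#' summaries, truth summaries, pairwise comparisons and cluster
#' prevalence. Deterministic given (config, seed).
#'
#' When `outdir` is given, the effective configuration is serialized to
#' `manifest.json` before execution, per-stage progress goes to
#' `log.txt`, and results are written as CSV/JSON (`truth.csv`,
#' `vesicles.csv`, `summaries.csv`, `truth_summaries.csv`,
#' `summaries.json`, `comparisons.json`, `matching.csv`). A failing stage
#' propagates an error naming the stage and tomogram; partial outputs are
#' kept next to a `FAILED` marker file.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created), or `NULL` for in-memory only.
#' @param keep_volumes keep rendered volumes in the returned object
#'   (memory-hungry; default `FALSE`).
#' @return An object of class `vesiclehood_run`: list with `records`,
#'   `summaries`, `truth_summaries`, `comparisons`, `matching`,
#'   `cluster_stats`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL, keep_volumes = FALSE) {
  stopifnot(inherits(config, "run_config"))
  logf <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(outdir, "log.txt")
    cat(sprintf("vesiclehood run, seed %d, %s\n", config$seed,
                format(Sys.time())), file = logf)
  }
  say <- function(...) {
    msg <- sprintf(...)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  manifest <- list(seed = config$seed,
                   use_wedge = config$use_wedge,
                   use_noise = config$use_noise,
                   detection = unclass(config$detection),
                   maturity = unclass(config$maturity),
                   clusters = unclass(config$clusters),
                   regions = lapply(config$regions, function(r)
                     list(name = r$name, landmark = r$landmark,
                          distance_um = r$distance_um,
                          n_tomograms = r$n_tomograms,
                          generator = unclass(r$generator))))
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

  fail <- function(stage, tomo, e) {
    if (!is.null(outdir))
      cat(sprintf("FAILED at stage '%s' (%s): %s\n", stage, tomo,
                  conditionMessage(e)), file = file.path(outdir, "FAILED"))
    stop(sprintf("stage '%s' failed for %s: %s", stage, tomo,
                 conditionMessage(e)), call. = FALSE)
  }

  records <- list(); truths <- list(); clusters_truth <- list()
  matching <- list(); fields_by_region <- list(); manifest_rows <- list()
  volumes <- list()
  for (ri in seq_along(config$regions)) {
    rg <- config$regions[[ri]]
    rname <- assign_region(rg$distance_um, rg$landmark, config$region_specs)
    say("region preset '%s' -> assigned '%s' (%s, %.1f um), %d tomogram(s)",
        rg$name, rname, rg$landmark, rg$distance_um, rg$n_tomograms)
    for (ti in seq_len(rg$n_tomograms)) {
      tomo_id <- sprintf("%s_t%02d", rg$name, ti)
      gcfg <- rg$generator
      gcfg$seed <- .derive_seed(config$seed, ri, ti)
      tomo <- tryCatch(
        generate_tomogram(gcfg, use_wedge = config$use_wedge,
                          use_noise = config$use_noise),
        error = function(e) fail("generate", tomo_id, e))
      labs <- tryCatch(
        suppressWarnings(segment_vesicles(tomo$volume, config$detection)),
        error = function(e) fail("segment", tomo_id, e))
      recs <- tryCatch(
        measure_vesicles(labs, config$detection$boundary_policy),
        error = function(e) fail("measure", tomo_id, e))
      recs <- tryCatch(
        classify_vesicles(recs, tomo$volume, labs, config$maturity),
        error = function(e) fail("classify", tomo_id, e))
      recs <- tryCatch(
        detect_clusters(recs, tomo$volume, labs, config$clusters,
                        config$maturity),
        error = function(e) fail("clusters", tomo_id, e))
      m <- match_to_truth(labs, tomo$labels)
      if (nrow(recs) > 0) {
        recs$tomogram_id <- tomo_id
        recs$region_label <- rname
      }
      tv <- tomo$field$vesicles
      if (nrow(tv) > 0) tv$region_label <- rname
      records[[tomo_id]] <- recs
      truths[[tomo_id]] <- tv
      clusters_truth[[tomo_id]] <- tomo$field$clusters
      matching[[tomo_id]] <- data.frame(
        tomogram_id = tomo_id, region_label = rname,
        n_truth = m$n_truth, n_pred = m$n_pred,
        n_matched = nrow(m$pairs),
        recall = m$recall, precision = m$precision,
        mean_iou = if (nrow(m$pairs)) mean(m$pairs$iou) else NA_real_)
      fields_by_region[[rname]] <- c(fields_by_region[[rname]],
                                     list(tomo$field))
      manifest_rows[[tomo_id]] <- data.frame(
        tomogram_id = tomo_id, region_label = rname,
        landmark = rg$landmark, distance_um = rg$distance_um,
        volume_um3 = slab_volume_um3(gcfg))
      if (keep_volumes) volumes[[tomo_id]] <- tomo
      say("  %s: %d truth / %d detected, recall %.2f precision %.2f",
          tomo_id, m$n_truth, m$n_pred, m$recall, m$precision)
    }
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  truths <- do.call(rbind, c(truths, make.row.names = FALSE))
  matching <- do.call(rbind, c(matching, make.row.names = FALSE))
  tomo_manifest <- do.call(rbind, c(manifest_rows, make.row.names = FALSE))
  attr(records, "table_type") <- "vesicles"
  attr(truths, "table_type") <- "truth"
  attr(tomo_manifest, "table_type") <- "manifest"

  res <- summarize_run(records, tomo_manifest, config$region_specs)
  truth_summaries <- do.call(rbind, lapply(names(fields_by_region),
    function(rn) summarize_truth_pooled(fields_by_region[[rn]], rn)))
  if (!is.null(truth_summaries))
    attr(truth_summaries, "table_type") <- "summaries"

  out <- structure(list(records = records, truth = truths,
                        summaries = res$summaries,
                        comparisons = res$comparisons,
                        cluster_stats = res$cluster_stats,
                        truth_summaries = truth_summaries,
                        matching = matching,
                        tomo_manifest = tomo_manifest,
                        manifest = manifest,
                        volumes = if (keep_volumes) volumes else NULL),
                   class = "vesiclehood_run")
  if (!is.null(outdir)) {
    write_table(records, file.path(outdir, "vesicles.csv"))
    write_table(truths, file.path(outdir, "truth.csv"))
    write_table(res$summaries, file.path(outdir, "summaries.csv"))
    if (!is.null(truth_summaries))
      write_table(truth_summaries, file.path(outdir, "truth_summaries.csv"))
    write_table(tomo_manifest, file.path(outdir, "tomograms.csv"))
    write.csv(matching, file.path(outdir, "matching.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(summaries = res$summaries,
           comparisons = lapply(res$comparisons, unclass),
           cluster_stats = res$cluster_stats),
      file.path(outdir, "summaries.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("outputs written to %s", outdir)
  }
  out
}

#' Summarize measured records by region
#'
#' The resumable tail of the pipeline: given a vesicle table and the
#' tomogram manifest (id, region, landmark distance, volume), computes the
#' per-region summaries, all pairwise diameter comparisons and per-region
#' cluster prevalence. Re-running this on a saved `vesicles.csv` +
#' `tomograms.csv` reproduces the pipeline's summary outputs exactly.
#'
#' @param records `vesicles`-schema data.frame.
#' @param tomo_manifest `manifest`-schema data.frame.
#' @param region_specs list of [region_spec()]s.
#' @return list with `summaries`, `comparisons`, `cluster_stats`.
#' @export
summarize_run <- function(records, tomo_manifest,
                          region_specs = default_region_specs()) {
  regions <- unique(tomo_manifest$region_label)
  regions <- regions[!is.na(regions)]
  summaries <- list(); cluster_stats <- list(); by_region <- list()
  for (rn in regions) {
    tm <- tomo_manifest[tomo_manifest$region_label == rn, , drop = FALSE]
    rr <- records[!is.na(records$region_label) &
                    records$region_label == rn, , drop = FALSE]
    summaries[[rn]] <- summarize_region(rr, tm$volume_um3, rn, nrow(tm))
    cluster_stats[[rn]] <- count_clusters(rr)
    by_region[[rn]] <- rr
  }
  summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))
  if (!is.null(summaries)) attr(summaries, "table_type") <- "summaries"
  comparisons <- list()
  if (length(regions) > 1) {
    for (i in seq_len(length(regions) - 1))
      for (j in (i + 1):length(regions)) {
        a <- by_region[[regions[i]]]; b <- by_region[[regions[j]]]
        if (sum(is.finite(a$diameter_nm)) >= 2 &&
            sum(is.finite(b$diameter_nm)) >= 2)
          comparisons[[paste(regions[i], "vs", regions[j])]] <-
            compare_regions(a, b, "diameter")
      }
  }
  list(summaries = summaries, comparisons = comparisons,
       cluster_stats = cluster_stats)
}

#' @export
print.vesiclehood_run <- function(x, ...) {
  cat("<vesiclehood_run>\n")
  if (!is.null(x$summaries)) print(x$summaries)
  for (nm in names(x$comparisons)) {
    cat(nm, ": ")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}
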