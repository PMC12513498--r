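#' Run the full analysis pipeline
#'
#' Orchestrates volume reading, aorta segmentation (classical detector or
#' external masks), extent selection, ring construction, fat windowing, FAI
#' computation, report writing and cohort statistics as one reproducible
#' run. Per-patient failures are recorded and excluded from statistics,
#' never silently dropped; the run fails only if every patient fails.
#'
#' @param config a named list, or the path of a YAML file, with elements:
#' \describe{
#'   \item{manifest}{data frame (or CSV path) with columns `id`, `volume`
#'     (path), optional `mask` (path).}
#'   \item{patient_table}{optional CSV path or data frame with clinical
#'     columns keyed by `id` (processed by [derive_clinical()]); a `group`
#'     column enables the ROC stage.}
#'   \item{ring}{optional list of [ring_params()] arguments.}
#'   \item{detector}{optional list of [detector_config()] arguments.}
#'   \item{stats}{optional list: `positive_groups` (character), `seed`
#'     (integer, required when present), `boot` (bootstrap replicates).}
#'   \item{out_dir}{output directory.}
#' }
#' @return Invisibly, a list with `results` (report data frame), `roc`
#'   (roc_result or `NULL`), `excluded` (ids), `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dir.create(file.path(out_dir, "detection_reports"), showWarnings = FALSE)

  manifest <- config$manifest
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (is.null(manifest)) manifest <- data.frame(id = character(),
                                                volume = character())
  stopifnot(all(c("id", "volume") %in% names(manifest)))

  params <- do.call(ring_params, as.list(config$ring))
  det_cfg <- do.call(detector_config, as.list(config$detector))

  results <- list()
  errors <- character()
  for (i in seq_len(nrow(manifest))) {
    id <- as.character(manifest$id[i])
    res <- tryCatch({
      vol <- read_ct_series(manifest$volume[i])
      mask <- NULL
      if ("mask" %in% names(manifest) && !is.na(manifest$mask[i]) &&
          nzchar(manifest$mask[i]))
        mask <- read_mask(manifest$mask[i], vol)
      r <- fai_pipeline(vol, mask = mask, params = params, config = det_cfg)
      if (!is.null(r$detection))
        jsonlite::write_json(
          r$detection, file.path(out_dir, "detection_reports",
                                 paste0(id, ".json")),
          auto_unbox = TRUE, digits = NA)
      r
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", id, conditionMessage(e)))
      r <- list(aa_fai = NA_real_, ct_pvat_area = NA_real_, n_fat_pixels = 0L,
                n_ring_pixels = 0L, n_slices = 0L, flags = "error",
                per_slice = NULL)
      class(r) <- "fai_result"
      r
    })
    results[[id]] <- res
  }

  records <- config$patient_table
  if (is.character(records)) records <- read.csv(records)
  if (!is.null(records)) records <- derive_clinical(records)
  report <- write_report(results, file.path(out_dir, "results.csv"),
                         records = records)

  excluded <- names(results)[vapply(results, function(r)
    is.na(r$aa_fai) || any(r$flags %in% c("detection_failed", "error")), TRUE)]

  roc <- NULL
  stats_cfg <- config$stats
  if (!is.null(stats_cfg) && !is.null(records) && "group" %in% names(records)) {
    if (is.null(stats_cfg$seed)) stop("stats.seed is mandatory when statistics are requested")
    ok <- setdiff(names(results), excluded)
    fai <- vapply(results[ok], function(r) r$aa_fai, 0)
    grp <- records$group[match(ok, records$id)]
    pos <- grp %in% stats_cfg$positive_groups
    if (any(pos) && any(!pos)) {
      roc <- roc_analysis(fai, pos, boot = stats_cfg$boot %||% 2000,
                          seed = stats_cfg$seed)
      jsonlite::write_json(
        list(auc = roc$auc, auc_ci = roc$auc_ci, cutoff = roc$cutoff,
             sensitivity = roc$sensitivity, specificity = roc$specificity,
             n_pos = roc$n_pos, n_neg = roc$n_neg,
             positive_orientation = roc$positive_orientation),
        file.path(out_dir, "roc.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  provenance <- list(
    package = "aafai", version = as.character(packageVersion("aafai")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    ring = unclass(params), detector = unclass(det_cfg),
    stats = stats_cfg, n_patients = nrow(manifest),
    n_analyzed = nrow(manifest) - length(excluded),
    excluded = as.list(excluded), errors = as.list(errors))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (nrow(manifest) == 0) warning("empty manifest; header-only outputs written")
  if (nrow(manifest) > 0 && length(excluded) == nrow(manifest))
    stop("all patients failed analysis")
  invisible(list(results = report, roc = roc, excluded = excluded,
                 provenance = provenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
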