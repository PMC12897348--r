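#' Phase table for a cohort's recordings
#'
#' Runs band-pass filtering and log-variance segmentation on every
#' recording and stacks the results into one long table, ready to write as
#' CSV (`subject_id, route, phase_index, kind, start_sample, end_sample`;
#' sample indices 0-based, half-open).
#'
#' @param cohort a [SoundCohort-class] with audio
#' @param ... passed to [logvarSegment()]
#' @return data.frame, one row per detected phase.
#' @export
phaseTable <- function(cohort, ...) {
  out <- list()
  for (sid in subjectTable(cohort)$subject_id) {
    recs <- subjectRecordings(cohort, sid)
    for (route in c("nose", "mouth")) {
      ph <- suppressWarnings(logvarSegment(bandpassBreath(recs[[route]]), ...))
      if (nrow(ph))
        out[[length(out) + 1L]] <- cbind(subject_id = sid, route = route, ph)
    }
  }
  do.call(rbind, out)
}

#' Write a feature table as CSV with a JSON sidecar
#'
#' One row per subject (columns: subject_id, severity, then features);
#' the sidecar records the feature families, extraction parameters, and
#' any fitted normalization metadata.
#'
#' @param table a [FeatureTable-class]
#' @param path CSV output path (sidecar written as `<path>.json`)
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  df <- data.frame(subject_id = colnames(table),
                   severity = severityLabels(table),
                   t(featureValues(table)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(family = as.list(featureFamily(table)),
               extraction = metadata(table)$extraction,
               norm_meta = metadata(table)$norm_meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a selection report as JSON
#'
#' @param report a `SelectionReport` from [selectTaskFeatures()] /
#'   [rfeSelect()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(report, path) {
  out <- list(task = report$task,
              stage1_kept = report$stage1_kept,
              stage2_ranking = as.list(report$stage2_ranking),
              final_selected = report$final_selected,
              design_features = report$design_features,
              thresholds = report$thresholds,
              cv_path = report$cv_path)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Persist a trained one-vs-one bundle
#'
#' Writes one model blob per task plus a JSON manifest (tasks, winning
#' families, feature lists, OOB metrics, search log).
#'
#' @param bundle an [OvoBundle-class]
#' @param dir output directory (created)
#' @return `dir`, invisibly.
#' @export
writeOvoBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  taskNames <- vapply(bundle@tasks, paste, character(1), collapse = "_vs_")
  for (i in seq_along(bundle@tasks))
    saveRDS(bundle@models[[i]], file.path(dir, paste0(taskNames[i], ".rds")))
  manifest <- list(
    tasks = taskNames,
    family = vapply(bundle@models, `[[`, character(1), "family"),
    features = stats::setNames(bundle@features, taskNames),
    oob = stats::setNames(bundle@oob, taskNames),
    search_log = bundle@searchLog)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
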