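#' Measure a batch of calibrated images
#'
#' Segments and measures each image, continuing past per-image failures
#' (the workflow expects some images to need manual segmentation; those are
#' reported, not fatal).
#'
#' @param images list of [calibrated_image()] objects, or character paths
#'   to calibrated TIFF files.
#' @param ids sample identifiers; defaults to file names or list names.
#' @param rois optional list of [roi_polygon()] manual selections, matched
#'   by position; a non-`NULL` entry takes precedence over automated
#'   segmentation for that image.
#' @param seg a [segmentation_params()].
#' @param geometry a [geometry_config()].
#' @return list with `records` (measured rows), `failures` (data.frame of
#'   id + reason) and `warnings` (per-sample segmentation warnings).
#' @export
measure_images <- function(images, ids = NULL, rois = NULL,
                           seg = segmentation_params(),
                           geometry = geometry_config()) {
  if (is.character(images)) {
    paths <- images
    if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(paths))
    images <- as.list(paths)
  } else if (is.null(ids)) {
    ids <- names(images) %||% sprintf("image_%02d", seq_along(images))
  }
  records <- list()
  failures <- list()
  warns <- list()
  for (i in seq_along(images)) {
    id <- ids[i]
    res <- try({
      img <- images[[i]]
      if (is.character(img)) img <- read_calibrated_tiff(img)
      roi <- if (!is.null(rois) && length(rois) >= i) rois[[i]] else NULL
      if (!is.null(roi)) {
        ct <- roi_to_contour(roi, img$pixel_size, image_height = nrow(img$pixels))
        mask <- NULL
      } else {
        mask <- auto_segment(img, seg)
        if (length(attr(mask, "warnings")))
          warns[[id]] <- attr(mask, "warnings")
        ct <- mask_to_contour(mask)
      }
      measure_organoid(ct, image = img, mask = mask, config = geometry, file = id)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures[[id]] <- conditionMessage(attr(res, "condition"))
    } else {
      records[[id]] <- res
    }
  }
  recs <- if (length(records)) do.call(rbind, records) else NULL
  if (!is.null(recs)) rownames(recs) <- NULL
  list(records = recs,
       failures = data.frame(id = names(failures),
                             reason = unlist(failures) %||% character(0),
                             stringsAsFactors = FALSE, row.names = NULL),
       warnings = warns)
}

#' One-shot screen: images to QC report
#'
#' Runs the full pipeline: segment and measure every input image, pool with
#' the reference morphometric table, fit the scaled-PCA morphospace, and
#' cluster for the retain/discard decision. Images that fail segmentation
#' are listed as requiring manual segmentation and the batch continues.
#'
#' @param input input images: paths or [calibrated_image()] list.
#' @param reference reference records: a measured data.frame or a path to a
#'   feature-table CSV.
#' @param config a [cluster_config()].
#' @param seg a [segmentation_params()].
#' @param geometry a [geometry_config()].
#' @param include analysis features.
#' @param ids,rois forwarded to [measure_images()].
#' @param out_dir optional directory; when given, `features.csv`,
#'   `qc_report.csv`, `scores.csv`, `var_pct.csv`, `cos2.csv` and a JSON
#'   provenance block are written there.
#' @return list of class `screen_result`: `report` ([qc_decision()] report
#'   with model), `records`, `failures`, `warnings`.
#' @export
run_screen <- function(input, reference, config = cluster_config(),
                       seg = segmentation_params(),
                       geometry = geometry_config(),
                       include = analysis_features(),
                       ids = NULL, rois = NULL, out_dir = NULL) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- read_feature_table(reference)
  meas <- measure_images(input, ids = ids, rois = rois, seg = seg,
                         geometry = geometry)
  if (is.null(meas$records))
    ms_validation("every input image failed segmentation/measurement; nothing to screen")
  report <- run_qc(meas$records, reference, config = config, include = include)
  out <- structure(list(report = report, records = meas$records,
                        failures = meas$failures, warnings = meas$warnings,
                        config = config),
                   class = "screen_result")
  if (!is.null(out_dir)) write_screen_outputs(out, out_dir)
  out
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$report)
  if (nrow(x$failures))
    cat(sprintf("%d image(s) need manual segmentation: %s\n", nrow(x$failures),
                paste(x$failures$id, collapse = ", ")))
  invisible(x)
}

write_screen_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(x$records, file.path(out_dir, "features.csv"))
  utils::write.csv(x$report$samples, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  model <- x$report$model
  sc <- data.frame(Sample = model$sample_ids,
                   X = model$scores[, 1L],
                   Y = if (ncol(model$scores) >= 2L) model$scores[, 2L] else NA_real_,
                   Z = if (ncol(model$scores) >= 3L) model$scores[, 3L] else NA_real_)
  utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(model$var_pct),
                              var_pct = model$var_pct),
                   file.path(out_dir, "var_pct.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$cos2), file.path(out_dir, "cos2.csv"))
  prov <- list(config = unclass(x$config),
               retained_components = x$report$retained_components,
               n_reference = sum(x$report$samples$role == "reference"),
               n_input = sum(x$report$samples$role == "input"),
               failures = x$failures,
               package_version = as.character(utils::packageVersion("morphoscreen")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Screen a synthetic cohort end to end
#'
#' Measures every rendered cohort image (reference and input) through the
#' segmentation + morphometry pipeline and runs the QC decision of the
#' input organoids against the measured reference pool.
#'
#' @param cohort a [sample_cohort()].
#' @param config a [cluster_config()].
#' @param seg,geometry pipeline parameter objects.
#' @return a `qc_report` (see [run_qc()]) plus element `truth`: the cohort
#'   class labels of the input samples.
#' @export
screen_cohort <- function(cohort, config = cluster_config(),
                          seg = segmentation_params(),
                          geometry = geometry_config()) {
  if (is.null(cohort$images))
    ms_validation("cohort was generated with contours_only = TRUE; nothing to segment")
  meas <- measure_images(cohort$images, ids = cohort$samples$id,
                         seg = seg, geometry = geometry)
  if (nrow(meas$failures))
    ms_warn(paste("cohort images failed segmentation:",
                  paste(meas$failures$id, collapse = ", ")))
  rec <- meas$records
  is_ref <- rec$file %in% cohort$samples$id[cohort$samples$role == "reference"]
  report <- run_qc(rec[!is_ref, ], rec[is_ref, ], config = config)
  report$truth <- cohort$samples[cohort$samples$role == "input",
                                 c("id", "class")]
  report
}
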