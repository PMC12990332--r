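#' Clustering configuration for the QC decision
#'
#' Defaults reproduce the reference workflow: k = 3 clusters, 25 random
#' restarts, RNG seed 123, and retention of the principal components whose
#' cumulative variance fraction exceeds 0.9.
#'
#' @param k number of clusters.
#' @param n_start random restarts for k-means.
#' @param seed RNG seed set immediately before clustering.
#' @param variance_threshold cumulative-variance cutoff for PC retention.
#' @param max_iter iteration cap per k-means run.
#' @export
cluster_config <- function(k = 3L, n_start = 25L, seed = 123L,
                           variance_threshold = 0.9, max_iter = 100L) {
  stopifnot(k >= 1L, n_start >= 1L, variance_threshold > 0,
            variance_threshold <= 1, max_iter >= 1L)
  structure(list(k = as.integer(k), n_start = as.integer(n_start),
                 seed = as.integer(seed), variance_threshold = variance_threshold,
                 max_iter = as.integer(max_iter)),
            class = "cluster_config")
}

#' Pool input and reference records into one feature matrix
#'
#' The QC decision compares input organoids against the curated reference
#' pool in a common morphospace, so standardization and PCA are computed on
#' the pooled matrix.
#'
#' @param input_records,reference_records `morphometric_record` data.frames
#'   sharing the analysis features.
#' @param include features to carry, as in [select_features()].
#' @return a [select_features()] matrix with per-sample `role` labels.
#' @export
integrate_reference <- function(input_records, reference_records,
                                include = analysis_features()) {
  input_records <- as.data.frame(input_records)
  reference_records <- as.data.frame(reference_records)
  if (!nrow(reference_records))
    ms_validation("reference set is empty; the QC decision is undefined without reference organoids")
  if (!nrow(input_records)) ms_validation("no input records")
  internal <- ifelse(include %in% names(.analysis_feature_map),
                     .analysis_feature_map[include], include)
  for (nm in c("input", "reference")) {
    df <- if (nm == "input") input_records else reference_records
    # the derived dne_r0 is computable from dne and average_radius
    have <- internal %in% names(df) |
      (internal == "dne_r0" & all(c("dne", "average_radius") %in% names(df)))
    if (any(!have))
      ms_schema(paste0(nm, " records lack feature(s): ",
                       paste(include[!have], collapse = ", ")))
  }
  ids <- c(input_records$file, reference_records$file)
  if (anyDuplicated(ids))
    ms_validation(paste("duplicated sample id(s) across input and reference:",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  shared <- intersect(names(input_records), names(reference_records))
  pooled <- rbind(input_records[, shared], reference_records[, shared])
  role <- c(rep("input", nrow(input_records)),
            rep("reference", nrow(reference_records)))
  select_features(pooled, include = include, role = role)
}

#' Number of principal components to retain
#'
#' The smallest m whose cumulative variance fraction exceeds the threshold
#' (strict inequality, as in the reference rule
#' `which(explained_variance > 0.9)[1]`).
#'
#' @param model a [pca_morphospace()] model.
#' @param threshold cumulative-variance fraction.
#' @export
retain_components <- function(model, threshold = 0.9) {
  cum <- cumsum(model$var_pct) / 100
  m <- which(cum > threshold)[1L]
  if (is.na(m)) {
    ms_warn("no component set exceeds the variance threshold; retaining all components")
    m <- length(model$var_pct)
  }
  as.integer(m)
}

#' k-means clustering of morphospace scores
#'
#' Runs `stats::kmeans` with `n_start` random restarts under the configured
#' seed, keeping the restart with the lowest within-cluster sum of squares.
#' This is the reference workflow's own clustering call, so with the same
#' seed the partition is identical to it. Labels are canonicalized by order
#' of first occurrence, making reports byte-stable.
#'
#' @param scores samples x retained-components score matrix.
#' @param config a [cluster_config()].
#' @return list of class `kmeans_partition`: `labels` (integer, canonical),
#'   `inertia` (total within-cluster sum of squares), `centers`.
#' @export
kmeans_cluster <- function(scores, config = cluster_config()) {
  scores <- as.matrix(scores)
  if (config$k > nrow(scores))
    ms_validation(sprintf("k = %d exceeds the number of samples (%d)",
                          config$k, nrow(scores)))
  set.seed(config$seed)
  km <- stats::kmeans(scores, centers = config$k, nstart = config$n_start,
                      iter.max = config$max_iter)
  relabel <- match(km$cluster, unique(km$cluster))
  centers <- km$centers[unique(km$cluster), , drop = FALSE]
  structure(list(labels = relabel, inertia = km$tot.withinss, centers = centers),
            class = "kmeans_partition")
}

#' Retain/discard decision from cluster membership
#'
#' An input organoid is retained iff its cluster contains at least one
#' reference organoid; clusters populated only by input samples mark those
#' samples for exclusion. Reference samples are reported without a
#' decision. The per-cluster composition is included so the decision can be
#' supervised when k is uninformative.
#'
#' @param labels per-sample cluster ids.
#' @param role per-sample `"reference"` / `"input"` labels.
#' @param sample_ids sample identifiers.
#' @return object of class `qc_report` with elements `samples` (data.frame:
#'   sample_id, role, cluster, decision) and `clusters` (per-cluster
#'   reference and input counts).
#' @export
qc_decision <- function(labels, role, sample_ids = NULL) {
  if (length(labels) != length(role))
    ms_validation("labels and roles have different lengths")
  if (!any(role == "reference"))
    ms_validation("no reference samples present; the QC decision is undefined")
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%02d", seq_along(labels))
  if (length(unique(labels)) == 1L)
    ms_warn("all samples fall in a single cluster; k is uninformative and every input is retained")
  ref_clusters <- unique(labels[role == "reference"])
  decision <- ifelse(role == "reference", "n/a-reference",
                     ifelse(labels %in% ref_clusters, "retain", "discard"))
  samples <- data.frame(sample_id = sample_ids, role = role,
                        cluster = as.integer(labels), decision = decision,
                        stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster = sort(unique(labels)),
    n_reference = vapply(sort(unique(labels)),
                         function(cl) sum(labels == cl & role == "reference"), integer(1)),
    n_input = vapply(sort(unique(labels)),
                     function(cl) sum(labels == cl & role == "input"), integer(1)))
  structure(list(samples = samples, clusters = clusters), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n_in <- sum(x$samples$role == "input")
  n_ret <- sum(x$samples$decision == "retain")
  cat(sprintf("<qc_report> %d reference + %d input organoids: %d retained, %d discarded\n",
              sum(x$samples$role == "reference"), n_in, n_ret, n_in - n_ret))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Morphology-based quality control of input organoids
#'
#' The full decision stage: pool input and reference records, fit the
#' scaled-PCA morphospace, retain the components explaining more than the
#' configured share of variance (default 90%), k-means cluster all samples
#' in the retained-component space, and retain each input organoid iff it
#' co-clusters with reference organoids.
#'
#' @param input_records,reference_records measured `morphometric_record`
#'   data.frames.
#' @param config a [cluster_config()].
#' @param include analysis features, as in [select_features()].
#' @return a `qc_report` with `model` ([pca_morphospace()]),
#'   `retained_components`, `partition` and `config` attached as elements.
#' @export
run_qc <- function(input_records, reference_records,
                   config = cluster_config(), include = analysis_features()) {
  fm <- integrate_reference(input_records, reference_records, include = include)
  model <- pca_morphospace(fm, scale = TRUE)
  m <- retain_components(model, config$variance_threshold)
  part <- kmeans_cluster(model$scores[, seq_len(m), drop = FALSE], config)
  rep <- qc_decision(part$labels, fm$role, fm$sample_ids)
  rep$model <- model
  rep$retained_components <- m
  rep$partition <- part
  rep$config <- config
  rep
}
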