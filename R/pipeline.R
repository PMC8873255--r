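#' Pipeline run configuration
#'
#' Aggregates every tunable threshold of the analysis in one validated
#' object; the defaults are the exploratory choices the analysis was
#' designed around (10 m endpoint slack, 1-20 min and 100 m segment
#' bounds, 100 m grid, 0.5 Jaccard threshold, 120 degree complexity
#' threshold, 1 min / 10 m stop rule, 5 min graph dwell threshold, 10-node
#' graph minimum, 10-bin histograms, 50 repeated LOO runs of 10,000 SGD
#' steps, 20 SVM splits holding out 20 percent).
#'
#' @param slack_radius,min_duration,max_duration,min_length Segment
#'   extraction thresholds (m, s, s, m).
#' @param gap_threshold Bout-splitting gap (s).
#' @param cell_size Grid resolution (m).
#' @param jaccard_threshold Segment-similarity threshold.
#' @param complexity_threshold Turning-angle threshold (degrees).
#' @param static_radius,min_stop_duration Stop detection (m, s).
#' @param dwell_threshold Graph transit-removal dwell (s).
#' @param min_nodes Graph-task inclusion threshold.
#' @param min_alone Alone-segment inclusion threshold (strict).
#' @param bins Histogram bins.
#' @param runs,steps,lr LOO repetitions, SGD step budget, learning rate.
#' @param repeats,test_fraction SVM splits and held-out fraction.
#' @param tz Timezone for home-estimation calendar days.
#' @param master_seed Seed for every stochastic stage.
#' @return A list of class `mm_run_config`.
#' @export
run_config <- function(slack_radius = 10, min_duration = 60,
                       max_duration = 1200, min_length = 100,
                       gap_threshold = 60, cell_size = 100,
                       jaccard_threshold = 0.5, complexity_threshold = 120,
                       static_radius = 10, min_stop_duration = 60,
                       dwell_threshold = 300, min_nodes = 10,
                       min_alone = 5, bins = 10, runs = 50, steps = 10000,
                       lr = 1e-3, repeats = 20, test_fraction = 0.2,
                       tz = "UTC", master_seed = 1) {
  stopifnot(slack_radius > 0, min_duration > 0, min_duration < max_duration,
            min_length > 0, cell_size > 0, bins >= 2, runs >= 1,
            steps >= 1, lr > 0, repeats >= 1,
            test_fraction > 0, test_fraction < 1)
  structure(as.list(environment()), class = "mm_run_config")
}

#' Load a cohort from an input directory
#'
#' Expects `metadata.csv` (`participant_id,group`), one trace file per
#' participant (`<participant_id>.csv` or `.gpx`) and optionally
#' `annotations.csv`.
#'
#' @param input_dir Directory with the exchange files.
#' @return A list with `traces`, `metadata`, `annotations`.
#' @export
load_cohort <- function(input_dir) {
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("missing metadata.csv in ", input_dir)
  metadata <- read_metadata(meta_path)
  traces <- list()
  for (i in seq_len(nrow(metadata))) {
    pid <- metadata$participant_id[i]
    path <- file.path(input_dir, paste0(pid, ".csv"))
    if (!file.exists(path)) path <- file.path(input_dir, paste0(pid, ".gpx"))
    if (!file.exists(path)) stop("missing trace file for participant ", pid)
    traces[[pid]] <- read_trace(path, pid, metadata$group[i])
  }
  ann_path <- file.path(input_dir, "annotations.csv")
  annotations <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  list(traces = traces, metadata = metadata, annotations = annotations)
}

seg_param_of <- function(config)
  segment_params(config$slack_radius, config$min_duration,
                 config$max_duration, config$min_length)

# per-participant preparation + all-segment features; NULL records dropped
prepare_cohort <- function(cohort, config) {
  grid <- grid_spec(config$cell_size)
  out <- list()
  for (pid in names(cohort$traces)) {
    prep <- prepare_participant(cohort$traces[[pid]], cohort$annotations,
                                seg_param_of(config), config$gap_threshold)
    if (nrow(prep$segments) == 0) {
      warning("participant ", pid, " has zero segments; excluded",
              call. = FALSE)
      next
    }
    out[[pid]] <- list(group = cohort$traces[[pid]]$group, prep = prep,
                       segments = prep$segments)
  }
  out
}

participant_feature_record <- function(p, config, segments = p$segments) {
  grid <- grid_spec(config$cell_size)
  participant_features(p$prep, segments, grid,
                       jaccard_threshold = config$jaccard_threshold,
                       complexity_threshold = config$complexity_threshold,
                       static_radius = config$static_radius,
                       min_stop_duration = config$min_stop_duration,
                       tz = config$tz)
}

# pooled per-group raw values for the aggregate comparison panels
pool_spatiotemporal <- function(pf_list, groups) {
  pool <- function(extract, per_participant = FALSE) {
    vals <- list(control = numeric(0), patient = numeric(0))
    for (id in names(pf_list)) {
      v <- extract(pf_list[[id]])
      vals[[groups[[id]]]] <- c(vals[[groups[[id]]]], v)
    }
    vals
  }
  list(
    segment_similarity = pool(function(pf)
      pf$seg$similarity[!is.na(pf$seg$similarity)]),
    entropy = pool(function(pf) pf$entropy),
    distance_from_home = pool(function(pf) pf$seg$distance_from_home),
    stop_durations = pool(function(pf) unlist(pf$stop_durations)),
    complexity = pool(function(pf) as.numeric(pf$seg$complexity)),
    total_turning_angle = pool(function(pf) pf$seg$total_turning_angle))
}

#' Run the complete analysis pipeline
#'
#' Ingests (or accepts) a cohort, extracts segments, computes the
#' spatiotemporal and graph features, produces the group comparison tables
#' (KS + Cohen's d) for the patient-versus-control spatiotemporal task,
#' the alone-versus-accompanied task and the graph task, runs the
#' leave-one-out logistic-regression comparisons of feature combinations
#' and the alone/accompanied SVM, and writes CSV tables plus a JSON
#' summary and a config snapshot to `output_dir`.  Every stochastic step
#' is seeded from `config$master_seed`, so a rerun is byte-identical.
#'
#' @param input Either an input directory (see [load_cohort()]) or a
#'   cohort bundle from [generate_cohort()].
#' @param config A [run_config()].
#' @param output_dir Output directory (created if missing).
#' @param loo_subsets,graph_subsets Feature-combination lists for the two
#'   LOO reports; sensible defaults mirror the combinations compared in
#'   the analysis.
#' @return The summary list, invisibly; all artefacts are on disk.
#' @export
run_pipeline <- function(input, config = run_config(), output_dir,
                         loo_subsets = default_loo_subsets(),
                         graph_subsets = default_graph_subsets()) {
  cohort <- if (is.character(input)) load_cohort(input) else input
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- prepare_cohort(cohort, config)
  groups <- vapply(parts, function(p) p$group, character(1))
  grid <- grid_spec(config$cell_size)

  all_segments <- do.call(rbind, lapply(parts, function(p) p$segments))
  write_segments(all_segments, file.path(output_dir, "segments.csv"))

  # graphs from the full traces (all movements)
  graph_info <- lapply(parts, function(p) {
    g <- build_graph(p$prep$trace, grid, config$dwell_threshold)
    nc <- igraph::vcount(g)
    tab <- if (nc >= 2) centralities(g) else NULL
    list(node_count = nc, tab = tab)
  })

  # --- task A: patients' alone segments vs controls -----------------------
  for (pid in names(parts)) parts[[pid]]$node_count <- graph_info[[pid]]$node_count
  taskA <- apply_cohort_filters(parts, "spatiotemporal",
                                min_alone = config$min_alone)
  pfA <- list()
  for (pid in names(taskA)) {
    pf <- participant_feature_record(taskA[[pid]], config,
                                     taskA[[pid]]$segments)
    if (!is.null(pf)) pfA[[pid]] <- pf
  }
  groupsA <- vapply(names(pfA), function(id) taskA[[id]]$group, character(1))
  cmpA <- group_comparison(pool_spatiotemporal(pfA, as.list(groupsA)))
  utils::write.csv(cmpA, file.path(output_dir, "comparison_spatiotemporal.csv"),
                   row.names = FALSE)

  featA <- lapply(names(pfA), function(id) {
    c(list(group = groupsA[[id]]), assemble_feature_values(pfA[[id]]))
  })
  names(featA) <- names(pfA)
  looA <- NULL
  if (sum(groupsA == "control") >= 2 && sum(groupsA == "patient") >= 2) {
    looA <- feature_combination_report(featA, loo_subsets,
                                       bins = config$bins, runs = config$runs,
                                       steps = config$steps, lr = config$lr,
                                       seed = config$master_seed)
    utils::write.csv(looA, file.path(output_dir, "loo_spatiotemporal.csv"),
                     row.names = FALSE)
  } else {
    message("too few participants per group; LOO classification skipped")
  }

  # --- task B: alone vs accompanied patient segments ----------------------
  pat_ids <- names(parts)[groups == "patient"]
  segB <- NULL; svmB <- NULL; cmpB <- NULL
  if (length(pat_ids) > 0) {
    pfB <- list()
    for (pid in pat_ids) {
      pf <- participant_feature_record(parts[[pid]], config)
      if (!is.null(pf)) pfB[[pid]] <- pf
    }
    segB <- do.call(rbind, lapply(pfB, function(pf) pf$seg))
    lab <- segB$companionship
    if (sum(lab == "alone") >= 10 && sum(lab == "accompanied") >= 10) {
      vals <- function(col) list(
        control = segB[[col]][lab == "alone"],       # "control" slot = alone
        patient = segB[[col]][lab == "accompanied"])
      cmpB <- group_comparison(list(
        complexity = vals("complexity"),
        total_turning_angle = vals("total_turning_angle"),
        n_stops = vals("n_stops"),
        distance_from_home = vals("distance_from_home")))
      names(cmpB)[names(cmpB) == "cohens_d"] <- "cohens_d_alone_minus_accompanied"
      utils::write.csv(cmpB,
                       file.path(output_dir, "comparison_alone_accompanied.csv"),
                       row.names = FALSE)
      svmB <- classify_alone_accompanied(
        segB, feature_cols = c("complexity", "total_turning_angle"),
        test_fraction = config$test_fraction, repeats = config$repeats,
        seed = config$master_seed)
      utils::write.csv(data.frame(repeat_idx = seq_along(svmB$accuracies),
                                  accuracy = svmB$accuracies),
                       file.path(output_dir, "svm_alone_accompanied.csv"),
                       row.names = FALSE)
    } else {
      message("too few labelled segments; alone/accompanied task skipped")
    }
  }

  # --- task C: graph features, all segments -------------------------------
  taskC <- apply_cohort_filters(parts, "graph", min_nodes = config$min_nodes)
  cmpC <- NULL; looC <- NULL
  if (length(taskC) > 0) {
    node_counts <- vapply(names(taskC), function(id)
      as.numeric(graph_info[[id]]$node_count), numeric(1))
    groupsC <- vapply(taskC, function(p) p$group, character(1))
    cent_pool <- function(col) {
      vals <- list(control = numeric(0), patient = numeric(0))
      for (id in names(taskC)) {
        vals[[groupsC[[id]]]] <- c(vals[[groupsC[[id]]]],
                                   graph_info[[id]]$tab[[col]])
      }
      vals
    }
    nc_pool <- list(control = node_counts[groupsC == "control"],
                    patient = node_counts[groupsC == "patient"])
    if (length(nc_pool$control) > 0 && length(nc_pool$patient) > 0) {
      cmpC <- group_comparison(list(node_count = nc_pool,
                                    closeness = cent_pool("closeness"),
                                    betweenness = cent_pool("betweenness"),
                                    degree_centrality = cent_pool("degree_centrality")))
      utils::write.csv(cmpC, file.path(output_dir, "comparison_graph.csv"),
                       row.names = FALSE)
    }
    if (sum(groupsC == "control") >= 2 && sum(groupsC == "patient") >= 2) {
      featC <- list()
      for (id in names(taskC)) {
        pf <- participant_feature_record(taskC[[id]], config)
        if (is.null(pf)) next
        featC[[id]] <- c(list(group = groupsC[[id]]),
                         assemble_feature_values(pf, graph_info[[id]]$tab,
                                                 graph_info[[id]]$node_count))
      }
      looC <- feature_combination_report(featC, graph_subsets,
                                         bins = config$bins,
                                         runs = config$runs,
                                         steps = config$steps, lr = config$lr,
                                         seed = config$master_seed)
      utils::write.csv(looC, file.path(output_dir, "loo_graph.csv"),
                       row.names = FALSE)
    }
  }

  summary <- list(
    n_participants = length(parts),
    n_controls = sum(groups == "control"),
    n_patients = sum(groups == "patient"),
    n_segments = nrow(all_segments),
    spatiotemporal = list(
      n_included = length(pfA),
      comparison = cmpA,
      loo = looA),
    alone_accompanied = list(
      comparison = cmpB,
      median_accuracy = if (!is.null(svmB)) svmB$median_accuracy else NULL),
    graph = list(n_included = length(taskC), comparison = cmpC, loo = looC))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(config), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Default feature combinations for the spatiotemporal LOO report
#' @return List of character vectors.
#' @export
default_loo_subsets <- function() {
  list("entropy", "segment_similarity", "stop_durations",
       "distance_from_home", "complexity",
       c("entropy", "segment_similarity"),
       c("entropy", "stop_durations"),
       c("segment_similarity", "stop_durations", "entropy"),
       c("segment_similarity", "entropy", "distance_from_home"),
       c("segment_similarity", "entropy", "complexity"))
}

#' Default feature combinations for the graph-task LOO report
#' @return List of character vectors.
#' @export
default_graph_subsets <- function() {
  list("node_count", "closeness", "betweenness", "degree_centrality",
       c("segment_similarity", "entropy"),
       c("node_count", "closeness", "betweenness", "degree_centrality"),
       c("segment_similarity", "entropy", "node_count", "closeness",
         "betweenness", "degree_centrality"))
}

#' Sweep the histogram bin count of the LOO classification
#'
#' Reruns [loo_classify()] for each bin setting with otherwise identical
#' seeds and settings; duplicate bin values are flagged in the output.
#'
#' @param features As for [loo_classify()].
#' @param feature_subset Feature names to use throughout the sweep.
#' @param bins_list Integer vector of bin counts.
#' @param ... Passed to [loo_classify()].
#' @return Data frame with one row per entry of `bins_list`.
#' @export
bin_sweep <- function(features, feature_subset, bins_list, ...) {
  if (length(bins_list) == 0)
    return(data.frame(bins = integer(0), median_sensitivity = numeric(0),
                      median_specificity = numeric(0),
                      uncertainty = numeric(0), duplicate = logical(0)))
  rows <- lapply(seq_along(bins_list), function(i) {
    res <- loo_classify(features, feature_subset, bins = bins_list[i], ...)
    data.frame(bins = bins_list[i],
               median_sensitivity = res$median_sensitivity,
               median_specificity = res$median_specificity,
               uncertainty = res$uncertainty,
               duplicate = duplicated(bins_list)[i])
  })
  do.call(rbind, rows)
}
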