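#' End-to-end pipeline
#'
#' Sequences the full analysis — binning, depth, normalization, the CBS and
#' HMM arms, method-comparison metrics, cohort recurrence, and cohort
#' statistics — from a single validated configuration, writing a manifest
#' that records every configurable parameter and seed so a run is
#' reproducible from its config alone.
#'
#' @name cli_orchestration
NULL

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = "cfcna_out",
    bins = list(mode = "fixed", width = 5e5, n_bins = 5500,
                min_mappable_fraction = 0.9),
    normalize = list(panel_mode = "median", gc_span = 0.3, eps = 1),
    cbs = list(alpha = 0.01, n_perm = 1000, gain_threshold = 0.2,
               loss_threshold = -0.2),
    hmm = list(normal_grid = c(0.7, 0.8, 0.9, 0.95, 0.99),
               self_transition = 0.999, emission_df = 3,
               max_iter = 50, tol = 1e-3),
    recurrence = list(n_perm = 1000, q_threshold = 0.25),
    paths = list(layout = NULL, gc_track = NULL, mappability = NULL,
                 depth_table = NULL, panel = NULL, cohort_table = NULL))
}

# merge user config into defaults, rejecting unknown keys
merge_config <- function(user, defaults = pipeline_defaults()) {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", key)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]])
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config a named list of overrides, or a path to a JSON file of
#'   them. Unknown keys are rejected; omitted keys take documented
#'   defaults.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- merge_config(config)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline from file inputs
#'
#' Stages: read layout/tracks, build + annotate + mask bins, load the depth
#' table, build the panel from control columns, normalize all samples, run
#' both segmentation arms, summarize and compare them, run recurrence on
#' the highest-tumor-fraction sample per dog, and compute cohort
#' statistics. Any stage failure aborts with the stage name. Outputs and a
#' JSON manifest go to \code{config$out_dir}.
#'
#' @param config a \code{pipeline_config} (or list / JSON path coercible to
#'   one). Requires \code{paths$layout}, \code{paths$mappability},
#'   \code{paths$gc_track}, \code{paths$depth_table}, and
#'   \code{paths$cohort_table} (a TSV with dog_id, sample_id, group,
#'   timepoint; control samples have group "control").
#' @return Invisibly, a run report list (also serialized in the manifest).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  for (p in c("layout", "mappability", "gc_track", "depth_table",
              "cohort_table")) {
    if (is.null(cfg$paths[[p]]))
      stop("missing required config field: paths$", p)
    if (!file.exists(cfg$paths[[p]]))
      stop("input not found for paths$", p, ": ", cfg$paths[[p]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  layout <- stage("layout", read_layout_tsv(cfg$paths$layout))
  mp <- stage("tracks", read_track(cfg$paths$mappability))
  gc <- stage("tracks", read_track(cfg$paths$gc_track))
  scheme <- stage("bins", {
    sc <- if (cfg$bins$mode == "fixed")
      build_fixed_bins(layout, cfg$bins$width)
    else build_adaptive_bins(layout, mp, cfg$bins$n_bins)
    sc <- annotate_bins(sc, gc, mp)
    mask_bins(sc, cfg$bins$min_mappable_fraction)
  })
  write_bins_bed(scheme, file.path(cfg$out_dir, "bins.bed"))

  cohort <- stage("cohort_table",
                  utils::read.table(cfg$paths$cohort_table, sep = "\t",
                                    header = TRUE, stringsAsFactors = FALSE))
  profiles <- stage("depth", load_depth_table(cfg$paths$depth_table, scheme))
  ctrl_ids <- cohort$sample_id[cohort$group == "control"]
  case_ids <- setdiff(names(profiles), ctrl_ids)
  if (length(ctrl_ids) < 2)
    stop("pipeline stage 'panel' failed: need >= 2 control samples")

  pon <- stage("panel", build_panel(profiles[ctrl_ids], scheme,
                                    mode = cfg$normalize$panel_mode))
  write_panel_tsv(pon, scheme, file.path(cfg$out_dir, "panel.tsv"))

  norms <- stage("normalize", lapply(profiles[case_ids], to_log2_ratio,
                                     pon = pon, scheme = scheme,
                                     eps = cfg$normalize$eps))

  hcfg <- hmm_config(normal_grid = cfg$hmm$normal_grid,
                     self_transition = cfg$hmm$self_transition,
                     emission_df = cfg$hmm$emission_df,
                     max_iter = cfg$hmm$max_iter, tol = cfg$hmm$tol)
  hmm_fits <- stage("hmm_arm", lapply(norms, estimate_tumor_fraction,
                                      scheme = scheme, config = hcfg))
  cbs_sets <- stage("cbs_arm", lapply(norms, function(np) {
    ss <- segment_cbs(np, scheme, alpha = cfg$cbs$alpha,
                      n_perm = cfg$cbs$n_perm, seed = cfg$seed)
    merge_adjacent_same_state(
      assign_copy_states(ss, cfg$cbs$gain_threshold,
                         cfg$cbs$loss_threshold))
  }))
  write_seg(lapply(hmm_fits, `[[`, "segments"),
            file.path(cfg$out_dir, "hmm_arm.seg"))
  write_seg(cbs_sets, file.path(cfg$out_dir, "cbs_arm.seg"))

  metrics <- stage("metrics", {
    sum_h <- mapply(summarize_segments, norms,
                    lapply(hmm_fits, `[[`, "segments"), SIMPLIFY = FALSE)
    sum_c <- mapply(summarize_segments, norms, cbs_sets, SIMPLIFY = FALSE)
    list(hmm = sum_h, cbs = sum_c,
         comparison = compare_methods(sum_h, sum_c))
  })

  tf_table <- data.frame(
    sample_id = names(hmm_fits),
    tumor_fraction = vapply(hmm_fits,
                            function(f) f$estimate$tumor_fraction, 0),
    stringsAsFactors = FALSE)
  tf_table <- merge(cohort, tf_table, by = "sample_id")
  utils::write.table(tf_table, file.path(cfg$out_dir, "tumor_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rec <- stage("recurrence", {
    mal <- tf_table[tf_table$group == "malignant", ]
    if (!nrow(mal)) return(NULL)
    best <- select_max_tf_sample(mal)
    sets <- lapply(hmm_fits[best$sample_id], `[[`, "segments")
    lapply(c("gain", "loss"), function(dir) {
      tr <- gscore(sets, scheme, dir)
      tr <- permutation_significance(tr, n_perm = cfg$recurrence$n_perm,
                                     seed = cfg$seed,
                                     q_threshold = cfg$recurrence$q_threshold)
      write_recurrence_tsv(tr,
        file.path(cfg$out_dir, paste0("recurrence_", dir, ".tsv")),
        file.path(cfg$out_dir, paste0("recurrence_", dir, ".bed")))
      tr
    })
  })

  stats_out <- stage("cohort_stats", {
    pre <- tf_table[tf_table$timepoint == "pre", ]
    out <- list()
    if (all(c("benign", "malignant") %in% pre$group)) {
      ben <- pre$tumor_fraction[pre$group == "benign"]
      mal <- pre$tumor_fraction[pre$group == "malignant"]
      out$rank_sum <- rank_sum_test(mal, ben)
      out$roc <- roc_auc(pre$tumor_fraction, pre$group == "malignant")
    }
    paired <- merge(tf_table[tf_table$timepoint == "pre",
                             c("dog_id", "tumor_fraction")],
                    tf_table[tf_table$timepoint == "post",
                             c("dog_id", "tumor_fraction")],
                    by = "dog_id", suffixes = c("_pre", "_post"))
    if (nrow(paired) >= 3)
      out$paired <- paired_signed_rank(paired$tumor_fraction_pre,
                                       paired$tumor_fraction_post)
    out
  })

  report <- list(
    config = unclass(cfg),
    n_samples = length(norms), n_controls = length(ctrl_ids),
    n_bins = n_bins(scheme),
    stages = c("layout", "bins", "depth", "panel", "normalize",
               "hmm_arm", "cbs_arm", "metrics", "recurrence",
               "cohort_stats"),
    tumor_fractions = tf_table,
    segment_comparison_p = metrics$comparison$p_value,
    rank_sum_p = if (!is.null(stats_out$rank_sum))
      stats_out$rank_sum$p_value,
    auc = if (!is.null(stats_out$roc)) stats_out$roc$auc,
    paired_p = if (!is.null(stats_out$paired)) stats_out$paired$p_value)
  jsonlite::write_json(report, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(report, list(metrics = metrics, recurrence = rec,
                           hmm_fits = hmm_fits, cbs_sets = cbs_sets)))
}

#' One-command demo on simulated data
#'
#' Simulates a cohort with \code{\link{simulate_cohort}}, writes its file
#' representation under \code{out_dir/sim}, and runs
#' \code{\link{run_pipeline}} on those files.
#'
#' @param seed RNG seed for the simulation and all downstream permutation
#'   streams.
#' @param out_dir output directory.
#' @param config optional \code{sim_config} overriding the default cohort.
#' @param cbs_n_perm,rec_n_perm permutation counts for the demo (reduced
#'   from the analysis defaults to keep the demo fast).
#' @return The pipeline run report (invisible).
#' @export
run_demo <- function(seed = 7, out_dir = "cfcna_demo", config = NULL,
                     cbs_n_perm = 200, rec_n_perm = 200) {
  if (is.null(config)) config <- sim_config(seed = seed)
  bundle <- simulate_cohort(config)
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)
  write_layout_tsv(bundle$reference$layout, file.path(sim_dir, "layout.tsv"))
  write_track(bundle$reference$gc_track, file.path(sim_dir, "gc.bedgraph"))
  write_track(bundle$reference$mappability_track,
              file.path(sim_dir, "mappability.bedgraph"))
  all_profiles <- c(bundle$controls,
                    unlist(lapply(bundle$cases, function(d) d$samples),
                           recursive = FALSE, use.names = FALSE))
  write_depth_table(all_profiles, bundle$scheme,
                    file.path(sim_dir, "depth.tsv"))
  ctrl <- data.frame(
    dog_id = paste0("ctrl_", seq_along(bundle$controls)),
    sample_id = vapply(bundle$controls, `[[`, "", "sample_id"),
    group = "control", timepoint = "pre", true_tf = 0,
    stringsAsFactors = FALSE)
  cohort <- rbind(ctrl, bundle$cohort_table)
  utils::write.table(cohort, file.path(sim_dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(bundle$cases, function(d)
    list(group = d$group, tf_pre = d$tf_pre, truth = d$truth)),
    file.path(sim_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  run_pipeline(pipeline_config(list(
    seed = seed, out_dir = out_dir,
    cbs = list(n_perm = cbs_n_perm),
    recurrence = list(n_perm = rec_n_perm),
    paths = list(layout = file.path(sim_dir, "layout.tsv"),
                 gc_track = file.path(sim_dir, "gc.bedgraph"),
                 mappability = file.path(sim_dir, "mappability.bedgraph"),
                 depth_table = file.path(sim_dir, "depth.tsv"),
                 cohort_table = file.path(sim_dir, "cohort.tsv")))))
}
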