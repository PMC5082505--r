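# Orchestration of the three analyses: ROI-level pairwise tests,
# network contrast matrix, connectomic threshold sweep.

#' Pipeline run configuration
#'
#' Validated bundle of the tunable analysis parameters; echoed verbatim
#' into the output directory by [run_pipeline()] so every run is auditable.
#'
#' @param tr repetition time, seconds.
#' @param f_low,f_high pass band, Hz.
#' @param rd_radius sphere radius for relative displacement, mm.
#' @param variance_fraction confound SVD retention fraction.
#' @param half_lives autocorrelation component half-lives, TRs.
#' @param threshold_range binarization percentiles for the graph sweep.
#' @param method connectivity estimator (`"pooled"` or `"per_edge"`).
#' @param exclude_outliers drop motion-flagged subjects from group
#'   statistics (per-subject matrices are always computed).
#' @param despike apply the median/MAD despiker to ROI series first.
#' @param despike_z robust z threshold for the despiker.
#' @param seed integer seed recorded in the run log.
#' @return object of class `run_config`.
#' @export
run_config <- function(tr = 2, f_low = 0.009, f_high = 0.1, rd_radius = 80,
                       variance_fraction = 0.99,
                       half_lives = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                       threshold_range = 85:99,
                       method = c("pooled", "per_edge"),
                       exclude_outliers = FALSE, despike = FALSE,
                       despike_z = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(tr > 0, f_low >= 0, f_low < f_high, rd_radius > 0,
            variance_fraction > 0, variance_fraction <= 1,
            all(half_lives > 0),
            all(threshold_range >= 0 & threshold_range < 100))
  structure(list(tr = tr, f_low = f_low, f_high = f_high,
                 rd_radius = rd_radius,
                 variance_fraction = variance_fraction,
                 half_lives = half_lives,
                 threshold_range = threshold_range, method = method,
                 exclude_outliers = exclude_outliers, despike = despike,
                 despike_z = despike_z, seed = as.integer(seed)),
            class = "run_config")
}

#' Pairwise ROI-level group tests
#'
#' Tests every unique ROI pair's edge value across subjects
#' (patient minus control, optional sex covariate), Bonferroni-corrected
#' over the number of pairs — the ROI-level analysis style used for an
#' 8-ROI default-mode set, where 8 ROIs give a 28-comparison family.
#'
#' @param conn_list per-subject `connectivity_matrix` objects.
#' @param groups,sex per-subject labels.
#' @param rois optional ROI indices or names to restrict the pair set.
#' @return data.frame: `roi_a`, `roi_b`, `t`, `p`, `p_bonferroni`,
#'   `survives`.
#' @export
pairwise_edge_tests <- function(conn_list, groups, sex = NULL, rois = NULL) {
  z0 <- conn_list[[1]]$z
  if (is.null(rois)) rois <- seq_len(nrow(z0))
  if (is.character(rois)) rois <- match(rois, rownames(z0))
  pairs <- utils::combn(rois, 2)
  m <- ncol(pairs)
  g <- as.integer(groups == "patient")
  rows <- lapply(seq_len(m), function(e) {
    i <- pairs[1, e]; j <- pairs[2, e]
    vals <- vapply(conn_list, function(cm) cm$z[i, j], numeric(1))
    res <- pooled_t_covariate(vals, g, sex)
    data.frame(roi_a = rownames(z0)[i], roi_b = rownames(z0)[j],
               t = res$statistic, p = res$p_two_tailed)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p, m)
  out$survives <- out$p_bonferroni < 0.05
  out
}

#' Group tests of graph metrics at every threshold
#'
#' @param sweep_list per-subject [metric_sweep()] tables.
#' @param groups,sex per-subject labels.
#' @param metrics metric columns to test.
#' @return data.frame with one row per metric x threshold: `t`, `p`, and
#'   `p_bonferroni` over the number of thresholds.
#' @export
sweep_group_tests <- function(sweep_list, groups, sex = NULL,
                              metrics = c("clustering", "efficiency",
                                          "small_world",
                                          "isolate_fraction")) {
  g <- as.integer(groups == "patient")
  thresholds <- sweep_list[[1]]$percentile
  n_thr <- length(thresholds)
  rows <- list()
  for (metric in metrics) {
    for (r in seq_len(n_thr)) {
      vals <- vapply(sweep_list, function(tbl) tbl[[metric]][r], numeric(1))
      res <- if (stats::sd(vals) < 1e-12) {
        list(statistic = 0, p_two_tailed = 1)
      } else {
        pooled_t_covariate(vals, g, sex)
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, percentile = thresholds[r],
        t = res$statistic, p = res$p_two_tailed)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p, n_thr)
  out$survives <- out$p_bonferroni < 0.05
  out
}

#' Run the full lesion-connectomics pipeline on a cohort
#'
#' Stages, in order: motion summaries and outlier flags; per-subject
#' confound designs and connectivity matrices; across-subject motion
#' residualization of every edge; ROI-level pairwise group tests;
#' network block matrices, lesion profiles and the group contrast matrix;
#' segregation group test; graph-metric sweep with per-threshold group
#' tests (Bonferroni over thresholds). A failure in any stage aborts with
#' a stage-named error.
#'
#' @param cohort list of `subject_record`s, or a manifest path readable by
#'   [read_cohort()].
#' @param partition a [network_partition()] (or partition TSV path).
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, result tables, the
#'   echoed config and a JSON run log are written there.
#' @param roi_subset optional ROI set for the pairwise edge tests
#'   (default: all ROIs if <= 12, else the lesion network's ROIs).
#' @return list with elements `motion`, `conn` (per-subject matrices,
#'   residualized), `pairwise`, `blocks`, `contrast`, `segregation`,
#'   `sweeps`, `sweep_tests`, `log`.
#' @export
run_pipeline <- function(cohort, partition, config = run_config(),
                         output_dir = NULL, roi_subset = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(cohort)) cohort <- stage("read", read_cohort(cohort))
  if (is.character(partition)) {
    partition <- stage("read", read_partition_tsv(partition))
  }
  groups <- vapply(cohort, `[[`, character(1), "group")
  sexes <- vapply(cohort, `[[`, character(1), "sex")
  ids <- vapply(cohort, `[[`, character(1), "id")

  motion <- stage("motion", {
    mean_rd <- vapply(cohort, function(s) {
      relative_displacement(s$motion_params, config$rd_radius)$mean_rd
    }, numeric(1))
    flags <- flag_motion_outliers(mean_rd[groups == "control"], mean_rd)
    data.frame(id = ids, group = groups, sex = sexes, mean_rd = mean_rd,
               flagged = flags)
  })

  family <- ar_family(ncol(cohort[[1]]$roi_series), config$half_lives)
  confound_m <- integer(length(cohort))
  n_dct <- NA_integer_
  conn_list <- stage("connectivity", lapply(seq_along(cohort), function(i) {
    subj <- cohort[[i]]
    series <- subj$roi_series
    if (config$despike) {
      series <- t(apply(series, 1, despike_interpolate, config$despike_z))
      rownames(series) <- rownames(subj$roi_series)
    }
    rd <- relative_displacement(subj$motion_params, config$rd_radius)$rd
    conf <- build_confound_design(rd, subj$artifact_series, tr = config$tr,
                                  f_low = config$f_low,
                                  f_high = config$f_high,
                                  variance_fraction = config$variance_fraction)
    confound_m[i] <<- conf$m
    n_dct <<- conf$k_dct
    connectivity_matrix(series, conf, method = config$method,
                        family = family)
  }))
  conn_list <- stage("residualize",
                     residualize_cohort(conn_list, motion$mean_rd))

  keep <- if (config$exclude_outliers) !motion$flagged else rep(TRUE, length(cohort))
  g_keep <- groups[keep]
  s_keep <- sexes[keep]

  pairwise <- stage("pairwise", {
    if (is.null(roi_subset)) {
      roi_subset <- if (nrow(conn_list[[1]]$z) <= 12) {
        seq_len(nrow(conn_list[[1]]$z))
      } else {
        lesion_net <- which(partition$labels ==
                              partition$labels[partition$lesion_rois[1]])
        utils::head(union(partition$lesion_rois, lesion_net), 8)
      }
    }
    pairwise_edge_tests(conn_list[keep], g_keep, s_keep, roi_subset)
  })

  blocks <- stage("blocks", lapply(conn_list, block_means,
                                   partition = partition))
  lesion_profs <- stage("blocks", t(vapply(conn_list, lesion_profile,
                                           numeric(partition$n_networks),
                                           partition = partition)))
  contrast <- stage("contrast",
                    network_contrast_matrix(blocks[keep], g_keep, s_keep,
                                            lesion_profiles =
                                              lesion_profs[keep, , drop = FALSE]))
  seg <- stage("segregation", {
    s_vals <- vapply(blocks, segregation, numeric(1))
    list(values = s_vals,
         test = pooled_t_covariate(s_vals[keep], g_keep, s_keep),
         mean_control = mean(s_vals[keep][g_keep == "control"]),
         mean_patient = mean(s_vals[keep][g_keep == "patient"]))
  })

  sweeps <- stage("graphs", lapply(conn_list, metric_sweep,
                                   p_range = config$threshold_range))
  sweep_tests <- stage("graphs",
                       sweep_group_tests(sweeps[keep], g_keep, s_keep))

  log <- list(
    n_subjects = length(cohort), n_controls = sum(groups == "control"),
    n_patients = sum(groups == "patient"),
    n_flagged = sum(motion$flagged), excluded = ids[!keep],
    n_rois = nrow(conn_list[[1]]$z),
    n_volumes = ncol(cohort[[1]]$roi_series),
    confound_svd_m = confound_m, n_dct_columns = n_dct,
    n_confound_columns = conn_list[[1]]$m_confounds,
    eff_df = conn_list[[1]]$eff_df,
    method = config$method, seed = config$seed,
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(motion = motion, conn = conn_list, pairwise = pairwise,
                 blocks = blocks, lesion_profiles = lesion_profs,
                 contrast = contrast, segregation = seg, sweeps = sweeps,
                 sweep_tests = sweep_tests, config = config, log = log)
  if (!is.null(output_dir)) stage("write", write_results(result, output_dir))
  result
}

write_results <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$motion, "motion.tsv")
  wt(result$pairwise, "pairwise_tests.tsv")
  wt(data.frame(network = rownames(result$contrast$t_mat),
                result$contrast$t_mat, check.names = FALSE),
     "contrast_t.tsv")
  wt(data.frame(network = rownames(result$contrast$mask),
                result$contrast$mask, check.names = FALSE),
     "contrast_mask.tsv")
  wt(data.frame(id = result$motion$id, group = result$motion$group,
                segregation = result$segregation$values),
     "segregation.tsv")
  sweep_all <- do.call(rbind, lapply(seq_along(result$sweeps), function(i) {
    cbind(id = result$motion$id[i], result$sweeps[[i]])
  }))
  wt(sweep_all, "graph_sweep.tsv")
  wt(result$sweep_tests, "graph_sweep_tests.tsv")
  yaml::write_yaml(unclass(result$config),
                   file.path(output_dir, "config.yaml"))
  jsonlite::write_json(result$log, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
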