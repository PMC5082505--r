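# ROI-level analysis in the style of an 8-ROI default-mode study: per-edge
# ReML connectivity for the lesion network's ROIs, motion residualization,
# and group tests over the 28 pairwise comparisons with Bonferroni
# correction.

source("analysis/00_common.R")

dat <- load_cohort()
spec <- study_spec()
roles <- spec$network_roles
dmn_rois <- union(spec$lesion_rois,
                  which(dat$partition$labels == roles[["DMN"]]))[1:8]

cat("Computing per-edge ReML connectivity for", length(dmn_rois),
    "DMN ROIs over", length(dat$cohort), "subjects...\n")
fam <- ar_family(ncol(dat$cohort[[1]]$roi_series))
conns <- lapply(dat$cohort, function(subj) {
  rd <- relative_displacement(subj$motion_params)$rd
  conf <- build_confound_design(rd, subj$artifact_series, tr = spec$tr)
  suppressWarnings(
    connectivity_matrix(subj$roi_series[dmn_rois, ], conf,
                        method = "per_edge", family = fam))
})
mean_rd <- vapply(dat$cohort, function(s) {
  relative_displacement(s$motion_params)$mean_rd
}, numeric(1))
conns <- residualize_cohort(conns, mean_rd)

groups <- vapply(dat$cohort, `[[`, character(1), "group")
sexes <- vapply(dat$cohort, `[[`, character(1), "sex")
tests <- pairwise_edge_tests(conns, groups, sexes)
write_tsv(tests, "dmn_pairwise_tests.tsv")
lesion_ids <- rownames(dat$cohort[[1]]$roi_series)[spec$lesion_rois]
lesion_rows <- tests[tests$roi_a %in% lesion_ids |
                       tests$roi_b %in% lesion_ids, ]
cat(nrow(tests), "pairwise tests;", sum(tests$survives),
    "survive Bonferroni over", nrow(tests), "comparisons\n")
cat("Lesion-ROI edges: mean patient-minus-control t =",
    round(mean(lesion_rows$t), 2), "\n")
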