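# Network-level analysis: pooled-ReML connectivity for all 120 ROIs,
# block means over the 8 networks, lesion connectivity profile, the group
# contrast matrix with Bonferroni families, and the segregation test.

source("analysis/00_common.R")

dat <- load_cohort()
cfg <- run_config(seed = MASTER_SEED)
res <- run_pipeline(dat$cohort, dat$partition, cfg,
                    output_dir = file.path(OUT_DIR, "pipeline"))

roles <- study_spec()$network_roles
tmat <- res$contrast$t_mat
cat("Contrast matrix over", nrow(tmat), "networks (",
    sum(upper.tri(tmat)), "pairwise tests )\n")
cat("thalamic-precuneus T =",
    round(tmat[roles[["thalamic"]], roles[["precuneus"]]], 2),
    "; DMN-FEN T =", round(tmat[roles[["DMN"]], roles[["FEN"]]], 2), "\n")
cat("Lesion row: DMN T =",
    round(res$contrast$lesion_t[roles[["DMN"]]], 2),
    "( Bonferroni mask", res$contrast$lesion_mask[roles[["DMN"]]], ")\n")
seg <- res$segregation
cat("Segregation: controls", round(seg$mean_control, 3), "patients",
    round(seg$mean_patient, 3), "; T =",
    round(seg$test$statistic, 2), ", p =",
    signif(seg$test$p_two_tailed, 3), "\n")
write_tsv(data.frame(network = rownames(tmat), round(tmat, 3),
                     check.names = FALSE), "contrast_t.tsv")
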