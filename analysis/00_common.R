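# Shared setup for the analysis drivers: the desk-scale study conditions
# (120 ROIs in 8 networks, 148 volumes at TR = 2 s; 20 controls and 6
# patients) and a deterministic cohort loader. Each numbered script is
# self-contained: it regenerates the cohort from the master seed if the
# written dataset is not on disk.

suppressMessages(library(lesionconn))

MASTER_SEED <- 20160301L
DATA_DIR <- "scratch/dataset"
OUT_DIR <- "results/analysis"
dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

study_spec <- function() cohort_spec(seed = MASTER_SEED)

load_cohort <- function() {
  manifest <- file.path(DATA_DIR, "manifest.tsv")
  if (file.exists(manifest)) {
    list(cohort = read_cohort(manifest),
         partition = read_partition_tsv(file.path(DATA_DIR, "partition.tsv"),
                                        study_spec()$network_names))
  } else {
    spec <- study_spec()
    list(cohort = generate_cohort(spec, 20, 6, seed = MASTER_SEED),
         partition = generate_partition(spec))
  }
}

write_tsv <- function(x, name) {
  utils::write.table(x, file.path(OUT_DIR, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat("  wrote", file.path(OUT_DIR, name), "\n")
}
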