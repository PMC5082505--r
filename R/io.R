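# Plain-text dataset interfaces: per-subject time-series and motion files,
# partition table, cohort manifest, config echo.

check_tsv_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed file ", path, ": fewer than 2 lines")
  n_fields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(n_fields != n_fields[1])
  if (length(bad) > 0) {
    stop("malformed row in ", path, " at line ", bad[1], ": expected ",
         n_fields[1], " fields, found ", n_fields[bad[1]])
  }
  invisible(TRUE)
}

#' Write a synthetic cohort to a plain-text dataset
#'
#' Produces one ROI-by-volume TSV and one six-column whitespace-delimited
#' motion file (translations mm, rotations radians) per subject, an
#' artifact-series TSV per subject, a partition TSV
#' (`roi_id`, `network_label`, `is_lesion`), a cohort manifest TSV and the
#' generating specification echoed to YAML.
#'
#' @param cohort list of `subject_record`s (e.g. [generate_cohort()]).
#' @param spec the [cohort_spec()] used to generate them.
#' @param dir output directory (created if needed).
#' @return path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  part <- generate_partition(spec)
  roi_ids <- rownames(cohort[[1]]$roi_series)
  utils::write.table(
    data.frame(roi_id = roi_ids, network_label = part$labels,
               is_lesion = as.integer(seq_along(part$labels) %in%
                                        part$lesion_rois)),
    file.path(dir, "partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- lapply(cohort, function(subj) {
    ts_path <- file.path(dir, paste0(subj$id, "_timeseries.tsv"))
    mot_path <- file.path(dir, paste0(subj$id, "_motion.txt"))
    art_path <- file.path(dir, paste0(subj$id, "_artifacts.tsv"))
    ts <- data.frame(roi_id = rownames(subj$roi_series),
                     subj$roi_series, check.names = FALSE)
    colnames(ts) <- c("roi_id", paste0("vol", seq_len(ncol(subj$roi_series))))
    utils::write.table(ts, ts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(format(subj$motion_params, digits = 10), mot_path,
                       sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    art <- data.frame(signal = rownames(subj$artifact_series),
                      subj$artifact_series, check.names = FALSE)
    colnames(art) <- c("signal", paste0("vol", seq_len(ncol(subj$artifact_series))))
    utils::write.table(art, art_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(id = subj$id, group = subj$group, sex = subj$sex,
               timeseries = basename(ts_path), motion = basename(mot_path),
               artifacts = basename(art_path))
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(spec)[!vapply(unclass(spec), is.matrix,
                                         logical(1))],
                   file.path(dir, "spec.yaml"))
  invisible(manifest_path)
}

#' Read an ROI-by-volume time-series TSV
#'
#' @param path TSV with a `roi_id` column followed by one column per volume.
#' @return ROI x T numeric matrix with ROI row names.
#' @export
read_timeseries_tsv <- function(path) {
  check_tsv_lines(path)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed file ", path, ": non-numeric values")
  dimnames(m) <- list(df[[1]], NULL)
  m
}

#' Read a six-column rigid-body motion parameter file
#'
#' Normalizes common dialects to the package convention: columns 1-3
#' translations in mm, columns 4-6 rotations in radians.
#'
#' @param path whitespace-delimited file, one row per volume, six columns.
#' @param dialect `"trans_rot"` (translations first, default) or
#'   `"rot_trans"` (rotations first).
#' @param rotation_units `"radians"` (default) or `"degrees"`.
#' @return T x 6 numeric matrix in translations-then-rotations order,
#'   rotations in radians.
#' @export
read_motion_file <- function(path, dialect = c("trans_rot", "rot_trans"),
                             rotation_units = c("radians", "degrees")) {
  dialect <- match.arg(dialect)
  rotation_units <- match.arg(rotation_units)
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("malformed motion file ", path, ": expected 6 columns")
  if (!is.numeric(m)) stop("malformed motion file ", path, ": non-numeric")
  if (dialect == "rot_trans") m <- m[, c(4:6, 1:3), drop = FALSE]
  if (rotation_units == "degrees") {
    m[, 4:6] <- m[, 4:6] * pi / 180
  }
  dimnames(m) <- NULL
  m
}

#' Read a partition TSV
#'
#' @param path TSV with columns `roi_id`, `network_label`, `is_lesion`.
#' @param network_names optional names for the K networks.
#' @return a [network_partition()].
#' @export
read_partition_tsv <- function(path, network_names = NULL) {
  check_tsv_lines(path)
  df <- utils::read.delim(path)
  network_partition(df$network_label, network_names,
                    which(df$is_lesion == 1))
}

#' Read a cohort from a manifest
#'
#' @param manifest_path manifest TSV written by [write_cohort()]; file paths
#'   are resolved relative to its directory.
#' @param motion_dialect,motion_units forwarded to [read_motion_file()].
#' @return list of `subject_record`s.
#' @export
read_cohort <- function(manifest_path, motion_dialect = "trans_rot",
                        motion_units = "radians") {
  check_tsv_lines(manifest_path)
  manifest <- utils::read.delim(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    art <- read_timeseries_tsv(file.path(base, row$artifacts))
    structure(list(
      roi_series = read_timeseries_tsv(file.path(base, row$timeseries)),
      motion_params = read_motion_file(file.path(base, row$motion),
                                       motion_dialect, motion_units),
      artifact_series = art,
      group = row$group, sex = row$sex, id = row$id),
      class = "subject_record")
  })
}

#' Write a connectivity matrix as square and long-format TSVs
#'
#' @param conn a `connectivity_matrix`.
#' @param path output path for the square matrix; the long-format edge
#'   table goes to `<path base>_edges.tsv`.
#' @export
write_connectivity_tsv <- function(conn, path) {
  z <- conn$z
  utils::write.table(data.frame(roi_id = rownames(z), z,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  long <- data.frame(roi_a = rownames(z)[ut[, 1]],
                     roi_b = colnames(z)[ut[, 2]],
                     z = z[ut], eff_df = conn$eff_df)
  utils::write.table(long, sub("\\.tsv$", "_edges.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
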