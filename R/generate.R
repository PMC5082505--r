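# Synthetic subject and cohort generation.

# K x K correlation matrix of latent innovations: baseline cross-network
# correlation, patient deltas applied on the correlation scale, projected
# back to a valid correlation matrix (eigenvalue floor, re-normalized).
latent_correlation <- function(spec, group) {
  k <- spec$n_networks
  c_mat <- matrix(spec$base_rho, k, k)
  diag(c_mat) <- 1
  if (identical(group, "patient")) {
    roles <- spec$network_roles
    tp <- c(roles[["thalamic"]], roles[["precuneus"]])
    df <- c(roles[["DMN"]], roles[["FEN"]])
    c_mat[tp[1], tp[2]] <- c_mat[tp[2], tp[1]] <- c_mat[tp[1], tp[2]] - spec$delta_tp
    c_mat[df[1], df[2]] <- c_mat[df[2], df[1]] <- c_mat[df[1], df[2]] + spec$delta_df
  }
  c_mat[] <- pmin(pmax(c_mat, -0.999), 0.999)
  diag(c_mat) <- 1
  eig <- eigen(c_mat, symmetric = TRUE)
  if (min(eig$values) < 1e-6) {
    vals <- pmax(eig$values, 1e-6)
    c_mat <- eig$vectors %*% (vals * t(eig$vectors))
    d <- sqrt(diag(c_mat))
    c_mat <- c_mat / tcrossprod(d)
  }
  c_mat
}

# Stationary AR(1) latent signals with innovation correlation c_mat;
# unit marginal variance, cross-network correlation equal to c_mat.
ar1_latents <- function(n_volumes, phi, c_mat) {
  k <- ncol(c_mat)
  eig <- eigen(c_mat, symmetric = TRUE)
  root <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  innov <- matrix(stats::rnorm(n_volumes * k), n_volumes, k) %*% root
  g <- matrix(0, n_volumes, k)
  g[1, ] <- innov[1, ]
  s <- sqrt(1 - phi^2)
  for (t in 2:n_volumes) g[t, ] <- phi * g[t - 1, ] + s * innov[t, ]
  g
}

ar1_series <- function(n, phi) {
  x <- numeric(n)
  innov <- stats::rnorm(n)
  x[1] <- innov[1]
  s <- sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + s * innov[t]
  x
}

# Rigid-body motion trace: slow random-walk drift in all six parameters,
# with occasional translation jumps ("spikes"). Rotation step sizes are
# scaled by a nominal 80 mm head radius so rotations and translations
# contribute comparably to relative displacement.
generate_motion <- function(spec) {
  t_len <- spec$n_volumes
  sd_tr <- spec$baseline_rd / sqrt(6)
  sd_rot <- spec$baseline_rd / (80 * sqrt(6))
  steps <- cbind(matrix(stats::rnorm(3 * t_len, sd = sd_tr), t_len, 3),
                 matrix(stats::rnorm(3 * t_len, sd = sd_rot), t_len, 3))
  spikes <- stats::runif(t_len) < spec$spike_rate
  spikes[1] <- FALSE
  if (any(spikes)) {
    n_sp <- sum(spikes)
    dir <- matrix(stats::rnorm(3 * n_sp), n_sp, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    steps[spikes, 1:3] <- steps[spikes, 1:3] + spec$spike_amp * dir
  }
  steps[1, ] <- 0
  list(params = apply(steps, 2, cumsum), spikes = spikes)
}

# Artifact proxies (white matter, CSF, whole brain): low-pass filtered
# noise plus the motion spike indicator scaled by spike_amp, so the
# confound model has both slow physiological drift and spike structure
# to remove.
generate_artifacts <- function(spec, spikes) {
  t_len <- spec$n_volumes
  out <- matrix(0, 3, t_len,
                dimnames = list(c("white_matter", "csf", "whole_brain"), NULL))
  for (j in 1:3) {
    lp <- stats::filter(stats::rnorm(t_len + 8), rep(1 / 5, 5), sides = 1)
    lp <- as.numeric(lp[-seq_len(8)])
    out[j, ] <- lp / stats::sd(lp) + as.numeric(spikes) * spec$spike_amp
  }
  out
}

#' Generate one synthetic subject
#'
#' ROI series follow \eqn{x_i(t) = a_i g_{k(i)}(t) + g G(t) + \epsilon_i(t)}
#' with AR(1) network latents (innovations correlated across networks),
#' an independent AR(1) global signal G, and white noise. Patients receive
#' the effect deltas described in [cohort_spec()]; lesion-ROI *signal*
#' components are attenuated by `alpha_lesion` while noise is untouched.
#'
#' @param spec a [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @param sex `"M"` or `"F"`.
#' @param seed integer seed; identical `(spec, group, sex, seed)` give
#'   bit-identical records.
#' @param id subject identifier string.
#' @return a `subject_record`: list with `roi_series` (ROI x T matrix),
#'   `motion_params` (T x 6: translations mm, rotations radians),
#'   `artifact_series` (3 x T), `group`, `sex`, `id`.
#' @export
generate_subject <- function(spec, group = c("control", "patient"),
                             sex = c("M", "F"), seed = spec$seed,
                             id = paste0(group, "_", seed)) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  sex <- match.arg(sex)
  with_seed(seed, {
    part <- generate_partition(spec)
    c_mat <- latent_correlation(spec, group)
    lat <- ar1_latents(spec$n_volumes, spec$latent_ar, c_mat)
    glob <- ar1_series(spec$n_volumes, spec$latent_ar)
    a <- rep(spec$within_coupling, spec$n_rois)
    if (group == "patient") a <- a + spec$delta_within
    signal <- t(lat[, part$labels, drop = FALSE]) * a +
      matrix(glob, spec$n_rois, spec$n_volumes, byrow = TRUE) *
        spec$global_coupling
    if (group == "patient" && length(spec$lesion_rois) > 0) {
      signal[spec$lesion_rois, ] <- signal[spec$lesion_rois, ] *
        (1 - spec$alpha_lesion)
    }
    noise <- matrix(stats::rnorm(spec$n_rois * spec$n_volumes,
                                 sd = spec$noise_sd),
                    spec$n_rois, spec$n_volumes)
    roi_series <- signal + noise
    rownames(roi_series) <- paste0("roi", seq_len(spec$n_rois))
    mot <- generate_motion(spec)
    art <- generate_artifacts(spec, mot$spikes)
    structure(list(roi_series = roi_series, motion_params = mot$params,
                   artifact_series = art, group = group, sex = sex, id = id),
              class = "subject_record")
  })
}

#' Generate a control/patient cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the whole cohort is reproducible. Sexes are interleaved to approximate
#' `sex_ratio` within each group.
#'
#' @param spec a [cohort_spec()].
#' @param n_controls,n_patients cohort sizes (each >= 1).
#' @param seed master seed (default `spec$seed`).
#' @param sex_ratio target fraction of males per group.
#' @return list of `subject_record`s, controls first.
#' @export
generate_cohort <- function(spec, n_controls, n_patients, seed = spec$seed,
                            sex_ratio = 0.5) {
  stopifnot(n_controls >= 1, n_patients >= 1)
  groups <- c(rep("control", n_controls), rep("patient", n_patients))
  make_sexes <- function(n) {
    n_m <- round(sex_ratio * n)
    sexes <- rep("F", n)
    if (n_m > 0) sexes[seq(1, by = 2, length.out = min(n_m, ceiling(n / 2)))] <- "M"
    extra <- n_m - ceiling(n / 2)
    if (extra > 0) sexes[seq(2, by = 2, length.out = extra)] <- "M"
    sexes
  }
  sexes <- c(make_sexes(n_controls), make_sexes(n_patients))
  ids <- c(sprintf("ctrl%02d", seq_len(n_controls)),
           sprintf("pat%02d", seq_len(n_patients)))
  lapply(seq_along(groups), function(i) {
    generate_subject(spec, groups[i], sexes[i],
                     seed = derive_seed(seed, i), id = ids[i])
  })
}

#' Generate a voxel block around a reference series
#'
#' Fixture for the SVD time-series extractor: each voxel equals
#' `+/- series + noise`, with the sign pattern given by `sign_flips`.
#'
#' @param series length-T reference signal.
#' @param n_voxels number of voxels (>= 1).
#' @param voxel_noise_sd noise standard deviation.
#' @param sign_flips logical vector recycled over voxels; `TRUE` negates.
#' @param seed integer seed.
#' @return `n_voxels` x T matrix.
#' @export
generate_voxel_block <- function(series, n_voxels, voxel_noise_sd = 0,
                                 sign_flips = FALSE, seed = 1L) {
  stopifnot(n_voxels >= 1)
  series <- as.numeric(series)
  signs <- ifelse(rep_len(as.logical(sign_flips), n_voxels), -1, 1)
  with_seed(seed, {
    base <- outer(signs, series)
    base + matrix(stats::rnorm(n_voxels * length(series),
                               sd = voxel_noise_sd),
                  n_voxels, length(series))
  })
}
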