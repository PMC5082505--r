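#' Specify a synthetic resting-state cohort
#'
#' Defines the generative model used to build control and patient cohorts
#' with the statistical structure the connectivity analyses assume: each of
#' K functional networks has a latent AR(1) Gaussian signal; cross-network
#' dependence is induced by correlating latent innovations; every ROI loads
#' on its network latent and on a shared global signal, plus white noise.
#'
#' Default couplings are calibrated so that, at the desk-scale effective
#' degrees of freedom of the full analysis (about 40), control cohorts show
#' mean within-network edge Z near 1.05 and between-network Z near 0.2, and
#' patients mean within-network Z near 1.15 — the magnitudes reported for
#' real lesion cohorts — so within- and between-network edge distributions
#' overlap realistically at sparse graph thresholds.
#'
#' Patients differ from controls by (i) attenuation of the signal component
#' of lesion-ROI series by `alpha_lesion` (noise unchanged, so lesion SNR and
#' hence lesion-network coupling drop), (ii) an increment `delta_within` to
#' every ROI's within-network loading (raising network segregation),
#' (iii) a decrement `delta_tp` to the thalamic-precuneus latent correlation,
#' and (iv) an increment `delta_df` to the DMN-frontoexecutive latent
#' correlation. Effect directions mirror the connectional/connectomic
#' diaschisis pattern reported after focal hippocampal lesions.
#'
#' @param n_rois number of ROIs.
#' @param partition_sizes integer vector, ROIs per network; must sum to
#'   `n_rois`. Its length sets the number of networks K.
#' @param n_volumes number of time points (volumes) per series.
#' @param tr repetition time, seconds.
#' @param latent_ar AR(1) coefficient of the network latents, in (-1, 1).
#' @param within_coupling loading of each ROI on its network latent.
#' @param global_coupling loading of each ROI on the shared global signal.
#' @param noise_sd standard deviation of ROI-level white noise.
#' @param base_rho baseline correlation between latent innovations of
#'   different networks.
#' @param network_roles named integer vector mapping the roles `"DMN"`,
#'   `"FEN"`, `"thalamic"`, `"precuneus"` to network indices; required
#'   whenever the corresponding patient effects are nonzero.
#' @param network_names optional character vector of K network names.
#' @param lesion_rois integer indices of the designated lesion ROIs
#'   (default: the first two ROIs of the DMN network).
#' @param alpha_lesion fraction in \[0, 1\] by which patients' lesion-ROI
#'   signal amplitude is attenuated.
#' @param delta_within patient increment to `within_coupling`.
#' @param delta_tp patient decrement of the thalamic-precuneus latent
#'   correlation.
#' @param delta_df patient increment of the DMN-FEN latent correlation.
#' @param baseline_rd typical per-volume relative displacement, mm.
#' @param spike_rate expected motion spikes per volume.
#' @param spike_amp spike translation amplitude, mm.
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_rois = 12, partition_sizes = c(3, 3, 3, 3),
#'                     n_volumes = 100)
#' part <- generate_partition(spec)
#' table(part$labels)
#' @export
cohort_spec <- function(n_rois = 120,
                        partition_sizes = rep(15L, 8L),
                        n_volumes = 148,
                        tr = 2,
                        latent_ar = 0.3,
                        within_coupling = 0.34,
                        global_coupling = 0.1,
                        noise_sd = 0.91,
                        base_rho = 0.15,
                        network_roles = c(DMN = 1L, FEN = 2L,
                                          thalamic = 3L, precuneus = 4L),
                        network_names = NULL,
                        lesion_rois = NULL,
                        alpha_lesion = 0.5,
                        delta_within = 0.029,
                        delta_tp = 0.1,
                        delta_df = 0.1,
                        baseline_rd = 0.1,
                        spike_rate = 0.05,
                        spike_amp = 1.0,
                        seed = 1L) {
  k <- length(partition_sizes)
  if (sum(partition_sizes) != n_rois) {
    stop("configuration error: partition_sizes must sum to n_rois (",
         sum(partition_sizes), " != ", n_rois, ")")
  }
  if (any(partition_sizes < 1)) stop("configuration error: empty network")
  if (abs(latent_ar) >= 1) stop("latent_ar must lie in (-1, 1)")
  if (alpha_lesion < 0 || alpha_lesion > 1) stop("alpha_lesion must be in [0, 1]")
  if (noise_sd < 0 || baseline_rd < 0 || spike_amp < 0 || spike_rate < 0) {
    stop("standard deviations, rates and amplitudes must be non-negative")
  }
  needed <- c(DMN = alpha_lesion != 0 || delta_df != 0,
              FEN = delta_df != 0,
              thalamic = delta_tp != 0,
              precuneus = delta_tp != 0)
  for (role in names(needed)[needed]) {
    idx <- network_roles[[role]] %||% NA_integer_
    if (is.na(idx) || idx < 1 || idx > k) {
      stop("network_roles must map '", role, "' to a valid network index ",
           "when its effect is nonzero")
    }
  }
  if (is.null(network_names)) {
    base <- c("DMN", "FEN", "thalamic", "precuneus")
    network_names <- paste0("net", seq_len(k))
    for (role in intersect(names(network_roles), base)) {
      idx <- network_roles[[role]]
      if (!is.na(idx) && idx >= 1 && idx <= k) network_names[idx] <- role
    }
  }
  stopifnot(length(network_names) == k)
  if (is.null(lesion_rois)) {
    dmn <- network_roles[["DMN"]]
    first_dmn <- sum(partition_sizes[seq_len(dmn - 1)]) + 1L
    lesion_rois <- first_dmn + seq_len(min(2L, partition_sizes[dmn])) - 1L
  }
  lesion_rois <- as.integer(lesion_rois)
  if (any(lesion_rois < 1 | lesion_rois > n_rois)) {
    stop("lesion_rois out of range")
  }
  structure(list(
    n_rois = as.integer(n_rois), partition_sizes = as.integer(partition_sizes),
    n_networks = as.integer(k), n_volumes = as.integer(n_volumes), tr = tr,
    latent_ar = latent_ar, within_coupling = within_coupling,
    global_coupling = global_coupling, noise_sd = noise_sd,
    base_rho = base_rho, network_roles = network_roles,
    network_names = network_names, lesion_rois = lesion_rois,
    alpha_lesion = alpha_lesion, delta_within = delta_within,
    delta_tp = delta_tp, delta_df = delta_df,
    baseline_rd = baseline_rd, spike_rate = spike_rate,
    spike_amp = spike_amp, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Build the ROI-to-network partition for a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return a `network_partition`: list with integer `labels` (one per ROI),
#'   `network_names`, and the designated `lesion_rois` set.
#' @export
generate_partition <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- rep.int(seq_len(spec$n_networks), spec$partition_sizes)
  network_partition(labels, spec$network_names, spec$lesion_rois)
}

#' Construct a network partition
#'
#' @param labels integer network label per ROI (values 1..K).
#' @param network_names optional character names, length K.
#' @param lesion_rois integer indices of lesion ROIs (possibly empty).
#' @export
network_partition <- function(labels, network_names = NULL,
                              lesion_rois = integer(0)) {
  labels <- as.integer(labels)
  k <- max(labels)
  if (!setequal(unique(labels), seq_len(k))) {
    stop("labels must use every network index 1..K")
  }
  if (is.null(network_names)) network_names <- paste0("net", seq_len(k))
  stopifnot(length(network_names) == k)
  lesion_rois <- as.integer(lesion_rois)
  if (any(lesion_rois < 1 | lesion_rois > length(labels))) {
    stop("lesion_rois out of range")
  }
  structure(list(labels = labels, n_networks = k,
                 network_names = network_names,
                 lesion_rois = lesion_rois),
            class = "network_partition")
}

#' Analytic within-minus-between correlation gap of the generative model
#'
#' For a control subject the model implies ROI-pair correlation
#' \eqn{(a^2 \rho_{kl} + g^2) / (a^2 + g^2 + \sigma^2)} where
#' \eqn{\rho_{kl}} is 1 within a network and `base_rho` between networks,
#' so the within-minus-between gap is
#' \eqn{a^2 (1 - \rho) / (a^2 + g^2 + \sigma^2)}.
#'
#' @param spec a [cohort_spec()].
#' @return the expected gap in Pearson correlation units.
#' @export
analytic_correlation_gap <- function(spec) {
  a2 <- spec$within_coupling^2
  tot <- a2 + spec$global_coupling^2 + spec$noise_sd^2
  a2 * (1 - spec$base_rho) / tot
}
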