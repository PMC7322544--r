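#' Generate synthetic ion-channel potency panels
#'
#' Draws per-compound latent log10 potencies for IKr, INa, ICaL and IKs,
#' log-uniformly over `ic50_range` (defaults span the observed extremes of
#' the packaged panels, 0.007-300 uM), then produces correlated PX and HTS
#' assay readings with multiplicative log-normal inter-assay scatter, an
#' independent per-cell chance of an `ND` (not determined) censoring, and
#' Hill coefficients uniform near 1. Deterministic given the seed.
#'
#' @param n Number of compounds.
#' @param ic50_range `c(low, high)` in uM for the log-uniform latent draw.
#' @param nd_prob Per-cell probability of ND censoring.
#' @param hill_range Uniform range for Hill coefficients.
#' @param inter_assay_sd Log10 sd of the PX/HTS disagreement (0 makes the
#'   platforms identical per channel).
#' @param seed Integer seed.
#' @return List of class `qts_synth_panels`: `panel` (long data.frame:
#'   compound, channel, assay, ic50, hill, status) and `latent` (matrix of
#'   latent log10 IC50s, one row per compound).
#' @export
synth_compound_panels <- function(n = 73, ic50_range = c(0.007, 300),
                                  nd_prob = 0.2, hill_range = c(0.8, 1.2),
                                  inter_assay_sd = 0.3, seed = 1L) {
  stopifnot(n >= 1, ic50_range[1] > 0, ic50_range[2] > ic50_range[1],
            nd_prob >= 0, nd_prob <= 1, hill_range[1] > 0,
            hill_range[2] >= hill_range[1], inter_assay_sd >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  channels <- c("IKr", "INa", "ICaL", "IKs")
  lr <- log10(ic50_range)
  latent <- matrix(runif(n * length(channels), lr[1], lr[2]), nrow = n,
                   dimnames = list(NULL, channels))
  layout <- data.frame(
    channel = c("IKr", "INa", "IKs", "IKr", "INa", "ICaL"),
    assay   = c("PX", "PX", "PX", "HTS", "HTS", "HTS"),
    stringsAsFactors = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    df <- layout
    df$compound <- i
    df$ic50 <- 10^(latent[i, df$channel] +
                     rnorm(nrow(df), 0, inter_assay_sd))
    df$hill <- runif(nrow(df), hill_range[1], hill_range[2])
    nd <- runif(nrow(df)) < nd_prob
    df$status <- ifelse(nd, "ND", "measured")
    df$ic50[nd] <- NA_real_
    df$hill[nd] <- NA_real_
    rows[[i]] <- df
  }
  panel <- do.call(rbind, rows)[, c("compound", "channel", "assay",
                                    "ic50", "hill", "status")]
  structure(list(panel = panel, latent = latent),
            class = "qts_synth_panels")
}

# block map for one synthetic compound/approach (same channel sources as
# assemble_drug_block on the packaged panels)
synth_block <- function(panels, compound, approach = c("PX", "HTS")) {
  approach <- match.arg(approach)
  pick <- if (approach == "PX") {
    list(IKr = c("PX", "IKr"), IKs = c("PX", "IKs"),
         INa = c("PX", "INa"), ICaL = c("HTS", "ICaL"))
  } else {
    list(IKr = c("HTS", "IKr"), INa = c("HTS", "INa"),
         ICaL = c("HTS", "ICaL"))
  }
  p <- panels$panel
  block <- list()
  for (ch in names(pick)) {
    row <- p[p$compound == compound & p$assay == pick[[ch]][1] &
               p$channel == pick[[ch]][2], , drop = FALSE]
    if (nrow(row) == 1L && row$status == "measured") {
      block[[ch]] <- list(ic50 = row$ic50, hill = row$hill)
    }
  }
  block
}

#' Generate synthetic in-vivo QTc outcomes with known ground truth
#'
#' Emulates the two qualitative mechanisms the margin and reclassification
#' stages exploit: the QTc EC5 of a prolonging compound is a fixed multiple
#' of its hERG (PX IKr latent) IC50 with multiplicative log-normal noise,
#' and compounds whose latent ICaL potency lies within `ca_balance_fold` of
#' their IKr potency are non-prolonging (calcium-balanced mixed blockers).
#' Non-prolonging compounds receive a censored highest-tested concentration
#' drawn below their hERG IC20.
#'
#' @param panels A `qts_synth_panels`.
#' @param margin_c True EC5 = `margin_c` x hERG IC50 (default 0.3).
#' @param noise_sd Log10 sd of the outcome noise.
#' @param ca_balance_fold Fold window that flips a compound to
#'   non-prolonging.
#' @param censor_offset_log10 Mean log10 distance of the censored Cmax
#'   below the hERG IC20.
#' @param seed Integer seed.
#' @return Data.frame (compound, positive, qtc_ec5, cmax_noeffect,
#'   true_ec5, mechanism) with the generator parameters as attribute
#'   `"ground_truth"`.
#' @export
synth_invivo_outcomes <- function(panels, margin_c = 0.3, noise_sd = 0.25,
                                  ca_balance_fold = 2,
                                  censor_offset_log10 = 0.5, seed = 1L) {
  stopifnot(inherits(panels, "qts_synth_panels"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) + 1L)
  n <- nrow(panels$latent)
  herg <- 10^panels$latent[, "IKr"]
  ca <- 10^panels$latent[, "ICaL"]
  balanced <- abs(panels$latent[, "ICaL"] - panels$latent[, "IKr"]) <=
    log10(ca_balance_fold)
  out <- data.frame(compound = seq_len(n), positive = !balanced,
                    qtc_ec5 = NA_real_, cmax_noeffect = NA_real_,
                    true_ec5 = margin_c * herg,
                    mechanism = ifelse(balanced, "ca_balanced",
                                       "herg_margin"))
  pos <- out$positive
  out$qtc_ec5[pos] <- out$true_ec5[pos] * 10^rnorm(sum(pos), 0, noise_sd)
  ic20 <- ic20_from_ic50(herg, 1)
  out$cmax_noeffect[!pos] <- ic20[!pos] *
    10^(-abs(rnorm(sum(!pos), censor_offset_log10, noise_sd)))
  attr(out, "ground_truth") <- list(margin_c = margin_c,
                                    noise_sd = noise_sd,
                                    ca_balance_fold = ca_balance_fold)
  out
}

#' Generate a tree-structured synthetic tPKPD training set
#'
#' Samples potency-like features and produces a log10 EC5 target from a
#' known two-regime piecewise-linear response surface (split on the hERG
#' pIC50) plus Gaussian noise, so that tree recovery, leave-one-out error
#' and pruning behaviour can be scored against the generator.
#'
#' @param n Number of training compounds.
#' @param noise_sd Gaussian noise sd in log10 units.
#' @param threshold Split location on `herg_pic50`.
#' @param seed Integer seed.
#' @return List of class `qts_synth_tpkpd`: `x` (features), `y` (targets),
#'   `truth` (split feature/threshold and per-regime coefficients,
#'   noiseless targets).
#' @export
synth_tpkpd_dataset <- function(n = 80, noise_sd = 0.15, threshold = 0,
                                seed = 1L) {
  stopifnot(n >= 4)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) + 2L)
  x <- data.frame(herg_pic50 = runif(n, -2.5, 2.5),
                  ca_pic50 = runif(n, -2.5, 1),
                  na_pic50 = runif(n, -2.5, 1))
  low <- x$herg_pic50 <= threshold
  y0 <- ifelse(low,
               0.8 - 0.25 * x$herg_pic50,
               0.2 - 0.9 * x$herg_pic50 + 0.3 * x$ca_pic50)
  y <- y0 + rnorm(n, 0, noise_sd)
  truth <- list(split_feature = "herg_pic50", threshold = threshold,
                low_regime = c(intercept = 0.8, herg_pic50 = -0.25),
                high_regime = c(intercept = 0.2, herg_pic50 = -0.9,
                                ca_pic50 = 0.3),
                y_noiseless = y0, noise_sd = noise_sd)
  structure(list(x = x, y = y, truth = truth), class = "qts_synth_tpkpd")
}

half_cos_rise <- function(t, t_start, dur, from, to) {
  s <- (t - t_start) / dur
  ifelse(t < t_start, from,
         ifelse(t > t_start + dur, to,
                from + (to - from) * (1 - cos(pi * s)) / 2))
}

#' Generate a parametric action-potential and calcium-transient waveform
#'
#' Closed-form single-beat traces whose APD90 and CTD90 (measured from the
#' maximum upstroke rate, per [compute_biomarkers()]) equal the requested
#' values by construction: a half-cosine upstroke (maximum slope at its
#' midpoint) followed by a linear repolarisation whose slope is chosen so
#' the 90% level is crossed exactly `apd90` after the upstroke reference,
#' and the analogous shape for the calcium transient. Optionally adds an
#' early-afterdepolarisation bump during late repolarisation or a
#' repolarisation-failure plateau.
#'
#' @param apd90,ctd90 Requested durations (ms).
#' @param cl Cycle length (ms).
#' @param dt Sampling interval (ms).
#' @param rmp,vpeak Resting and peak voltage (mV).
#' @param ca_dia,ca_amp Diastolic level and amplitude of the transient
#'   (arbitrary concentration units).
#' @param ead One of `"none"`, `"bump"` (adds a +`ead_amp` mV deflection at
#'   80% repolarisation) or `"fail"` (voltage pinned at -20 mV from 60%
#'   repolarisation onward).
#' @param ead_amp Bump amplitude (mV).
#' @return A `qts_trace` data.frame (`time`, `v`, `cai`).
#' @export
synth_ap_trace <- function(apd90 = 270, ctd90 = 300, cl = 1000, dt = 0.2,
                           rmp = -85, vpeak = 40, ca_dia = 0.1,
                           ca_amp = 0.9, ead = c("none", "bump", "fail"),
                           ead_amp = 15) {
  ead <- match.arg(ead)
  stopifnot(apd90 > 0, ctd90 >= 0, vpeak > rmp, ca_amp > 0)
  if (apd90 >= 0.85 * cl || ctd90 >= 0.85 * cl) {
    stop("requested durations do not fit in the cycle", call. = FALSE)
  }
  t0 <- 10; rise <- 2
  time <- seq(0, cl, by = dt)
  amp <- vpeak - rmp
  t_ref <- t0 + rise / 2               # max dV/dt of the half-cosine rise
  t_peak <- t0 + rise
  level90 <- rmp + 0.1 * amp
  t90 <- t_ref + apd90
  stopifnot(t90 > t_peak)
  slope <- (vpeak - level90) / (t90 - t_peak)
  v <- half_cos_rise(time, t0, rise, rmp, vpeak)
  decay <- time > t_peak
  v[decay] <- pmax(rmp, vpeak - slope * (time[decay] - t_peak))
  if (ead == "bump") {
    t80 <- t_peak + (vpeak - (rmp + 0.2 * amp)) / slope
    v <- v + ead_amp * exp(-0.5 * ((time - t80) / 6)^2) *
      as.numeric(time > t_peak)
  } else if (ead == "fail") {
    t60 <- t_peak + (vpeak - (rmp + 0.4 * amp)) / slope
    v[time >= t60] <- pmax(v[time >= t60], -20)
  }

  ca_t0 <- t0 + 2; ca_rise <- 20
  ca_ref <- ca_t0 + ca_rise / 2
  ca_peak_t <- ca_t0 + ca_rise
  ca_level90 <- ca_dia + 0.1 * ca_amp
  ca_t90 <- ca_ref + ctd90
  cai <- half_cos_rise(time, ca_t0, ca_rise, ca_dia, ca_dia + ca_amp)
  if (ca_t90 > ca_peak_t) {
    ca_slope <- (ca_amp - 0.1 * ca_amp) / (ca_t90 - ca_peak_t)
    cd <- time > ca_peak_t
    cai[cd] <- pmax(ca_dia, ca_dia + ca_amp - ca_slope * (time[cd] - ca_peak_t))
  } else {
    cai[time > ca_peak_t] <- ca_dia    # degenerate: immediate return
  }
  tr <- data.frame(time = time, v = v, cai = cai)
  class(tr) <- c("qts_trace", "data.frame")
  tr
}
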