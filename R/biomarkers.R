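#' Abnormality detection thresholds
#'
#' The screening thresholds are not biophysical constants; they are
#' operational settings and can be tuned per study.
#'
#' @param depol_dvdt_min Minimum upstroke velocity (mV/ms) for a beat to
#'   count as elicited.
#' @param depol_vpeak_min Minimum peak voltage (mV).
#' @param repol_fail_v Voltage (mV) above which the cell is considered not
#'   repolarised at cycle end.
#' @param ead_dvdt Sustained positive dV/dt (mV/ms) during late
#'   repolarisation that flags an early afterdepolarisation.
#' @param ead_min_dur Minimum duration (ms) of that positive slope.
#' @param ead_v_range Voltage window (mV) in which the EAD detector is
#'   active (below the plateau, above the resting range).
#' @return List of thresholds.
#' @export
abnormality_control <- function(depol_dvdt_min = 10, depol_vpeak_min = 0,
                                repol_fail_v = -40, ead_dvdt = 0.01,
                                ead_min_dur = 2, ead_v_range = c(-70, 0)) {
  list(depol_dvdt_min = depol_dvdt_min, depol_vpeak_min = depol_vpeak_min,
       repol_fail_v = repol_fail_v, ead_dvdt = ead_dvdt,
       ead_min_dur = ead_min_dur, ead_v_range = ead_v_range)
}

trace_dvdt <- function(time, v) {
  n <- length(time)
  dv <- diff(v) / diff(time)
  c(dv[1], (dv[-1] + dv[-(n - 1)]) / 2, dv[n - 1])
}

# first linear-interpolated downward crossing of `level` after index `from`
cross_down <- function(time, v, level, from) {
  idx <- seq(from, length(v) - 1L)
  hit <- idx[v[idx] > level & v[idx + 1L] <= level]
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  time[i] + (v[i] - level) / (v[i] - v[i + 1L]) * (time[i + 1L] - time[i])
}

#' Detect repolarisation and depolarisation abnormalities
#'
#' A beat is depolarisation-abnormal when no action potential is elicited
#' (peak voltage or maximum upstroke velocity below threshold).
#' Repolarisation is abnormal when the membrane fails to return below the
#' configured level by cycle end, or when a sustained positive voltage
#' slope reappears during late repolarisation (an early
#' afterdepolarisation).
#'
#' @param trace Data.frame with columns `time` (ms), `v` (mV) and
#'   optionally `cai`.
#' @param control Thresholds from [abnormality_control()].
#' @return List with logical elements `repol_abnormal`, `depol_abnormal`.
#' @export
detect_abnormalities <- function(trace, control = abnormality_control()) {
  time <- trace$time; v <- trace$v
  dvdt <- trace_dvdt(time, v)
  vpeak <- max(v)
  depol <- max(dvdt) < control$depol_dvdt_min || vpeak < control$depol_vpeak_min
  repol <- FALSE
  if (!depol) {
    if (v[length(v)] > control$repol_fail_v) repol <- TRUE
    if (!repol) {
      ipeak <- which.max(v)
      after <- seq(ipeak, length(v))
      active <- v[after] < control$ead_v_range[2] &
        v[after] > control$ead_v_range[1] &
        dvdt[after] > control$ead_dvdt
      # longest consecutive run of positive-slope samples in the window
      r <- rle(active)
      if (any(r$values)) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          dur <- time[after[ends[k]]] - time[after[starts[k]]]
          if (dur >= control$ead_min_dur) { repol <- TRUE; break }
        }
      }
    }
  }
  list(repol_abnormal = repol, depol_abnormal = depol)
}

#' Extract action-potential and calcium-transient biomarkers from one beat
#'
#' Durations are measured from the instant of maximum upstroke velocity
#' (dV/dt max for the AP, maximum d\[Ca\]/dt for the transient), which makes
#' them insensitive to stimulus artefacts. APDx is the time to x%
#' repolarisation of the amplitude (Vpeak - RMP); CTDx the time to x% decay
#' of the transient amplitude toward the pre-stimulus diastolic level. The
#' electromechanical-window surrogate is `emw = ctd90 - apd90` by
#' definition.
#'
#' @param trace Data.frame with `time` (ms), `v` (mV), `cai` (intracellular
#'   calcium; any consistent unit).
#' @param control Thresholds from [abnormality_control()].
#' @return List of class `qts_biomarkers`: apd50, apd90, ctd50, ctd90, emw,
#'   dvdt_max, rmp, vpeak, repol_abnormal, depol_abnormal.
#' @export
compute_biomarkers <- function(trace, control = abnormality_control()) {
  stopifnot(all(c("time", "v") %in% names(trace)))
  time <- trace$time; v <- trace$v
  stopifnot(length(time) >= 5, !is.unsorted(time, strictly = TRUE))
  ab <- detect_abnormalities(trace, control)
  out <- list(apd50 = NA_real_, apd90 = NA_real_, ctd50 = NA_real_,
              ctd90 = NA_real_, emw = NA_real_,
              dvdt_max = NA_real_, rmp = NA_real_, vpeak = NA_real_,
              repol_abnormal = ab$repol_abnormal,
              depol_abnormal = ab$depol_abnormal)
  class(out) <- "qts_biomarkers"
  if (ab$depol_abnormal) return(out)

  dvdt <- trace_dvdt(time, v)
  iup <- which.max(dvdt)
  t_up <- time[iup]
  pre <- which(time < t_up)
  if (!length(pre)) pre <- which(time >= max(time) - 10)
  out$rmp <- min(v[pre])
  out$vpeak <- max(v)
  out$dvdt_max <- dvdt[iup]
  amp <- out$vpeak - out$rmp
  ipeak <- which.max(v)
  for (x in c(50, 90)) {
    level <- out$rmp + (1 - x / 100) * amp
    tc <- cross_down(time, v, level, ipeak)
    out[[paste0("apd", x)]] <- if (is.na(tc)) NA_real_ else tc - t_up
  }

  if (!is.null(trace$cai)) {
    cai <- trace$cai
    dca <- trace_dvdt(time, cai)
    ica_up <- which.max(dca)
    t_ca <- time[ica_up]
    pre_ca <- which(time < t_ca)
    if (!length(pre_ca)) pre_ca <- 1L
    dia <- min(cai[pre_ca])
    ca_peak_i <- which.max(cai)
    ca_amp <- cai[ca_peak_i] - dia
    if (ca_amp > 0) {
      for (x in c(50, 90)) {
        level <- dia + (1 - x / 100) * ca_amp
        tc <- cross_down(time, cai, level, ca_peak_i)
        out[[paste0("ctd", x)]] <- if (is.na(tc)) NA_real_ else tc - t_ca
      }
    }
  }
  out$emw <- out$ctd90 - out$apd90
  if (!any(is.na(c(out$apd50, out$apd90)))) {
    stopifnot(out$apd50 <= out$apd90 + 1e-9)
  }
  out
}

#' @export
print.qts_biomarkers <- function(x, ...) {
  cat(sprintf(paste0("APD50 %.1f  APD90 %.1f  CTD50 %.1f  CTD90 %.1f  ",
                     "EMw %.1f ms\n"),
              x$apd50, x$apd90, x$ctd50, x$ctd90, x$emw))
  cat(sprintf("dV/dt max %.1f mV/ms  RMP %.1f mV  Vpeak %.1f mV\n",
              x$dvdt_max, x$rmp, x$vpeak))
  if (x$repol_abnormal) cat("repolarisation abnormality flagged\n")
  if (x$depol_abnormal) cat("depolarisation abnormality flagged\n")
  invisible(x)
}

#' Average biomarkers across a model population
#'
#' Means are taken over the population members without abnormality flags,
#' mirroring the exclusion of abnormal virtual cells from averaged
#' endpoints; the abnormal count is carried alongside.
#'
#' @param sets List of `qts_biomarkers`.
#' @param conc Drug concentration (uM) the sets were simulated at.
#' @return List of class `qts_popsummary`: `concentration`, `n_total`,
#'   `n_abnormal`, `all_abnormal`, and `means` (named list; `NA`s when
#'   every member is abnormal).
#' @export
summarize_population <- function(sets, conc) {
  stopifnot(length(sets) >= 1)
  fields <- c("apd50", "apd90", "ctd50", "ctd90", "emw",
              "dvdt_max", "rmp", "vpeak")
  ok <- vapply(sets, function(s) !s$repol_abnormal && !s$depol_abnormal,
               logical(1))
  means <- setNames(rep(NA_real_, length(fields)), fields)
  if (any(ok)) {
    for (f in fields) {
      vals <- vapply(sets[ok], function(s) s[[f]], numeric(1))
      means[[f]] <- mean(vals)
    }
  }
  structure(list(concentration = conc, n_total = length(sets),
                 n_abnormal = sum(!ok), all_abnormal = !any(ok),
                 means = as.list(means)),
            class = "qts_popsummary")
}

#' Collapse concentration-response changes into a directional call
#'
#' Relative changes versus the drug-free control are computed per
#' concentration; changes smaller than `threshold_pct` percent are treated
#' as flat. The ordered sequence of supra-threshold signs is collapsed to
#' arrow notation: `"up"`, `"down"`, `"down-up"`, `"up-down"` or `"flat"`.
#'
#' @param summaries List of `qts_popsummary` ordered by concentration; the
#'   first must be the control (concentration 0).
#' @param endpoint `"apd90"` or `"emw"` (any summarised biomarker allowed).
#' @param threshold_pct Flatness threshold in percent, default 5.
#' @return List of class `qts_direction`: `endpoint`, `direction`,
#'   `rel_change` (fractional changes by concentration).
#' @export
directional_effect <- function(summaries, endpoint, threshold_pct = 5) {
  stopifnot(length(summaries) >= 2)
  stopifnot(summaries[[1]]$concentration == 0)
  ctrl <- summaries[[1]]$means[[endpoint]]
  if (is.na(ctrl)) stop("control mean undefined for ", endpoint, call. = FALSE)
  conc <- vapply(summaries[-1], function(s) s$concentration, numeric(1))
  vals <- vapply(summaries[-1], function(s) s$means[[endpoint]], numeric(1))
  rel <- (vals - ctrl) / abs(ctrl)
  supra <- which(!is.na(rel) & abs(rel) >= threshold_pct / 100)
  signs <- sign(rel[supra])
  collapsed <- signs[c(TRUE, diff(signs) != 0)[seq_along(signs)]]
  direction <- if (!length(collapsed)) "flat" else
    paste(ifelse(collapsed > 0, "up", "down"), collapse = "-")
  structure(list(endpoint = endpoint, direction = direction,
                 rel_change = setNames(rel, conc),
                 threshold_pct = threshold_pct),
            class = "qts_direction")
}
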