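#' Concentration giving 20% channel block
#'
#' Under the Hill pore-block model `1 / (1 + (C/IC50)^h)`, 20% block occurs
#' at `IC50 * 4^(-1/h)`; at a Hill coefficient of 1 this is a quarter of the
#' IC50, and as `h` grows the IC20 approaches the IC50 (step-block limit).
#'
#' @param ic50 IC50 in uM (vectorised).
#' @param hill Hill coefficient(s), default 1.
#' @return IC20 in uM.
#' @export
ic20_from_ic50 <- function(ic50, hill = 1) {
  if (any(ic50 <= 0) || any(hill <= 0)) {
    stop("ic50 and hill must be positive", call. = FALSE)
  }
  ic50 * 4^(-1 / hill)
}

#' hERG/MK-499 safety-margin classification
#'
#' A compound with a defined in-vivo QTc EC5 is a true positive when the
#' channel IC20 lies below or within `fold`-fold of the EC5, otherwise a
#' false negative. A compound without in-vivo QTc prolongation is a true
#' negative when the IC20 exceeds the highest free plasma concentration
#' achieved, otherwise a false positive (a censored IC20 counts as exceeding
#' it; equality resolves to TN).
#'
#' @param ic20 IC20 in uM, or a censored value such as `">30"` (string), or
#'   a numeric with `ic20_censored = TRUE`.
#' @param outcome Outcome list as in [compound_record()] (`positive`,
#'   `qtc_ec5`, `cmax_noeffect`).
#' @param fold Margin width, default 5.
#' @param ic20_censored Logical; `TRUE` when `ic20` is a lower bound.
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
margin_rule <- function(ic20, outcome, fold = 5, ic20_censored = FALSE) {
  if (is.character(ic20)) {
    p <- parse_concentration(ic20)
    ic20 <- p$value
    ic20_censored <- p$censored
  }
  stopifnot(is.numeric(ic20), length(ic20) == 1L, ic20 > 0)
  if (outcome$positive) {
    if (ic20_censored) {
      if (ic20 <= fold * outcome$qtc_ec5) {
        stop("censored IC20 bound below the margin threshold is undecidable",
             call. = FALSE)
      }
      return("FN")
    }
    if (ic20 <= fold * outcome$qtc_ec5) "TP" else "FN"
  } else {
    if (ic20_censored || ic20 >= outcome$cmax_noeffect) "TN" else "FP"
  }
}

direction_has <- function(direction, what) {
  if (is.na(direction) || direction %in% c("NA", "")) return(NA)
  what %in% strsplit(direction, "-", fixed = TRUE)[[1]]
}

#' In-silico qualitative classification
#'
#' A compound is called positive in silico when the simulated APD90 shows a
#' supra-threshold increase and the simulated electromechanical window (EMw)
#' a supra-threshold decrease at one or more tested concentrations;
#' otherwise negative. Crossing with the in-vivo outcome yields the
#' confusion label.
#'
#' @param apd90_dir,emw_dir Direction strings (`"up"`, `"down"`, `"flat"`,
#'   `"down-up"`, `"up-down"`), from [directional_effect()] or the printed
#'   table.
#' @param outcome Outcome list (`positive`, ...).
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
insilico_rule <- function(apd90_dir, emw_dir, outcome) {
  up <- direction_has(apd90_dir, "up")
  down <- direction_has(emw_dir, "down")
  if (is.na(up) || is.na(down)) {
    stop("directional call unavailable", call. = FALSE)
  }
  pos <- up && down
  if (outcome$positive) {
    if (pos) "TP" else "FN"
  } else {
    if (pos) "FP" else "TN"
  }
}

#' tPKPD-based reclassification of in-silico calls
#'
#' Negative in-silico calls (TN/FN) are not re-analysed. A TP stays TP when
#' the tPKPD-predicted QTc EC5 lies within `fold`-fold of the observed EC5
#' or below it, and becomes FN on a larger over-prediction. An FP becomes TN
#' when the predicted EC5 exceeds the highest concentration achieved in vivo
#' without QTc prolongation, and stays FP otherwise; equality at the
#' censoring bound resolves to TN.
#'
#' @param label In-silico confusion label (`"TP"`, `"TN"`, `"FP"`, `"FN"`).
#' @param predicted_ec5 tPKPD-predicted QTc EC5 (uM).
#' @param outcome Outcome list.
#' @param fold Margin width, default 5.
#' @return Adjusted confusion label.
#' @export
tpkpd_reclassify <- function(label, predicted_ec5, outcome, fold = 5) {
  stopifnot(label %in% c("TP", "TN", "FP", "FN"))
  if (label %in% c("TN", "FN")) return(label)
  if (is.null(predicted_ec5) || is.na(predicted_ec5)) {
    stop("a tPKPD prediction is required to reclassify a positive call",
         call. = FALSE)
  }
  if (label == "TP") {
    if (predicted_ec5 < outcome$qtc_ec5 ||
        predicted_ec5 <= fold * outcome$qtc_ec5) "TP" else "FN"
  } else {                                # FP
    if (predicted_ec5 >= outcome$cmax_noeffect) "TN" else "FP"
  }
}

#' Tabulate confusion labels
#'
#' @param labels Character vector of `"TP"`, `"TN"`, `"FP"`, `"FN"` (other
#'   values rejected).
#' @return A `qts_confusion` object (tp/tn/fp/fn counts).
#' @export
confusion_matrix <- function(labels) {
  labels <- labels[!is.na(labels)]
  bad <- setdiff(unique(labels), c("TP", "TN", "FP", "FN"))
  if (length(bad)) {
    stop("invalid confusion labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(tp = sum(labels == "TP"), tn = sum(labels == "TN"),
                 fp = sum(labels == "FP"), fn = sum(labels == "FN")),
            class = "qts_confusion")
}

#' @export
print.qts_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (n = %d): TP %d  TN %d  FP %d  FN %d\n",
              x$tp + x$tn + x$fp + x$fn, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Round a proportion to a whole percentage, halves up
#'
#' Report-time rounding used for the headline percentages (72.5% prints as
#' 73%, matching conventional half-up presentation rather than R's
#' round-half-even).
#'
#' @param x Proportion(s) in \[0, 1\].
#' @return Integer percentage(s).
#' @export
percent_rounded <- function(x) as.integer(floor(100 * x + 0.5))

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Predictive metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy, each with a two-sided 95% interval (Wilson score by default,
#' Clopper-Pearson optionally). Ratios with a zero denominator are reported
#' as `NA` with `n = 0` rather than propagated.
#'
#' @param m A `qts_confusion`.
#' @param ci `"wilson"` or `"clopper-pearson"`.
#' @param conf Confidence level.
#' @return Data.frame with columns metric, x, n, estimate, lower, upper.
#' @export
predictive_metrics <- function(m, ci = c("wilson", "clopper-pearson"),
                               conf = 0.95) {
  stopifnot(inherits(m, "qts_confusion"))
  ci <- match.arg(ci)
  total <- m$tp + m$tn + m$fp + m$fn
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  defs <- list(sensitivity = c(m$tp, m$tp + m$fn),
               specificity = c(m$tn, m$tn + m$fp),
               ppv = c(m$tp, m$tp + m$fp),
               npv = c(m$tn, m$tn + m$fn),
               accuracy = c(m$tp + m$tn, total))
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      return(data.frame(metric = nm, x = 0L, n = 0L, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    }
    int <- if (ci == "wilson") wilson_ci(x, n, conf) else
      as.numeric(binom.test(x, n, conf.level = conf)$conf.int)
    data.frame(metric = nm, x = x, n = n, estimate = x / n,
               lower = int[1], upper = int[2])
  })
  do.call(rbind, rows)
}
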