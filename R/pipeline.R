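#' Derive confusion labels for one classification stage
#'
#' Produces per-compound confusion labels for a stage/approach pair either
#' by reading the printed label columns (`source = "printed"`) or by
#' re-applying the stage's rule to the printed numeric inputs
#' (`source = "rules"`): the IC20 margin rule for `"margin"`, the
#' APD90-up + EMw-down rule for `"insilico"`, and the 5-fold/censoring
#' reclassification of the in-silico labels for `"tpkpd"`. Compounds whose
#' required inputs are `NA`/`ND` (untested, or arrows not legible) yield
#' `NA` labels and are excluded from tabulation.
#'
#' @param dataset A `qts_dataset`.
#' @param stage `"margin"`, `"insilico"` or `"tpkpd"`.
#' @param approach `"PX"` or `"HTS"`.
#' @param source `"printed"` or `"rules"`.
#' @param fold Margin width for the rules, default 5.
#' @return Data.frame (nce, label).
#' @export
stage_labels <- function(dataset, stage = c("margin", "insilico", "tpkpd"),
                         approach = c("PX", "HTS"),
                         source = c("printed", "rules"), fold = 5) {
  stage <- match.arg(stage); approach <- match.arg(approach)
  source <- match.arg(source)
  a <- tolower(approach)
  tab <- if (stage == "margin") dataset$margin else dataset$insilico
  ids <- as.integer(tab$nce)
  printed_col <- switch(stage,
                        margin = paste0(a, "_label"),
                        insilico = paste0(a, "_insilico_label"),
                        tpkpd = paste0(a, "_adjusted_label"))
  labels <- rep(NA_character_, length(ids))
  if (source == "printed") {
    lab <- tab[[printed_col]]
    labels <- ifelse(lab %in% c("TP", "TN", "FP", "FN"), lab, NA_character_)
  } else {
    oc <- parse_concentration(tab$qtc_ec5)
    for (i in seq_along(ids)) {
      outcome <- list(positive = !oc$censored[i],
                      qtc_ec5 = if (!oc$censored[i]) oc$value[i] else NULL,
                      cmax_noeffect = if (oc$censored[i]) oc$value[i] else NULL)
      labels[i] <- switch(
        stage,
        margin = {
          cell <- tab[[if (approach == "PX") "px_herg_ic20" else
                         "hts_mk499_ic20"]][i]
          if (cell %in% c("ND", "NA")) NA_character_ else
            margin_rule(cell, outcome, fold)
        },
        insilico = {
          ad <- tab[[paste0(a, "_apd90_dir")]][i]
          ed <- tab[[paste0(a, "_emw_dir")]][i]
          if (ad == "NA" || ed == "NA") NA_character_ else
            insilico_rule(ad, ed, outcome)
        },
        tpkpd = {
          base <- tab[[paste0(a, "_insilico_label")]][i]
          pred <- tab[[paste0(a, "_tpkpd_ec5")]][i]
          if (!base %in% c("TP", "TN", "FP", "FN")) NA_character_ else
            tpkpd_reclassify(base, suppressWarnings(as.numeric(pred)),
                             outcome, fold)
        })
    }
  }
  data.frame(nce = ids, label = labels, stringsAsFactors = FALSE)
}

#' Evaluate every classification stage on a compound dataset
#'
#' Runs all three classification stages (hERG/MK-499 IC20 margin,
#' qualitative in-silico, tPKPD-adjusted) for both assay approaches,
#' tabulates confusion matrices, and computes predictive metrics with 95%
#' intervals. This is the desk-scale evaluation entry point: it consumes
#' the packaged printed inputs only and involves no ODE work.
#'
#' @param dataset A `qts_dataset` (default: the packaged tables).
#' @param source `"printed"` labels or `"rules"` re-derivation.
#' @param fold Margin width, default 5.
#' @return Nested list `result[[stage]][[approach]]` with elements
#'   `labels`, `confusion` and `metrics`, of class `qts_evaluation`.
#' @export
evaluate_dataset <- function(dataset = load_compound_dataset(),
                             source = c("printed", "rules"), fold = 5) {
  source <- match.arg(source)
  out <- list()
  for (stage in c("margin", "insilico", "tpkpd")) {
    out[[stage]] <- list()
    for (approach in c("PX", "HTS")) {
      lab <- stage_labels(dataset, stage, approach, source, fold)
      cm <- confusion_matrix(lab$label)
      out[[stage]][[approach]] <- list(labels = lab, confusion = cm,
                                       metrics = predictive_metrics(cm))
    }
  }
  structure(out, class = "qts_evaluation", source = source)
}

metric_pct <- function(evaluation, stage, approach, metric) {
  m <- evaluation[[stage]][[approach]]$metrics
  percent_rounded(m$estimate[m$metric == metric])
}

#' @export
print.qts_evaluation <- function(x, ...) {
  cat("Classification performance (", attr(x, "source"), " inputs)\n",
      sep = "")
  for (stage in names(x)) {
    for (approach in names(x[[stage]])) {
      cm <- x[[stage]][[approach]]$confusion
      cat(sprintf(
        paste0("  %-8s %-3s  n=%2d  TP %2d TN %2d FP %2d FN %2d  ",
               "acc %3d%%  sens %3d%%  spec %3d%%\n"),
        stage, approach, cm$tp + cm$tn + cm$fp + cm$fn,
        cm$tp, cm$tn, cm$fp, cm$fn,
        metric_pct(x, stage, approach, "accuracy"),
        metric_pct(x, stage, approach, "sensitivity"),
        metric_pct(x, stage, approach, "specificity")))
    }
  }
  invisible(x)
}

#' Simulate one compound and produce its directional calls
#'
#' Runs the population simulation for a drug block map over the
#' concentration grid and collapses the population-mean APD90 and EMw
#' responses into directional calls, the inputs of the in-silico
#' classification rule.
#'
#' @param block Drug block map (named list of `list(ic50, hill)`).
#' @param variants List of `qts_variant`s (the control population).
#' @param grid Concentration grid (uM), control first.
#' @param protocol Pacing protocol.
#' @param control_protocol Pacing protocol for the drug-free steady-state
#'   runs (defaults to `protocol`).
#' @param threshold_pct Directional flatness threshold (percent).
#' @param ... Passed to the simulator (tolerances, cell type).
#' @return List: `summaries` (per concentration), `apd90` and `emw`
#'   directional calls.
#' @export
insilico_profile <- function(block, variants, grid = concentration_grid(),
                             protocol = pacing_protocol(),
                             control_protocol = protocol,
                             threshold_pct = 5, ...) {
  summaries <- simulate_compound(block, variants, grid, protocol,
                                 control_protocol, ...)
  list(summaries = summaries,
       apd90 = directional_effect(summaries, "apd90", threshold_pct),
       emw = directional_effect(summaries, "emw", threshold_pct))
}

#' Export population summaries as a tidy table
#'
#' @param summaries List of `qts_popsummary`.
#' @return Data.frame with one row per concentration: n_total, n_abnormal
#'   and the population-mean biomarkers.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    cbind(data.frame(concentration = s$concentration, n_total = s$n_total,
                     n_abnormal = s$n_abnormal),
          as.data.frame(s$means))
  }))
}
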