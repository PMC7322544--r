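#' Negative log10 potency on the micromolar scale
#'
#' Potencies enter the tPKPD regression as `-log10(IC50 in uM)` (values in
#' nM are first converted to uM). Note this is 6 units away from the molar
#' pIC50 convention; the micromolar scale is used consistently for both the
#' potency features and the log EC5 target.
#'
#' @param ic50_um IC50 in uM (> 0, vectorised).
#' @return Dimensionless negative log10 potency.
#' @export
pic50 <- function(ic50_um) {
  if (any(!is.finite(ic50_um)) || any(ic50_um <= 0)) {
    stop("ic50 must be positive and finite", call. = FALSE)
  }
  -log10(ic50_um)
}

#' Feature specification for the tPKPD model
#'
#' Reads the per-approach feature layout (potency features and simulated
#' population-mean biomarkers at given concentration ranks) from a config
#' file. Rank 1 is the highest non-zero tested concentration. The shipped
#' default assigns, per approach: PX - IKr pIC50 + Hill, ICaL (fluorescence)
#' pIC50, INa pIC50, dV/dt max at rank 3, RMP at rank 4, Vpeak at rank 5,
#' APD50 at rank 3; HTS - MK-499 (IKr), INa and ICaL pIC50s, RMP at rank 5,
#' CTD50 at rank 2.
#'
#' @param path CSV config file; default the packaged `feature_spec.csv`.
#' @return Data.frame with columns approach, kind, assay, channel,
#'   transform, biomarker, rank.
#' @export
feature_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_spec.csv", package = "qtsilico")
  }
  spec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("approach", "kind", "assay", "channel", "transform",
            "biomarker", "rank")
  stopifnot(all(need %in% names(spec)))
  spec
}

rank_concentration <- function(grid, rank) {
  nz <- sort(grid[grid > 0], decreasing = TRUE)
  if (rank < 1 || rank > length(nz)) {
    stop("concentration rank ", rank, " outside the non-zero grid",
         call. = FALSE)
  }
  nz[rank]
}

#' Assemble one compound's tPKPD feature vector
#'
#' Concatenates transformed potencies (ND potencies imputed at `nd_ic50`)
#' and the specified population-mean simulated biomarkers at the specified
#' concentration ranks.
#'
#' @param record A `qts_compound`.
#' @param summaries List of `qts_popsummary` covering the grid (control
#'   first); may be `NULL` when the spec has no simulated features.
#' @param spec Feature specification rows (one approach's subset of
#'   [feature_spec()]).
#' @param nd_ic50 Imputation IC50 (uM) for ND potencies, default 300
#'   (10x the top tested concentration).
#' @return Named numeric feature vector.
#' @export
assemble_features <- function(record, summaries = NULL, spec,
                              nd_ic50 = 300) {
  vals <- numeric(0)
  grid <- if (!is.null(summaries)) {
    vapply(summaries, function(s) s$concentration, numeric(1))
  } else NULL
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    if (row$kind == "potency") {
      sel <- record$panel$assay == row$assay &
        record$panel$channel == row$channel
      prow <- record$panel[sel, , drop = FALSE]
      if (nrow(prow) != 1L) {
        stop("panel entry not found: ", row$assay, " ", row$channel,
             call. = FALSE)
      }
      if (prow$status == "NA" && row$channel == "IKr") {
        cond <- structure(
          class = c("qts_approach_inapplicable", "error", "condition"),
          list(message = paste0("compound ", record$id,
                                ": IKr potency not tested"), call = NULL))
        stop(cond)
      }
      nm <- tolower(paste(row$assay, row$channel, row$transform, sep = "_"))
      vals[nm] <- if (row$transform == "hill") {
        if (prow$status == "measured" && !is.na(prow$hill)) prow$hill else 1
      } else {
        ic50 <- if (prow$status == "measured") prow$ic50 else nd_ic50
        pic50(ic50)
      }
    } else {
      if (is.null(summaries)) {
        stop("simulated features requested but no summaries given",
             call. = FALSE)
      }
      conc <- rank_concentration(grid, row$rank)
      s <- summaries[[which(grid == conc)]]
      nm <- tolower(paste0(row$biomarker, "_rank", row$rank))
      vals[nm] <- s$means[[row$biomarker]]
    }
  }
  vals
}

#' Train the tPKPD M5 model on log10 QTc EC5
#'
#' Only compounds with a defined (non-censored) QTc EC5 may train the
#' regressor; censored compounds are scored at predict time for
#' reclassification but contribute no training signal. The returned fit
#' includes deterministic leave-one-out predictions.
#'
#' @param features Data.frame of numeric features (one row per compound).
#' @param log_ec5 Numeric log10 QTc EC5 (uM scale).
#' @param censored Logical vector; any `TRUE` entries are rejected.
#' @param control An [m5_control()].
#' @return List of class `qts_tpkpd`: `tree`, `loo` (held-out log10
#'   predictions), `features`, `log_ec5`.
#' @export
train_tpkpd <- function(features, log_ec5, censored = NULL,
                        control = m5_control()) {
  features <- as.data.frame(features)
  if (!is.null(censored) && any(censored)) {
    stop("censored outcomes cannot train the tPKPD regressor; ",
         "drop them before fitting", call. = FALSE)
  }
  if (length(log_ec5) < 10) {
    stop("at least 10 EC5-defined compounds are required", call. = FALSE)
  }
  tree <- m5tree(features, log_ec5, control)
  loo <- m5_loo(features, log_ec5, control)
  structure(list(tree = tree, loo = loo, features = features,
                 log_ec5 = log_ec5),
            class = "qts_tpkpd")
}

#' @export
print.qts_tpkpd <- function(x, ...) {
  rmse <- sqrt(mean((x$loo - x$log_ec5)^2))
  cat(sprintf("tPKPD M5 model: n = %d, LOO RMSE %.3f log10 units\n",
              length(x$log_ec5), rmse))
  print(x$tree)
  invisible(x)
}

#' Predict a free-plasma QTc EC5 from the tPKPD model
#'
#' @param model A `qts_tpkpd` (or bare `m5tree` fitted on log10 EC5).
#' @param features Data.frame (or named vector) of feature values.
#' @return Data.frame with `log_ec5` and the back-transformed `ec5` (uM).
#' @export
predict_ec5 <- function(model, features) {
  tree <- if (inherits(model, "qts_tpkpd")) model$tree else model
  if (is.numeric(features) && !is.data.frame(features)) {
    features <- as.data.frame(as.list(features))
  }
  lp <- predict(tree, features)
  data.frame(log_ec5 = lp, ec5 = 10^lp)
}

#' Predicted-versus-observed unity-line report
#'
#' For in-vivo-positive compounds, tabulates the fold distance of the
#' tPKPD-predicted EC5 from the observed EC5
#' (`max(pred/actual, actual/pred)`) and the fraction within `fold`-fold of
#' the unity line.
#'
#' @param predicted,actual Positive concentrations (uM).
#' @param ids Optional identifiers.
#' @param fold Band width, default 5.
#' @return Data.frame (id, predicted, actual, fold_ratio, within) with the
#'   fraction within the band as attribute `"fraction_within"`.
#' @export
unity_line_report <- function(predicted, actual, ids = seq_along(predicted),
                              fold = 5) {
  stopifnot(length(predicted) == length(actual),
            all(predicted > 0), all(actual > 0))
  fr <- pmax(predicted / actual, actual / predicted)
  out <- data.frame(id = ids, predicted = predicted, actual = actual,
                    fold_ratio = fr, within = fr <= fold)
  attr(out, "fraction_within") <- mean(out$within)
  out
}
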