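#' Parse a possibly censored concentration cell
#'
#' Table cells for in-vivo potency use a `">x"` convention: the QTc effect
#' threshold was not reached up to a free plasma concentration of `x` uM,
#' so the value is right-censored. This helper parses either a plain decimal
#' or a `">"`-prefixed decimal.
#'
#' @param text Character vector of cells, e.g. `"0.07"` or `">3"`.
#' @return A data.frame with columns `value` (numeric, uM) and `censored`
#'   (logical; `TRUE` means "no effect up to `value`").
#' @examples
#' parse_concentration(c(">3", "0.07"))
#' @export
parse_concentration <- function(text) {
  text <- as.character(text)
  out <- data.frame(value = rep(NA_real_, length(text)),
                    censored = rep(NA, length(text)))
  for (i in seq_along(text)) {
    cell <- gsub("[[:space:]]", "", text[i])
    if (is.na(cell) || !nzchar(cell)) {
      stop("cannot parse concentration cell ", i, ": ",
           deparse(text[i]), call. = FALSE)
    }
    cens <- startsWith(cell, ">")
    num <- if (cens) substring(cell, 2L) else cell
    if (!grepl("^[0-9]+(\\.[0-9]+)?$", num)) {
      stop("cannot parse concentration cell ", i, ": ",
           deparse(text[i]), call. = FALSE)
    }
    out$value[i] <- as.numeric(num)
    out$censored[i] <- cens
  }
  out
}

#' Load the packaged compound tables
#'
#' Reads the three packaged CSV transcriptions of the study's compound-level
#' tables: the ion-channel potency panels (PatchXpress hERG/hNav1.5/IKs and
#' high-throughput hCav1.2/MK-499/hNav1.5 IC50s), the hERG/MK-499 IC20
#' margin table with in-vivo QTc EC5 outcomes and printed confusion labels,
#' and the in-silico directional / tPKPD table. All printed cells are kept
#' verbatim as strings (`"ND"`, `"NA"`, `">x"` literals included) so that
#' re-serialisation is lossless; parsed numeric views are derived on demand.
#'
#' @param path Directory containing `table3_panels.csv`, `table4_margin.csv`
#'   and `table5_insilico_tpkpd.csv`. Defaults to the copies shipped with
#'   the package.
#' @return An object of class `qts_dataset`: a list with elements `panels`,
#'   `margin`, `insilico` (character data.frames as printed), and counts
#'   `n_px`, `n_hts`.
#' @export
load_compound_dataset <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "qtsilico")
  }
  files <- c(panels = "table3_panels.csv",
             margin = "table4_margin.csv",
             insilico = "table5_insilico_tpkpd.csv")
  tabs <- lapply(files, function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("fixture file not found: ", fp, call. = FALSE)
    read.csv(fp, colClasses = "character", check.names = FALSE,
             na.strings = character(0))
  })
  ds <- structure(tabs, class = "qts_dataset")
  ds$n_px <- sum(ds$insilico$px_insilico_label != "NA")
  ds$n_hts <- sum(ds$insilico$hts_insilico_label != "NA")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  for (nm in c("panels", "margin", "insilico")) {
    ids <- as.integer(ds[[nm]]$nce)
    if (anyDuplicated(ids)) {
      stop("duplicate compound ids in ", nm, " table", call. = FALSE)
    }
    if (nrow(ds[[nm]]) != 73L || !identical(sort(ids), 1:73)) {
      stop(nm, " table must contain compounds 1-73 exactly", call. = FALSE)
    }
  }
  # outcome/label consistency: negative labels go with censored outcomes
  oc <- parse_concentration(ds$insilico$qtc_ec5)
  for (col in c("px_insilico_label", "hts_insilico_label")) {
    lab <- ds$insilico[[col]]
    bad <- (lab %in% c("TN", "FP") & !oc$censored) |
      (lab %in% c("TP", "FN") & oc$censored)
    if (any(bad)) {
      stop("outcome/label inconsistency in ", col, " for compound(s) ",
           paste(ds$insilico$nce[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(ds)
}

#' Write a compound dataset back to CSV
#'
#' Serialises the three tables with the same columns and literal cell values
#' they were loaded with, so `write_compound_dataset(load_compound_dataset())`
#' round-trips byte-identically.
#'
#' @param dataset A `qts_dataset`.
#' @param path Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_compound_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "qts_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- c(panels = "table3_panels.csv",
             margin = "table4_margin.csv",
             insilico = "table5_insilico_tpkpd.csv")
  out <- character(0)
  for (nm in names(files)) {
    fp <- file.path(path, files[[nm]])
    write.csv(dataset[[nm]], fp, row.names = FALSE, quote = FALSE)
    out <- c(out, fp)
  }
  invisible(out)
}

#' @export
print.qts_dataset <- function(x, ...) {
  cat("Compound dataset: 73 NCEs\n")
  cat("  PatchXpress (PX) in-silico records:", x$n_px, "\n")
  cat("  High-throughput (HTS) in-silico records:", x$n_hts, "\n")
  invisible(x)
}

#' Extract one compound's record
#'
#' Assembles a single compound's ion-channel panel (typed and parsed),
#' in-vivo outcome, and the printed per-table values into one structure.
#'
#' @param dataset A `qts_dataset`.
#' @param id Compound number (1-73).
#' @param hill Named numeric vector of Hill coefficient overrides keyed by
#'   `"<assay>.<channel>"` (e.g. `c(PX.IKr = 1.2)`); the default Hill
#'   coefficient is 1 for every entry (the tables do not print them).
#' @return A list of class `qts_compound` with elements `id`, `panel`
#'   (data.frame: channel, assay, ic50, hill, status, top_tested),
#'   `outcome` (list: positive, qtc_ec5, cmax_noeffect) and `printed`
#'   (the raw table rows for this compound).
#' @export
compound_record <- function(dataset, id, hill = NULL) {
  stopifnot(inherits(dataset, "qts_dataset"))
  id <- as.integer(id)
  prow <- dataset$panels[as.integer(dataset$panels$nce) == id, , drop = FALSE]
  mrow <- dataset$margin[as.integer(dataset$margin$nce) == id, , drop = FALSE]
  irow <- dataset$insilico[as.integer(dataset$insilico$nce) == id, , drop = FALSE]
  if (nrow(prow) != 1L) stop("unknown compound id: ", id, call. = FALSE)

  cells <- data.frame(
    channel = c("IKr", "INa", "IKs", "ICaL", "IKr", "INa"),
    assay   = c("PX", "PX", "PX", "HTS", "HTS", "HTS"),
    cell    = c(prow$px_herg_ic50, prow$px_hnav15_ic50, prow$px_iks_ic50,
                prow$hts_hcav12_ic50, prow$hts_mk499_ic50, prow$hts_hnav15_ic50),
    stringsAsFactors = FALSE)
  cells$status <- ifelse(cells$cell == "ND", "ND",
                  ifelse(cells$cell == "NA", "NA", "measured"))
  cells$ic50 <- suppressWarnings(as.numeric(cells$cell))
  cells$top_tested <- ifelse(cells$status == "ND", 30, NA_real_)
  key <- paste(cells$assay, cells$channel, sep = ".")
  cells$hill <- ifelse(cells$status == "measured", 1, NA_real_)
  if (!is.null(hill)) {
    hit <- match(key, names(hill))
    cells$hill[!is.na(hit) & cells$status == "measured"] <-
      hill[hit[!is.na(hit) & cells$status == "measured"]]
  }
  stopifnot(all(cells$ic50[cells$status == "measured"] > 0))

  oc <- parse_concentration(mrow$qtc_ec5)
  outcome <- list(positive = !oc$censored,
                  qtc_ec5 = if (!oc$censored) oc$value else NULL,
                  cmax_noeffect = if (oc$censored) oc$value else NULL)

  structure(list(id = id,
                 panel = cells[, c("channel", "assay", "ic50", "hill",
                                   "status", "top_tested")],
                 outcome = outcome,
                 printed = list(panels = prow, margin = mrow, insilico = irow)),
            class = "qts_compound")
}

#' @export
print.qts_compound <- function(x, ...) {
  cat("Compound", x$id, "-",
      if (x$outcome$positive) {
        paste0("QTc EC5 ", x$outcome$qtc_ec5, " uM")
      } else {
        paste0("no QTc effect up to ", x$outcome$cmax_noeffect, " uM")
      }, "\n")
  print(x$panel, row.names = FALSE)
  invisible(x)
}

#' Assemble the pore-block parameter map for one approach
#'
#' The simulation consumes one IC50/Hill pair per blocked channel. The PX
#' approach combines PatchXpress IKr, IKs and INa with the fluorescence
#' hCav1.2 ICaL potency; the HTS approach combines MK-499 binding (IKr) with
#' the high-throughput hNav1.5 and hCav1.2 potencies. Channels with an
#' `"ND"` potency (no meaningful inhibition at the top tested concentration,
#' 30 uM, above the 10 uM simulation ceiling) contribute no block and are
#' omitted from the map. A missing (`"NA"`, untested) IKr potency makes the
#' approach inapplicable for that compound, signalled as a condition of
#' class `qts_approach_inapplicable`.
#'
#' @param record A `qts_compound` from [compound_record()].
#' @param approach `"PX"` or `"HTS"`.
#' @return Named list (by channel) of `list(ic50, hill)` block parameters;
#'   possibly empty when the whole panel is ND.
#' @export
assemble_drug_block <- function(record, approach = c("PX", "HTS")) {
  stopifnot(inherits(record, "qts_compound"))
  approach <- match.arg(approach)
  pick <- if (approach == "PX") {
    list(IKr = c("PX", "IKr"), IKs = c("PX", "IKs"),
         INa = c("PX", "INa"), ICaL = c("HTS", "ICaL"))
  } else {
    list(IKr = c("HTS", "IKr"), INa = c("HTS", "INa"),
         ICaL = c("HTS", "ICaL"))
  }
  panel <- record$panel
  block <- list()
  for (ch in names(pick)) {
    sel <- panel$assay == pick[[ch]][1] & panel$channel == pick[[ch]][2]
    row <- panel[sel, , drop = FALSE]
    if (row$status == "NA") {
      if (ch == "IKr") {
        cond <- structure(
          class = c("qts_approach_inapplicable", "error", "condition"),
          list(message = paste0("compound ", record$id, ": ", approach,
                                " approach inapplicable (IKr potency not tested)"),
               call = sys.call(-1)))
        stop(cond)
      }
      next  # untested non-IKr channel: no block information
    }
    if (row$status == "ND") next  # <10% inhibition at 30 uM: no block
    block[[ch]] <- list(ic50 = row$ic50,
                        hill = if (is.na(row$hill)) 1 else row$hill)
  }
  block
}

#' Compounds applicable to an assay approach
#'
#' Applicability follows the printed in-silico table: a compound enters an
#' approach's analysis when its in-silico label column is not `"NA"`
#' (73 compounds for PX, 51 for HTS).
#'
#' @param dataset A `qts_dataset`.
#' @param approach `"PX"` or `"HTS"`.
#' @return Integer vector of compound ids.
#' @export
applicable_compounds <- function(dataset, approach = c("PX", "HTS")) {
  approach <- match.arg(approach)
  col <- if (approach == "PX") "px_insilico_label" else "hts_insilico_label"
  as.integer(dataset$insilico$nce[dataset$insilico[[col]] != "NA"])
}
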