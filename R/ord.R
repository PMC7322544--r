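#' @keywords internal
.ord_state_names <- c(
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt")

.ord_currents <- c("INa", "INaL", "Ito", "IKr", "IKs", "IK1",
                   "ICaL", "INaCa", "INaK")

#' Model initial conditions
#'
#' The published resting initial state of the human ventricular myocyte
#' model (endocardial cell). Concentrations are in mM, voltage in mV.
#'
#' @return Named numeric state vector (41 entries).
#' @export
ord_initial_state <- function() {
  setNames(c(
    -87, 7, 7, 145, 145, 1.0e-4, 1.0e-4, 1.2, 1.2,
    0, 1, 1, 1, 1, 1, 0, 1, 1,
    0, 1, 1, 0, 1, 1,
    0, 1, 1, 1, 1, 1, 0, 1, 1,
    0, 0, 0, 0, 1, 0, 0, 0),
    .ord_state_names)
}

#' Define a population member by conductance scale factors
#'
#' A model variant scales the maximal conductance/permeability of nine
#' sarcolemmal currents; the baseline cell has all factors equal to 1.
#'
#' @param scale Named numeric vector over (a subset of) `INa`, `INaL`,
#'   `Ito`, `IKr`, `IKs`, `IK1`, `ICaL`, `INaCa`, `INaK`; all positive.
#'   Unnamed currents keep factor 1.
#' @param variant_id Optional integer identifier.
#' @return Object of class `qts_variant`.
#' @export
model_variant <- function(scale = NULL, variant_id = NA_integer_) {
  factors <- setNames(rep(1, length(.ord_currents)), .ord_currents)
  if (!is.null(scale)) {
    bad <- setdiff(names(scale), .ord_currents)
    if (length(bad)) stop("unknown current(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(scale <= 0)) stop("scale factors must be positive", call. = FALSE)
    factors[names(scale)] <- scale
  }
  structure(list(scale = factors, variant_id = variant_id),
            class = "qts_variant")
}

#' @export
print.qts_variant <- function(x, ...) {
  cat("AP model variant", if (!is.na(x$variant_id)) x$variant_id else "",
      "\n")
  print(round(x$scale, 3))
  invisible(x)
}

#' Hill pore-block conductance scaling
#'
#' Fraction of maximal conductance remaining at drug concentration `conc`:
#' `1 / (1 + (conc / ic50)^hill)`. At `conc = ic50` the factor is 0.5 for
#' any Hill coefficient, and the factor decreases monotonically with
#' concentration.
#'
#' @param conc Drug concentration in uM (>= 0, vectorised).
#' @param ic50 Half-maximal inhibitory concentration in uM (> 0).
#' @param hill Hill coefficient (> 0), default 1.
#' @return Scaling factor in (0, 1].
#' @export
pore_block_scale <- function(conc, ic50, hill = 1) {
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(ic50 <= 0) || any(hill <= 0)) {
    stop("ic50 and hill must be positive", call. = FALSE)
  }
  1 / (1 + (conc / ic50)^hill)
}

#' Per-current conductance factors for a drug block map at one concentration
#'
#' @param block Named list by channel (`IKr`, `IKs`, `INa`, `ICaL`) of
#'   `list(ic50, hill)`; channels absent from the map are unblocked.
#' @param conc Concentration in uM.
#' @return Named numeric vector over the nine scalable currents.
#' @export
block_factors <- function(block, conc) {
  factors <- setNames(rep(1, length(.ord_currents)), .ord_currents)
  for (ch in names(block)) {
    if (!ch %in% .ord_currents) {
      stop("cannot block unknown current: ", ch, call. = FALSE)
    }
    b <- block[[ch]]
    factors[[ch]] <- pore_block_scale(conc, b$ic50,
                                      if (is.null(b$hill)) 1 else b$hill)
  }
  factors
}

ord_parms <- function(variant, factors, stim, celltype = 0) {
  eff <- variant$scale * factors
  c(unname(eff), stim, celltype, 0, 0)
}

#' Evaluate the model right-hand side
#'
#' Direct access to the state derivative, mainly for verification (e.g.
#' quiescence of the unstimulated resting cell, equivalence of variant and
#' pore-block conductance scaling).
#'
#' @param state Named state vector as from [ord_initial_state()].
#' @param t Time (ms); the equations are autonomous, so this only matters
#'   through the stimulus you supply.
#' @param variant A `qts_variant`.
#' @param factors Named block-factor vector from [block_factors()] (defaults
#'   to no block).
#' @param stim Stimulus current in uA/uF (negative depolarises), default 0.
#' @param celltype 0 endo, 1 epi, 2 mid.
#' @return Named derivative vector.
#' @export
ord_deriv <- function(state, t = 0, variant = model_variant(),
                      factors = NULL, stim = 0, celltype = 0) {
  if (is.null(factors)) factors <- block_factors(list(), 0)
  p <- ord_parms(variant, factors, stim, celltype)
  out <- .Call(C_ord_deriv, as.numeric(state), as.numeric(t), as.numeric(p))
  setNames(out, .ord_state_names)
}

#' Pacing protocol
#'
#' @param cycle_length Basic cycle length in ms (default 1000, i.e. 1 Hz).
#' @param n_beats Number of paced beats.
#' @param stim_amplitude Stimulus current density in uA/uF (negative
#'   depolarises; default -80).
#' @param stim_duration Stimulus duration in ms (default 0.5).
#' @return List of class `qts_protocol`.
#' @export
pacing_protocol <- function(cycle_length = 1000, n_beats = 500,
                            stim_amplitude = -80, stim_duration = 0.5) {
  stopifnot(cycle_length > stim_duration, stim_duration > 0, n_beats >= 1)
  structure(list(cycle_length = cycle_length, n_beats = n_beats,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "qts_protocol")
}

solve_segment <- function(state, times, parms, rtol, atol) {
  out <- deSolve::ode(y = state, times = times, func = "ord_derivs",
                      parms = parms, dllname = "qtsilico",
                      initfunc = "ord_initmod", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failure (istate ", attr(out, "istate")[1], ")",
         call. = FALSE)
  }
  out
}

#' Pace one model variant and return the final beat
#'
#' Integrates the drug-scaled model for `n_beats` cycles from `init`
#' (defaulting to the model's resting initial conditions; pass a stored
#' control steady state for drug runs) and returns the last cycle sampled on
#' a fixed output grid.
#'
#' @param variant A `qts_variant`.
#' @param block Drug block map (named list of `list(ic50, hill)`), or `NULL`.
#' @param conc Drug concentration in uM applied to `block`.
#' @param protocol A [pacing_protocol()].
#' @param init Optional initial state (named vector).
#' @param dt_out Output sampling interval of the final beat (ms).
#' @param rtol,atol Solver tolerances.
#' @param celltype 0 endo (default), 1 epi, 2 mid.
#' @return Data.frame of class `qts_trace` with columns `time`, `v`, `cai`
#'   (calcium in mM), one cycle starting at the stimulus; the final full
#'   state is attached as attribute `"final_state"`.
#' @export
ord_simulate <- function(variant = model_variant(), block = NULL, conc = 0,
                         protocol = pacing_protocol(), init = NULL,
                         dt_out = 0.2, rtol = 1e-6, atol = 1e-8,
                         celltype = 0) {
  stopifnot(inherits(protocol, "qts_protocol"))
  factors <- block_factors(if (is.null(block)) list() else block, conc)
  p_on <- ord_parms(variant, factors, protocol$stim_amplitude, celltype)
  p_off <- ord_parms(variant, factors, 0, celltype)
  state <- if (is.null(init)) ord_initial_state() else init
  cl <- protocol$cycle_length
  sd_ <- protocol$stim_duration
  trace <- NULL
  for (beat in seq_len(protocol$n_beats)) {
    last <- beat == protocol$n_beats
    t_stim <- if (last) seq(0, sd_, by = min(dt_out, sd_ / 2)) else c(0, sd_)
    if (t_stim[length(t_stim)] < sd_) t_stim <- c(t_stim, sd_)
    seg1 <- tryCatch(
      solve_segment(state, t_stim, p_on, rtol, atol),
      error = function(e) stop("beat ", beat, ": ", conditionMessage(e),
                               call. = FALSE))
    state <- seg1[nrow(seg1), 1 + seq_along(state)]
    t_rest <- if (last) unique(c(seq(sd_, cl, by = dt_out), cl)) else c(sd_, cl)
    seg2 <- tryCatch(
      solve_segment(setNames(as.numeric(state), .ord_state_names),
                    t_rest, p_off, rtol, atol),
      error = function(e) stop("beat ", beat, ": ", conditionMessage(e),
                               call. = FALSE))
    state <- setNames(as.numeric(seg2[nrow(seg2), 1 + seq_along(state)]),
                      .ord_state_names)
    if (last) {
      m <- rbind(as.matrix(seg1), as.matrix(seg2)[-1, , drop = FALSE])
      trace <- data.frame(time = m[, "time"], v = m[, "v"],
                          cai = m[, "cai"])
    }
  }
  attr(trace, "final_state") <- state
  class(trace) <- c("qts_trace", "data.frame")
  trace
}

# per-session cache of control steady states, keyed by variant + protocol
.steady_cache <- new.env(parent = emptyenv())

#' Control steady state of a variant under pacing
#'
#' Paces the drug-free variant from the resting initial conditions and
#' returns the end-of-run state. Results are cached per session keyed by the
#' variant's scale factors and the protocol, so repeated drug runs for the
#' same variant reuse one control run.
#'
#' @inheritParams ord_simulate
#' @return Named state vector.
#' @export
ord_steady_state <- function(variant = model_variant(),
                             protocol = pacing_protocol(),
                             rtol = 1e-6, atol = 1e-8, celltype = 0) {
  key <- paste(c(format(variant$scale, digits = 15), protocol$cycle_length,
                 protocol$n_beats, protocol$stim_amplitude,
                 protocol$stim_duration, rtol, atol, celltype),
               collapse = "|")
  if (!is.null(.steady_cache[[key]])) return(.steady_cache[[key]])
  tr <- ord_simulate(variant, NULL, 0, protocol, rtol = rtol, atol = atol,
                     celltype = celltype)
  st <- attr(tr, "final_state")
  .steady_cache[[key]] <- st
  st
}

#' Sample a candidate population of model variants
#'
#' Scale factors are drawn independently per current, uniformly on the
#' given ranges; the draw is deterministic given the seed.
#'
#' @param n Number of variants.
#' @param ranges Named list by current of `c(low, high)` (0 < low < high);
#'   defaults to `[0.5, 1.5]` for all nine scalable currents.
#' @param seed Integer seed.
#' @return List of `qts_variant`s with ids `1:n`.
#' @export
sample_population <- function(n, ranges = NULL, seed = 1L) {
  stopifnot(n >= 1)
  if (is.null(ranges)) {
    ranges <- setNames(rep(list(c(0.5, 1.5)), length(.ord_currents)),
                       .ord_currents)
  }
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    stopifnot(length(r) == 2, r[1] > 0, r[2] > r[1])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    sc <- vapply(names(ranges), function(nm) {
      runif(1, ranges[[nm]][1], ranges[[nm]][2])
    }, numeric(1))
    model_variant(sc, variant_id = i)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default control-biomarker acceptance ranges
#'
#' Reconstruction defaults for calibrating the sampled population against
#' human ventricular control electrophysiology: members whose drug-free
#' biomarkers fall inside all ranges (and show no abnormality) are
#' accepted. Ranges follow published human ventricular values and are
#' deliberately wide; they are settings, not measurements.
#'
#' @return Named list of `c(low, high)` per biomarker.
#' @export
default_calibration_ranges <- function() {
  list(apd90 = c(180, 440), apd50 = c(110, 350),
       rmp = c(-95, -80), vpeak = c(10, 60), dvdt_max = c(100, 1000))
}

#' Calibrate a candidate population against control biomarkers
#'
#' Simulates every candidate drug-free, extracts biomarkers from the final
#' beat, and keeps the members whose biomarkers fall inside all acceptance
#' ranges with no abnormality flags. Order is preserved.
#'
#' @param variants List of `qts_variant`s.
#' @param acceptance_ranges Named list of `c(low, high)` per biomarker.
#' @param protocol A [pacing_protocol()].
#' @param ... Passed to [ord_simulate()].
#' @return List with `accepted` (variants), `biomarkers` (list, all
#'   candidates), `accepted_ids`.
#' @export
calibrate_population <- function(variants,
                                 acceptance_ranges = default_calibration_ranges(),
                                 protocol = pacing_protocol(), ...) {
  bm <- lapply(variants, function(vv) {
    tr <- ord_simulate(vv, NULL, 0, protocol, ...)
    compute_biomarkers(tr)
  })
  ok <- vapply(seq_along(variants), function(i) {
    b <- bm[[i]]
    if (b$repol_abnormal || b$depol_abnormal) return(FALSE)
    for (nm in names(acceptance_ranges)) {
      val <- b[[nm]]
      if (is.na(val)) return(FALSE)
      r <- acceptance_ranges[[nm]]
      if (val < r[1] || val > r[2]) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(ok)) {
    warning("calibration accepted no population members", call. = FALSE)
  }
  list(accepted = variants[ok], biomarkers = bm,
       accepted_ids = which(ok))
}

#' Default simulated concentration grid
#'
#' The tested concentrations, in uM, including the drug-free control.
#'
#' @return Numeric vector `c(0, 0.03, 0.1, 0.3, 1, 3, 10)`.
#' @export
concentration_grid <- function() c(0, 0.03, 0.1, 0.3, 1, 3, 10)

#' Simulate a compound across a population and concentration grid
#'
#' Every variant is first paced drug-free to its own control steady state
#' (cached); each drug run then starts from that state. Population
#' summaries are returned per concentration.
#'
#' @param block Drug block map (see [assemble_drug_block()]).
#' @param variants List of `qts_variant`s.
#' @param grid Concentration grid, uM; must start at 0 (control).
#' @param protocol Pacing protocol for the drug runs.
#' @param control_protocol Pacing protocol for each variant's drug-free
#'   steady-state run (defaults to `protocol`).
#' @param ... Passed to [ord_simulate()].
#' @return List of `qts_popsummary`, one per grid concentration.
#' @export
simulate_compound <- function(block, variants, grid = concentration_grid(),
                              protocol = pacing_protocol(),
                              control_protocol = protocol, ...) {
  stopifnot(length(grid) >= 2, grid[1] == 0, !is.unsorted(grid, strictly = TRUE))
  lapply(grid, function(conc) {
    sets <- lapply(variants, function(vv) {
      st <- ord_steady_state(vv, control_protocol, ...)
      tr <- ord_simulate(vv, block, conc, protocol, init = st, ...)
      compute_biomarkers(tr)
    })
    summarize_population(sets, conc)
  })
}
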