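test_that("pore-block scaling has the Hill closed form", {
  expect_equal(pore_block_scale(0, 3, 1.2), 1)
  expect_equal(pore_block_scale(1, 1, 1), 0.5)
  expect_equal(pore_block_scale(10, 1, 2), 1 / 101)
  # scale(IC50) = 0.5 for any Hill coefficient
  for (h in c(0.5, 1, 1.7, 4)) expect_equal(pore_block_scale(2, 2, h), 0.5)
  # monotone decreasing in concentration
  sc <- pore_block_scale(c(0, 0.03, 0.1, 0.3, 1, 3, 10), 0.5, 1.3)
  expect_true(all(diff(sc) < 0))
  expect_error(pore_block_scale(-1, 1, 1), "non-negative")
})

test_that("the unstimulated resting cell is quiescent", {
  quiet <- pacing_protocol(n_beats = 3, stim_amplitude = -1e-10)
  tr <- ord_simulate(protocol = quiet)
  st <- attr(tr, "final_state")
  d <- ord_deriv(st)
  expect_lt(abs(d[["v"]]), 1e-3)
  # gates stay in [0, 1], concentrations positive, everything finite
  gates <- st[c("m", "hf", "hs", "j", "d", "xs1", "xk1", "nca")]
  expect_true(all(gates >= 0 & gates <= 1 + 1e-12))
  expect_true(all(st[c("nai", "ki", "cai", "cansr")] > 0))
  expect_true(all(is.finite(st)))
})

test_that("blocking a channel equals scaling the variant's conductance", {
  st <- ord_initial_state()
  st[["v"]] <- -20  # away from rest so every current is active
  f <- block_factors(list(IKr = list(ic50 = 1, hill = 1)), 1)  # 0.5 on IKr
  d_block <- ord_deriv(st, factors = f)
  d_scale <- ord_deriv(st, variant = model_variant(c(IKr = 0.5)))
  expect_equal(d_block, d_scale, tolerance = 1e-14)
  # full block equals zeroing the conductance (factor floor at 1e-12)
  f0 <- block_factors(list(IKs = list(ic50 = 1e-9, hill = 1)), 1e6)
  d0 <- ord_deriv(st, factors = f0)
  dz <- ord_deriv(st, variant = model_variant(c(IKs = 1e-12)))
  expect_equal(d0, dz, tolerance = 1e-10)
  # all factors one: identical to control
  d1 <- ord_deriv(st, factors = block_factors(list(), 0))
  expect_identical(d1, ord_deriv(st))
})

test_that("a no-drug block map reproduces the control trace bit-for-bit", {
  p <- pacing_protocol(n_beats = 5)
  tr_ctrl <- ord_simulate(protocol = p)
  tr_zero <- ord_simulate(block = pure_ikr_block, conc = 0, protocol = p)
  expect_identical(tr_ctrl$v, tr_zero$v)
  expect_identical(tr_ctrl$cai, tr_zero$cai)
})

test_that("paced control approaches a quasi-steady state", {
  st <- ord_steady_state(protocol = ctrl_protocol)
  one_more <- ord_simulate(init = st, protocol = pacing_protocol(n_beats = 1))
  two_more <- ord_simulate(init = st, protocol = pacing_protocol(n_beats = 2))
  a1 <- compute_biomarkers(one_more)$apd90
  a2 <- compute_biomarkers(two_more)$apd90
  expect_lt(abs(a2 - a1), 0.5)
  # control biomarkers in the human ventricular range
  b <- compute_biomarkers(one_more)
  expect_gt(b$apd90, 180); expect_lt(b$apd90, 440)
  expect_gt(b$rmp, -95); expect_lt(b$rmp, -80)
  expect_gt(b$vpeak, 10)
})

test_that("APD90 is non-decreasing under increasing IKr block", {
  st <- ord_steady_state(protocol = ctrl_protocol)
  p <- pacing_protocol(n_beats = 20)
  apd <- vapply(c(1, 0.75, 0.5, 0.25), function(keep) {
    tr <- ord_simulate(variant = model_variant(c(IKr = keep)),
                       protocol = p, init = st)
    compute_biomarkers(tr)$apd90
  }, numeric(1))
  expect_true(all(diff(apd) > 0))
})

test_that("biomarkers are insensitive to one order of solver tolerance", {
  st <- ord_steady_state(protocol = ctrl_protocol)
  p <- pacing_protocol(n_beats = 5)
  b1 <- compute_biomarkers(ord_simulate(protocol = p, init = st,
                                        rtol = 1e-6, atol = 1e-8))
  b2 <- compute_biomarkers(ord_simulate(protocol = p, init = st,
                                        rtol = 1e-7, atol = 1e-9))
  expect_lt(abs(b1$apd90 - b2$apd90), 1)
  expect_lt(abs(b1$ctd90 - b2$ctd90), 1)
})

test_that("population sampling is deterministic and within ranges", {
  pop1 <- sample_population(10, seed = 3)
  pop2 <- sample_population(10, seed = 3)
  expect_identical(pop1, pop2)
  scales <- t(vapply(pop1, function(v) v$scale, numeric(9)))
  expect_true(all(scales >= 0.5 & scales <= 1.5))
  expect_equal(vapply(pop1, function(v) v$variant_id, integer(1)), 1:10)
  # custom narrow ranges give a near-baseline variant
  near <- sample_population(1, ranges = list(IKr = c(1, 1 + 1e-9)), seed = 1)
  expect_equal(unname(near[[1]]$scale[["IKr"]]), 1, tolerance = 1e-6)
  expect_error(sample_population(2, ranges = list(IKr = c(1.5, 0.5))))
})

test_that("calibration keeps members inside the biomarker ranges", {
  pop <- test_population()
  cal <- calibrate_population(pop, protocol = ctrl_protocol)
  expect_gt(length(cal$accepted), 0)
  expect_equal(vapply(cal$accepted, function(v) v$variant_id, integer(1)),
               cal$accepted_ids)
  ranges <- default_calibration_ranges()
  for (i in cal$accepted_ids) {
    b <- cal$biomarkers[[i]]
    for (nm in names(ranges)) {
      expect_gte(b[[nm]], ranges[[nm]][1])
      expect_lte(b[[nm]], ranges[[nm]][2])
    }
  }
  # unbounded ranges accept everything that is not abnormal
  wide <- list(apd90 = c(0, Inf))
  cal2 <- calibrate_population(pop, acceptance_ranges = wide,
                               protocol = ctrl_protocol)
  normals <- vapply(cal2$biomarkers, function(b) {
    !b$repol_abnormal && !b$depol_abnormal
  }, logical(1))
  expect_equal(cal2$accepted_ids, which(normals))
  # a range excluding the control value rejects the baseline variant
  expect_warning(
    cal3 <- calibrate_population(list(model_variant()),
                                 acceptance_ranges = list(apd90 = c(100, 150)),
                                 protocol = ctrl_protocol),
    "no population members")
  expect_length(cal3$accepted, 0)
})
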