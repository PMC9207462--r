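test_that("standard-curve efficiency matches the closed form", {
  conc <- 10^(0:-4)
  exact <- data.frame(concentration = conc,
                      cq = 30 - 3.3219 * log10(conc))  # slope -3.3219
  fit <- fit_standard_curve(exact)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-10)
  expect_equal(fit$efficiency_percent, (10^(1 / 3.3219) - 1) * 100,
               tolerance = 1e-10)
  expect_equal(fit$efficiency_percent, 100, tolerance = 1e-2)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # slope -3.0
  s3 <- data.frame(concentration = conc, cq = 30 - 3 * log10(conc))
  expect_equal(fit_standard_curve(s3)$efficiency_percent,
               (10^(1 / 3) - 1) * 100, tolerance = 1e-10)
  # duplicating exact collinear points does not move the fit
  dup <- rbind(exact, exact)
  fit2 <- fit_standard_curve(dup)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit2$efficiency_percent, fit$efficiency_percent,
               tolerance = 1e-10)
  # degenerate inputs
  expect_error(fit_standard_curve(exact[1:2, ]), "at least 3")
  expect_error(fit_standard_curve(data.frame(concentration = c(-1, 1, 2),
                                             cq = 1:3)), "positive")
  flat <- data.frame(concentration = conc, cq = 20 + 3 * log10(conc))
  expect_warning(bad <- fit_standard_curve(flat), "undefined")
  expect_true(is.na(bad$efficiency_percent))
})

test_that("single-reference 2^-ddCq quantification is exact on constructed data", {
  # control: target 2 cycles above ref; experiment: target at ref level
  m <- rbind(tgt = c(27, 27, 25, 25), ref = c(25, 25, 25, 25))
  cq <- make_cq(m, group = c("ctl", "ctl", "trt", "trt"),
                condition = c("control", "control", "experiment", "experiment"))
  q <- relative_expression_single(cq, "tgt", "ref")
  expect_equal(q$rq, c(1, 1, 4, 4))
  s <- attr(q, "summary")
  expect_equal(s$mean_rq[s$group == "ctl"], 1)   # control mean RQ = 1
  expect_equal(s$sd_rq[s$group == "ctl"], 0)
  # shifting the reference everywhere changes nothing
  m2 <- m; m2["ref", ] <- m2["ref", ] + 1
  cq2 <- make_cq(m2, group = cq$metadata$group,
                 condition = cq$metadata$condition)
  expect_equal(relative_expression_single(cq2, "tgt", "ref")$rq, q$rq)
  # a global per-sample shift (loading effect) changes nothing
  delta <- c(0.5, -1, 2, 0.25)
  m3 <- sweep(m, 2, delta, "+")
  cq3 <- make_cq(m3, group = cq$metadata$group,
                 condition = cq$metadata$condition)
  expect_equal(relative_expression_single(cq3, "tgt", "ref")$rq, q$rq)
  # no usable control sample is fatal
  cq4 <- make_cq(m, group = rep("trt", 4), condition = rep("experiment", 4))
  expect_error(relative_expression_single(cq4, "tgt", "ref"), "control")
})

test_that("double-reference ddCq averages the single-reference ddCq", {
  set.seed(77)
  m <- rbind(tgt = rnorm(8, 28, 1), r1 = rnorm(8, 22, 0.5),
             r2 = rnorm(8, 24, 0.5))
  cond <- rep(c("control", "experiment"), each = 4)
  cq <- make_cq(m, group = rep(c("ctl", "trt"), each = 4), condition = cond)
  d <- relative_expression_double(cq, "tgt", "r1", "r2")
  s1 <- relative_expression_single(cq, "tgt", "r1")
  s2 <- relative_expression_single(cq, "tgt", "r2")
  expect_equal(d$ddcq, (s1$ddcq + s2$ddcq) / 2, tolerance = 1e-12)
  # identity: double-reference RQ = geometric mean of single-reference RQs
  expect_equal(d$rq, sqrt(s1$rq * s2$rq), tolerance = 1e-12)
  # identical reference profiles collapse to the single-reference result
  m5 <- rbind(m, r3 = m["r1", ])
  cq5 <- make_cq(m5, group = cq$metadata$group, condition = cond)
  d5 <- relative_expression_double(cq5, "tgt", "r1", "r3")
  expect_equal(d5$rq, s1$rq, tolerance = 1e-12)
  # symmetric in the two references
  d_swap <- relative_expression_double(cq, "tgt", "r2", "r1")
  expect_equal(d_swap$rq, d$rq)
  expect_error(relative_expression_double(cq, "tgt", "r1", "r1"), "differ")
  # worked arithmetic: single ddCq of -2 and -4 combine to -3, RQ = 8
  expect_equal(2^-mean(c(-2, -4)), 8)
})

test_that("concordance matrices behave like Pearson correlation", {
  v <- c(1, 2, 3, 5, 4)
  cc <- normalization_concordance(list(a = v, b = v, c = -v))
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_equal(cc, t(cc))
  expect_warning(z <- normalization_concordance(list(a = v, b = rep(2, 5))),
                 "zero-variance")
  expect_true(is.na(z["a", "b"]))
  expect_error(normalization_concordance(list(a = 1:3, b = 1:4)),
               "same length")
  # two nearly identical references give highly concordant RQ series
  sim <- simulate_target_experiment(
    matrix(c(2, 1, -1), 1, 3, dimnames = list("tgt", c("t1", "t2", "t3"))),
    n_references = 2, n_replicates = 4, noise_sd = 0.05, seed = 101)
  q1 <- relative_expression_single(sim$cq, "tgt", "ref1")
  q2 <- relative_expression_single(sim$cq, "tgt", "ref2")
  cc2 <- normalization_concordance(list(ref1 = log2(q1$rq),
                                        ref2 = log2(q2$rq)))
  expect_gt(cc2["ref1", "ref2"], 0.95)
})
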