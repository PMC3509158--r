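test_that("function transformations match the registry", {
  expect_equal(transform_function(0, "wood"), 0)        # ln(0 + 1)
  expect_equal(transform_function(4, "forage"), 2)      # sqrt
  expect_equal(transform_function(8.8, "cations"), asin(sqrt(0.088)))
  expect_equal(transform_function(8.8, "cations"), 0.3012, tolerance = 1e-4)
  expect_equal(transform_function(c(0, 9), "infiltration"), c(0, 3))
  expect_error(transform_function(120, "cations"),
               class = "fallowfun_invalid_argument")
  expect_error(transform_function(-1, "wood"),
               class = "fallowfun_invalid_argument")
  # the scaling constant is configurable and re-scales the transform
  expect_equal(transform_function(5, "cations", cations_scale = 10),
               asin(sqrt(0.5)))
})

test_that("type reference takes the mean of the 3 highest and the mean", {
  prof <- make_profiles(wood_t = 1:5, forage_t = 1:5, cations_t = 1:5,
                        infiltration_t = 1:5)
  ref <- type_reference(prof)
  expect_equal(ref$max3, rep(4, 4))   # (3+4+5)/3
  expect_equal(ref$mean, rep(3, 4))
  # all-equal values: maximum equals the mean
  prof2 <- make_profiles(rep(2, 4), rep(2, 4), rep(2, 4), rep(2, 4))
  ref2 <- type_reference(prof2)
  expect_equal(ref2$max3, rep(2, 4))
  expect_equal(ref2$mean, rep(2, 4))
  # exactly 3 plots: maximum is their mean
  prof3 <- make_profiles(c(1, 2, 6), c(1, 2, 6), c(1, 2, 6), c(1, 2, 6))
  expect_equal(type_reference(prof3)$max3, rep(3, 4))
  expect_error(type_reference(prof3[1:2, ]),
               class = "fallowfun_invalid_argument")
})

test_that("proportion above threshold counts inclusively over 4 functions", {
  ref <- make_reference(max3 = c(2, 2, 4, 2), mean = 1)
  at_max <- make_profiles(2, 2, 4, 2)
  expect_equal(proportion_above(at_max, ref, 0.5)$prop_above, 1.0)
  zeros <- make_profiles(0, 0, 0, 0)
  expect_equal(proportion_above(zeros, ref, 0.5)$prop_above, 0.0)
  # x = (1, 2, 3, 0.4) vs tau*M = (1, 1, 2, 1): three of four qualify
  toy <- make_profiles(1, 2, 3, 0.4)
  pa <- proportion_above(toy, ref, 0.5)
  expect_equal(pa$prop_above, 0.75)
  expect_equal(pa$prop_asin, asin(sqrt(0.75)))
})

test_that("proportion above is monotone in function values and threshold", {
  set.seed(8)
  ref <- make_reference(max3 = runif(4, 1, 3), mean = 1)
  base <- make_profiles(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 3),
                        runif(1, 0, 3))
  for (tau in c(0.25, 0.5, 0.75)) {
    p0 <- proportion_above(base, ref, tau)$prop_above
    bumped <- base
    bumped$wood_t <- bumped$wood_t + 1
    expect_gte(proportion_above(bumped, ref, tau)$prop_above, p0)
  }
  taus <- c(0.25, 0.5, 0.75, 1)
  props <- vapply(taus, function(tau)
    proportion_above(base, ref, tau)$prop_above, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("mean percentage excess is zero at the mean and averages to zero", {
  ref <- make_reference(max3 = 3, mean = c(1, 2, 1, 2))
  at_mean <- make_profiles(1, 2, 1, 2)
  expect_equal(mean_percentage_excess(at_mean, ref)$mpe, 0)
  # one function doubled, three at their means: mean(100, 0, 0, 0)
  up <- make_profiles(2, 2, 1, 2)
  expect_equal(mean_percentage_excess(up, ref)$mpe, 25)
  # algebraic identity: averaging over the defining plots returns exactly 0
  set.seed(31)
  prof <- make_profiles(runif(18, 0.5, 3), runif(18, 0.5, 3),
                        runif(18, 0.1, 1.5), runif(18, 2, 25))
  refd <- type_reference(prof)
  expect_equal(mean(mean_percentage_excess(prof, refd)$mpe), 0,
               tolerance = 1e-12)
  # degenerate non-positive mean is refused
  bad_ref <- make_reference(max3 = 3, mean = c(0, 1, 1, 1))
  expect_error(mean_percentage_excess(at_mean, bad_ref),
               class = "fallowfun_invalid_argument")
})

test_that("jointness counts plots above both thresholds of a pair", {
  # all plots at their maxima: every pair joint in both modes
  prof <- make_profiles(rep(2, 5), rep(2, 5), rep(2, 5), rep(2, 5))
  ref <- make_reference(max3 = 2, mean = 2)
  for (mode in c("half_max", "above_mean")) {
    j <- jointness(prof, ref, mode)
    expect_equal(nrow(j), 6)
    expect_equal(j$count, rep(5, 6))
  }
  # toy: values as fractions of M for the wood-forage pair
  M <- 2
  prof2 <- make_profiles(wood_t = c(1.0, 0.6, 0.2) * M,
                         forage_t = c(1.0, 0.4, 0.9) * M,
                         cations_t = 0, infiltration_t = 0)
  ref2 <- make_reference(max3 = M, mean = M)
  j2 <- jointness(prof2, ref2, "half_max")
  expect_equal(j2$count[j2$fn_a == "wood" & j2$fn_b == "forage"], 1)
  # above-mean with one plot above and one below on both functions
  prof3 <- make_profiles(wood_t = c(3, 1), forage_t = c(3, 1),
                         cations_t = c(3, 1), infiltration_t = c(3, 1))
  ref3 <- make_reference(max3 = 3, mean = 2)
  j3 <- jointness(prof3, ref3, "above_mean")
  expect_equal(j3$count, rep(1, 6))
  # jointness can never exceed either single-function incidence
  set.seed(77)
  prof4 <- make_profiles(runif(12, 0, 3), runif(12, 0, 3),
                         runif(12, 0, 3), runif(12, 0, 3))
  ref4 <- type_reference(prof4)
  j4 <- jointness(prof4, ref4, "half_max")
  singles <- vapply(c("wood", "forage", "cations", "infiltration"), function(fn) {
    m <- ref4$max3[ref4$fn == fn]
    sum(prof4[[paste0(fn, "_t")]] >= 0.5 * m)
  }, numeric(1))
  for (i in seq_len(nrow(j4))) {
    expect_lte(j4$count[i], min(singles[j4$fn_a[i]], singles[j4$fn_b[i]]))
  }
})

test_that("with positive values each function has a plot above half-maximum", {
  set.seed(19)
  for (rep in 1:20) {
    prof <- make_profiles(runif(8, 0.01, 4), runif(8, 0.01, 4),
                          runif(8, 0.01, 4), runif(8, 0.01, 4))
    ref <- type_reference(prof)
    pa <- proportion_above(prof, ref, 0.5)
    for (fn in c("wood", "forage", "cations", "infiltration")) {
      m <- ref$max3[ref$fn == fn]
      expect_gte(sum(prof[[paste0(fn, "_t")]] >= 0.5 * m), 1)
    }
  }
})
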