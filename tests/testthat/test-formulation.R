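test_that("Weibull release honors lag, asymptote and the closed form", {
  p <- weibull_params(100, 3.12, 0.94, 0)
  expect_equal(weibull_release(weibull_params(80, 2, 1, 1.5), 1.5), 0)
  expect_equal(weibull_release(p, 1e6), 100, tolerance = 1e-12)
  expect_equal(weibull_release(weibull_params(73, 2, 1.2, 0), 1e6), 73,
               tolerance = 1e-12)
  # at t with t^beta = alpha the exponent is exactly -1
  t_star <- 3.12^(1 / 0.94)
  expect_equal(weibull_release(p, t_star), 100 * (1 - exp(-1)),
               tolerance = 1e-10)
  expect_equal(round(weibull_release(p, t_star), 2), 63.21)

  expect_error(weibull_params(100, -1, 1), "alpha")
  expect_error(weibull_params(100, 1, 0), "beta")
  expect_error(weibull_params(0, 1, 1), "f_max")
  expect_error(weibull_release(p, -0.5), "non-negative")

  # monotone non-decreasing for a spread of shapes
  set.seed(4)
  for (i in 1:20) {
    pp <- weibull_params(runif(1, 50, 100), runif(1, 0.5, 6),
                         runif(1, 0.5, 2.5), runif(1, 0, 1))
    y <- weibull_release(pp, seq(0, 24, by = 0.1))
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y <= pp$f_max + 1e-12))
  }
})

test_that("Weibull fitting round-trips noiseless curves and flags bad input", {
  grid <- c(0.5, 1:12)
  for (truth in list(weibull_params(100, 3.12, 0.94),
                     weibull_params(100, 1.53, 0.87),
                     weibull_params(92, 5.01, 1.09))) {
    prof <- dissolution_profile(grid, weibull_release(truth, grid))
    fit <- fit_weibull(prof, fix_fmax = truth$f_max)
    expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 1e-4)
    expect_lt(abs(fit$beta - truth$beta) / truth$beta, 1e-4)
    expect_lt(attr(fit, "rss"), 1e-8)
    fit_free <- fit_weibull(prof)
    expect_lt(abs(fit_free$f_max - truth$f_max) / truth$f_max, 1e-4)
    expect_lt(abs(fit_free$alpha - truth$alpha) / truth$alpha, 1e-3)
  }
  expect_error(fit_weibull(dissolution_profile(grid, rep(0, 13))),
               "no release")
  expect_error(fit_weibull(dissolution_profile(1:3, c(10, 20, 30))),
               "at least 4")
})

test_that("Weibull fit recovers parameters within 10% under 2% CV noise", {
  truth <- weibull_params(100, 3.12, 0.94)
  unit <- generate_dissolution_replicates(truth, cv = 2, n_units = 1,
                                          seed = 42)[[1]]
  fit <- fit_weibull(unit, fix_fmax = 100)
  expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 0.10)
  expect_lt(abs(fit$beta - truth$beta) / truth$beta, 0.10)
})

test_that("f2 matches its closed forms and is independent of grid size", {
  grid <- default_dissolution_grid()
  base <- dissolution_profile(grid, seq(10, 90, length.out = length(grid)))
  same <- dissolution_profile(grid, base$released)
  expect_equal(similarity_f2(base, same), 100)

  shift10 <- dissolution_profile(grid, base$released - 10)
  expect_equal(similarity_f2(base, shift10), 50 * log10(100 / sqrt(101)),
               tolerance = 1e-12)
  expect_equal(round(similarity_f2(base, shift10), 2), 49.89)
  expect_equal(round(similarity_f2(base, shift10)), 50)
  # same result on a completely different grid length
  g2 <- seq(1, 10, by = 1.5)
  b2 <- dissolution_profile(g2, seq(20, 80, length.out = length(g2)))
  s2 <- dissolution_profile(g2, b2$released - 10)
  expect_equal(round(similarity_f2(b2, s2)), 50)

  shift5 <- dissolution_profile(grid, base$released - 5)
  expect_equal(similarity_f2(base, shift5), 50 * log10(100 / sqrt(26)),
               tolerance = 1e-12)
  expect_equal(round(similarity_f2(base, shift5), 2), 64.63)

  expect_error(similarity_f2(base, b2), "same time grid")
})

test_that("f2 is symmetric, bounded by 100 and monotone in offset", {
  grid <- default_dissolution_grid()
  set.seed(7)
  for (i in 1:10) {
    a <- dissolution_profile(grid, cummax(runif(13, 0, 100)))
    b <- dissolution_profile(grid, cummax(runif(13, 0, 100)))
    expect_equal(similarity_f2(a, b), similarity_f2(b, a))
    expect_lte(similarity_f2(a, b), 100)
    if (!isTRUE(all.equal(a$released, b$released)))
      expect_lt(similarity_f2(a, b), 100)
  }
  base <- dissolution_profile(grid, seq(35, 70, length.out = 13))
  f2s <- vapply(1:30, function(off)
    similarity_f2(base, dissolution_profile(grid, base$released - off)),
    numeric(1))
  expect_true(all(diff(f2s) < 0))
})

test_that("delta modification follows the stated construction rules", {
  ref <- reference_dissolution_profile()
  expect_equal(max(ref$released), 100)

  same <- apply_delta_modification(ref, 0)
  expect_equal(same$released, ref$released)
  expect_equal(similarity_f2(ref, same), 100)

  plus10 <- apply_delta_modification(ref, 10)
  mid <- which.min(abs(ref$released - 50))
  expect_equal(plus10$released[mid], ref$released[mid] + 10)
  expect_equal(plus10$released[ref$times >= 12], 100)

  plus20 <- apply_delta_modification(ref, 20)
  expect_true(all(plus20$released[ref$times >= 7] == 100))
  expect_lt(max(plus20$released[ref$times < 7]), 100 + 1e-9)

  expect_error(apply_delta_modification(ref, -20), "negative release")
})

test_that("small uncapped deltas reproduce the constant-offset f2 closed form", {
  ref <- reference_dissolution_profile()
  for (delta in c(1, 2, 3)) {
    mod <- apply_delta_modification(ref, delta)
    uncapped <- mod$released < 100 & ref$released < 100
    f2_restricted <- 50 * log10(
      100 / sqrt(1 + mean((ref$released[uncapped] - mod$released[uncapped])^2)))
    expect_lt(abs(f2_restricted - 50 * log10(100 / sqrt(1 + delta^2))), 0.01)
  }
})

test_that("make_virtual_formulation handles both modification modes", {
  ref <- reference_dissolution_profile()
  expect_error(make_virtual_formulation(ref), "exactly one")
  expect_error(make_virtual_formulation(ref, delta = 5, trigger_ph = 6),
               "exactly one")

  # trigger mode: release curve untouched; refit of a pure Weibull sample
  # recovers the reference parameters
  pure <- sample_formulation(reference_formulation())
  vf <- make_virtual_formulation(pure, trigger_ph = 6.0)
  expect_equal(vf$trigger_ph, 6.0)
  expect_lt(abs(vf$weibull$alpha - 3.12) / 3.12, 1e-4)
  expect_lt(abs(vf$weibull$beta - 0.94) / 0.94, 1e-4)
  expect_true(is.na(vf$f2_vs_reference))
  expect_equal(vf$provenance$type, "trigger_ph")

  vd <- make_virtual_formulation(ref, delta = 10)
  expect_equal(vd$provenance, list(type = "delta", delta = 10))
  expect_false(is.na(vd$f2_vs_reference))
  expect_lt(vd$weibull$alpha, 3.12)  # faster release fits a smaller scale
})

test_that("bootstrap f2 degenerates correctly and is seed-stable", {
  p <- weibull_params(100, 3.12, 0.94)
  ident <- generate_dissolution_replicates(p, cv = 0, n_units = 3)
  b0 <- bootstrap_f2(ident, ident, n_boot = 200, seed = 1)
  expect_equal(b0$estimate, 100)
  expect_equal(diff(b0$ci), 0)

  # cv = 0 equals the plain f2 of the mean curves
  q <- weibull_params(100, 2.56, 0.91)
  tu0 <- generate_dissolution_replicates(q, cv = 0, n_units = 3)
  b1 <- bootstrap_f2(ident, tu0, n_boot = 200, seed = 2)
  plain <- similarity_f2(sample_formulation(virtual_formulation(p)),
                         sample_formulation(virtual_formulation(q)))
  expect_equal(b1$estimate, plain, tolerance = 1e-12)

  expect_warning(bootstrap_f2(ident, tu0, n_boot = 50, seed = 1), "unstable")

  ru <- generate_dissolution_replicates(p, cv = 3, n_units = 12, seed = 10)
  tu <- generate_dissolution_replicates(q, cv = 3, n_units = 12, seed = 20)
  ba <- bootstrap_f2(ru, tu, n_boot = 500, seed = 30)
  bb <- bootstrap_f2(ru, tu, n_boot = 500, seed = 30)
  expect_identical(ba$samples, bb$samples)
  # percentile interval brackets the f2 of the observed mean profiles
  expect_lte(ba$ci[1], ba$f2_of_means)
  expect_gte(ba$ci[2], ba$f2_of_means)
})

test_that("dissolution replicates are mean-preserving and well-formed", {
  p <- weibull_params(100, 3.12, 0.94)
  grid <- default_dissolution_grid()
  u0 <- generate_dissolution_replicates(p, cv = 0, n_units = 4, seed = 1)
  for (u in u0) expect_equal(u$released, weibull_release(p, grid))

  one <- generate_dissolution_replicates(p, cv = 5, n_units = 1, seed = 3)
  expect_length(one, 1)
  expect_s3_class(one[[1]], "dissolution_profile")

  many <- generate_dissolution_replicates(p, cv = 5, n_units = 10000, seed = 9)
  relmat <- vapply(many, function(u) u$released, numeric(length(grid)))
  base <- weibull_release(p, grid)
  # mean-preservation checked away from the 100% clip
  mid <- base > 20 & base < 85
  expect_true(all(abs(rowMeans(relmat)[mid] - base[mid]) / base[mid] < 0.01))
})

test_that("dissolution profile and formulation validators reject bad input", {
  expect_error(dissolution_profile(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(dissolution_profile(1:3, c(5, 4, 6)), "non-decreasing")
  expect_error(dissolution_profile(1:3, c(5, 6, 101)), "\\[0, 100\\]")
  expect_error(virtual_formulation(weibull_params(100, 1, 1),
                                   trigger_ph = 10), "trigger_ph")
  lib <- formulation_library()
  expect_length(lib, 9)
  expect_equal(lib$reference$weibull$alpha, 3.12)
  expect_equal(lib$`pH6`$trigger_ph, 6.0)
  expect_equal(lib$`+10%`$f2_vs_reference, 50.8)
})
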