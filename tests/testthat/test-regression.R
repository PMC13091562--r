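# Regression models: OLS, one-phase decay, breakpoint, model comparisons.

test_that("OLS recovers exact lines and matches the normal equations", {
  x <- c(20, 25, 32, 36)
  f <- fit_linear(x, 0.66 * x + 14.79)
  expect_equal(f$slope, 0.66, tolerance = 1e-10)
  expect_equal(f$intercept, 14.79, tolerance = 1e-10)
  expect_equal(f$r2, 1)
  # two points: exact interpolation
  f2 <- fit_linear(c(1, 2), c(3, 7))
  expect_equal(f2$slope, 4)
  expect_equal(f2$r2, 1)
  # random data vs closed-form normal equations
  set.seed(21)
  xr <- rnorm(50); yr <- 2 - 3 * xr + rnorm(50)
  fr <- fit_linear(xr, yr)
  beta <- solve(crossprod(cbind(1, xr)), crossprod(cbind(1, xr), yr))
  expect_equal(fr$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fr$slope, beta[2], tolerance = 1e-10)
  expect_error(fit_linear(rep(1, 5), rnorm(5)), "constant")
})

test_that("one-phase decay recovers the published curve from noise-free data", {
  x <- seq(26, 36, length.out = 40)
  f <- fit_one_phase_decay(x, decay_curve(x))
  expect_true(f$converged)
  expect_equal(f$k, 0.27, tolerance = 0.27 * 5e-4)        # 3 significant figures
  expect_equal(f$C, -69.06, tolerance = abs(-69.06) * 5e-4)
  expect_equal(f$A, 20.3e5, tolerance = 20.3e5 * 1e-3)
  expect_gt(f$r2, 0.999999)
})

test_that("decay fit handles the degenerate flat response", {
  f <- fit_one_phase_decay(1:10, rep(4, 10))
  expect_true(f$degenerate)
  expect_equal(f$C, 4)
  expect_equal(f$A, 0)
  expect_equal(f$k, 0)
})

test_that("decay fit beats a 50^3 grid search on noisy data", {
  set.seed(31)
  x <- runif(30, 26, 36)
  y <- decay_curve(x) + rnorm(30, 0, 30)
  f <- fit_one_phase_decay(x, y)
  As <- 10^seq(4, 8, length.out = 50)
  ks <- seq(0.05, 0.6, length.out = 50)
  Cs <- seq(-400, 400, length.out = 50)
  best <- Inf
  for (A in As) for (k in ks) {
    e <- A * exp(-k * x)
    for (C in Cs) best <- min(best, sum((y - e - C)^2))
  }
  expect_lte(f$sse, best + 1e-6)
})

test_that("breakpoint fit recovers the published segmented model", {
  x <- seq(26, 36, by = 0.5)
  f <- fit_breakpoint(x, breakpoint_curve(x))
  expect_false(f$unidentifiable)
  expect_equal(f$b2, 31.88, tolerance = 0.02)
  expect_equal(f$b1, -307.47, tolerance = 0.5)
  expect_equal(f$b3, 60.48, tolerance = 0.05)
  # profile SSE at the winner is <= every grid candidate
  expect_true(all(f$sse <= f$grid$sse + 1e-9))
})

test_that("flat data flags the breakpoint as unidentifiable", {
  f <- fit_breakpoint(seq(26, 36, 0.5), rep(3, 21))
  expect_true(f$unidentifiable)
  expect_equal(f$b3, 3)
  expect_true(is.na(f$b2))
})

test_that("breakpoint fixed at max(x) reduces to the linear fit", {
  set.seed(41)
  x <- seq(26, 36, 0.5)
  y <- -50 * x + 2000 + rnorm(length(x), 0, 5)
  bf <- fit_breakpoint(x, y, fix_b2 = max(x))
  lf <- fit_linear(x, y)
  expect_equal(bf$b1, lf$slope, tolerance = 1e-8)
  # plateau is the line's value at the breakpoint
  expect_equal(bf$b3, lf$intercept + lf$slope * max(x), tolerance = 1e-6)
})

test_that("fitters are scale-consistent in the response", {
  set.seed(51)
  x <- seq(26, 36, length.out = 30)
  y <- decay_curve(x) + rnorm(30, 0, 20)
  c_mul <- 3.5
  f1 <- fit_one_phase_decay(x, y)
  f2 <- fit_one_phase_decay(x, c_mul * y)
  expect_equal(f2$k, f1$k, tolerance = 1e-4)
  expect_equal(f2$A / f1$A, c_mul, tolerance = 1e-3)
  expect_equal(f2$C / f1$C, c_mul, tolerance = 1e-3)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-6)
  yb <- breakpoint_curve(x) + rnorm(30, 0, 5)
  b1f <- fit_breakpoint(x, yb)
  b2f <- fit_breakpoint(x, c_mul * yb)
  expect_equal(b2f$b2, b1f$b2, tolerance = 1e-3)
  expect_equal(b2f$b1 / b1f$b1, c_mul, tolerance = 1e-4)
  l1 <- fit_linear(x, y); l2 <- fit_linear(x, c_mul * y)
  expect_equal(l2$slope / l1$slope, c_mul, tolerance = 1e-10)
  expect_equal(l2$r2, l1$r2, tolerance = 1e-12)
})

test_that("identical groups give F = 0, p = 1 in both line comparisons", {
  set.seed(61)
  x <- runif(20, 0, 10); y <- 2 * x + 1 + rnorm(20)
  cmp <- compare_linear_fits(x, y, x, y)
  expect_equal(cmp$slopes$statistic, 0, tolerance = 1e-10)
  expect_equal(cmp$slopes$p, 1, tolerance = 1e-10)
  expect_equal(cmp$intercepts$statistic, 0, tolerance = 1e-10)
  expect_equal(cmp$intercepts$p, 1, tolerance = 1e-10)
})

test_that("line comparison F matches the nested-SSE computation", {
  set.seed(62)
  xA <- runif(15); yA <- 1 + 2 * xA + rnorm(15, 0, 0.3)
  xB <- runif(18); yB <- 2 + 1.5 * xB + rnorm(18, 0, 0.3)
  cmp <- compare_linear_fits(xA, yA, xB, yB)
  sse <- function(fit) sum(residuals(fit)^2)
  x <- c(xA, xB); y <- c(yA, yB); g <- factor(rep(1:2, c(15, 18)))
  sse_full <- sse(lm(y ~ g * x)); sse_cs <- sse(lm(y ~ g + x)); sse_1 <- sse(lm(y ~ x))
  n <- 33
  expect_equal(cmp$slopes$statistic, (sse_cs - sse_full) / (sse_full / (n - 4)),
               tolerance = 1e-10)
  expect_equal(cmp$intercepts$statistic, (sse_1 - sse_cs) / (sse_cs / (n - 3)),
               tolerance = 1e-10)
})

test_that("parallel-lines simulation: slope test calibrated, intercept test powered", {
  set.seed(63)
  n_rep <- 200
  slope_ok <- 0; int_ok <- 0
  for (r in seq_len(n_rep)) {
    xA <- runif(200, 0, 10); xB <- runif(200, 0, 10)
    yA <- 2 * xA + 1 + rnorm(200, 0, 0.5)
    yB <- 2 * xB + 2 + rnorm(200, 0, 0.5)
    cmp <- compare_linear_fits(xA, yA, xB, yB)
    if (cmp$slopes$p > 0.05) slope_ok <- slope_ok + 1
    if (cmp$intercepts$p < 0.001) int_ok <- int_ok + 1
  }
  expect_gt(slope_ok / n_rep, 0.85)         # ~size 0.05 under H0
  expect_gt(int_ok / n_rep, 0.99)           # near-certain detection
})

test_that("identical groups give p = 1 for the decay-rate comparison", {
  x <- seq(26, 36, length.out = 20)
  set.seed(71)
  y <- decay_curve(x) + rnorm(20, 0, 10)
  cmp <- compare_decay_rates(x, y, x, y)
  expect_equal(cmp$statistic, 0, tolerance = 1e-6)
  expect_equal(cmp$p, 1, tolerance = 1e-6)
  # nested inequality holds by construction
  expect_gte(cmp$sse[["shared"]], cmp$sse[["separate"]] - 1e-9)
})

test_that("distinct decay rates are detected with high power", {
  set.seed(72)
  n_rep <- 200
  rej <- 0
  for (r in seq_len(n_rep)) {
    xA <- runif(50, 26, 33); xB <- runif(50, 26, 33)
    yA <- 5.1e5 * exp(-0.27 * xA) - 124.6
    yA <- yA + rnorm(50, 0, 0.05 * abs(yA))
    yB <- 0.4e5 * exp(-0.14 * xB) - 329.1
    yB <- yB + rnorm(50, 0, 0.05 * abs(yB))
    cmp <- compare_decay_rates(xA, yA, xB, yB)
    expect_gte(cmp$sse[["shared"]], cmp$sse[["separate"]] - 1e-6)
    if (cmp$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.9)
})
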