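# Regression models: ordinary least squares, one-phase exponential decay,
# segmented (breakpoint) model, and extra-sum-of-squares model comparisons.

#' Ordinary least-squares linear fit
#'
#' @param x Predictor series (non-constant, n >= 2).
#' @param y Response series.
#' @return A `linear_fit`: list with `slope`, `intercept`, `r2`, `sse`,
#'   `df`, `n`, `p_slope` (NA when n < 3).
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  p <- if (n >= 3)
    suppressWarnings(summary(fit)$coefficients["x", "Pr(>|t|)"]) else NA_real_
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r2 = r2, sse = sse, df = n - 2L, n = n, p_slope = p),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g x + %.4g  (R2 = %.3f, n = %d, p = %.3g)\n",
              x$slope, x$intercept, x$r2, x$n, x$p_slope))
  invisible(x)
}

# Conditional linear LS of y = A exp(-k x) + C for fixed k.
.decay_profile_sse <- function(k, x, y) {
  z <- exp(-k * x)
  fit <- stats::lm(y ~ z)
  list(sse = sum(stats::residuals(fit)^2),
       A = unname(stats::coef(fit)["z"]),
       C = unname(stats::coef(fit)["(Intercept)"]))
}

#' Fit a one-phase exponential decay y = A exp(-k x) + C
#'
#' Nonlinear least squares with a multi-start strategy: five plateau
#' candidates C0 below min(y), each seeding a log-linear regression of
#' log(y - C0) on x for (A0, k0), refined by Levenberg-Marquardt with the
#' bound k >= 0. The best-SSE solution is kept; non-convergence of every
#' start yields `converged = FALSE` rather than a silent wrong answer.
#'
#' This (A, k, C) parameterization is equivalent to the spreadsheet
#' convention (Y0, plateau, K) via A = Y0 - plateau, C = plateau, k = K.
#'
#' @param x Predictor (e.g. core temperature, degC), n >= 4, non-degenerate.
#' @param y Response (e.g. emergence latency, s).
#' @param init Optional named list/vector with elements A, k, C used as an
#'   additional start.
#' @return A `decay_fit`: list with `A`, `k`, `C`, `r2`, `sse`, `n`,
#'   `converged`, `degenerate`, `iterations`.
#' @export
fit_one_phase_decay <- function(x, y, init = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  if (diff(range(x)) <= 0) stop("x range must be > 0", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {  # documented degenerate case: flat response
    return(structure(list(A = 0, k = 0, C = mean(y), r2 = 1, sse = 0, n = n,
                          converged = TRUE, degenerate = TRUE, iterations = 0L),
                     class = "decay_fit"))
  }
  rng <- diff(range(y))
  margins <- c(0.001, 0.01, 0.05, 0.1, 0.3) * rng
  starts <- lapply(margins, function(m) {
    C0 <- min(y) - m
    ylog <- log(y - C0)
    lf <- stats::lm(ylog ~ x)
    k0 <- max(-unname(stats::coef(lf)["x"]), 1e-6)
    A0 <- exp(unname(stats::coef(lf)["(Intercept)"]))
    list(A = A0, k = k0, C = C0)
  })
  if (!is.null(init)) starts <- c(starts, list(as.list(init)[c("A", "k", "C")]))
  best <- NULL
  iters <- 0L
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-k * x) + C,
                        start = st,
                        lower = c(A = -Inf, k = 0, C = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      co <- stats::coef(fit)
      best <- list(A = unname(co["A"]), k = unname(co["k"]), C = unname(co["C"]),
                   sse = sse, iter = fit$convInfo$finIter)
    }
    iters <- iters + 1L
  }
  if (is.null(best)) {
    # last resort: profile k on a coarse grid so callers still get a flagged fit
    ks <- seq(0, 2, length.out = 201)
    sses <- vapply(ks, function(k) .decay_profile_sse(k, x, y)$sse, numeric(1))
    kb <- ks[which.min(sses)]
    pr <- .decay_profile_sse(kb, x, y)
    return(structure(list(A = pr$A, k = kb, C = pr$C,
                          r2 = 1 - pr$sse / sst, sse = pr$sse, n = n,
                          converged = FALSE, degenerate = FALSE, iterations = 0L),
                     class = "decay_fit"))
  }
  structure(list(A = best$A, k = best$k, C = best$C,
                 r2 = max(0, min(1, 1 - best$sse / sst)), sse = best$sse, n = n,
                 converged = TRUE, degenerate = FALSE,
                 iterations = as.integer(best$iter)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("One-phase decay: y = %.4g * exp(-%.4g x) + %.4g  (R2 = %.3f, n = %d%s)\n",
              x$A, x$k, x$C, x$r2, x$n,
              if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

# Conditional LS for the segmented model at fixed breakpoint b2:
# y = b1 * pmin(x - b2, 0) + b3.
.breakpoint_conditional <- function(x, y, b2) {
  z <- pmin(x - b2, 0)
  if (stats::sd(z) == 0) {
    b3 <- mean(y)
    return(list(b1 = 0, b3 = b3, sse = sum((y - b3)^2)))
  }
  fit <- stats::lm(y ~ z)
  list(b1 = unname(stats::coef(fit)["z"]),
       b3 = unname(stats::coef(fit)["(Intercept)"]),
       sse = sum(stats::residuals(fit)^2))
}

#' Fit the segmented (breakpoint) latency model
#'
#' Model: y = b1 * (x < b2) * (x - b2) + b3 — a sloped segment below the
#' breakpoint b2 joined continuously to a plateau b3 above it. The fit
#' profiles b2 over a grid spanning the interior of x (default step
#' 0.01 degC, candidates with at least 2 points on each side), solving the
#' conditional linear least squares for (b1, b3) at each candidate, keeps
#' the SSE-minimizing b2 (smallest b2 on ties), then polishes with a local
#' continuous optimization around the grid winner.
#'
#' @param x Predictor (degC), n >= 5.
#' @param y Response (s).
#' @param grid_step Grid step for the b2 profile (default 0.01).
#' @param fix_b2 Optionally fix the breakpoint and return the conditional
#'   fit only (no profiling).
#' @return A `breakpoint_fit`: list with `b1` (pre-break slope), `b2`
#'   (breakpoint), `b3` (plateau), `r2`, `sse`, `n`, `unidentifiable`,
#'   and `grid` (profile data.frame b2/sse) unless fixed.
#' @export
fit_breakpoint <- function(x, y, grid_step = 0.01, fix_b2 = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sst <- sum((y - mean(y))^2)
  if (!is.null(fix_b2)) {
    cf <- .breakpoint_conditional(x, y, fix_b2)
    return(structure(list(b1 = cf$b1, b2 = fix_b2, b3 = cf$b3,
                          r2 = if (sst > 0) 1 - cf$sse / sst else 1,
                          sse = cf$sse, n = n, unidentifiable = FALSE),
                     class = "breakpoint_fit"))
  }
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  xs <- sort(x)
  lo <- xs[3]                      # >= 2 points strictly below candidates > xs[2]
  hi <- xs[n - 1]                  # >= 2 points at or above
  cand <- seq(ceiling(lo / grid_step) * grid_step, hi, by = grid_step)
  cand <- cand[vapply(cand, function(b) sum(x < b) >= 2 && sum(x >= b) >= 2, TRUE)]
  if (!length(cand)) stop("no admissible breakpoint candidates", call. = FALSE)
  prof <- vapply(cand, function(b) .breakpoint_conditional(x, y, b)$sse, numeric(1))
  # flat profile (e.g. flat data): breakpoint unidentifiable
  if (sst == 0 || diff(range(prof)) <= 1e-10 * max(sst, 1)) {
    return(structure(list(b1 = 0, b2 = NA_real_, b3 = mean(y),
                          r2 = if (sst > 0) 1 - min(prof) / sst else 1,
                          sse = min(prof), n = n, unidentifiable = TRUE,
                          grid = data.frame(b2 = cand, sse = prof)),
                     class = "breakpoint_fit"))
  }
  i <- which.min(prof)             # first minimum = smallest b2 on ties
  b2 <- cand[i]
  # local continuous polish around the grid winner
  lo_p <- if (i > 1) cand[i - 1] else max(lo, b2 - grid_step)
  hi_p <- if (i < length(cand)) cand[i + 1] else min(hi, b2 + grid_step)
  if (hi_p > lo_p) {
    op <- stats::optimize(function(b) .breakpoint_conditional(x, y, b)$sse,
                          interval = c(lo_p, hi_p), tol = 1e-6)
    if (op$objective < prof[i] - 1e-12 * max(prof[i], 1)) b2 <- op$minimum
  }
  cf <- .breakpoint_conditional(x, y, b2)
  structure(list(b1 = cf$b1, b2 = b2, b3 = cf$b3,
                 r2 = if (sst > 0) max(0, min(1, 1 - cf$sse / sst)) else 1,
                 sse = cf$sse, n = n, unidentifiable = FALSE,
                 grid = data.frame(b2 = cand, sse = prof)),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$unidentifiable)
    cat(sprintf("Breakpoint fit: unidentifiable (flat profile); plateau b3 = %.4g\n", x$b3))
  else
    cat(sprintf("Breakpoint fit: b1 = %.4g, b2 = %.4g, b3 = %.4g  (R2 = %.3f, n = %d)\n",
                x$b1, x$b2, x$b3, x$r2, x$n))
  invisible(x)
}

.comparison_result <- function(test, statistic, df1, df2, p, null_desc) {
  structure(list(test = test, statistic = statistic, df = c(df1, df2),
                 p = p, null = null_desc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: F(%g, %g) = %.4g, p = %.4g  [H0: %s]\n",
              x$test, x$df[1], x$df[2], x$statistic, x$p, x$null))
  invisible(x)
}

#' Compare two linear fits (slopes, then intercepts)
#'
#' Classical extra-sum-of-squares F tests for two regression lines:
#' (i) common slope vs separate slopes; (ii) given a common slope, common
#' intercept vs separate intercepts (test of parallel lines, then of
#' elevation). Identical groups give F = 0, p = 1 for both.
#'
#' @param xA,yA Group A predictor and response.
#' @param xB,yB Group B predictor and response.
#' @return List with `slopes` and `intercepts`, each a `comparison_result`,
#'   plus the three nested SSEs in `sse` (full, common_slope, single_line).
#' @export
compare_linear_fits <- function(xA, yA, xB, yB) {
  nA <- length(xA); nB <- length(xB)
  if (nA < 3 || nB < 3) stop("each group needs n >= 3", call. = FALSE)
  x <- c(xA, xB); y <- c(yA, yB)
  g <- factor(rep(c("A", "B"), c(nA, nB)))
  if (stats::sd(xA) == 0 || stats::sd(xB) == 0)
    stop("singular pooled design (constant predictor in a group)", call. = FALSE)
  n <- nA + nB
  sse_full <- sum(stats::residuals(stats::lm(y ~ g * x))^2)     # 4 params
  sse_cs   <- sum(stats::residuals(stats::lm(y ~ g + x))^2)     # 3 params
  sse_one  <- sum(stats::residuals(stats::lm(y ~ x))^2)         # 2 params
  f_slope <- max(0, (sse_cs - sse_full)) / (sse_full / (n - 4))
  p_slope <- if (sse_full == 0 && sse_cs == sse_full) 1 else
    stats::pf(f_slope, 1, n - 4, lower.tail = FALSE)
  f_int <- max(0, (sse_one - sse_cs)) / (sse_cs / (n - 3))
  p_int <- if (sse_cs == 0 && sse_one == sse_cs) 1 else
    stats::pf(f_int, 1, n - 3, lower.tail = FALSE)
  list(slopes = .comparison_result("slope comparison", f_slope, 1, n - 4,
                                   p_slope, "equal slopes"),
       intercepts = .comparison_result("intercept comparison", f_int, 1, n - 3,
                                       p_int, "equal intercepts given equal slopes"),
       sse = c(full = sse_full, common_slope = sse_cs, single_line = sse_one))
}

# SSE of the joint two-group decay model with a shared rate k: for fixed k
# the per-group (A, C) are conditional linear LS, so the shared-k SSE is a
# smooth 1-D profile in k.
.shared_k_sse <- function(k, xA, yA, xB, yB) {
  .decay_profile_sse(k, xA, yA)$sse + .decay_profile_sse(k, xB, yB)$sse
}

#' Compare decay rates between two groups
#'
#' Extra-sum-of-squares F test of a shared decay rate: the 5-parameter
#' joint model (A1, C1, A2, C2, common k) against the 6-parameter separate
#' model (per-group A, k, C). Both SSEs are computed by profiling k (the
#' conditional (A, C) solve is linear), which guarantees the nested
#' inequality SSE_shared >= SSE_separate.
#'
#' @param xA,yA,xB,yB Per-group predictor (degC) and response (s).
#' @param k_max Upper bound of the k profile search (default 2 /degC).
#' @return A `comparison_result` with extra elements `k_shared`,
#'   `k_separate` (length 2) and `sse` (shared, separate).
#' @export
compare_decay_rates <- function(xA, yA, xB, yB, k_max = 2) {
  if (length(xA) < 4 || length(xB) < 4) stop("each group needs n >= 4", call. = FALSE)
  prof_k <- function(x, y) {
    op <- stats::optimize(function(k) .decay_profile_sse(k, x, y)$sse,
                          interval = c(0, k_max), tol = 1e-8)
    op
  }
  opA <- prof_k(xA, yA); opB <- prof_k(xB, yB)
  sse_sep <- opA$objective + opB$objective
  opS <- stats::optimize(.shared_k_sse, interval = c(0, k_max), tol = 1e-8,
                         xA = xA, yA = yA, xB = xB, yB = yB)
  sse_sh <- opS$objective
  n <- length(xA) + length(xB)
  f <- max(0, sse_sh - sse_sep) / (sse_sep / (n - 6))
  p <- if (sse_sep == 0 && sse_sh <= sse_sep + 1e-12) 1 else
    stats::pf(f, 1, n - 6, lower.tail = FALSE)
  res <- .comparison_result("decay-rate comparison", f, 1, n - 6, p, "equal k")
  res$k_shared <- opS$minimum
  res$k_separate <- c(A = opA$minimum, B = opB$minimum)
  res$sse <- c(shared = sse_sh, separate = sse_sep)
  res
}
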