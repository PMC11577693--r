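test_that("MLR equals the difference in arm means, cross-checked against lm", {
  # saturated means with zero spread: the point estimate would be 100, but
  # se = 0 makes inference degenerate, so the fit is flagged missing
  sat <- fit_mlr(manual_trial(c(0, 0), c(100, 100)))
  expect_false(sat$converged)
  same <- manual_trial(c(10, 20, 30), c(10, 20, 30))
  f <- fit_mlr(same)
  expect_equal(f$estimate, 0)
  expect_equal(f$p_value, 1)

  sp <- scenario_spec(effect_x = 11, n = 100, grid = "BP10", nsim = 1,
                      seed = 17)
  for (r in 1:5) {
    tr <- generate_trial(sp, r)
    f <- fit_mlr(tr)
    expect_equal(f$estimate,
                 mean(tr$observed[tr$arm == 1]) - mean(tr$observed[tr$arm == 0]))
    lmfit <- summary(lm(observed ~ arm, data = as.data.frame(tr)))
    expect_equal(f$estimate, unname(lmfit$coefficients["arm", "Estimate"]))
    expect_equal(f$se, unname(lmfit$coefficients["arm", "Std. Error"]),
                 tolerance = 1e-10)
    expect_equal(f$p_value, unname(lmfit$coefficients["arm", "Pr(>|t|)"]),
                 tolerance = 1e-10)
    expect_true(f$ci_low <= f$estimate && f$estimate <= f$ci_upp)
  }
  # zero within-arm variance in both arms -> degenerate, flagged missing
  degen <- fit_mlr(manual_trial(c(50, 50), c(50, 50)))
  expect_false(degen$converged)
  expect_true(is.na(degen$estimate))
})

test_that("tobit log-likelihood reduces to the Normal regression likelihood without censoring", {
  tr <- manual_trial(c(30, 40, 55, 60), c(45, 50, 70, 75))
  y <- tr$observed
  b0 <- mean(y[tr$arm == 0]); b1 <- mean(y[tr$arm == 1]) - b0
  res <- y - (b0 + b1 * tr$arm)
  s2 <- mean(res^2)
  ll_normal <- sum(dnorm(res, 0, sqrt(s2), log = TRUE))
  expect_equal(tobit_loglik(b0, b1, log(sqrt(s2)), tr), ll_normal,
               tolerance = 1e-12)
})

test_that("a boundary observation contributes a Normal tail term", {
  one <- structure(
    list(arm = 0L, latent = -5, clamped = 0, observed = 0,
         rep_index = 1L, scenario_id = "one"),
    class = "trial_dataset"
  )
  # eta at the bound: contribution log Phi(0) = log 0.5
  expect_equal(tobit_loglik(0, 0, log(5), one), log(0.5))
  one$observed <- 100
  expect_equal(tobit_loglik(100, 0, log(7), one), log(0.5))
  # non-finite parameters give a non-finite value, never an error
  expect_identical(tobit_loglik(NaN, 0, 0, one), -Inf)
})

test_that("analytic tobit score matches finite differences", {
  sp <- scenario_spec(effect_x = 22, n = 100, grid = "RE4", nsim = 1,
                      seed = 23)
  tr <- generate_trial(sp, 1)
  cells <- prosim:::tobit_cells(tr, 0, 100)
  f <- function(p) prosim:::tobit_loglik_cells(p, cells, 0, 100)
  set.seed(1)
  for (i in 1:5) {
    p <- c(runif(1, 30, 70), runif(1, -10, 30), log(runif(1, 10, 35)))
    g_an <- prosim:::tobit_score_cells(p, cells, 0, 100)
    g_fd <- num_grad(f, p)
    expect_equal(g_an, g_fd, tolerance = 1e-5)
  }
})

test_that("tobit equals MLR when no observation sits on a boundary", {
  sp <- scenario_spec(mu = 50, sigma = 10, effect_x = 4.4, n = 100,
                      grid = "MH26", nsim = 1, seed = 31)
  checked <- 0
  for (r in 1:10) {
    tr <- generate_trial(sp, r)
    if (any(tr$observed %in% c(0, 100))) next
    checked <- checked + 1
    fm <- fit_mlr(tr)
    ft <- fit_tobit(tr)
    expect_true(ft$converged)
    expect_equal(ft$estimate, fm$estimate, tolerance = 1e-6)
    # residual SD differs only by the n vs n-2 divisor
    n <- length(tr$arm)
    expect_equal(ft$aux$sigma^2 * n / (n - 2),
                 fm$se^2 / (1 / 50 + 1 / 50) * 1, # pooled variance
                 tolerance = 1e-4)
  }
  expect_gt(checked, 3)
})

test_that("tobit agrees with an interval-censored survreg fit", {
  skip_if_not_installed("survival")
  sp <- scenario_spec(effect_x = 22, n = 200, grid = "RE4", nsim = 1,
                      seed = 37)
  for (r in 1:4) {
    tr <- generate_trial(sp, r)
    y <- tr$observed
    t1 <- ifelse(y <= 0, NA, y)
    t2 <- ifelse(y >= 100, NA, y)
    sv <- survival::survreg(
      survival::Surv(t1, t2, type = "interval2") ~ arm,
      data = data.frame(t1 = t1, t2 = t2, arm = tr$arm),
      dist = "gaussian"
    )
    ft <- fit_tobit(tr)
    expect_true(ft$converged)
    expect_equal(ft$estimate, unname(coef(sv)["arm"]), tolerance = 1e-4)
    expect_equal(ft$se, sqrt(sv$var["arm", "arm"]), tolerance = 1e-3)
    expect_equal(ft$aux$sigma, sv$scale, tolerance = 1e-4)
  }
})

test_that("tobit exceeds MLR under heavy right-censoring", {
  sp <- scenario_spec(mu = 50, sigma = 22, effect_x = 22, n = 200,
                      grid = "RE4", nsim = 1, seed = 41)
  bigger <- vapply(1:10, function(r) {
    tr <- generate_trial(sp, r)
    fit_tobit(tr)$estimate > fit_mlr(tr)$estimate
  }, NA)
  expect_true(all(bigger))
})

test_that("tobit flags unidentifiable trials instead of erroring", {
  expect_false(fit_tobit(manual_trial(c(0, 0, 0), c(0, 0, 0)))$converged)
  expect_false(fit_tobit(manual_trial(c(100, 100), c(100, 100)))$converged)
})

test_that("median fit equals the brute-force LAD vertex solution on odd arms", {
  set.seed(53)
  g <- make_grid(10)
  for (i in 1:8) {
    y0 <- clamp_and_discretise(rnorm(11, 50, 22), g)
    y1 <- clamp_and_discretise(rnorm(13, 61, 22), g)
    f <- fit_median(manual_trial(y0, y1))
    expect_equal(f$estimate, lad_brute_force(y0, y1))
    expect_equal(f$estimate, median(y1) - median(y0))
  }
  ident <- fit_median(manual_trial(c(10, 20, 30, 44), c(10, 20, 30, 44)))
  expect_equal(ident$estimate, 0)
})

test_that("degenerate residual spread makes the median fit missing", {
  expect_false(fit_median(manual_trial(rep(40, 6), rep(60, 6)))$converged)
})

test_that("all estimators are shift-equivariant and arm-swap antisymmetric", {
  sp <- scenario_spec(effect_x = 11, n = 100, grid = "BP10", nsim = 1,
                      seed = 43)
  tr <- generate_trial(sp, 1)
  y0 <- tr$observed[tr$arm == 0]; y1 <- tr$observed[tr$arm == 1]
  c_shift <- 7.5
  for (fitter in list(fit_mlr, fit_median)) {
    a <- fitter(manual_trial(y0, y1))
    b <- fitter(manual_trial(y0 + c_shift, y1 + c_shift))
    expect_equal(b$estimate, a$estimate, tolerance = 1e-10)
    expect_equal(b$se, a$se, tolerance = 1e-10)
    sw <- fitter(manual_trial(y1, y0))
    expect_equal(sw$estimate, -a$estimate, tolerance = 1e-10)
    expect_equal(sw$p_value, a$p_value, tolerance = 1e-10)
  }
  # tobit: shift scores and both bounds together
  a <- fit_tobit(manual_trial(y0, y1), lower = 0, upper = 100)
  b <- fit_tobit(manual_trial(y0 + c_shift, y1 + c_shift),
                 lower = 0 + c_shift, upper = 100 + c_shift)
  expect_equal(b$estimate, a$estimate, tolerance = 1e-6)
  sw <- fit_tobit(manual_trial(y1, y0))
  expect_equal(sw$estimate, -a$estimate, tolerance = 1e-4)
  expect_equal(sw$p_value, a$p_value, tolerance = 1e-3)
})

test_that("tobit optimum is stable under random restarts", {
  sp <- scenario_spec(effect_x = 17.6, n = 100, grid = "RE4", nsim = 1,
                      seed = 47)
  tr <- generate_trial(sp, 1)
  cells <- prosim:::tobit_cells(tr, 0, 100)
  negll <- function(p) -prosim:::tobit_loglik_cells(p, cells, 0, 100)
  neggr <- function(p) -prosim:::tobit_score_cells(p, cells, 0, 100)
  ref <- fit_tobit(tr)
  set.seed(2)
  for (i in 1:5) {
    start <- c(runif(1, 20, 80), runif(1, -20, 40), log(runif(1, 5, 60)))
    opt <- optim(start, negll, neggr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    expect_equal(opt$par[2], ref$estimate, tolerance = 1e-4)
  }
})

test_that("unknown methods are rejected with the valid set listed", {
  tr <- manual_trial(c(1, 2, 3), c(4, 5, 6))
  expect_error(fit_methods(tr, "OLS"), "MLR, TOBIT, MEDIAN")
  expect_error(fit_methods(tr, character(0)), "at least one")
  res <- fit_methods(tr, c("mlr", "median"))
  expect_named(res, c("MLR", "MEDIAN"))
})
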