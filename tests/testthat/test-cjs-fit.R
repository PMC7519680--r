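all_group_levels <- c("3", "4", "5", "6", "7plus")

const_tau <- function(x) setNames(rep(x, 5), all_group_levels)

test_that("the m-array likelihood equals the exhaustive history oracle", {
  # property sweep over random tiny datasets and parameter draws
  set.seed(101)
  spec <- cjs_spec(tau = ~ 0 + group)
  for (rep in 1:40) {
    K <- sample(3:4, 1)
    n <- sample(2:6, 1)
    d <- random_tiny_data(K, n, groups = sample(all_group_levels, 2))
    phi <- runif(1, 0.3, 0.95)
    p <- runif(1, 0.2, 0.9)
    tau <- setNames(runif(5, 0.05, 0.8), all_group_levels)
    m <- build_marray(d)
    nll_m <- transient_cjs_nll(theta_for(phi, p, tau), m, spec)
    nll_o <- oracle_nll(d, phi, p, as.list(tau))
    expect_equal(nll_m, nll_o, tolerance = 1e-10)
  }
})

test_that("with tau = 0 the likelihood reduces to the plain CJS value", {
  set.seed(102)
  d <- random_tiny_data(4, 6, groups = c("3", "4"))
  m <- build_marray(d)
  phi <- 0.8
  p <- 0.55
  nll_plain <- transient_cjs_nll(
    c(qlogis(phi), qlogis(p)), m, cjs_spec(tau = NULL)
  )
  nll_oracle <- oracle_nll(d, phi, p, as.list(const_tau(0)))
  expect_equal(nll_plain, nll_oracle, tolerance = 1e-10)
})

test_that("a saturated tiny case approaches zero log-mass at the boundary", {
  # one cohort, two occasions, everyone re-seen; phi * p -> 1 gives mass -> 1
  d <- encounter_data(c("11", "11", "11"), group = "3")
  m <- build_marray(d)
  nll <- transient_cjs_nll(c(15, 15), m, cjs_spec(tau = NULL))
  expect_lt(nll, 1e-4)
})

test_that("non-finite parameters are refused", {
  d <- random_tiny_data(3, 3)
  m <- build_marray(d)
  expect_error(
    transient_cjs_nll(c(NaN, 0), m, cjs_spec(tau = NULL)),
    "non-finite"
  )
})

test_that("estimates recover the generating parameters with sensible CIs", {
  cfg <- sim_config(
    n_occasions = 12,
    releases = c("3" = 120, "4" = 120, "5" = 120, "6" = 120, "7plus" = 120),
    phi = 0.92, p = 0.6,
    tau = c("3" = 0.05, "4" = 0.15, "5" = 0.25, "6" = 0.45, "7plus" = 0.65)
  )
  d <- simulate_histories(cfg, seed = 200)
  fit <- fit_transient_cjs(d, cjs_spec(tau = ~ 0 + group), n_restarts = 1)
  expect_true(fit$converged)
  te <- dplyr::distinct(dplyr::select(
    tibble::as_tibble(tau_estimates(fit)), "group", "tau", "lower", "upper"
  ))
  truth <- c(0.05, 0.15, 0.25, 0.45, 0.65)
  covered <- truth >= te$lower & truth <= te$upper
  expect_gte(sum(covered), 4L)
  expect_equal(te$tau, truth, tolerance = 0.35)
  # survival and detection recovered on the link scale
  expect_equal(plogis(fit$estimates[["phi:(Intercept)"]]), 0.92, tolerance = 0.03)
  expect_equal(plogis(fit$estimates[["p:(Intercept)"]]), 0.6, tolerance = 0.05)
})

test_that("AIC prefers the no-transience model when tau is zero", {
  wins <- vapply(1:10, function(r) {
    cfg <- sim_config(
      n_occasions = 8,
      releases = c("3" = 60, "4" = 60, "5" = 60, "6" = 60, "7plus" = 60),
      phi = 0.9, p = 0.6, tau = const_tau(0)
    )
    d <- simulate_histories(cfg, seed = 300 + r)
    m <- build_marray(d)
    f0 <- fit_transient_cjs(m, cjs_spec(tau = NULL), n_restarts = 0)
    f1 <- fit_transient_cjs(m, cjs_spec(tau = ~1), n_restarts = 0)
    f0$aic < f1$aic
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("two-occasion data refuse a transience fit", {
  d <- encounter_data(c("10", "11", "10"), group = "3")
  expect_error(
    fit_transient_cjs(d, cjs_spec(tau = ~1)),
    "fewer than 3 occasions"
  )
})

test_that("direct and two-class parameterizations reach the same likelihood", {
  cfg <- sim_config(
    n_occasions = 8,
    releases = c("3" = 80, "4" = 80, "5" = 80, "6" = 80, "7plus" = 80),
    phi = 0.9, p = 0.6,
    tau = c("3" = 0.1, "4" = 0.2, "5" = 0.3, "6" = 0.5, "7plus" = 0.7)
  )
  d <- simulate_histories(cfg, seed = 400)
  m <- build_marray(d)
  f_direct <- fit_transient_cjs(m, cjs_spec(tau = ~ 0 + group), n_restarts = 1)
  f_two <- fit_transient_cjs(m,
    cjs_spec(tau = ~ 0 + group, parameterization = "two_class"),
    n_restarts = 1
  )
  expect_equal(f_direct$logLik, f_two$logLik, tolerance = 1e-5)
  # implied tau agrees between parameterizations
  td <- dplyr::distinct(dplyr::select(
    tibble::as_tibble(tau_estimates(f_direct)), "group", "tau"
  ))
  tt <- dplyr::distinct(dplyr::select(
    tibble::as_tibble(tau_estimates(f_two)), "group", "tau"
  ))
  expect_equal(td$tau, tt$tau, tolerance = 1e-3)
})

test_that("tau identities hold in the two-class back-transformation", {
  # phi_new = phi_res -> tau = 0; phi_new = 0.43, phi_res = 0.86 -> tau = 0.5
  expect_equal(1 - 0.86 / 0.86, 0)
  d <- random_tiny_data(4, 6)
  m <- build_marray(d)
  spec <- cjs_spec(tau = ~1, parameterization = "two_class")
  designs_probe <- fit_transient_cjs(m, spec, n_restarts = 0)
  te <- tau_estimates(designs_probe)
  expect_true(all(te$tau <= 1 + 1e-9))
  # arithmetic of the ratio definition
  expect_equal(1 - 0.43 / 0.86, 0.5)
})

test_that("ANODEV brackets and bounds behave correctly", {
  cfg <- case_study_preset(n_occasions = 12)
  d <- simulate_histories(cfg, seed = 500)
  m <- build_marray(d)
  f_cst <- fit_transient_cjs(m, cjs_spec(tau = ~group), n_restarts = 1)
  f_cov <- fit_transient_cjs(m, cjs_spec(tau = ~ group + cov), n_restarts = 1)
  f_time <- fit_transient_cjs(m, cjs_spec(tau = ~ group + time), n_restarts = 1)
  an <- anodev(f_cst, f_cov, f_time)
  expect_gte(an$pct_deviance, 0 - 1e-9)
  expect_lte(an$pct_deviance, 1 + 1e-9)
  # the covariate drives tau in the generator, so it should explain most of
  # the temporal signal
  expect_gt(an$pct_deviance, 0.5)
  expect_error(anodev(f_cov, f_cst, f_time), "nested")

  # degenerate identities: cov == time gives 1, cov == constant gives 0
  f_fake_cov <- f_time
  f_fake_cov$np <- f_cst$np + 1
  expect_equal(anodev(f_cst, f_fake_cov, f_time)$pct_deviance, 1)
  f_fake_cov2 <- f_cst
  f_fake_cov2$np <- f_cst$np + 1
  expect_equal(anodev(f_cst, f_fake_cov2, f_time)$pct_deviance, 0)
})

test_that("the AIC table ranks, weighs and guards against mixed data", {
  cfg <- sim_config(
    n_occasions = 6,
    releases = c("3" = 40, "4" = 40, "5" = 40, "6" = 40, "7plus" = 40),
    phi = 0.9, p = 0.6, tau = const_tau(0.3)
  )
  d <- simulate_histories(cfg, seed = 600)
  m <- build_marray(d)
  f1 <- fit_transient_cjs(m, cjs_spec(tau = ~1), n_restarts = 0)
  f2 <- fit_transient_cjs(m, cjs_spec(tau = ~ 0 + group), n_restarts = 0)
  single <- aic_table(only = f1)
  expect_equal(single$delta_AIC, 0)
  expect_equal(single$weight, 1)
  tab <- aic_table(dot = f1, grouped = f2)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$AIC, sort(tab$AIC))
  # two models 2 AIC units apart have weight ratio e
  w <- exp(-c(0, 2) / 2) / sum(exp(-c(0, 2) / 2))
  expect_equal(w[1] / w[2], exp(1), tolerance = 1e-12)

  d_other <- simulate_histories(cfg, seed = 601)
  f_other <- fit_transient_cjs(build_marray(d_other), cjs_spec(tau = ~1),
    n_restarts = 0
  )
  expect_error(aic_table(f1, f_other), "same dataset")
})

test_that("permuting individuals leaves the fit invariant", {
  cfg <- sim_config(
    n_occasions = 6,
    releases = c("3" = 30, "4" = 30, "5" = 30, "6" = 30, "7plus" = 30),
    phi = 0.9, p = 0.6, tau = const_tau(0.3)
  )
  d <- simulate_histories(cfg, seed = 700)
  perm <- sample(nrow(d))
  d2 <- encounter_data(history_matrix(d)[perm, ],
    group = d$group[perm], id = d$id[perm]
  )
  f1 <- fit_transient_cjs(build_marray(d), cjs_spec(tau = ~ 0 + group), n_restarts = 0)
  f2 <- fit_transient_cjs(build_marray(d2), cjs_spec(tau = ~ 0 + group), n_restarts = 0)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom form", {
  cfg <- sim_config(
    n_occasions = 6,
    releases = c("3" = 30, "4" = 30, "5" = 30, "6" = 30, "7plus" = 30),
    phi = 0.9, p = 0.6, tau = const_tau(0.3)
  )
  d <- simulate_histories(cfg, seed = 800)
  f <- fit_transient_cjs(d, cjs_spec(tau = ~1), n_restarts = 0)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(td), f$np)
  gl <- glance(f)
  expect_equal(gl$AIC, f$aic)
  expect_equal(gl$np, f$np)
})

test_that("transience estimates concentrate as release numbers grow", {
  err_at <- function(n_rel) {
    errs <- vapply(1:3, function(r) {
      cfg <- sim_config(
        n_occasions = 6,
        releases = c("3" = n_rel, "4" = 0, "5" = 0, "6" = 0, "7plus" = 0),
        phi = 0.9, p = 0.6,
        tau = c("3" = 0.3, "4" = 0, "5" = 0, "6" = 0, "7plus" = 0)
      )
      d <- simulate_histories(cfg, seed = 900 + 10 * log10(n_rel) + r)
      f <- fit_transient_cjs(build_marray(d), cjs_spec(tau = ~1), n_restarts = 0)
      abs(plogis(f$estimates[["tau:(Intercept)"]]) - 0.3)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(100, 1000, 5000), err_at, numeric(1))
  expect_lt(errs[3], errs[1])
})
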