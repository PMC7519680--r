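#' Specify a transient-CJS model
#'
#' Model structures are formulas over three predictors: `group` (the
#' age-at-first-breeding class, a factor), `time` (occasion/interval index, a
#' factor) and `cov` (the per-occasion environmental covariate, standardized
#' before entering the design). All parameters use a logit link. The
#' transience probability `tau` applies to the first interval after initial
#' marking: a newly marked cohort's apparent survival over that interval is
#' `(1 - tau) * phi`, while previously marked animals survive with the
#' resident `phi`.
#'
#' With `parameterization = "two_class"` the model instead estimates a
#' separate first-interval apparent survival `phi_new` (on the same design as
#' `tau`), the classical two-class transient parameterization; the implied
#' transience probability is then `1 - phi_new / phi`. Both
#' parameterizations maximize the same likelihood.
#'
#' @param tau Formula for the transience probability (e.g. `~ group`,
#'   `~ group + cov`, `~ group + time`), or `NULL` for a plain CJS model
#'   without transience.
#' @param phi Formula for resident survival.
#' @param p Formula for detection.
#' @param parameterization `"direct"` (estimate `tau` on the logit scale,
#'   the default) or `"two_class"`.
#' @return A `cjs_spec`.
#' @export
cjs_spec <- function(tau = ~group, phi = ~1, p = ~1,
                     parameterization = c("direct", "two_class")) {
  structure(
    list(
      tau = tau, phi = phi, p = p,
      parameterization = match.arg(parameterization)
    ),
    class = "cjs_spec"
  )
}

uses_cov <- function(f) !is.null(f) && "cov" %in% all.vars(f)

# design grids: phi and tau over (group, interval t = 1..K-1); p over
# (group, occasion j = 2..K). `cov` is the standardized covariate at the
# left occasion of the interval (for phi/tau) or at the occasion itself (p).
build_designs <- function(spec, groups, K, covariate) {
  needs_cov <- uses_cov(spec$tau) || uses_cov(spec$phi) || uses_cov(spec$p)
  if (needs_cov && is.null(covariate)) {
    abort("model references `cov` but the dataset carries no covariate")
  }
  z <- NULL
  if (!is.null(covariate)) {
    z <- as.numeric(scale(covariate))
    if (anyNA(z)) z <- rep(0, length(covariate))
  }
  grid_t <- tidyr::expand_grid(
    group = factor(groups, levels = groups),
    time = factor(seq_len(K - 1L), levels = seq_len(K - 1L))
  )
  if (!is.null(z)) grid_t$cov <- z[as.integer(grid_t$time)]
  grid_p <- tidyr::expand_grid(
    group = factor(groups, levels = groups),
    time = factor(2:K, levels = 2:K)
  )
  if (!is.null(z)) grid_p$cov <- z[as.integer(as.character(grid_p$time))]

  mk <- function(f, grid) {
    if (is.null(f)) {
      return(NULL)
    }
    X <- stats::model.matrix(f, grid)
    if (qr(X)$rank < ncol(X)) {
      abort("design matrix is rank deficient; simplify the model structure")
    }
    X
  }
  list(
    phi = mk(spec$phi, grid_t),
    p = mk(spec$p, grid_p),
    tau = mk(spec$tau, grid_t),
    grid_t = grid_t, grid_p = grid_p
  )
}

theta_blocks <- function(designs) {
  n_phi <- ncol(designs$phi)
  n_p <- ncol(designs$p)
  n_tau <- if (is.null(designs$tau)) 0L else ncol(designs$tau)
  list(
    phi = seq_len(n_phi),
    p = n_phi + seq_len(n_p),
    tau = if (n_tau > 0) n_phi + n_p + seq_len(n_tau) else integer(0),
    n = n_phi + n_p + n_tau
  )
}

# unpack theta into per-(group, time) probability matrices
link_probs <- function(theta, designs, blocks, groups, K) {
  # grids are expand_grid(group, time): time varies fastest within group
  phi <- matrix(plogis(designs$phi %*% theta[blocks$phi]),
    length(groups), K - 1L, byrow = TRUE
  )
  p <- matrix(plogis(designs$p %*% theta[blocks$p]),
    length(groups), K - 1L, byrow = TRUE
  )
  tau <- if (length(blocks$tau) > 0) {
    matrix(plogis(designs$tau %*% theta[blocks$tau]),
      length(groups), K - 1L, byrow = TRUE
    )
  } else {
    matrix(0, length(groups), K - 1L)
  }
  list(phi = phi, p = p, tau = tau)
}

# m-array as dense arrays for the likelihood
marray_arrays <- function(marray) {
  K <- attr(marray, "n_occasions")
  groups <- levels(marray$group)
  G <- length(groups)
  M <- array(0, dim = c(G, 2L, K, K),
    dimnames = list(groups, c("newly_marked", "previously_marked"), NULL, NULL))
  NEV <- array(0, dim = c(G, 2L, K),
    dimnames = list(groups, c("newly_marked", "previously_marked"), NULL))
  gi <- as.integer(marray$group)
  ci <- as.integer(marray$mark_class)
  for (r in seq_len(nrow(marray))) {
    t <- marray$release[r]
    j <- marray$recapture[r]
    if (is.na(j)) {
      NEV[gi[r], ci[r], t] <- NEV[gi[r], ci[r], t] + marray$n[r]
    } else {
      M[gi[r], ci[r], t, j] <- M[gi[r], ci[r], t, j] + marray$n[r]
    }
  }
  list(M = M, never = NEV, K = K, groups = groups)
}

# cell probabilities P[t, j] of first re-encounter at j for a release at t,
# given per-interval survival phi_g[t] and detection p_g[j-1] (p indexed by
# occasion via column j - 1 of the p matrix)
cell_prob_matrix <- function(phi_g, p_g, K) {
  P <- matrix(0, K, K)
  for (t in seq_len(K - 1L)) {
    surv <- phi_g[t]
    for (j in (t + 1L):K) {
      P[t, j] <- surv * p_g[j - 1L]
      if (j < K) surv <- surv * phi_g[j] * (1 - p_g[j - 1L])
    }
  }
  P
}

#' Negative log-likelihood of a transient-CJS model
#'
#' Multinomial likelihood over the m-array cells, with newly marked cohorts'
#' first-interval apparent survival reduced to `(1 - tau) * phi` (or replaced
#' by `phi_new` under the two-class parameterization). The value is the
#' negated sum of multinomial log-masses over cohorts, up to the
#' data-dependent multinomial coefficient (constant in the parameters).
#'
#' @param theta Parameter vector on the link scale, ordered
#'   (phi, p, tau/phi_new) with columns as in the model design.
#' @param marray An `marray_df` (see [build_marray()]).
#' @param spec A `cjs_spec`.
#' @return Scalar negative log-likelihood.
#' @export
transient_cjs_nll <- function(theta, marray, spec) {
  if (any(!is.finite(theta))) abort("non-finite parameter value")
  arr <- marray_arrays(marray)
  designs <- build_designs(spec, arr$groups, arr$K, attr(marray, "covariate"))
  blocks <- theta_blocks(designs)
  if (length(theta) != blocks$n) {
    abort(sprintf("theta has length %d but the design needs %d", length(theta), blocks$n))
  }
  nll_from_arrays(theta, arr, designs, blocks, spec)
}

nll_from_arrays <- function(theta, arr, designs, blocks, spec) {
  K <- arr$K
  groups <- arr$groups
  pr <- link_probs(theta, designs, blocks, groups, K)
  two_class <- spec$parameterization == "two_class" && length(blocks$tau) > 0
  ll <- 0
  for (g in seq_along(groups)) {
    P_res <- cell_prob_matrix(pr$phi[g, ], pr$p[g, ], K)
    # newly marked: scale the whole row by the first-interval adjustment
    first_adj <- if (two_class) {
      pr$tau[g, ] / pmax(pr$phi[g, ], 1e-300) # tau slot holds phi_new
    } else {
      1 - pr$tau[g, ]
    }
    for (cls in 1:2) {
      adj <- if (cls == 1L) first_adj else rep(1, K - 1L)
      for (t in seq_len(K - 1L)) {
        m_row <- arr$M[g, cls, t, ]
        nev <- arr$never[g, cls, t]
        if (all(m_row == 0) && nev == 0) next
        cells <- P_res[t, ] * adj[t]
        chi <- max(1 - sum(cells), 0)
        pos <- which(m_row > 0)
        if (length(pos)) ll <- ll + sum(m_row[pos] * log(pmax(cells[pos], 1e-300)))
        if (nev > 0) ll <- ll + nev * log(max(chi, 1e-300))
      }
      # releases at the final occasion contribute no information
    }
  }
  -ll
}

# saturated multinomial log-likelihood of the m-array (for deviances)
saturated_loglik <- function(marray) {
  arr <- marray_arrays(marray)
  ll <- 0
  for (g in seq_len(dim(arr$M)[1])) {
    for (cls in 1:2) {
      for (t in seq_len(arr$K)) {
        m_row <- arr$M[g, cls, t, ]
        nev <- arr$never[g, cls, t]
        R <- sum(m_row) + nev
        if (R == 0) next
        counts <- c(m_row[m_row > 0], if (nev > 0) nev)
        ll <- ll + sum(counts * log(counts / R))
      }
    }
  }
  ll
}

#' Fit a transient-CJS model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization of the m-array multinomial likelihood,
#' with random restarts on the link scale. The covariance matrix comes from
#' the numerically differentiated Hessian at the optimum; estimates whose
#' link-scale magnitude exceeds 10 are flagged as boundary estimates. The
#' deviance is reported relative to the saturated multinomial model, so
#' deviance ratios (ANODEV) are invariant to constants.
#'
#' @param data An `encounter_df` or an `marray_df`.
#' @param spec A `cjs_spec`.
#' @param starts Optional starting values on the link scale.
#' @param n_restarts Number of additional random restarts (drawn near 0).
#' @param seed Seed for the restart draws.
#' @return A `transient_cjs` fit object; see [tidy.transient_cjs()],
#'   [glance.transient_cjs()] and [tau_estimates()].
#' @export
fit_transient_cjs <- function(data, spec = cjs_spec(), starts = NULL,
                              n_restarts = 5, seed = 1L) {
  marray <- if (inherits(data, "marray_df")) data else build_marray(data)
  arr <- marray_arrays(marray)
  if (arr$K < 3L && !is.null(spec$tau)) {
    abort("transience is not identifiable with fewer than 3 occasions")
  }
  if (arr$K < 2L) abort("need at least 2 occasions")
  designs <- build_designs(spec, arr$groups, arr$K, attr(marray, "covariate"))
  blocks <- theta_blocks(designs)

  obj <- function(th) nll_from_arrays(th, arr, designs, blocks, spec)

  set.seed(as.integer(seed))
  start_list <- list(starts %||% rep(0, blocks$n))
  if (n_restarts > 0) {
    start_list <- c(start_list, lapply(seq_len(n_restarts), function(i) {
      rnorm(blocks$n, 0, 0.5)
    }))
  }
  fits <- lapply(start_list, function(s0) {
    tryCatch(
      optim(s0, obj, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) abort("optimization failed from every start")
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  converged <- any(vapply(fits, function(f) f$convergence == 0, logical(1)))
  if (!converged) {
    warn("optimizer did not report convergence; returning best incumbent")
  }

  H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
  vcov <- if (!is.null(H)) {
    # boundary estimates can make the Hessian numerically singular; fall
    # back to the Moore-Penrose inverse so interior coefficients keep
    # usable standard errors
    tryCatch(solve(H), error = function(e) {
      tryCatch(MASS::ginv(H), error = function(e2) {
        matrix(NA_real_, blocks$n, blocks$n)
      })
    })
  } else {
    matrix(NA_real_, blocks$n, blocks$n)
  }

  nms <- c(
    paste0("phi:", colnames(designs$phi)),
    paste0("p:", colnames(designs$p)),
    if (length(blocks$tau) > 0) {
      paste0(
        if (spec$parameterization == "two_class") "phi_new:" else "tau:",
        colnames(designs$tau)
      )
    }
  )
  est <- setNames(best$par, nms)
  dimnames(vcov) <- list(nms, nms)

  ll <- -best$value
  ll_sat <- saturated_loglik(marray)
  np <- blocks$n
  structure(
    list(
      estimates = est, vcov = vcov,
      logLik = ll, deviance = 2 * (ll_sat - ll),
      np = np, aic = -2 * ll + 2 * np,
      spec = spec, designs = designs, blocks = blocks,
      marray = marray, n_released = sum(marray$n),
      converged = converged,
      boundary = abs(best$par) > 10,
      # last-interval survival and final-occasion detection are confounded
      # when both are time dependent; flag rather than split the product
      confounded_tail = uses_time(spec$phi) && uses_time(spec$p)
    ),
    class = "transient_cjs"
  )
}

uses_time <- function(f) !is.null(f) && "time" %in% all.vars(f)

#' @export
print.transient_cjs <- function(x, ...) {
  cat(sprintf(
    "<transient_cjs> %d parameters, logLik %.3f, deviance %.3f, AIC %.2f%s\n",
    x$np, x$logLik, x$deviance, x$aic,
    if (!x$converged) " (NOT CONVERGED)" else ""
  ))
  if (any(x$boundary)) {
    cat("  boundary estimates:", paste(names(x$estimates)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a transient-CJS fit
#'
#' @param x A `transient_cjs`.
#' @param ... Unused.
#' @return A tibble with link-scale estimates, standard errors and Wald
#'   statistics, one row per coefficient.
#' @method tidy transient_cjs
#' @export
tidy.transient_cjs <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(se),
    statistic = unname(x$estimates / se),
    p.value = 2 * stats::pnorm(abs(unname(x$estimates / se)), lower.tail = FALSE),
    boundary = unname(x$boundary)
  )
}

#' @rdname tidy.transient_cjs
#' @return `glance()`: a one-row tibble with fit summaries.
#' @method glance transient_cjs
#' @export
glance.transient_cjs <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, deviance = x$deviance, AIC = x$aic,
    np = x$np, n_released = x$n_released, converged = x$converged
  )
}

#' Transience probability estimates from a fitted model
#'
#' Back-transforms the fitted transience structure to per-(group, interval)
#' probabilities with delta-method standard errors and 95% confidence
#' intervals computed on the logit scale (so the intervals respect \[0, 1\]).
#' Under the two-class parameterization the implied
#' `tau = 1 - phi_new / phi` is returned (point estimates only, with an
#' undefined-tau flag where resident survival is estimated at zero).
#'
#' @param fit A `transient_cjs` fitted with a transience structure.
#' @param level Confidence level.
#' @return A tibble of class `tau_estimates` with columns `group`, `time`,
#'   `cov` (if present), `tau`, `se`, `lower`, `upper`.
#' @export
tau_estimates <- function(fit, level = 0.95) {
  if (length(fit$blocks$tau) == 0) {
    abort("the model has no transience structure")
  }
  grid <- fit$designs$grid_t
  zq <- qnorm(1 - (1 - level) / 2)
  if (fit$spec$parameterization == "direct") {
    X <- fit$designs$tau
    th <- fit$estimates[fit$blocks$tau]
    V <- fit$vcov[fit$blocks$tau, fit$blocks$tau, drop = FALSE]
    eta <- as.numeric(X %*% th)
    se_eta <- sqrt(pmax(rowSums((X %*% V) * X), 0))
    out <- tibble::tibble(
      group = grid$group, time = as.integer(as.character(grid$time)),
      tau = plogis(eta),
      se = plogis(eta) * (1 - plogis(eta)) * se_eta,
      lower = plogis(eta - zq * se_eta),
      upper = plogis(eta + zq * se_eta)
    )
  } else {
    phi_new <- plogis(as.numeric(fit$designs$tau %*% fit$estimates[fit$blocks$tau]))
    phi_res <- plogis(as.numeric(fit$designs$phi %*% fit$estimates[fit$blocks$phi]))
    tau <- ifelse(phi_res > 0, 1 - phi_new / phi_res, NA_real_)
    out <- tibble::tibble(
      group = grid$group, time = as.integer(as.character(grid$time)),
      tau = tau, se = NA_real_, lower = NA_real_, upper = NA_real_
    )
  }
  if ("cov" %in% names(grid)) out$cov <- grid$cov
  class(out) <- c("tau_estimates", class(out))
  out
}

#' Analysis of deviance for a covariate model
#'
#' Locates a covariate model between the constant and fully time-dependent
#' models on the same data: the proportion of temporal deviance explained is
#' `(Dev_cst - Dev_cov) / (Dev_cst - Dev_time)` and the F statistic has
#' `(np_cov - np_cst, np_time - np_cov)` degrees of freedom.
#'
#' @param fit_constant,fit_covariate,fit_time Nested `transient_cjs` fits
#'   (constant within covariate within time) on identical data.
#' @return A one-row tibble with `F_stat`, `df1`, `df2`, `pct_deviance`
#'   and `p_value`.
#' @export
anodev <- function(fit_constant, fit_covariate, fit_time) {
  fits <- list(fit_constant, fit_covariate, fit_time)
  n_rel <- vapply(fits, function(f) f$n_released, numeric(1))
  if (length(unique(n_rel)) != 1L) {
    abort("ANODEV requires fits on the same dataset")
  }
  np <- vapply(fits, function(f) f$np, numeric(1))
  if (!(np[1] < np[2] && np[2] < np[3])) {
    abort("models must be nested: constant within covariate within time")
  }
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  df1 <- np[2] - np[1]
  df2 <- np[3] - np[2]
  F_stat <- ((dev[1] - dev[2]) / df1) / ((dev[2] - dev[3]) / df2)
  tibble::tibble(
    F_stat = F_stat, df1 = df1, df2 = df2,
    pct_deviance = (dev[1] - dev[2]) / (dev[1] - dev[3]),
    p_value = pf(F_stat, df1, df2, lower.tail = FALSE)
  )
}

#' AIC model-selection table
#'
#' @param ... `transient_cjs` fits of the same data, optionally named.
#' @return A tibble sorted by AIC with `delta_AIC` and Akaike weights.
#' @export
aic_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "transient_cjs")) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  n_rel <- vapply(fits, function(f) f$n_released, numeric(1))
  if (length(unique(n_rel)) != 1L) {
    abort("AIC comparison requires fits on the same dataset")
  }
  out <- tibble::tibble(
    model = names(fits),
    np = unname(vapply(fits, function(f) f$np, numeric(1))),
    logLik = unname(vapply(fits, function(f) f$logLik, numeric(1))),
    deviance = unname(vapply(fits, function(f) f$deviance, numeric(1))),
    AIC = unname(vapply(fits, function(f) f$aic, numeric(1)))
  ) |>
    dplyr::arrange(.data$AIC) |>
    dplyr::mutate(
      delta_AIC = .data$AIC - min(.data$AIC),
      weight = exp(-.data$delta_AIC / 2) / sum(exp(-.data$delta_AIC / 2))
    )
  out
}
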