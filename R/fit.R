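#' Fit a progressive multistate model to panel-observed data
#'
#' Maximum-likelihood fitting of a continuous-time Markov multistate
#' model to intermittently observed state data, with exactly observed
#' death times, state-level censoring, and proportional-intensity
#' covariate effects.  Intensities are parameterized on the log scale so
#' they stay positive; the likelihood and its analytic gradient are
#' evaluated in compiled code and maximized by BFGS, optionally from
#' several jittered starting points.  The covariance of the estimates is
#' the inverse observed information (numerical Hessian of the
#' log-likelihood at the optimum).
#'
#' @param observations Data frame of observation records: `patient_id`,
#'   `time` (years since index), `state`, `kind`
#'   (`panel`/`exact_death`/`censored`), optional `censor_set`
#'   (`|`-separated state names).  Per patient, records must be
#'   time-ordered and only the last record may be a death or censoring
#'   record.
#' @param covariates Data frame of per-patient baseline covariates
#'   (column `patient_id` plus the variables named in `spec`), or
#'   `NULL`.  If the table also has a `time` column (years since
#'   index), covariates are treated as time-varying: each observation
#'   interval uses the most recent covariate row at or before its left
#'   endpoint (carry-forward), while predictions use the baseline row.
#' @param spec An [msm_spec()].
#' @param starts Number of starting points (first is a crude
#'   occurrence/exposure estimate, the rest are jittered around it).
#' @param init Optional numeric vector of starting values (overrides the
#'   crude estimate).
#' @param seed Optional seed for the start-point jitter.
#' @param control Passed to [stats::optim()] (`maxit`, `reltol`, ...).
#' @return An object of class `"dmpath_fit"` with components `par`
#'   (MLEs, log scale), `vcov`, `loglik`, `AIC`, `npar`, `converged`,
#'   `spec`, and the hazard-ratio table via [hazard_ratios()].
#' @seealso [hazard_ratios()], [lrt()], [pmatrix()], [pmatrix_ci()],
#'   [screen_covariates()], [fit_without_death()]
#' @export
msm_fit <- function(observations, covariates = NULL, spec = msm_spec(),
                    starts = 1L, init = NULL, seed = NULL, control = list()) {
  cl <- match.call()
  prep <- prepare_msm_data(observations, covariates, spec)
  if (!prep$forward_ok)
    stop("observations contain a state pair impossible under the progressive model")
  ntrans <- nrow(spec$transitions)

  if (is.null(init)) init <- crude_init(prep)
  if (length(init) != prep$npar)
    stop("init has length ", length(init), ", expected ", prep$npar)

  memo <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!identical(memo$key, key)) {
      memo$val <- msm_loglik_cpp(theta, prep, want_grad = TRUE)
      memo$key <- key
    }
    memo$val
  }
  fn <- function(theta) {
    v <- eval_at(theta)$loglik
    if (!is.finite(v)) -1e12 else v
  }
  gr <- function(theta) {
    v <- eval_at(theta)
    if (!is.finite(v$loglik)) rep(0, length(theta)) else v$grad
  }

  ctrl <- utils::modifyList(list(fnscale = -1, maxit = 500, reltol = 1e-10), control)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  start_list <- list(init)
  if (starts > 1L)
    for (k in seq_len(starts - 1L))
      start_list[[k + 1L]] <- init + stats::rnorm(length(init), 0, 0.25)

  best <- NULL
  for (s0 in start_list) {
    opt <- tryCatch(
      stats::optim(s0, fn, gr, method = "BFGS", control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed from every starting point")

  par <- best$par
  names(par) <- prep$par_names
  H <- tryCatch(stats::optimHess(par, fn, gr, control = ctrl), error = function(e) NULL)
  singular <- FALSE
  if (is.null(H)) {
    V <- matrix(NA_real_, prep$npar, prep$npar); singular <- TRUE
  } else {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) {
      V <- MASS::ginv(-H); singular <- TRUE
    }
  }
  dimnames(V) <- list(prep$par_names, prep$par_names)

  ll <- best$value
  fit <- structure(list(
    call = cl, spec = spec, par = par, vcov = V,
    loglik = ll, npar = prep$npar, AIC = -2 * ll + 2 * prep$npar,
    converged = best$convergence == 0 && !singular,
    optim = list(convergence = best$convergence, counts = best$counts,
                 singular_information = singular),
    ids = prep$ids, Z = prep$Zfull, prof_of_patient = prep$prof_of_patient,
    time_varying = prep$time_varying,
    var_cols = prep$var_cols, col_type = prep$col_type,
    beta_trans = prep$beta_trans, beta_col = prep$beta_col,
    beta_var = prep$beta_var,
    n_patients = length(prep$ids), n_obs = prep$nobs,
    n_intervals = prep$nintervals), class = "dmpath_fit")
  fit
}

## Crude occurrence/exposure starting values: observed direct jumps over
## person-time at risk in the origin state, floored away from zero.
crude_init <- function(prep) {
  ntrans <- nrow(prep$spec$transitions)
  tf <- prep$spec$transitions[, 1] - 1L; tt <- prep$spec$transitions[, 2] - 1L
  expo <- numeric(length(prep$spec$states))
  cnt <- numeric(ntrans)
  iv <- prep$iv
  for (j in seq_along(iv$from)) {
    expo[iv$from[j] + 1L] <- expo[iv$from[j] + 1L] + iv$dt[j]
    if (iv$type[j] == 0L) {
      hit <- which(tf == iv$from[j] & tt == iv$to[j])
      if (length(hit)) cnt[hit] <- cnt[hit] + 1
    } else if (iv$type[j] == 1L) {
      hit <- which(tf == iv$from[j] & tt == (prep$spec$death - 1L))
      if (length(hit)) cnt[hit] <- cnt[hit] + 1
    }
  }
  rate <- (cnt + 0.5) / pmax(expo[tf + 1L], 1)
  c(pmin(pmax(log(rate), log(1e-4)), log(2)), rep(0, prep$npar - ntrans))
}

#' @export
print.dmpath_fit <- function(x, ...) {
  cat("Progressive multistate model fit (panel likelihood)\n")
  cat(sprintf("%d patients, %d observation records, %d intervals\n",
              x$n_patients, x$n_obs, x$n_intervals))
  cat(sprintf("log-likelihood %.3f, AIC %.2f, %d parameters%s\n",
              x$loglik, x$AIC, x$npar,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("\nBaseline intensities (per person-year):\n")
  print(round(baseline_intensities(x), 5))
  invisible(x)
}

#' Baseline transition intensities with Wald confidence intervals
#' @param fit A [msm_fit()] result.
#' @param level Confidence level.
#' @return Matrix with columns `rate`, `lower`, `upper`.
#' @export
baseline_intensities <- function(fit, level = 0.95) {
  ntrans <- nrow(fit$spec$transitions)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$par[seq_len(ntrans)]
  se <- sqrt(diag(fit$vcov)[seq_len(ntrans)])
  out <- cbind(rate = exp(est), lower = exp(est - z * se), upper = exp(est + z * se))
  rownames(out) <- fit$spec$labels
  out
}

#' Hazard-ratio table of a fitted multistate model
#'
#' One row per (transition, covariate coefficient): hazard ratio
#' `exp(beta)` with Wald confidence interval
#' `exp(beta +- z * se)` and two-sided p-value.
#'
#' @param fit A [msm_fit()] result.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `transition`, `covariate`, `HR`,
#'   `lower`, `upper`, `p`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  ntrans <- nrow(fit$spec$transitions)
  nb <- fit$npar - ntrans
  if (nb == 0L)
    return(data.frame(transition = character(0), covariate = character(0),
                      HR = numeric(0), lower = numeric(0), upper = numeric(0),
                      p = numeric(0)))
  idx <- ntrans + seq_len(nb)
  beta <- fit$par[idx]
  se <- sqrt(diag(fit$vcov)[idx])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  zstat <- beta / se
  nm <- names(fit$par)[idx]
  tr <- sub(":.*$", "", nm)
  cv <- sub("^[^:]*:", "", nm)
  data.frame(transition = tr, covariate = cv,
             HR = exp(beta), lower = exp(beta - zq * se),
             upper = exp(beta + zq * se),
             p = 2 * stats::pnorm(-abs(zstat)), row.names = NULL)
}

#' @export
summary.dmpath_fit <- function(object, ...) {
  structure(list(fit = object, intensities = baseline_intensities(object),
                 hr = hazard_ratios(object)), class = "summary.dmpath_fit")
}

#' @export
print.summary.dmpath_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$hr)) {
    cat("\nHazard ratios [Wald 95% CI]:\n")
    hr <- x$hr
    hr$HR <- sprintf("%.3f [%.3f, %.3f]", hr$HR, hr$lower, hr$upper)
    hr$p <- format.pval(hr$p, digits = 3)
    print(hr[, c("transition", "covariate", "HR", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dmpath_fit <- function(object, ...) object$par

#' @export
vcov.dmpath_fit <- function(object, ...) object$vcov

#' @export
logLik.dmpath_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n_intervals,
            class = "logLik")
}

## Covariate vector used for population-level summaries: reference
## category (0) for factor dummies, sample mean for continuous columns.
default_profile <- function(fit) {
  if (ncol(fit$Z) == 0L) return(numeric(0))
  z <- colMeans(fit$Z)
  z[fit$col_type == "dummy"] <- 0
  z
}

## Build Q at the MLE for an expanded covariate row (named numeric over
## the design columns of fit$Z).
generator_at <- function(fit, zrow = NULL, par = fit$par) {
  spec <- fit$spec
  ntrans <- nrow(spec$transitions)
  q <- exp(par[seq_len(ntrans)])
  if (length(fit$beta_trans)) {
    if (is.null(zrow)) zrow <- default_profile(fit)
    beta <- par[ntrans + seq_along(fit$beta_trans)]
    for (b in seq_along(beta)) {
      t <- fit$beta_trans[b] + 1L
      q[t] <- q[t] * exp(beta[b] * zrow[fit$beta_col[b] + 1L])
    }
  }
  names(q) <- spec$labels
  build_generator(q, spec = spec)
}

#' Fitted transition probability matrix
#'
#' Evaluates `P(t) = exp(t*Q(z))` at the maximum-likelihood estimates,
#' for a stated covariate profile (default: reference categories for
#' factors, sample means for continuous covariates).
#'
#' @param fit A [msm_fit()] result.
#' @param t Horizon in years.
#' @param z Optional named covariate values on the original scale
#'   (e.g. `c(age = 60)`); unnamed entries keep the default profile.
#' @return Transition probability matrix with state dimnames.
#' @export
pmatrix <- function(fit, t = 1, z = NULL) {
  transition_probability(generator_at(fit, expand_profile(fit, z)), t)
}

## Translate user-level covariate values into the expanded design row.
expand_profile <- function(fit, z) {
  base <- default_profile(fit)
  if (is.null(z) || !length(z)) return(base)
  for (v in names(z)) {
    cols <- fit$var_cols[[v]]
    if (is.null(cols)) stop("covariate '", v, "' is not in the model")
    if (length(cols) == 1L && cols == v) {
      base[v] <- as.numeric(z[[v]])
    } else {
      base[cols] <- 0
      lev <- paste0(v, z[[v]])
      if (lev %in% cols) base[lev] <- 1
      # otherwise: the reference level, all dummies stay 0
    }
  }
  base
}

#' Parametric-bootstrap confidence intervals for P(t)
#'
#' Draws parameter vectors from the asymptotic normal distribution of
#' the MLE, recomputes the transition probability matrix for each draw,
#' and reports per-cell percentile intervals.
#'
#' @inheritParams pmatrix
#' @param B Number of draws.
#' @param seed Optional seed.
#' @param level Confidence level.
#' @return List with matrices `point`, `lower`, `upper`.
#' @export
pmatrix_ci <- function(fit, t = 1, z = NULL, B = 1000, seed = NULL, level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  V <- fit$vcov
  R <- tryCatch(chol(V), error = function(e)
    stop("singular covariance: cannot draw from the asymptotic normal"))
  zrow <- expand_profile(fit, z)
  point <- transition_probability(generator_at(fit, zrow), t)
  n <- length(fit$spec$states)
  draws <- array(NA_real_, c(B, n, n))
  for (b in seq_len(B)) {
    par_b <- fit$par + drop(t(R) %*% stats::rnorm(length(fit$par)))
    # cap draws of poorly identified log-rates; beyond this the
    # probabilities are saturated at 0/1 anyway
    par_b <- pmin(pmax(par_b, -30), 30)
    draws[b, , ] <- transition_probability(generator_at(fit, zrow, par = par_b), t)
  }
  a <- (1 - level) / 2
  lower <- apply(draws, c(2, 3), stats::quantile, probs = a)
  upper <- apply(draws, c(2, 3), stats::quantile, probs = 1 - a)
  dimnames(lower) <- dimnames(upper) <- dimnames(point)
  list(point = point, lower = lower, upper = upper)
}

#' Likelihood ratio test between nested multistate models
#'
#' @param fit_nested,fit_full Fits from [msm_fit()] on the same data,
#'   with the nested model's free parameters a subset of the full
#'   model's.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
lrt <- function(fit_nested, fit_full) {
  df <- fit_full$npar - fit_nested$npar
  if (df < 0) stop("fit_full has fewer parameters than fit_nested")
  stat <- 2 * (fit_full$loglik - fit_nested$loglik)
  if (stat < -1e-4)
    stop("full model has lower likelihood than nested model: fits are not ",
         "nested or did not converge")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p.value = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Simulate trajectories from a fitted model
#'
#' @param object A [msm_fit()] result.
#' @param nsim Number of trajectories.
#' @param seed Optional seed.
#' @param horizon Follow-up horizon in years.
#' @param z Optional covariate profile as in [pmatrix()].
#' @param ... Unused.
#' @return Data frame of state-entry times (`id`, `time`, `state`).
#' @export
simulate.dmpath_fit <- function(object, nsim = 1, seed = NULL, horizon = 5,
                                z = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Q <- generator_at(object, expand_profile(object, z))
  out <- lapply(seq_len(nsim), function(i) {
    tr <- simulate_trajectory(Q, horizon)
    data.frame(id = i, time = tr$time, state = tr$state)
  })
  do.call(rbind, out)
}
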