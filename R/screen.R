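#' Iterative per-transition covariate screening
#'
#' Starting from a full specification, repeatedly fits the model and
#' drops, per transition, every covariate whose Wald test is
#' non-significant (for a categorical covariate, only when all of its
#' levels are non-significant), then refits.  Iteration stops when
#' nothing was dropped, or when the AIC change between successive
#' models is small (|dAIC| < `aic_tol`) and no longer decreasing.
#' Covariates whose coefficients are not identified (missing or
#' non-finite standard errors, mirroring transitions with too few
#' observed events to converge) are treated as non-significant and
#' dropped.
#'
#' @param spec0 Starting [msm_spec()] with per-transition covariates.
#' @param observations,covariates As in [msm_fit()].
#' @param alpha Wald significance threshold for keeping a covariate.
#' @param aic_tol AIC-change stopping tolerance.
#' @param one_at_a_time Drop only the least significant covariate per
#'   iteration instead of all non-significant ones.
#' @param ... Passed to [msm_fit()].
#' @return List with `spec` (final), `fit` (final [msm_fit()] result),
#'   and `trace` (data frame: iteration, loglik, AIC, n_covariates,
#'   dropped).
#' @export
screen_covariates <- function(spec0, observations, covariates, alpha = 0.05,
                              aic_tol = 2, one_at_a_time = FALSE, ...) {
  if (!inherits(spec0, "msm_spec")) stop("spec0 must be an msm_spec")
  spec <- spec0
  trace <- data.frame(iteration = integer(0), loglik = numeric(0),
                      AIC = numeric(0), n_covariates = integer(0),
                      dropped = character(0))
  fit <- msm_fit(observations, covariates, spec, ...)
  it <- 1L
  prev_aic <- Inf
  repeat {
    hr <- hazard_ratios(fit)
    drop_tab <- character(0)
    if (nrow(hr)) {
      ntrans <- nrow(spec$transitions)
      hr$var <- fit$beta_var
      # per (transition, variable): drop when every level is non-significant
      for (t in seq_len(ntrans)) {
        lab <- spec$labels[t]
        for (v in unique(hr$var[hr$transition == lab])) {
          p <- hr$p[hr$transition == lab & hr$var == v]
          if (all(is.na(p) | p >= alpha))
            drop_tab <- c(drop_tab, paste0(lab, ":", v))
        }
      }
      if (one_at_a_time && length(drop_tab) > 1L) {
        worst <- vapply(drop_tab, function(d) {
          lab <- sub(":.*$", "", d); v <- sub("^[^:]*:", "", d)
          p <- hr$p[hr$transition == lab & hr$var == v]
          if (all(is.na(p))) Inf else max(p, na.rm = TRUE)
        }, numeric(1))
        drop_tab <- drop_tab[which.max(worst)]
      }
    }
    trace <- rbind(trace, data.frame(
      iteration = it, loglik = fit$loglik, AIC = fit$AIC,
      n_covariates = length(unlist(spec$covariates)),
      dropped = paste(drop_tab, collapse = "; ")))
    daic <- prev_aic - fit$AIC
    if (!length(drop_tab)) break
    if (is.finite(prev_aic) && abs(daic) < aic_tol && daic <= 0) break
    new_cov <- spec$covariates
    for (d in drop_tab) {
      lab <- sub(":.*$", "", d); v <- sub("^[^:]*:", "", d)
      new_cov[[lab]] <- setdiff(new_cov[[lab]], v)
    }
    spec_new <- msm_spec(spec$states, spec$transitions,
                         death = if (is.null(spec$death)) NULL else spec$states[spec$death],
                         covariates = new_cov)
    # warm start: the reduced model's parameters are a subset of the
    # current ones (kept in order), which also guarantees the refit
    # cannot do worse than the current fit at those values
    ntrans <- nrow(spec$transitions)
    dropped_pair <- vapply(seq_along(fit$beta_var), function(b) {
      lab <- hr$transition[b]
      paste0(lab, ":", fit$beta_var[b]) %in% drop_tab
    }, logical(1))
    init_new <- unname(c(fit$par[seq_len(ntrans)],
                         fit$par[ntrans + which(!dropped_pair)]))
    fit_new <- msm_fit(observations, covariates, spec_new, init = init_new, ...)
    prev_aic <- fit$AIC
    spec <- spec_new; fit <- fit_new
    it <- it + 1L
  }
  list(spec = spec, fit = fit, trace = trace)
}

#' Refit the multistate model without death transitions
#'
#' Removes all transitions into the exactly-observed absorbing state
#' from the model and converts each exact death record into state-level
#' censoring over the states forward-reachable from the patient's last
#' known living state.  Used to check whether covariate effects on the
#' complication transitions are robust to how mortality is modelled.
#'
#' @inheritParams msm_fit
#' @param ... Passed to [msm_fit()].
#' @return A [msm_fit()] result for the reduced model.
#' @export
fit_without_death <- function(observations, covariates = NULL,
                              spec = msm_spec(), ...) {
  if (is.null(spec$death)) stop("spec has no death state to remove")
  keep <- spec$transitions[, 2] != spec$death
  if (!any(keep)) stop("removing death transitions leaves an empty model")
  tr <- spec$transitions[keep, , drop = FALSE]
  cov <- spec$covariates[keep]
  names(cov) <- transition_labels(spec$states, tr)
  spec_nd <- msm_spec(spec$states, tr, death = NULL, covariates = cov)

  obs <- as.data.frame(observations)
  obs <- obs[order(obs$patient_id, obs$time), , drop = FALSE]
  if (is.null(obs$censor_set)) obs$censor_set <- NA_character_
  is_death <- obs$kind == "exact_death"
  if (any(is_death)) {
    for (i in which(is_death)) {
      prev <- max(which(obs$patient_id == obs$patient_id[i] &
                          seq_len(nrow(obs)) < i))
      r <- match(obs$state[prev], spec$states)
      cs <- censor_set_for(spec_nd, r)
      obs$kind[i] <- "censored"
      obs$state[i] <- obs$state[prev]
      obs$censor_set[i] <- paste(spec$states[cs], collapse = "|")
    }
  }
  msm_fit(obs, covariates, spec_nd, ...)
}
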