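## State of each patient at a grid time.  Two interpolation conventions
## for the interval-censored transitions: "midpoint" (a state change
## between consecutive visits is dated at the interval midpoint, the
## conditional mean under within-interval uniformity, which removes the
## first-order lag bias of panel observation) and "carry" (the state of
## the most recent visit).  Death is absorbing and persists; censored
## patients leave the risk set after their censoring time.
patient_state_grid <- function(observations, grid, spec,
                               interpolation = c("midpoint", "carry")) {
  interpolation <- match.arg(interpolation)
  obs <- as.data.frame(observations)
  obs <- obs[order(obs$patient_id, obs$time), , drop = FALSE]
  obs$.st <- match(as.character(obs$state), spec$states)
  ids <- unique(obs$patient_id)
  out <- matrix(NA_integer_, length(ids), length(grid),
                dimnames = list(ids, NULL))
  chunks <- split(seq_len(nrow(obs)), factor(obs$patient_id, levels = ids))
  for (i in seq_along(ids)) {
    o <- obs[chunks[[i]], , drop = FALSE]
    dth <- o$kind == "exact_death"
    death_t <- if (any(dth)) min(o$time[dth]) else Inf
    cns <- o$kind == "censored"
    cens_t <- if (any(cns)) min(o$time[cns]) else
      max(o$time)  # no terminal record: under observation until last visit
    pan <- o[o$kind == "panel", , drop = FALSE]
    step_t <- pan$time; step_s <- pan$.st
    if (interpolation == "midpoint" && nrow(pan) > 1L) {
      chg <- which(diff(pan$.st) != 0)
      step_t <- c(pan$time[1], (pan$time[chg] + pan$time[chg + 1L]) / 2)
      step_s <- c(pan$.st[1], pan$.st[chg + 1L])
    }
    j <- findInterval(grid, step_t)
    row <- ifelse(j >= 1L, step_s[pmax(j, 1L)], NA_integer_)
    row[grid > cens_t] <- NA_integer_
    if (is.finite(death_t) && !is.null(spec$death))
      row[grid >= death_t] <- spec$death
    out[i, ] <- row
  }
  out
}

#' Observed state prevalence over time
#'
#' At each grid time, every patient under observation contributes an
#' estimated current state.  With the default `"midpoint"`
#' interpolation, a state change between two visits is dated at the
#' interval midpoint (the conditional mean of an interval-censored
#' transition time, which avoids the lag bias of pure carry-forward);
#' `"carry"` uses the state of the most recent visit.  Death persists
#' once observed, and censored patients leave the risk set after their
#' censoring time.
#'
#' @param observations Observation records as in [msm_fit()].
#' @param grid Numeric vector of times (years).
#' @param spec An [msm_spec()].
#' @param interpolation `"midpoint"` (default) or `"carry"`.
#' @return Data frame: `time`, `state`, `n`, `observed` (fraction among
#'   patients under observation).
#' @export
observed_prevalence <- function(observations, grid, spec = msm_spec(),
                                interpolation = c("midpoint", "carry")) {
  if (!length(grid)) stop("grid must be nonempty")
  st <- patient_state_grid(observations, grid, spec, match.arg(interpolation))
  out <- expand.grid(time = grid, state = spec$states,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- 0L; out$observed <- NA_real_
  for (g in seq_along(grid)) {
    cnt <- tabulate(st[, g], nbins = length(spec$states))
    tot <- sum(cnt)
    sel <- out$time == grid[g]
    out$n[sel] <- cnt
    out$observed[sel] <- if (tot > 0) cnt / tot else NA_real_
  }
  out
}

#' Model-expected state prevalence over time
#'
#' Averages the fitted transition-probability row of the starting state
#' over the patients still under observation at each grid time,
#' evaluated at each patient's own covariates.
#'
#' @param fit A converged [msm_fit()] result.
#' @param observations The observation records the model was fitted to.
#' @param grid Numeric vector of times (years).
#' @param start Starting state index (default 1, the complication-free
#'   state every patient occupies at index).
#' @return Data frame: `time`, `state`, `expected`.
#' @export
expected_prevalence <- function(fit, observations, grid, start = 1L) {
  if (!length(grid)) stop("grid must be nonempty")
  spec <- fit$spec
  st <- patient_state_grid(observations, grid, spec)
  ids <- rownames(st)
  prof <- fit$prof_of_patient[match(ids, fit$ids)]
  uprof <- sort(unique(prof))
  out <- expand.grid(time = grid, state = spec$states,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$expected <- NA_real_
  # P(t) per unique covariate profile per grid time
  uZ <- fit$Z[match(uprof, fit$prof_of_patient), , drop = FALSE]
  Qs <- lapply(seq_along(uprof), function(k)
    generator_at(fit, if (ncol(uZ)) uZ[k, ] else NULL))
  for (g in seq_along(grid)) {
    rows <- matrix(0, length(uprof), length(spec$states))
    for (k in seq_along(uprof))
      rows[k, ] <- transition_probability(Qs[[k]], grid[g])[start, ]
    inset <- !is.na(st[, g])
    if (!any(inset)) next
    m <- colMeans(rows[match(prof[inset], uprof), , drop = FALSE])
    out$expected[out$time == grid[g]] <- m / sum(m)
  }
  out
}

#' Observed-versus-expected prevalence diagnostic
#'
#' Combines [observed_prevalence()] and [expected_prevalence()] into
#' the standard multistate goodness-of-fit display: if observed and
#' expected fractions track each other per state over time, the fitted
#' intensities are consistent with the raw panel data.
#'
#' @inheritParams expected_prevalence
#' @inheritParams observed_prevalence
#' @param grid Time grid; default 0 to 7 years by 0.5.
#' @return Data frame: `time`, `state`, `n`, `observed`, `expected`.
#' @export
prevalence_table <- function(fit, observations, grid = seq(0, 7, by = 0.5),
                             interpolation = c("midpoint", "carry")) {
  obs <- observed_prevalence(observations, grid, fit$spec,
                             match.arg(interpolation))
  exp <- expected_prevalence(fit, observations, grid)
  merge(obs, exp, by = c("time", "state"), sort = FALSE)
}

#' Plot observed versus expected prevalence
#'
#' One panel per state; observed fractions as a solid line with points,
#' model-expected fractions dashed.
#'
#' @param x A [msm_fit()] result.
#' @param observations Observation records used for the fit.
#' @param grid Time grid in years.
#' @param ... Unused.
#' @return Invisibly, the [prevalence_table()].
#' @export
plot.dmpath_fit <- function(x, observations, grid = seq(0, 7, by = 0.5), ...) {
  tab <- prevalence_table(x, observations, grid)
  states <- x$spec$states
  op <- graphics::par(mfrow = c(2, ceiling(length(states) / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in states) {
    d <- tab[tab$state == s, ]
    graphics::plot(d$time, d$observed, type = "b", pch = 16, ylim = c(0, 1),
                   xlab = "years since index", ylab = "prevalence", main = s)
    graphics::lines(d$time, d$expected, lty = 2)
  }
  invisible(tab)
}
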