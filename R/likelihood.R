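## Internal: turn observation records + covariates + spec into the flat
## interval structures consumed by the C++ likelihood kernel.

OBS_KINDS <- c("panel", "exact_death", "censored")

validate_observations <- function(observations, spec) {
  req <- c("patient_id", "time", "state", "kind")
  miss <- setdiff(req, names(observations))
  if (length(miss)) stop("observations lack column(s): ", paste(miss, collapse = ", "))
  st <- match(as.character(observations$state), spec$states)
  if (anyNA(st))
    stop("unknown state value(s): ",
         paste(unique(observations$state[is.na(st)]), collapse = ", "))
  kind <- as.character(observations$kind)
  if (!all(kind %in% OBS_KINDS))
    stop("kind must be one of: ", paste(OBS_KINDS, collapse = ", "))
  if (any(kind == "exact_death") &&
      (is.null(spec$death) || any(st[kind == "exact_death"] != spec$death)))
    stop("exact_death records must be in the exactly-observed absorbing state")
  invisible(st)
}

parse_censor_set <- function(x, spec) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  s <- match(strsplit(x, "|", fixed = TRUE)[[1]], spec$states)
  if (anyNA(s)) stop("unknown state in censor_set: ", x)
  s
}

prepare_msm_data <- function(observations, covariates, spec) {
  observations <- as.data.frame(observations)
  st <- validate_observations(observations, spec)
  observations$.state_idx <- st
  o <- order(observations$patient_id, observations$time)
  observations <- observations[o, , drop = FALSE]
  if (is.null(observations$censor_set)) observations$censor_set <- NA_character_

  reach <- reachable_matrix(spec)
  ids <- unique(observations$patient_id)

  # covariate design, factors expanded to dummies.  A "time" column in
  # the covariate table switches on time-varying mode: each observation
  # interval uses the patient's most recent covariate row at or before
  # the interval's left endpoint (carry-forward), while predictions and
  # summaries use the baseline (earliest) row.
  vars <- unique(unlist(spec$covariates))
  tv <- FALSE
  if (length(vars)) {
    if (is.null(covariates)) stop("spec has covariates but none were supplied")
    cov_all <- as.data.frame(covariates)
    if (!"patient_id" %in% names(cov_all)) stop("covariates need a patient_id column")
    miss <- setdiff(vars, names(cov_all))
    if (length(miss)) stop("covariates lack column(s): ", paste(miss, collapse = ", "))
    tv <- "time" %in% names(cov_all)
    if (tv) cov_all <- cov_all[order(cov_all$patient_id, cov_all$time), , drop = FALSE]
    if (!all(ids %in% cov_all$patient_id)) stop("covariates missing for some patients")
    blocks <- list(); var_cols <- list(); col_type <- character(0)
    for (v in vars) {
      x <- cov_all[[v]]
      if (anyNA(x)) stop("covariate '", v, "' has missing values; impute first")
      if (is.character(x)) x <- factor(x)
      if (is.factor(x)) {
        mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
        colnames(mm) <- paste0(v, levels(x)[-1])
        col_type <- c(col_type, rep("dummy", ncol(mm)))
      } else {
        mm <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, v))
        col_type <- c(col_type, "continuous")
      }
      var_cols[[v]] <- colnames(mm)
      blocks[[v]] <- mm
    }
    Zall <- do.call(cbind, blocks)
    rownames(Zall) <- NULL
    # baseline row per patient (earliest when time-varying)
    bidx <- match(ids, cov_all$patient_id)
    Zfull <- Zall[bidx, , drop = FALSE]
  } else {
    Zall <- Zfull <- matrix(numeric(0), nrow = length(ids), ncol = 0)
    var_cols <- list(); col_type <- character(0)
  }

  # parameter layout: log-baselines first, then betas per transition
  ntrans <- nrow(spec$transitions)
  beta_trans <- integer(0); beta_col <- integer(0); beta_names <- character(0)
  beta_var <- character(0)
  for (t in seq_len(ntrans)) {
    for (v in spec$covariates[[t]]) {
      cols <- var_cols[[v]]
      for (cn in cols) {
        beta_trans <- c(beta_trans, t - 1L)
        beta_col <- c(beta_col, match(cn, colnames(Zfull)) - 1L)
        beta_names <- c(beta_names, paste0(spec$labels[t], ":", cn))
        beta_var <- c(beta_var, v)
      }
    }
  }
  par_names <- c(paste0("logq(", spec$labels, ")"), beta_names)

  # unique baseline profiles (used by predictions and diagnostics)
  if (ncol(Zfull) > 0) {
    key <- apply(Zfull, 1, paste, collapse = "\r")
    prof_of_patient <- match(key, key[!duplicated(key)])
  } else {
    prof_of_patient <- rep(1L, length(ids))
  }

  # intervals between consecutive records per patient
  pid <- observations$patient_id
  idx_pat <- match(pid, ids)
  nrec <- nrow(observations)
  same <- idx_pat[-nrec] == idx_pat[-1]
  i0 <- which(same); i1 <- i0 + 1L
  from <- observations$.state_idx[i0]
  tost <- observations$.state_idx[i1]
  kind1 <- as.character(observations$kind[i1])
  kind0 <- as.character(observations$kind[i0])
  if (any(kind0 != "panel"))
    stop("only panel records may be followed by further records (patient ",
         pid[i0[which(kind0 != "panel")[1]]], ")")
  dt <- observations$time[i1] - observations$time[i0]
  if (any(dt < 0)) stop("observation times must be nondecreasing within patient")

  type <- integer(length(i0))
  cmask <- integer(length(i0))
  iv_to <- rep(-1L, length(i0))
  forward_ok <- TRUE
  for (j in seq_along(i0)) {
    if (kind1[j] == "panel") {
      type[j] <- 0L
      iv_to[j] <- tost[j] - 1L
      if (!reach[from[j], tost[j]]) forward_ok <- FALSE
    } else if (kind1[j] == "exact_death") {
      type[j] <- 1L
    } else {
      type[j] <- 2L
      cs <- parse_censor_set(observations$censor_set[i1[j]], spec)
      if (!length(cs)) cs <- censor_set_for(spec, from[j])
      cmask[j] <- sum(bitwShiftL(1L, cs - 1L))
    }
  }
  # zero-length same-state panel pairs contribute log P[r,r](0) = 0
  keep <- !(dt == 0 & type == 0L & (from - 1L) == iv_to)
  j0 <- i0[keep]

  # covariate profile per interval
  if (ncol(Zall) == 0L) {
    Z <- matrix(numeric(0), nrow = 1, ncol = 0)
    iv_prof <- rep(0L, length(j0))
  } else {
    if (!tv) {
      Ziv <- Zfull[idx_pat[j0], , drop = FALSE]
    } else {
      rows_of <- split(seq_len(nrow(cov_all)),
                       factor(cov_all$patient_id, levels = ids))
      pick <- integer(length(j0))
      for (k in seq_along(j0)) {
        rws <- rows_of[[idx_pat[j0[k]]]]
        at <- findInterval(observations$time[j0[k]], cov_all$time[rws])
        pick[k] <- rws[max(at, 1L)]
      }
      Ziv <- Zall[pick, , drop = FALSE]
    }
    ivkey <- apply(Ziv, 1, paste, collapse = "\r")
    uk <- !duplicated(ivkey)
    Z <- Ziv[uk, , drop = FALSE]
    iv_prof <- match(ivkey, ivkey[uk]) - 1L
  }

  list(spec = spec, ids = ids, Z = Z, Zfull = Zfull,
       prof_of_patient = prof_of_patient, time_varying = tv,
       var_cols = var_cols, col_type = col_type,
       beta_trans = beta_trans, beta_col = beta_col, beta_var = beta_var,
       par_names = par_names, npar = ntrans + length(beta_trans),
       forward_ok = forward_ok,
       iv = list(prof = iv_prof,
                 from = from[keep] - 1L, dt = dt[keep], type = type[keep],
                 to = iv_to[keep], cmask = cmask[keep]),
       nobs = nrec, nintervals = sum(keep))
}

msm_loglik_cpp <- function(theta, prep, want_grad = FALSE) {
  cpp_panel_loglik(theta, length(prep$spec$states),
                   prep$spec$transitions[, 1] - 1L, prep$spec$transitions[, 2] - 1L,
                   as.integer(prep$beta_trans), as.integer(prep$beta_col),
                   prep$Z,
                   as.integer(prep$iv$prof), as.integer(prep$iv$from),
                   as.numeric(prep$iv$dt), as.integer(prep$iv$type),
                   as.integer(prep$iv$to), as.integer(prep$iv$cmask),
                   if (is.null(prep$spec$death)) -1L else prep$spec$death - 1L,
                   want_grad)
}

#' Panel-data log-likelihood of a progressive multistate model
#'
#' Computes the intermittent-observation (panel) log-likelihood: for
#' each consecutive pair of records of a patient, a panel observation
#' contributes `log P[r,s](dt)`, an exactly observed death contributes
#' `log sum_k P[r,k](dt) * q[k,Death]` (the state just before death is
#' unknown), and a state-level-censored record contributes
#' `log sum_{s in censor_set} P[r,s](dt)`.
#'
#' @param params Flat parameter vector: one log baseline intensity per
#'   allowed transition (in the order of `spec$labels`), followed by the
#'   covariate coefficients per transition in spec order.
#' @param observations Data frame with columns `patient_id`, `time`
#'   (years), `state`, `kind` (`panel`/`exact_death`/`censored`) and
#'   optionally `censor_set` (state names separated by `|`).
#' @param covariates Data frame with `patient_id` and one row per
#'   patient of baseline covariate values, or `NULL`.
#' @param spec An [msm_spec()].
#' @return The log-likelihood (scalar); `-Inf` when an observed pair is
#'   impossible under the model.
#' @export
panel_loglik <- function(params, observations, covariates = NULL, spec = msm_spec()) {
  if (nrow(as.data.frame(observations)) == 0L) return(0)
  prep <- prepare_msm_data(observations, covariates, spec)
  if (length(params) != prep$npar)
    stop("params has length ", length(params), ", expected ", prep$npar)
  msm_loglik_cpp(as.numeric(params), prep)$loglik
}
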