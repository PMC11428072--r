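#' The five-state diabetes complication state space
#'
#' Ordered state labels for the progressive complication model: diabetes
#' with no complication (`DM`), first microvascular complication
#' (`Micro`), first macrovascular complication (`Macro`), both types of
#' complication (`Both`), and the absorbing `Death` state.
#'
#' @return Character vector of length 5.
#' @export
dm_states <- function() c("DM", "Micro", "Macro", "Both", "Death")

#' Allowed transitions of the progressive complication model
#'
#' The model is progressive: a patient moves forward only, one
#' complication at a time, and death is reachable from every living
#' state.  A direct jump from `DM` to `Both` is not allowed; recovery
#' transitions are not allowed.
#'
#' @return Integer matrix with columns `from`, `to` (state indices into
#'   [dm_states()]), one row per allowed transition.
#' @export
dm_transitions <- function() {
  m <- rbind(
    c(1L, 2L), # DM    -> Micro
    c(1L, 3L), # DM    -> Macro
    c(1L, 5L), # DM    -> Death
    c(2L, 4L), # Micro -> Both
    c(2L, 5L), # Micro -> Death
    c(3L, 4L), # Macro -> Both
    c(3L, 5L), # Macro -> Death
    c(4L, 5L)  # Both  -> Death
  )
  colnames(m) <- c("from", "to")
  m
}

transition_labels <- function(states, transitions) {
  paste0(states[transitions[, 1]], "->", states[transitions[, 2]])
}

#' Specify a progressive multistate transition model
#'
#' Defines the state space, the set of allowed transitions and, per
#' transition, the covariates whose proportional effects on the
#' transition intensity are to be estimated.  States must be ordered so
#' that every allowed transition moves to a strictly later state
#' (progressive / forward-only structure).
#'
#' @param states Ordered character vector of state names.
#' @param transitions Two-column integer matrix of allowed `(from, to)`
#'   state indices, each with `from < to`.
#' @param death Name of the exactly-observed absorbing state, or `NULL`
#'   if no state is observed exactly.  Defaults to `"Death"` when
#'   present among `states`.
#' @param covariates Covariate specification: `NULL` (no covariates), a
#'   character vector of covariate names applied to every transition, or
#'   a named list mapping transition labels (e.g. `"DM->Micro"`) to
#'   character vectors of covariate names.  Different transitions may
#'   use different covariate sets.
#' @return An object of class `"msm_spec"`.
#' @examples
#' msm_spec()                                  # covariate-free 5-state model
#' msm_spec(covariates = c("age", "female"))   # same covariates everywhere
#' msm_spec(covariates = list("DM->Micro" = "adi_cat"))
#' @export
msm_spec <- function(states = dm_states(), transitions = dm_transitions(),
                     death = if ("Death" %in% states) "Death" else NULL,
                     covariates = NULL) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicated state names")
  transitions <- matrix(as.integer(transitions), ncol = 2,
                        dimnames = list(NULL, c("from", "to")))
  if (nrow(transitions) < 1L) stop("at least one allowed transition is required")
  if (any(transitions < 1L) || any(transitions > length(states)))
    stop("transition indices out of range")
  if (any(transitions[, 1] >= transitions[, 2]))
    stop("model must be progressive: every transition needs from < to in state order")
  if (anyDuplicated(transitions)) stop("duplicated transitions")
  labs <- transition_labels(states, transitions)

  death_idx <- NULL
  if (!is.null(death)) {
    death_idx <- match(death, states)
    if (is.na(death_idx)) stop("death state '", death, "' not among states")
    if (any(transitions[, 1] == death_idx))
      stop("the exactly-observed absorbing state cannot have exit transitions")
  }

  cov_list <- stats::setNames(rep(list(character(0)), length(labs)), labs)
  if (!is.null(covariates)) {
    if (is.character(covariates)) {
      cov_list[] <- list(covariates)
    } else if (is.list(covariates)) {
      bad <- setdiff(names(covariates), labs)
      if (length(bad)) stop("unknown transition label(s): ", paste(bad, collapse = ", "))
      for (nm in names(covariates)) cov_list[[nm]] <- as.character(covariates[[nm]])
    } else stop("covariates must be NULL, a character vector, or a named list")
  }

  structure(list(states = states, transitions = transitions, labels = labs,
                 death = death_idx, covariates = cov_list),
            class = "msm_spec")
}

#' @export
print.msm_spec <- function(x, ...) {
  cat("Progressive multistate model specification\n")
  cat("States:", paste(x$states, collapse = " < "), "\n")
  cat("Transitions:\n")
  for (i in seq_along(x$labels)) {
    covs <- x$covariates[[i]]
    cat("  ", format(x$labels[i], width = 14),
        if (length(covs)) paste("~", paste(covs, collapse = " + ")) else "(baseline only)",
        "\n")
  }
  if (!is.null(x$death)) cat("Exactly observed absorbing state:", x$states[x$death], "\n")
  invisible(x)
}

## Reachability closure of the transition mask (includes staying put).
reachable_matrix <- function(spec) {
  n <- length(spec$states)
  A <- diag(n) > 0
  for (i in seq_len(nrow(spec$transitions)))
    A[spec$transitions[i, 1], spec$transitions[i, 2]] <- TRUE
  # Floyd-Warshall transitive closure (n is tiny)
  for (k in seq_len(n)) for (i in seq_len(n)) if (A[i, k]) A[i, ] <- A[i, ] | A[k, ]
  A
}

## Forward-reachable non-death states from state r, including r itself.
censor_set_for <- function(spec, r) {
  A <- reachable_matrix(spec)
  s <- which(A[r, ])
  if (!is.null(spec$death)) s <- setdiff(s, spec$death)
  s
}
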