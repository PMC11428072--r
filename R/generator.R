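#' Build a transition intensity (generator) matrix
#'
#' Assembles the generator matrix Q of a continuous-time Markov chain
#' from baseline transition intensities and, optionally,
#' proportional-intensity covariate effects: for an allowed transition
#' r -> s, `q_rs(z) = q0_rs * exp(sum_k beta_rs,k * z_k)`.  Off-diagonal
#' entries outside the allowed-transition mask are exactly zero and each
#' diagonal equals minus its row sum, so rows sum to zero.
#'
#' @param rates Named numeric vector of baseline intensities (per
#'   person-year), named by transition label (e.g. `"DM->Micro"`).
#'   Transitions not named get intensity 0.
#' @param betas Optional named list mapping transition labels to named
#'   numeric vectors of log-hazard-ratio coefficients.
#' @param z Optional named numeric vector of covariate values; required
#'   when `betas` is given.
#' @param spec An [msm_spec()] defining states and allowed transitions.
#' @return A square numeric matrix with state dimnames and attribute
#'   `"mask"` (logical matrix of allowed transitions).
#' @examples
#' Q <- build_generator(c("DM->Micro" = 0.1334, "DM->Macro" = 0.0508))
#' rowSums(Q)   # all zero
#' @export
build_generator <- function(rates, betas = NULL, z = NULL, spec = msm_spec()) {
  n <- length(spec$states)
  labs <- spec$labels
  if (is.null(names(rates))) {
    if (length(rates) != length(labs))
      stop("unnamed 'rates' must have one entry per allowed transition")
    names(rates) <- labs
  }
  bad <- setdiff(names(rates), labs)
  if (length(bad)) stop("unknown transition label(s): ", paste(bad, collapse = ", "))
  if (any(rates < 0)) stop("baseline intensities must be nonnegative")

  q <- stats::setNames(numeric(length(labs)), labs)
  q[names(rates)] <- rates
  if (!is.null(betas)) {
    bad <- setdiff(names(betas), labs)
    if (length(bad)) stop("unknown transition label(s) in betas: ", paste(bad, collapse = ", "))
    for (lab in names(betas)) {
      b <- betas[[lab]]
      if (is.null(names(b)) || is.null(z) || !all(names(b) %in% names(z)))
        stop("betas require a named covariate vector z covering ", lab)
      q[lab] <- q[lab] * exp(sum(b * z[names(b)]))
    }
  }
  if (any(!is.finite(q)))
    stop("non-finite intensity for transition(s): ",
         paste(names(q)[!is.finite(q)], collapse = ", "))

  Q <- matrix(0, n, n, dimnames = list(spec$states, spec$states))
  mask <- matrix(FALSE, n, n, dimnames = dimnames(Q))
  for (i in seq_along(labs)) {
    r <- spec$transitions[i, 1]; s <- spec$transitions[i, 2]
    Q[r, s] <- q[i]
    mask[r, s] <- TRUE
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "mask") <- mask
  Q
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' @param Q Generator matrix (nonnegative off-diagonals, zero row sums),
#'   e.g. from [build_generator()].
#' @param t Nonnegative time horizon (years).
#' @return Square matrix of transition probabilities; rows sum to 1.
#' @examples
#' Q <- build_generator(c("DM->Micro" = 0.1334, "DM->Macro" = 0.0508,
#'                        "DM->Death" = 0.003))
#' transition_probability(Q, 1)["DM", ]
#' @export
transition_probability <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single nonnegative number")
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  if (max(abs(rowSums(Q))) > 1e-8 * max(1, max(abs(Q))))
    stop("rows of Q must sum to zero")
  if (any(Q[row(Q) != col(Q)] < -1e-12)) stop("off-diagonal intensities must be nonnegative")
  P <- as.matrix(Matrix::expm(Q * t))
  # clip roundoff outside [0, 1]
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Calibrate death intensities to a target death-probability column
#'
#' Given the four forward complication intensities of the five-state
#' progressive model, solves the four death intensities (one per living
#' state) by one-dimensional root finding so that the matrix exponential
#' `exp(t*Q)` reproduces a stated death-column probability for each
#' living state at horizon `t`.  Rows are solved in reverse topological
#' order (`Both`, then `Micro` and `Macro`, then `DM`), so each solve is
#' a genuine 1-D problem.
#'
#' @param forward Named numeric vector of the four forward intensities
#'   (`DM->Micro`, `DM->Macro`, `Micro->Both`, `Macro->Both`).
#' @param death_probs Numeric vector of length 4 with target
#'   `P(t)[r, Death]` for r = DM, Micro, Macro, Both (probabilities, not
#'   percent).
#' @param t Horizon in years at which the death column is matched.
#' @param spec An [msm_spec()]; must be the standard 5-state model.
#' @return Named numeric vector over all 8 transitions, the four forward
#'   rates plus the four calibrated death intensities.
#' @export
calibrate_death_intensities <- function(forward, death_probs, t = 1,
                                        spec = msm_spec()) {
  stopifnot(length(death_probs) == 4L, all(death_probs >= 0), all(death_probs < 1))
  states <- spec$states
  death_labs <- paste0(states[1:4], "->", states[5])
  rates <- stats::setNames(numeric(length(spec$labels)), spec$labels)
  rates[names(forward)] <- forward
  # reverse topological order: a row's death-column entry depends only on
  # its own death rate and on rows of later states
  for (r in c(4L, 2L, 3L, 1L)) {
    lab <- death_labs[r]
    f <- function(q) {
      rr <- rates; rr[lab] <- q
      transition_probability(build_generator(rr, spec = spec), t)[r, 5] - death_probs[r]
    }
    sol <- stats::uniroot(f, c(0, 1), tol = 1e-13, extendInt = "upX")
    rates[lab] <- sol$root
  }
  rates
}
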