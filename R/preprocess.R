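#' Multiple imputation by chained equations
#'
#' Imputes missing baseline values by iteratively cycling through the
#' incomplete variables, fitting a conditional model for each on the
#' currently completed data and replacing its missing cells by draws
#' from that model: linear regression with residual noise for
#' continuous variables, logistic regression for binary variables, and
#' polytomous (multinomial) logistic regression for categorical
#' variables.  Missing cells are initialized by random draws from the
#' observed marginals; the stopping criterion is a fixed number of
#' cycles.  `m` completed datasets are produced and the one deviating
#' least from the observed-data means is flagged: the deviation score is
#' the sum over imputed variables of `|mean_imputed - mean_observed| /
#' sd_observed` (per-level absolute proportion differences for
#' categorical variables).
#'
#' Observed cells are never altered.  A variable that is 100% missing
#' is an error; a conditional fit that fails falls back to a marginal
#' draw with a warning.
#'
#' @param data Data frame; columns of class numeric, factor/character,
#'   or binary (0/1 or two-level factor).  Non-imputation columns (ids)
#'   can be excluded via `exclude`.
#' @param m Number of imputed datasets (default 10).
#' @param maxit Number of chained-equation cycles (default 10).
#' @param seed Seed for reproducible imputation.
#' @param exclude Character vector of columns to carry through
#'   untouched and not use as predictors (e.g. `"patient_id"`).
#' @return List of class `"dmpath_mice"`: `completed` (list of m data
#'   frames), `selected` (index of the least-deviating set), `scores`
#'   (deviation score per set), `missing_fraction` (per variable,
#'   before imputation).
#' @export
mice_impute <- function(data, m = 10, maxit = 10, seed = NULL,
                        exclude = "patient_id") {
  stopifnot(m >= 1, maxit >= 1)
  if (!is.null(seed)) set.seed(seed)
  data <- as.data.frame(data)
  keep_out <- intersect(exclude, names(data))
  work <- data[, setdiff(names(data), keep_out), drop = FALSE]
  for (v in names(work)) if (is.character(work[[v]])) work[[v]] <- factor(work[[v]])

  all_missing <- names(work)[vapply(work, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing))
    stop("variable(s) 100% missing: ", paste(all_missing, collapse = ", "))
  miss_frac <- vapply(work, function(x) mean(is.na(x)), numeric(1))
  targets <- names(work)[miss_frac > 0]

  if (!length(targets)) {
    return(structure(list(completed = rep(list(data), m), selected = 1L,
                          scores = rep(0, m), missing_fraction = miss_frac),
                     class = "dmpath_mice"))
  }

  kind_of <- function(x) {
    if (is.factor(x)) { if (nlevels(x) <= 2L) "binary" else "categorical" }
    else if (length(unique(stats::na.omit(x))) <= 2L) "binary01"
    else "continuous"
  }
  kinds <- vapply(work, kind_of, character(1))

  draw_marginal <- function(x, k) sample(stats::na.omit(x), k, replace = TRUE)

  impute_one <- function() {
    cur <- work
    for (v in targets)
      cur[[v]][is.na(work[[v]])] <- draw_marginal(work[[v]], sum(is.na(work[[v]])))
    for (cycle in seq_len(maxit)) {
      for (v in targets) {
        obs <- !is.na(work[[v]])
        preds <- setdiff(names(work), v)
        df <- cur[, c(v, preds), drop = FALSE]
        fml <- stats::as.formula(paste0("`", v, "` ~ ."))
        newvals <- tryCatch({
          switch(kinds[[v]],
            continuous = {
              fit <- stats::lm(fml, data = df[obs, , drop = FALSE])
              mu <- stats::predict(fit, newdata = df[!obs, , drop = FALSE])
              mu + stats::rnorm(sum(!obs), 0, summary(fit)$sigma)
            },
            binary01 = {
              fit <- suppressWarnings(
                stats::glm(fml, data = df[obs, , drop = FALSE], family = stats::binomial()))
              pr <- stats::predict(fit, newdata = df[!obs, , drop = FALSE],
                                   type = "response")
              stats::rbinom(sum(!obs), 1, pr)
            },
            binary = {
              fit <- suppressWarnings(
                stats::glm(fml, data = df[obs, , drop = FALSE], family = stats::binomial()))
              pr <- stats::predict(fit, newdata = df[!obs, , drop = FALSE],
                                   type = "response")
              levels(work[[v]])[1 + stats::rbinom(sum(!obs), 1, pr)]
            },
            categorical = {
              fit <- nnet::multinom(fml, data = df[obs, , drop = FALSE],
                                    trace = FALSE)
              pr <- stats::predict(fit, newdata = df[!obs, , drop = FALSE],
                                   type = "probs")
              if (is.null(dim(pr))) pr <- matrix(pr, nrow = sum(!obs))
              apply(pr, 1, function(p) sample(colnames(pr), 1, prob = p))
            })
        }, error = function(e) {
          warning("conditional model for '", v, "' failed (", conditionMessage(e),
                  "); falling back to a marginal draw", call. = FALSE)
          draw_marginal(work[[v]], sum(!obs))
        })
        cur[[v]][!obs] <- newvals
      }
    }
    cur
  }

  completed <- vector("list", m)
  for (i in seq_len(m)) completed[[i]] <- impute_one()

  # deviation of each completed set from the observed-data means
  score_one <- function(cur) {
    s <- 0
    for (v in targets) {
      xo <- stats::na.omit(work[[v]]); xi <- cur[[v]]
      if (is.factor(work[[v]])) {
        po <- prop.table(table(factor(xo, levels = levels(work[[v]]))))
        pi <- prop.table(table(factor(xi, levels = levels(work[[v]]))))
        s <- s + sum(abs(pi - po))
      } else {
        sdo <- stats::sd(xo); if (!is.finite(sdo) || sdo == 0) sdo <- 1
        s <- s + abs(mean(xi) - mean(xo)) / sdo
      }
    }
    s
  }
  scores <- vapply(completed, score_one, numeric(1))

  reattach <- function(cur) {
    for (v in keep_out) cur[[v]] <- data[[v]]
    cur[, names(data), drop = FALSE]
  }
  structure(list(completed = lapply(completed, reattach),
                 selected = which.min(scores), scores = scores,
                 missing_fraction = miss_frac),
            class = "dmpath_mice")
}

#' @export
print.dmpath_mice <- function(x, ...) {
  cat("Chained-equations imputation:", length(x$completed), "completed sets\n")
  cat("Selected set:", x$selected,
      sprintf("(deviation score %.4f)\n", x$scores[x$selected]))
  mf <- x$missing_fraction[x$missing_fraction > 0]
  if (length(mf)) {
    cat("Missing fractions before imputation:\n")
    print(round(mf, 3))
  }
  invisible(x)
}

#' Last observation carried forward
#'
#' Replaces each missing value in a time-ordered series by the most
#' recent observed value.  Leading missing values are left untouched
#' (they belong to baseline imputation, not follow-up carry-forward).
#'
#' @param x Vector ordered by time.
#' @return `x` with interior/trailing missing values filled.
#' @examples
#' locf(c(5, NA, NA, 7))   # 5 5 5 7
#' locf(c(NA, 4, NA))      # NA 4 4
#' @export
locf <- function(x) {
  obs <- which(!is.na(x))
  if (!length(obs)) return(x)
  idx <- findInterval(seq_along(x), obs)
  out <- x
  fill <- idx >= 1L
  out[fill] <- x[obs[idx[fill]]]
  out
}

#' Cluster ADI deciles into five paired categories
#'
#' The area deprivation index ranks census block groups from 1 (least
#' disadvantaged) to 10 (most disadvantaged); deciles are clustered
#' into five categories of two, with `"1-2"` (least disadvantaged) the
#' reference category.
#'
#' @param decile Integer vector with values in 1..10.
#' @return Factor with levels `"1-2"`, `"3-4"`, `"5-6"`, `"7-8"`,
#'   `"9-10"`; `NA` inputs stay `NA`.
#' @export
cluster_adi <- function(decile) {
  ok <- is.na(decile) | (decile %in% 1:10)
  if (!all(ok)) stop("ADI decile out of range 1..10: ",
                     paste(unique(decile[!ok]), collapse = ", "))
  labs <- c("1-2", "3-4", "5-6", "7-8", "9-10")
  factor(labs[ceiling(decile / 2)], levels = labs)
}
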