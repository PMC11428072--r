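test_that("LOCF fills from the most recent observed value only", {
  expect_equal(locf(c(5, NA, NA, 7)), c(5, 5, 5, 7))
  expect_equal(locf(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(locf(c(NA, 4, NA)), c(NA, 4, 4))
  expect_equal(locf(c(NA, NA)), c(NA, NA))
  # idempotent
  x <- c(NA, 3, NA, NA, 9, NA)
  expect_identical(locf(locf(x)), locf(x))
})

test_that("ADI deciles cluster into five paired categories", {
  expect_equal(as.character(cluster_adi(1:10)),
               rep(c("1-2", "3-4", "5-6", "7-8", "9-10"), each = 2))
  expect_identical(levels(cluster_adi(1)),
                   c("1-2", "3-4", "5-6", "7-8", "9-10"))
  expect_identical(levels(cluster_adi(1))[1], "1-2")  # reference category
  expect_true(is.na(cluster_adi(NA)))
  expect_error(cluster_adi(11), "out of range")
  expect_error(cluster_adi(0), "out of range")
})

test_that("imputation of a complete table returns m identical copies", {
  df <- data.frame(a = rnorm(50), b = rbinom(50, 1, 0.5))
  out <- mice_impute(df, m = 3, seed = 1)
  expect_length(out$completed, 3)
  for (k in 1:3) expect_identical(out$completed[[k]], df)
  expect_equal(out$selected, 1L)
})

test_that("chained equations recover a correlated margin under MCAR", {
  set.seed(417)
  n <- 2000; rho <- 0.8
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  miss <- runif(n) < 0.3
  df <- data.frame(x = x, y = ifelse(miss, NA, y))
  out <- mice_impute(df, m = 10, maxit = 10, seed = 2, exclude = character(0))
  expect_length(out$completed, 10)            # exactly m sets
  sel <- out$completed[[out$selected]]
  # observed cells never altered
  expect_identical(sel$y[!miss], df$y[!miss])
  expect_identical(sel$x, df$x)
  # imputed-variable mean within 3 SEs of the complete-data mean
  expect_lt(abs(mean(sel$y) - mean(y)), 3 / sqrt(n))
  # imputations preserve the cross-correlation to within 0.1
  expect_lt(abs(stats::cor(sel$x, sel$y) - rho), 0.1)
  # deviation-score selection is deterministic given the sets
  expect_equal(out$selected, which.min(out$scores))
})

test_that("binary and categorical variables are imputed on their own scales", {
  set.seed(418)
  n <- 600
  x <- rnorm(n)
  b <- rbinom(n, 1, plogis(x))
  g <- factor(sample(c("lo", "mid", "hi"), n, replace = TRUE))
  df <- data.frame(x = x, b = b, g = g)
  df$b[runif(n) < 0.25] <- NA
  df$g[runif(n) < 0.25] <- NA
  out <- mice_impute(df, m = 2, maxit = 3, seed = 3, exclude = character(0))
  sel <- out$completed[[1]]
  expect_true(all(sel$b %in% 0:1))
  expect_true(all(as.character(sel$g) %in% levels(g)))
  expect_false(anyNA(sel))
})

test_that("a fully missing variable is a named error", {
  df <- data.frame(a = rnorm(10), bad = NA_real_)
  expect_error(mice_impute(df, m = 2, seed = 1), "bad")
})
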