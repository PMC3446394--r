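# Logistic fitting, backward AIC stepwise, bootstrap inclusion and
# finalization.

test_that("logistic coefficient matches the closed-form 2x2 odds ratio", {
  # cases: 30 exposed / 10 unexposed; controls: 10 exposed / 30 unexposed
  x <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  y <- c(rep(1, 40), rep(0, 40))
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "exposed")), y)
  expect_equal(unname(fit$coefficients["exposed"]), log(9), tolerance = 1e-6)
  # AIC is definitional: 2(p+1) - 2 logL at the fitted coefficients
  lp <- fit$coefficients[1] + fit$coefficients[2] * x
  ll <- sum(y * lp - log(1 + exp(lp)))
  expect_equal(fit$aic, 2 * 2 - 2 * ll, tolerance = 1e-6)
})

test_that("logistic fit agrees with stats::glm", {
  set.seed(10)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0, 0.2)))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("Wald CIs cover the true coefficient at nominal rate", {
  set.seed(11)
  hits <- 0L
  for (r in 1:100) {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(0.5 + 1.0 * x))
    f <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
    b <- f$coefficients["x"]; s <- f$se["x"]
    if (1.0 >= b - 1.96 * s && 1.0 <= b + 1.96 * s) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("backward AIC search matches exhaustive enumeration at small p", {
  set.seed(12)
  for (r in 1:5) {
    n <- 250
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(n, 1, plogis(1.2 * X[, 1] - 0.9 * X[, 2]))
    res <- stepwise_backward_aic(X, y, screen_k = Inf)
    # greedy backward path enumerated independently with glm
    cur <- colnames(X)
    aic_of <- function(fs) {
      df <- data.frame(y = y, X[, fs, drop = FALSE])
      AIC(glm(y ~ ., data = df, family = binomial()))
    }
    repeat {
      a0 <- aic_of(cur)
      cand <- vapply(seq_along(cur), function(j) aic_of(cur[-j]), numeric(1))
      if (!length(cand) || min(cand) >= a0) break
      cur <- cur[-which.min(cand)]
      if (!length(cur)) break
    }
    expect_setequal(res$selected, cur)
  }
})

test_that("single null feature resolves by AIC against the intercept model", {
  set.seed(13)
  x <- rnorm(1000)
  y <- rbinom(1000, 1, 0.5)
  res <- stepwise_backward_aic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y,
                               screen_k = Inf)
  a_full <- AIC(glm(y ~ x, family = binomial()))
  a_null <- AIC(glm(y ~ 1, family = binomial()))
  expect_identical(length(res$selected), as.integer(a_full < a_null))
})

test_that("a strong predictor survives backward elimination among noise", {
  set.seed(14)
  keptn <- 0L
  for (r in 1:60) {
    n <- 500
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(n, 1, plogis(2 * X[, 1]))
    res <- stepwise_backward_aic(X, y, screen_k = 3)
    if ("f1" %in% res$selected) keptn <- keptn + 1L
  }
  expect_gte(keptn, 57L)   # >= 95%
})

test_that("accepted removals never increase the AIC along the path", {
  set.seed(15)
  X <- matrix(rnorm(300 * 20), 300, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(300, 1, plogis(0.7 * X[, 1]))
  for (k in list(3, Inf)) {
    res <- stepwise_backward_aic(X, y, screen_k = k)
    expect_true(all(diff(res$path$aic) < 0) || nrow(res$path) <= 1)
  }
})

test_that("bootstrap inclusion frequencies are reproducible and well-formed", {
  set.seed(16)
  X <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(150, 1, plogis(X[, 1]))
  cfg <- selection_config(n_bootstrap = 20, seed = 77)
  r1 <- bootstrap_inclusion(X, y, config = cfg)
  r2 <- bootstrap_inclusion(X, y, config = cfg)
  expect_identical(r1$inclusion_freq, r2$inclusion_freq)
  expect_true(all(r1$inclusion_freq >= 0 & r1$inclusion_freq <= 1))
  # B = 1: frequencies are 0 or 1
  r3 <- bootstrap_inclusion(X, y, config = selection_config(n_bootstrap = 1, seed = 5))
  expect_true(all(r3$inclusion_freq %in% c(0, 1)))
})

test_that("planted signals dominate noise in inclusion frequency", {
  set.seed(17)
  n <- 600
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(n, 1, plogis(X[, 1:3] %*% rep(0.8, 3)))
  cfg <- selection_config(n_bootstrap = 50, seed = 21)
  r <- bootstrap_inclusion(X, y, config = cfg)
  sig <- r$inclusion_freq[1:3]
  noise_mean <- mean(r$inclusion_freq[4:20])
  expect_true(all(sig > noise_mean))
})

test_that("finalization applies the frequency and pair rules", {
  set.seed(18)
  n <- 200
  A <- rnorm(n)
  X <- cbind(A = A, B = 0.99 * A + 0.05 * rnorm(n), C = rnorm(n))
  # synthetic selection result: A 0.9, B 0.8, C 0.75
  ret <- matrix(FALSE, 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  ret[1:18, "A"] <- TRUE; ret[1:16, "B"] <- TRUE; ret[1:15, "C"] <- TRUE
  res <- structure(list(inclusion_freq = colMeans(ret), retained = ret),
                   class = "selection_result")
  final <- finalize_selection(res, X)
  expect_identical(final, c("A", "C"))        # B pruned: rho(A,B) > 0.9
  # frequency exactly at threshold is excluded (strict inequality)
  ret2 <- ret; ret2[, ] <- FALSE; ret2[1:14, "C"] <- TRUE  # 0.70 exactly
  res2 <- structure(list(inclusion_freq = colMeans(ret2), retained = ret2),
                    class = "selection_result")
  expect_false("C" %in% finalize_selection(res2, X))
  # uncorrelated features above threshold are all kept
  X3 <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  final3 <- finalize_selection(res, X3)
  expect_identical(final3, c("A", "B", "C"))
})

test_that("substitution rule rescues a vote-split correlated cluster", {
  set.seed(19)
  n <- 200
  A <- rnorm(n)
  X <- cbind(A = A, B = 0.98 * A + 0.08 * rnorm(n), C = rnorm(n))
  # A and B alternate across resamples: each 50%, jointly 100%
  ret <- matrix(FALSE, 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  ret[1:10, "A"] <- TRUE; ret[11:20, "B"] <- TRUE
  res <- structure(list(inclusion_freq = colMeans(ret), retained = ret),
                   class = "selection_result")
  final <- finalize_selection(res, X)
  expect_identical(final, "A")   # cluster survives through its top member
})
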