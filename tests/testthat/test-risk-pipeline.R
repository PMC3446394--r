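# Matched split, preselection, scoring, AUC and evaluation.

fake_subjects <- function(n_sets, ratio = 2) {
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n_sets * (ratio + 1))),
    label = rep(c(rep("case", ratio), "control"), n_sets),
    matched_set_id = rep(sprintf("set%02d", seq_len(n_sets)), each = ratio + 1),
    stringsAsFactors = FALSE)
}

test_that("matched split keeps sets intact and halves them", {
  s <- fake_subjects(10)
  sp <- match_and_split(s, seed = 4)
  expect_length(sp$training_sets, 5)
  expect_length(sp$validation_sets, 5)
  # each side has 10 cases and 5 controls
  expect_identical(sum(s$label[sp$training] == "case"), 10L)
  expect_identical(sum(s$label[sp$training] == "control"), 5L)
  # no subject on both sides, over several seeds
  for (sd in 1:20) {
    sp2 <- match_and_split(s, seed = sd)
    expect_length(intersect(sp2$training, sp2$validation), 0)
    expect_identical(sort(c(sp2$training, sp2$validation)), seq_len(nrow(s)))
    # sets never straddle the split
    expect_length(intersect(s$matched_set_id[sp2$training],
                            s$matched_set_id[sp2$validation]), 0)
  }
  # same seed, same split; odd set count sends the extra set to training
  expect_identical(match_and_split(s, seed = 4)$training, sp$training)
  s2 <- fake_subjects(7)
  sp3 <- match_and_split(s2, seed = 1)
  expect_length(sp3$training_sets, 4)
})

test_that("preselection drops constants and near-duplicates in catalog order", {
  set.seed(20)
  n <- 200
  A <- rnorm(n)
  X <- cbind(f1 = A, f2 = A, f3 = rnorm(n), f4 = rep(2, n))
  kept <- preselect(X, rho = 0.98)
  expect_identical(as.character(kept), c("f1", "f3"))
  expect_setequal(attr(kept, "dropped"), c("f2", "f4"))
  # 50 independent uniforms at n = 200: nothing is dropped and the
  # correlations agree with a rank-based brute force
  U <- matrix(runif(200 * 50), 200, 50,
              dimnames = list(NULL, sprintf("u%02d", 1:50)))
  keptU <- preselect(U, rho = 0.98)
  expect_length(keptU, 50)
  C_pkg <- abs(cor(apply(U, 2, rank)))
  C_orc <- abs(cor(U, method = "spearman"))
  expect_equal(C_pkg, C_orc, tolerance = 1e-12)
})

test_that("scores are inverse-logit on the 0-100 scale", {
  m <- structure(list(features = "x", intercept = 0,
                      coefficients = c(x = 1), center = c(x = 0),
                      scale = c(x = 1)), class = "score_model")
  X <- matrix(c(0, -20, 20), ncol = 1, dimnames = list(NULL, "x"))
  s <- score_subjects(m, X)
  expect_equal(s[1], 50)
  expect_lt(s[2], 1e-3)
  expect_true(all(s >= 0 & s <= 100))
  expect_error(score_subjects(m, matrix(1, 2, 1, dimnames = list(NULL, "z"))),
               "lacks")
})

test_that("AUC equals all-pairs concordance counting", {
  expect_equal(auc_mw(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_mw(rep(5, 10), rep(5, 8)), 0.5)
  set.seed(21)
  for (r in 1:5) {
    ca <- sample(0:20, 50, replace = TRUE)    # ties guaranteed
    co <- sample(0:20, 50, replace = TRUE)
    expect_equal(auc_mw(ca, co), oracle_auc(ca, co))
  }
  expect_error(auc_mw(numeric(0), 1), "nonempty")
})

test_that("evaluation reports OR per SD with scale invariance", {
  set.seed(22)
  n <- 400
  subj <- data.frame(
    label = rep(c("case", "control"), each = n / 2),
    age = rnorm(n, 57, 10), bmi = rnorm(n, 25, 4),
    parity_class = sample(c("0", "1-2", "3+"), n, TRUE),
    family_history = rbinom(n, 1, 0.2) == 1,
    age_ftp = rnorm(n, 25, 4),
    pmd_true = runif(n, 5, 50), stringsAsFactors = FALSE)
  score <- 50 + 8 * (subj$label == "case") + rnorm(n, 0, 10)
  ev <- evaluate_score(score, subj)
  expect_identical(nrow(ev), 4L)
  expect_true(all(ev$ci_lower <= ev$or_per_sd & ev$or_per_sd <= ev$ci_upper))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  # multiplying the score by a positive constant leaves OR per SD unchanged
  ev2 <- evaluate_score(score * 37, subj)
  expect_equal(ev$or_per_sd, ev2$or_per_sd, tolerance = 1e-8)
  # adding an independent covariate barely moves the OR
  expect_lt(abs(log(ev$or_per_sd[ev$model == "age_bmi"]) -
                  log(ev$or_per_sd[ev$model == "unadjusted"])), 0.25)
})

test_that("null scores give nominal Wald coverage for the OR per SD", {
  set.seed(23)
  n <- 600
  covered <- 0L
  for (r in 1:100) {
    subj <- data.frame(label = rep(c("case", "control"), c(400, 200)),
                       stringsAsFactors = FALSE)
    score <- rnorm(n, 50, 10)          # independent of status
    ev <- evaluate_score(score, subj, adjust_sets = list(unadjusted = character(0)))
    if (ev$ci_lower <= 1 && 1 <= ev$ci_upper) covered <- covered + 1L
  }
  expect_gte(covered, 93L)
  expect_lte(covered, 99L)
})

test_that("two-stage selection output is contained in the stage-1 union", {
  set.seed(24)
  n <- 400
  X <- matrix(rnorm(n * 24), n, 24, dimnames = list(NULL, sprintf("g%d.f%02d",
    rep(1:3, each = 8), 1:24)))
  y <- rbinom(n, 1, plogis(1.2 * X[, 1] + 1.0 * X[, 9] - 1.1 * X[, 17]))
  groups <- split(colnames(X), rep(1:3, each = 8))
  cfg <- selection_config(n_bootstrap = 25, seed = 31)
  ts <- select_two_stage(X, y, groups, cfg)
  expect_true(all(ts$final_features %in% ts$stage1_union))
  expect_true(all(ts$stage1_union %in% colnames(X)))
  # disjoint strong group signals: every group's stage-1 set is nonempty
  for (g in 1:3)
    expect_gt(length(ts$stage1[[g]]$selected), 0)
})

test_that("planted features are recovered by the two-stage procedure", {
  set.seed(25)
  hits <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    n <- 500
    X <- matrix(rnorm(n * 16), n, 16,
                dimnames = list(NULL, sprintf("f%02d", 1:16)))
    y <- rbinom(n, 1, plogis(X[, 1] + X[, 9]))
    groups <- list(a = colnames(X)[1:8], b = colnames(X)[9:16])
    cfg <- selection_config(n_bootstrap = 25, seed = r)
    ts <- select_two_stage(X, y, groups, cfg)
    if (all(c("f01", "f09") %in% ts$final_features)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)    # >= 90% of replicates
})

test_that("the pipeline runner tolerates an all-null cohort", {
  set.seed(26)
  subj <- fake_subjects(40)              # 120 subjects
  n <- nrow(subj)
  X <- matrix(rnorm(n * 12), n, 12)
  colnames(X) <- feature_catalog()$feature_id[seq_len(12)]
  ft <- data.frame(subject_id = subj$subject_id, X, check.names = FALSE)
  subj$age <- rnorm(n, 57, 10); subj$bmi <- rnorm(n, 25, 4)
  subj$parity_class <- sample(c("0", "1-2", "3+"), n, TRUE)
  subj$family_history <- rbinom(n, 1, 0.2) == 1
  subj$age_ftp <- rnorm(n, 25, 4); subj$pmd_true <- runif(n, 5, 50)
  res <- suppressWarnings(
    run_texture_risk_pipeline(ft, subj, selection_config(n_bootstrap = 10, seed = 3)))
  expect_true(all(res$validation_scores >= 0 & res$validation_scores <= 100))
  expect_true(all(res$final_features %in% colnames(X)))
  expect_true(is.finite(res$auc))
})
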