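# The statistical analysis: matched training/validation split, Spearman
# correlation preselection, bootstrap stepwise backward AIC logistic
# selection within and across feature groups, Sauerbrei-Schumacher
# finalization (> 70% inclusion frequency, then pruning of > 0.9-correlated
# pairs), 0-100 score construction, and evaluation by validation AUC and
# odds ratio per SD with covariate-adjusted logistic models.

#' Configuration for the bootstrap selection procedure
#'
#' @param n_bootstrap number of bootstrap resamples (study scale: 500;
#'   reduced values are supported for testing — results then carry more
#'   Monte Carlo noise than a full 500-resample run)
#' @param preselect_rho Spearman threshold above which a later catalog
#'   column duplicates an earlier one (default 0.98)
#' @param freq_threshold inclusion-frequency cut, strict (default 0.70)
#' @param pair_rho correlated-pair threshold for finalization (default 0.90)
#' @param screen_k per-step number of deletion candidates confirmed by a
#'   fully converged refit in the stepwise search, preranked by the
#'   shared one-step AIC scores (see [stepwise_backward_aic()]); `Inf`
#'   evaluates every candidate by a converged refit (classical exact
#'   backward search, considerably slower at bootstrap scale)
#' @param seed integer seed for the bootstrap resamples
#' @return a `selection_config` list
#' @export
selection_config <- function(n_bootstrap = 500L, preselect_rho = 0.98,
                             freq_threshold = 0.70, pair_rho = 0.90,
                             screen_k = 3L, seed = 1L) {
  stopifnot(n_bootstrap >= 1L,
            preselect_rho > 0, preselect_rho < 1,
            freq_threshold > 0, freq_threshold < 1,
            pair_rho > 0, pair_rho < 1, screen_k >= 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 preselect_rho = preselect_rho,
                 freq_threshold = freq_threshold,
                 pair_rho = pair_rho, screen_k = screen_k,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Split matched sets into training and validation halves
#'
#' Matched sets — never individual subjects — are randomized 50/50, so
#' every set stays intact on one side. With an odd number of sets the
#' extra set goes to training.
#'
#' @param subjects data.frame with `subject_id` and `matched_set_id`
#' @param seed integer seed
#' @return list with `training` and `validation` (row indices into
#'   `subjects`) and `training_sets` / `validation_sets`
#' @export
match_and_split <- function(subjects, seed = 1L) {
  sets <- unique(subjects$matched_set_id)
  if (length(sets) < 2L) stop("need at least two matched sets to split")
  perm <- with_seed(derive_seed(seed, "split"), sample(sets))
  n_train <- ceiling(length(sets) / 2)
  tr_sets <- perm[seq_len(n_train)]
  list(training = which(subjects$matched_set_id %in% tr_sets),
       validation = which(!subjects$matched_set_id %in% tr_sets),
       training_sets = sort(tr_sets),
       validation_sets = sort(setdiff(sets, tr_sets)))
}

#' Preselect features by dropping near-duplicates
#'
#' Zero-variance columns are dropped first; then, walking the catalog
#' order, a later column is dropped if its absolute Spearman correlation
#' with any retained earlier column exceeds `rho`.
#'
#' @param X numeric matrix (subjects x features) with feature-id colnames
#' @param rho Spearman threshold (strict), default 0.98
#' @return character vector of retained feature ids, with attribute
#'   `dropped` naming the excluded ones
#' @export
preselect <- function(X, rho = 0.98) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  sds <- apply(X, 2, stats::sd)
  nonconst <- sds > 1e-10
  Xr <- apply(X[, nonconst, drop = FALSE], 2, rank)
  C <- abs(stats::cor(Xr))
  ids <- colnames(X)[nonconst]
  keep <- logical(length(ids))
  for (j in seq_along(ids)) {
    keep[j] <- !any(C[j, seq_len(j - 1)][keep[seq_len(j - 1)]] > rho)
  }
  retained <- ids[keep]
  attr(retained, "dropped") <- setdiff(colnames(X), retained)
  retained
}

#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around the package's IRLS fitter. `X` must not contain an
#' intercept column (one is added). Non-convergence and (quasi-)separation
#' are flagged, not silently ignored.
#'
#' @param X numeric matrix (n x p) of predictors
#' @param y 0/1 response vector
#' @param beta_start optional warm-start coefficients (length p + 1)
#' @return list with `coefficients` (intercept first), `se`, `loglik`,
#'   `aic`, `converged`, `separated`
#' @export
fit_logistic <- function(X, y, beta_start = NULL) {
  X1 <- cbind(`(Intercept)` = 1, X)
  stopifnot(nrow(X1) == length(y), all(y %in% c(0, 1)))
  fit <- logit_fit_cpp(X1, as.numeric(y), beta_start)
  names(fit$coefficients) <- colnames(X1)
  names(fit$se) <- colnames(X1)
  fit
}

#' Stepwise backward model selection by AIC
#'
#' Starting from the given feature set, repeatedly removes the single
#' feature whose removal most reduces the AIC and stops when no removal
#' reduces it. With finite `screen_k`, all candidate deletions are scored
#' each step by a one-step Newton downdate of the current fit (whose
#' evaluated likelihood can only understate the candidate model's
#' maximum, so candidate AICs are never understated) and the best
#' `screen_k` are confirmed by fully converged refits; every accepted
#' step strictly reduces the true AIC. `screen_k = Inf` evaluates every
#' candidate with a converged refit — the classical exact backward
#' search.
#'
#' @param X numeric matrix with named columns
#' @param y 0/1 response
#' @param start character vector of starting features (default: all)
#' @param screen_k candidate screening size (default `Inf`)
#' @return list with `selected` (features, in `start` order), `aic`,
#'   `path` (data.frame of removals)
#' @export
stepwise_backward_aic <- function(X, y, start = colnames(X), screen_k = Inf) {
  stopifnot(length(start) >= 1L, all(start %in% colnames(X)))
  Xs <- X[, start, drop = FALSE]
  exact <- !is.finite(screen_k)
  res <- backward_aic_cpp(Xs, as.numeric(y), exact = exact,
                          refit_tries = if (exact) 1L else as.integer(screen_k))
  list(selected = start[sort(res$selected)],
       aic = res$aic,
       path = data.frame(removed = start[res$removed], aic = res$aic_path,
                         stringsAsFactors = FALSE))
}

#' Bootstrap inclusion frequencies of a stepwise-selected model
#'
#' Draws `n_bootstrap` resamples of subjects (with replacement, same size
#' as the training set), runs the stepwise backward AIC search on each,
#' and records the fraction of resamples in which every feature is
#' retained. Resamples whose search fails are logged and counted; more
#' than 10% failures is an error. Reproducible given `config$seed`.
#'
#' @param X training feature matrix (named columns)
#' @param y 0/1 response
#' @param features starting feature set (e.g. one catalog group)
#' @param config a [selection_config()]
#' @return a `selection_result`: list with `inclusion_freq` (named),
#'   `n_bootstrap`, `n_failed`
#' @export
bootstrap_inclusion <- function(X, y, features = colnames(X), config = selection_config()) {
  stopifnot(all(features %in% colnames(X)))
  B <- config$n_bootstrap
  n <- nrow(X)
  retained <- matrix(FALSE, B, length(features),
                     dimnames = list(NULL, features))
  failed <- logical(B)
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(config$seed, "bootstrap", b),
                     sample.int(n, n, replace = TRUE))
    Xb <- X[idx, features, drop = FALSE]
    usable <- apply(Xb, 2, stats::sd) > 1e-10
    res <- tryCatch(
      stepwise_backward_aic(Xb[, usable, drop = FALSE], y[idx],
                            screen_k = config$screen_k),
      error = function(e) NULL)
    if (is.null(res)) { failed[b] <- TRUE; next }
    retained[b, res$selected] <- TRUE
  }
  if (sum(failed) > 0.1 * B)
    stop("more than 10% of bootstrap resamples failed (", sum(failed), "/", B, ")")
  ok <- retained[!failed, , drop = FALSE]
  structure(list(inclusion_freq = colMeans(ok),
                 retained = ok,
                 n_bootstrap = B, n_failed = sum(failed)),
            class = "selection_result")
}

#' Finalize a bootstrap selection (Sauerbrei-Schumacher rule)
#'
#' Two mechanisms identify stably selected features:
#' * individual rule: features whose inclusion frequency strictly exceeds
#'   `freq_threshold` are kept;
#' * substitution rule: strongly correlated features (training Spearman
#'   `|rho| > pair_rho`) substitute for one another across resamples and
#'   split their votes, so each correlated cluster that is *jointly*
#'   retained (any member present) in more than 90% of the resamples
#'   contributes its highest-frequency member even when no member passes
#'   the individual threshold.
#'
#' Finally, among the kept features, the lower-frequency member of every
#' pair with `|rho| > pair_rho` is dropped (ties keep the earlier catalog
#' column), so each cluster is represented at most once.
#'
#' @param result a `selection_result` from [bootstrap_inclusion()]
#' @param X training feature matrix (for the pair correlations)
#' @param config a [selection_config()]
#' @param cluster_freq joint-retention threshold for the substitution
#'   rule (default 0.90)
#' @return character vector of final features, in catalog (column) order
#' @export
finalize_selection <- function(result, X, config = selection_config(),
                               cluster_freq = 0.90) {
  freq <- result$inclusion_freq
  feats <- names(freq)
  kept <- feats[freq > config$freq_threshold]
  C <- if (length(feats) > 1L)
    abs(stats::cor(apply(X[, feats, drop = FALSE], 2, rank)))
  else matrix(1, 1, 1, dimnames = list(feats, feats))
  # substitution rule over rho-connected clusters of candidates
  if (!is.null(result$retained) && length(feats) > 1L) {
    parent <- seq_along(feats)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(length(feats) - 1L))
      for (j in seq(i + 1L, length(feats)))
        if (C[i, j] > config$pair_rho) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
    roots <- vapply(seq_along(feats), find, integer(1))
    for (r in unique(roots)) {
      members <- feats[roots == r]
      if (length(members) < 2L) next
      joint <- mean(rowSums(result$retained[, members, drop = FALSE]) > 0)
      if (joint > cluster_freq) {
        top <- members[order(-freq[members], match(members, colnames(X)))][1]
        kept <- union(kept, top)
      }
    }
  }
  if (length(kept) <= 1L)
    return(kept[order(match(kept, colnames(X)))])
  ord <- kept[order(-freq[kept], match(kept, colnames(X)))]
  final <- character(0)
  for (f in ord) {
    if (!length(final) || all(C[f, final] <= config$pair_rho))
      final <- c(final, f)
  }
  final[order(match(final, colnames(X)))]
}

#' Two-stage feature selection within and across feature groups
#'
#' Stage 1 runs [bootstrap_inclusion()] + [finalize_selection()] within
#' each feature group. Stage 2 repeats the procedure starting from the
#' union of the stage-1 selections, yielding the final feature set (a
#' subset of that union by construction). An empty stage-1 union is an
#' error (see [run_texture_risk_pipeline()] for the intercept-only
#' fallback used end to end).
#'
#' @param X training feature matrix
#' @param y 0/1 response
#' @param groups named list mapping group name -> character vector of
#'   feature ids (columns of `X`)
#' @param config a [selection_config()]
#' @return list with `stage1` (per-group results and selections),
#'   `final_features`, `stage2` (the across-group `selection_result`)
#' @export
select_two_stage <- function(X, y, groups, config = selection_config()) {
  stage1 <- lapply(seq_along(groups), function(gi) {
    feats <- intersect(groups[[gi]], colnames(X))
    if (!length(feats)) return(list(result = NULL, selected = character(0)))
    cfg_g <- config
    cfg_g$seed <- derive_seed(config$seed, paste0("group-", names(groups)[gi]))
    res <- bootstrap_inclusion(X, y, feats, cfg_g)
    list(result = res, selected = finalize_selection(res, X, cfg_g))
  })
  names(stage1) <- names(groups)
  union1 <- unlist(lapply(stage1, `[[`, "selected"), use.names = FALSE)
  union1 <- colnames(X)[colnames(X) %in% union1]
  if (!length(union1))
    stop("empty stage-1 union: no feature exceeded the inclusion-frequency threshold in any group")
  cfg2 <- config
  cfg2$seed <- derive_seed(config$seed, "across-groups")
  res2 <- bootstrap_inclusion(X, y, union1, cfg2)
  final <- finalize_selection(res2, X, cfg2)
  list(stage1 = stage1, final_features = final, stage2 = res2,
       stage1_union = union1)
}

#' Fit the score model on training data
#'
#' Multiple logistic regression of case status on the selected features
#' (standardized by the stored training means/SDs).
#'
#' @param X training feature matrix
#' @param y 0/1 response
#' @param features final feature set (may be empty: intercept-only model)
#' @return a `score_model`: intercept, per-feature log-odds coefficients,
#'   training centers/scales
#' @export
fit_score_model <- function(X, y, features) {
  if (!length(features)) {
    return(structure(list(features = character(0),
                          intercept = qlogis(mean(y)),
                          coefficients = numeric(0),
                          center = numeric(0), scale = numeric(0)),
                     class = "score_model"))
  }
  Xs <- X[, features, drop = FALSE]
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(Xs, 2, ctr), 2, scl, "/")
  fit <- fit_logistic(Z, y)
  structure(list(features = features,
                 intercept = fit$coefficients[1],
                 coefficients = fit$coefficients[-1],
                 center = ctr, scale = scl,
                 converged = fit$converged, separated = fit$separated),
            class = "score_model")
}

#' Score subjects on the 0-100 risk scale
#'
#' The inverse logit of the linear combination of the subject's feature
#' values with the trained coefficients and intercept, times 100.
#'
#' @param model a `score_model`
#' @param X feature matrix containing all model features
#' @return numeric vector of scores in `[0, 100]`
#' @export
score_subjects <- function(model, X) {
  stopifnot(inherits(model, "score_model"))
  if (!length(model$features))
    return(rep(100 * plogis(model$intercept), nrow(X)))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing))
    stop("feature table lacks model feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  Z <- sweep(sweep(X[, model$features, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  lp <- model$intercept + as.vector(Z %*% model$coefficients)
  100 * plogis(lp)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with ties counted 1/2.
#'
#' @param case_scores,control_scores numeric score vectors
#' @return AUC in `[0, 1]`
#' @export
auc_mw <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (n1 == 0L || n0 == 0L) stop("both groups must be nonempty")
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

default_adjust_sets <- function(with_pmd = TRUE) {
  s <- list(unadjusted = character(0),
            age_bmi = c("age", "bmi"),
            full = c("age", "bmi", "parity_class", "family_history", "age_ftp"))
  if (with_pmd)
    s$full_pmd <- c(s$full, "pmd_true")
  s
}

#' Evaluate a risk score against case-control status
#'
#' For each adjustment set, fits a logistic model of case status on the
#' SD-standardized score plus the adjusting covariates (parity entering
#' as a three-class factor), and reports the odds ratio per SD of score
#' with its 95% Wald confidence interval together with the AUC of the
#' model's predicted probabilities. Non-convergence is reported in the
#' `converged` column, never silently dropped.
#'
#' @param scores numeric score vector
#' @param subjects data.frame with `label` ("case"/"control") and the
#'   covariates `age, bmi, parity_class, family_history, age_ftp`
#'   (optionally `pmd_true`)
#' @param adjust_sets named list of covariate-name vectors; defaults to
#'   unadjusted, age+BMI, the full epidemiologic set, and full+PMD
#' @return data.frame with one row per adjustment set: `model`,
#'   `or_per_sd`, `ci_lower`, `ci_upper`, `auc`, `converged`
#' @export
evaluate_score <- function(scores, subjects,
                           adjust_sets = default_adjust_sets(
                             "pmd_true" %in% names(subjects))) {
  stopifnot(length(scores) == nrow(subjects))
  y <- as.integer(subjects$label == "case")
  s_sd <- stats::sd(scores)
  rows <- lapply(names(adjust_sets), function(nm) {
    covs <- adjust_sets[[nm]]
    df <- data.frame(y = y, subjects[, covs, drop = FALSE],
                     stringsAsFactors = FALSE)
    if ("parity_class" %in% names(df))
      df$parity_class <- factor(df$parity_class, levels = c("0", "1-2", "3+"))
    if (s_sd < 1e-12) {
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      pr <- predict(fit, type = "response")
      return(data.frame(model = nm, or_per_sd = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        auc = auc_mw(pr[y == 1], pr[y == 0]),
                        converged = fit$converged))
    }
    df$score_sd <- scores / s_sd
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    beta <- coef(fit)["score_sd"]
    se <- sqrt(diag(vcov(fit)))["score_sd"]
    pr <- predict(fit, type = "response")
    data.frame(model = nm,
               or_per_sd = exp(beta),
               ci_lower = exp(beta - 1.96 * se),
               ci_upper = exp(beta + 1.96 * se),
               auc = auc_mw(pr[y == 1], pr[y == 0]),
               converged = fit$converged,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Run the full texture risk pipeline on a cohort feature table
#'
#' Matched split, preselection (on training data), two-stage bootstrap
#' selection, training-side score model, validation scoring and
#' evaluation. When no feature survives selection (e.g. a null cohort),
#' the score degenerates to the intercept-only constant and the
#' validation AUC is 0.5 by construction.
#'
#' @param feature_table a `feature_table` from [extract_cohort()]
#' @param subjects cohort subject table (same row order as the feature
#'   table's `subject_id`)
#' @param config a [selection_config()]
#' @param split_seed seed for the matched split (defaults to
#'   `config$seed`)
#' @return list with `final_features`, `model`, `validation_scores`,
#'   `auc`, `evaluation` (data.frame), `split`, `selection`
#' @export
run_texture_risk_pipeline <- function(feature_table, subjects,
                                      config = selection_config(),
                                      split_seed = config$seed) {
  stopifnot(identical(feature_table$subject_id, subjects$subject_id))
  X <- as.matrix(feature_table[, setdiff(names(feature_table), "subject_id")])
  y <- as.integer(subjects$label == "case")
  sp <- match_and_split(subjects, seed = split_seed)
  Xtr <- X[sp$training, , drop = FALSE]
  ytr <- y[sp$training]
  kept <- preselect(Xtr, rho = config$preselect_rho)
  cat <- feature_catalog()
  groups <- split(cat$feature_id, cat$group)[unique(cat$group)]
  groups <- lapply(groups, intersect, y = kept)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  # standardize by training mean/SD for numerically well-conditioned fits
  # (AIC-based selection is invariant to affine rescaling of columns)
  ctr <- colMeans(Xtr[, kept, drop = FALSE])
  scl <- apply(Xtr[, kept, drop = FALSE], 2, stats::sd)
  Ztr <- sweep(sweep(Xtr[, kept, drop = FALSE], 2, ctr), 2, scl, "/")
  selection <- tryCatch(
    select_two_stage(Ztr, ytr, groups, config),
    error = function(e) {
      if (grepl("empty stage-1 union", conditionMessage(e)))
        list(stage1 = NULL, final_features = character(0), stage2 = NULL)
      else stop(e)
    })
  model <- fit_score_model(Xtr, ytr, selection$final_features)
  val_scores <- score_subjects(model, X[sp$validation, , drop = FALSE])
  yv <- y[sp$validation]
  evaluation <- evaluate_score(val_scores, subjects[sp$validation, , drop = FALSE])
  list(final_features = selection$final_features,
       model = model,
       validation_scores = val_scores,
       auc = auc_mw(val_scores[yv == 1], val_scores[yv == 0]),
       evaluation = evaluation,
       split = sp,
       selection = selection)
}
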