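# Synthetic matched case-control cohort: per-arm covariate distributions
# (age, BMI, parity class, family history, age at first term pregnancy,
# HRT), a ground-truth percent-dense-area surrogate (pmd_true), and one
# synthetic mammogram + ground-truth mask per subject. Cases and controls
# are matched `match_ratio`:1 on age within decades; case status shifts
# the two second-order texture parameters by `texture_effect` standard
# deviations.

arm_pair <- function(case, control) list(case = case, control = control)

#' Configuration of a synthetic case-control cohort
#'
#' Defaults reproduce the study-population structure the analysis assumes:
#' a 2:1 age-matched case-control design with per-arm covariate means/SDs
#' and class probabilities. `texture_effect` is the standardized shift
#' (delta) applied to the case arm's dense-blob contrast amplitude and
#' fatty-field correlation length; `density_fraction_range` is the uniform
#' range of the dense-tissue area fraction (identical in both arms, so the
#' planted texture signal is orthogonal to the PMD surrogate by design).
#'
#' @param n_controls,match_ratio,n_cases cohort sizes; exact matching
#'   requires `n_cases = match_ratio * n_controls`
#' @param age_mean_sd,bmi_mean_sd,age_ftp_mean_sd per-arm `c(mean, sd)`
#' @param parity_probs per-arm probabilities over the classes
#'   `{0, 1-2, >=3}` (must sum to 1)
#' @param fam_history_prob,hrt_prob per-arm probabilities
#' @param texture_effect standardized case-control texture shift (delta >= 0)
#' @param density_fraction_range dense-area fraction interval in `[0, 1]`
#' @param image_shape,pixel_spacing image geometry (pixels; cm/pixel)
#' @param seed master seed; all stages draw from named substreams of it
#' @param matching `"conditional"` (case ages drawn within each control's
#'   age decade; always feasible) or `"independent"` (both arms drawn
#'   i.i.d., then matched; errors if a decade cannot be matched)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_controls = 418L,
                          match_ratio = 2L,
                          n_cases = match_ratio * n_controls,
                          age_mean_sd = arm_pair(c(57.5, 10.8), c(57.3, 10.6)),
                          bmi_mean_sd = arm_pair(c(26.1, 5.0), c(24.6, 3.8)),
                          parity_probs = arm_pair(
                            c(0.155, 0.627, 0.219) / 1.001,
                            c(0.143, 0.534, 0.323)),
                          fam_history_prob = arm_pair(0.144, 0.197),
                          age_ftp_mean_sd = arm_pair(c(25.2, 4.6), c(25.6, 4.4)),
                          hrt_prob = arm_pair(0.298, 0.575),
                          texture_effect = 0,
                          density_fraction_range = c(0.05, 0.5),
                          image_shape = c(256L, 208L),
                          pixel_spacing = 0.02,
                          seed = 1L,
                          matching = c("conditional", "independent")) {
  cfg <- list(n_controls = as.integer(n_controls),
              match_ratio = as.integer(match_ratio),
              n_cases = as.integer(n_cases),
              age_mean_sd = age_mean_sd, bmi_mean_sd = bmi_mean_sd,
              parity_probs = parity_probs,
              fam_history_prob = fam_history_prob,
              age_ftp_mean_sd = age_ftp_mean_sd, hrt_prob = hrt_prob,
              texture_effect = texture_effect,
              density_fraction_range = density_fraction_range,
              image_shape = as.integer(image_shape),
              pixel_spacing = pixel_spacing,
              seed = as.integer(seed),
              matching = match.arg(matching))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_controls >= 1L, cfg$match_ratio >= 1L,
            cfg$texture_effect >= 0,
            length(cfg$density_fraction_range) == 2L,
            all(cfg$density_fraction_range >= 0),
            all(cfg$density_fraction_range <= 1),
            cfg$pixel_spacing > 0,
            length(cfg$image_shape) == 2L)
  if (cfg$n_cases != cfg$match_ratio * cfg$n_controls)
    stop("exact matching requires n_cases = match_ratio * n_controls")
  for (arm in c("case", "control")) {
    pp <- cfg$parity_probs[[arm]]
    if (abs(sum(pp) - 1) > 1e-9)
      stop("parity_probs for the ", arm, " arm must sum to 1")
    probs <- c(pp, cfg$fam_history_prob[[arm]], cfg$hrt_prob[[arm]])
    if (any(probs < 0) || any(probs > 1))
      stop("all probabilities must lie in [0, 1]")
  }
  invisible(cfg)
}

# inverse-CDF draw from N(mu, sd) truncated to [lo, hi)
rnorm_trunc <- function(n, mu, sd, lo, hi) {
  plo <- pnorm(lo, mu, sd); phi <- pnorm(hi, mu, sd)
  if (phi - plo < 1e-12) stop("truncation interval has no mass")
  qnorm(runif(n, plo, phi), mu, sd)
}

# generator texture parameter distributions; delta shifts the case arm
# by `delta` within-arm SDs: cases get higher local micro-texture
# contrast (film-grain amplitude, gray levels) and a shorter fatty-field
# correlation length (cm) — a busier, more heterogeneous parenchymal
# pattern. Both shifts lower lag-1 spatial correlation (their carriers
# add constructively there), while only the contrast shift drives the
# fine-scale wavelet detail energies, so the two channels remain
# separable in feature space.
texture_param_defaults <- function() {
  list(contrast = c(mean = 5, sd = 1),
       corr_len = c(mean = 0.12, sd = 0.024))
}

draw_covariates <- function(n, arm, cfg) {
  tp <- texture_param_defaults()
  is_case <- arm == "case"
  delta <- if (is_case) cfg$texture_effect else 0
  data.frame(
    bmi = rnorm(n, cfg$bmi_mean_sd[[arm]][1], cfg$bmi_mean_sd[[arm]][2]),
    parity_class = sample(c("0", "1-2", "3+"), n, replace = TRUE,
                          prob = cfg$parity_probs[[arm]]),
    family_history = rbinom(n, 1, cfg$fam_history_prob[[arm]]) == 1,
    age_ftp = rnorm(n, cfg$age_ftp_mean_sd[[arm]][1], cfg$age_ftp_mean_sd[[arm]][2]),
    hrt_ever = rbinom(n, 1, cfg$hrt_prob[[arm]]) == 1,
    pmd_true = 100 * runif(n, cfg$density_fraction_range[1],
                           cfg$density_fraction_range[2]),
    texture_contrast = pmax(rnorm(n, tp$contrast["mean"] +
                                    delta * tp$contrast["sd"],
                                  tp$contrast["sd"]), 1),
    texture_corr_len = pmax(rnorm(n, tp$corr_len["mean"] -
                                    delta * tp$corr_len["sd"],
                                  tp$corr_len["sd"]), 0.04),
    stringsAsFactors = FALSE)
}

#' Generate a matched synthetic case-control cohort
#'
#' Draws per-arm covariates from the configured distributions, forms
#' `match_ratio`:1 matched sets within age decades, and renders one
#' synthetic mammogram plus ground-truth mask per subject. Deterministic
#' given `config$seed`; covariates, ages and images draw from independent
#' named substreams, so any single subject's image can be regenerated in
#' isolation.
#'
#' @param config a [cohort_config()]
#' @param out_dir optional directory; when given, images and masks are
#'   written as PNG (`<subject_id>.png`, `<subject_id>_mask.png`) and the
#'   cohort table as `cohort.csv`. When `NULL` (default) images are kept
#'   in memory.
#' @param render set `FALSE` to skip image synthesis and return the
#'   covariate table only (useful when only the epidemiologic structure
#'   is needed)
#' @return a `synthetic_cohort`: list with `subjects` (data.frame),
#'   `images`, `masks` (lists, aligned to rows) and `config`
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL,
                            render = TRUE) {
  cfg <- validate_cohort_config(config)
  R <- cfg$match_ratio
  nK <- cfg$n_controls
  ctrl_age <- with_seed(derive_seed(cfg$seed, "ages-control"),
                        rnorm(nK, cfg$age_mean_sd$control[1], cfg$age_mean_sd$control[2]))
  case_age <- with_seed(derive_seed(cfg$seed, "ages-case"), {
    if (cfg$matching == "conditional") {
      # each control's cases drawn from the case-arm age distribution
      # truncated to the control's decade
      unlist(lapply(ctrl_age, function(a) {
        lo <- 10 * floor(a / 10)
        rnorm_trunc(R, cfg$age_mean_sd$case[1], cfg$age_mean_sd$case[2],
                    lo, lo + 10)
      }))
    } else {
      rnorm(cfg$n_cases, cfg$age_mean_sd$case[1], cfg$age_mean_sd$case[2])
    }
  })
  if (cfg$matching == "independent") {
    dec_k <- floor(ctrl_age / 10)
    dec_c <- floor(case_age / 10)
    assigned <- rep(NA_integer_, cfg$n_cases)
    for (d in sort(unique(dec_k))) {
      need <- R * sum(dec_k == d)
      pool <- which(dec_c == d & is.na(assigned))
      if (length(pool) < need)
        stop(sprintf(
          "impossible matching: age decile [%d, %d) has %d controls needing %d cases but only %d available",
          10 * d, 10 * (d + 1), sum(dec_k == d), need, length(pool)))
      assigned[pool[seq_len(need)]] <- d
    }
    # reorder cases so that each control's block of R cases shares its decade
    ord <- unlist(lapply(seq_len(nK), function(i) {
      pool <- which(dec_c == dec_k[i] & !is.na(assigned))
      take <- pool[seq_len(R)]
      assigned[take] <<- NA_integer_
      take
    }))
    case_age <- case_age[ord]
  }
  cov_c <- with_seed(derive_seed(cfg$seed, "covariates-case"),
                     draw_covariates(cfg$n_cases, "case", cfg))
  cov_k <- with_seed(derive_seed(cfg$seed, "covariates-control"),
                     draw_covariates(nK, "control", cfg))
  set_ids <- sprintf("set%04d", seq_len(nK))
  subj <- rbind(
    data.frame(subject_id = sprintf("case%04d", seq_len(cfg$n_cases)),
               label = "case",
               matched_set_id = rep(set_ids, each = R),
               age = case_age, cov_c, stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("ctrl%04d", seq_len(nK)),
               label = "control",
               matched_set_id = set_ids,
               age = ctrl_age, cov_k, stringsAsFactors = FALSE))
  n <- nrow(subj)
  subj$image_path <- NA_character_
  images <- vector("list", n)
  masks <- vector("list", n)
  img_seed <- derive_seed(cfg$seed, "images")
  for (i in seq_len(n)) {
    if (!render) break
    g <- generate_image(
      list(shape = cfg$image_shape, spacing = cfg$pixel_spacing,
           pmd = subj$pmd_true[i],
           grain_sd = subj$texture_contrast[i],
           corr_len_cm = subj$texture_corr_len[i]),
      seed = derive_seed(img_seed, subj$subject_id[i], i))
    subj$pmd_true[i] <- g$pmd_achieved
    images[[i]] <- g$image
    masks[[i]] <- g$mask
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      ip <- file.path(out_dir, paste0(subj$subject_id[i], ".png"))
      write_gray_png(g$image, ip)
      write_mask_png(g$mask, file.path(out_dir,
                                       paste0(subj$subject_id[i], "_mask.png")))
      subj$image_path[i] <- ip
    }
  }
  cohort <- structure(list(subjects = subj, images = images, masks = masks,
                           config = cfg),
                      class = "synthetic_cohort")
  if (!is.null(out_dir))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d cases, %d controls (%d:1 matched sets), delta = %g>\n",
    sum(x$subjects$label == "case"), sum(x$subjects$label == "control"),
    x$config$match_ratio, x$config$texture_effect))
  invisible(x)
}

#' Write the cohort covariate table as CSV
#'
#' Columns: `subject_id, label, matched_set_id, age, bmi, parity_class,
#' family_history, age_ftp, hrt_ever, pmd_true, image_path` (plus the
#' generator's texture parameters, kept for diagnostics).
#'
#' @param cohort a `synthetic_cohort`
#' @param path file path
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "label", "matched_set_id", "age", "bmi",
            "parity_class", "family_history", "age_ftp", "hrt_ever",
            "pmd_true", "image_path", "texture_contrast", "texture_corr_len")
  utils::write.csv(cohort$subjects[, cols], path, row.names = FALSE)
  invisible(path)
}
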