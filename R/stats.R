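#' Model specifications for the slowing analyses
#'
#' The four fitted linear mixed-effects models: maximal tapping speed,
#' relative decrease and absolute decrease each regress their response on
#' `AgeGroup * Finger + Sex + Sex:Finger` with a participant random
#' intercept; the time-course model regresses the binned tapping frequency
#' on `Time * Finger * AgeGroup + Sex + Sex:Finger` with `Time` a 6-level
#' within factor.
#'
#' @param name one of `"max_speed"`, `"relative_decrease"`,
#'   `"absolute_decrease"`, `"time_course"`.
#' @return a `model_spec` list: `name`, `response`, `fixed` (character
#'   vector of fixed-effect terms), `formula` (full mixed-model formula).
#' @export
model_spec <- function(name = c("max_speed", "relative_decrease",
                                "absolute_decrease", "time_course")) {
  name <- match.arg(name)
  response <- switch(name,
                     max_speed = "speed_max",
                     relative_decrease = "rel_decrease_pct",
                     absolute_decrease = "abs_decrease_hz",
                     time_course = "freq")
  fixed <- if (name == "time_course") {
    c("time_bin", "finger", "age_group", "time_bin:finger",
      "time_bin:age_group", "finger:age_group", "time_bin:finger:age_group",
      "sex", "sex:finger")
  } else {
    c("age_group", "finger", "age_group:finger", "sex", "sex:finger")
  }
  fml <- stats::as.formula(
    paste(response, "~", paste(fixed, collapse = " + "),
          "+ (1 | participant_id)"))
  structure(list(name = name, response = response, fixed = fixed,
                 formula = fml), class = "model_spec")
}

# Factor coding: sum-to-zero contrasts are required for type-III marginal
# F tests. Reference orderings are fixed so signs are reproducible.
prepare_model_data <- function(data, spec) {
  lvls <- list(age_group = c("young", "aged"), finger = FINGERS_TAPPING,
               sex = c("female", "male"), time_bin = paste0("t", 1:6))
  for (v in names(lvls)) {
    if (v %in% names(data)) data[[v]] <- factor(data[[v]], levels = lvls[[v]])
  }
  for (v in c("age_group", "finger", "sex", "time_bin")) {
    if (v %in% names(data)) {
      stats::contrasts(data[[v]]) <- stats::contr.sum(nlevels(data[[v]]))
    }
  }
  data
}

#' Robust outlier removal before model fitting
#'
#' Fits the model's fixed-effect design with MM-type robust regression and
#' drops observations whose standardized robust residual exceeds `cutoff`
#' in absolute value. Design cells (factor combinations) with fewer than 3
#' observations are protected from removal, with a warning. If the robust
#' fit fails to converge, a per-cell median/MAD standardization is used
#' instead.
#'
#' @param data feature (or time-course) table.
#' @param spec a [model_spec()].
#' @param cutoff absolute standardized-residual cutoff (default 2.5).
#' @return list with `data` (retained rows), `removed` (removal log with
#'   the standardized residual of every dropped row), `n_removed`.
#' @export
remove_outliers <- function(data, spec, cutoff = 2.5) {
  data <- prepare_model_data(data, spec)
  fixed_fml <- stats::as.formula(
    paste(spec$response, "~", paste(spec$fixed, collapse = " + ")))
  std_resid <- tryCatch({
    fit <- MASS::rlm(fixed_fml, data = data, method = "MM", maxit = 200)
    stats::residuals(fit) / fit$s
  }, error = function(e) {
    warning("MM-type robust fit failed (", conditionMessage(e),
            "); falling back to per-cell median/MAD", call. = FALSE)
    cell <- interaction(data[intersect(c("age_group", "finger", "sex",
                                         "time_bin"), names(data))],
                        drop = TRUE)
    y <- data[[spec$response]]
    r <- numeric(length(y))
    for (cl in levels(cell)) {
      i <- cell == cl
      s <- stats::mad(y[i])
      r[i] <- if (s > 0) (y[i] - stats::median(y[i])) / s else 0
    }
    r
  })
  cell_vars <- intersect(c("age_group", "finger", "sex", "time_bin"),
                         names(data))
  cell <- interaction(data[cell_vars], drop = TRUE)
  small <- names(table(cell))[table(cell) < 3L]
  protected <- cell %in% small
  if (any(protected & abs(std_resid) > cutoff)) {
    warning("outliers in design cells with < 3 observations were retained",
            call. = FALSE)
  }
  drop <- abs(std_resid) > cutoff & !protected
  removed <- data[drop, intersect(c("participant_id", "finger", "time_bin",
                                    spec$response), names(data))]
  if (nrow(removed)) removed$std_resid <- std_resid[drop]
  list(data = data[!drop, , drop = FALSE], removed = removed,
       n_removed = sum(drop))
}

#' Partial eta squared from an F statistic
#'
#' Effect-size measure for a fixed-effect F test:
#' `eta_p^2 = F * df1 / (F * df1 + df2)`.
#'
#' @param f F statistic (>= 0); vectorised.
#' @param df1 numerator degrees of freedom.
#' @param df2 denominator degrees of freedom.
#' @return partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_squared(9.115, 2, 465.24)   # ~0.04
#' partial_eta_squared(32.216, 2, 488.99)  # ~0.12
#' @export
partial_eta_squared <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 <= 0) || any(df2 <= 0)) {
    stop_param("require f >= 0 and positive degrees of freedom")
  }
  f * df1 / (f * df1 + df2)
}

#' Fit one of the slowing mixed-effects models
#'
#' Robust outlier removal (optional), a REML fit with a participant random
#' intercept, a type-III ANOVA table with Satterthwaite denominator degrees
#' of freedom under sum-to-zero factor coding, partial eta squared per
#' effect, and family-wise-error-corrected post-hoc contrasts of the
#' age-group difference within and between fingers.
#'
#' @param data a feature table ([compute_features()]) or, for the
#'   time-course model, a long table ([time_course_table()]).
#' @param model model name, see [model_spec()].
#' @param outlier_removal logical; apply [remove_outliers()] first.
#' @param outlier_cutoff passed to [remove_outliers()].
#' @param posthoc logical; compute [posthoc_contrasts()].
#' @param adjust multiplicity adjustment for the post-hoc family
#'   (`"mvt"` = single-step max-|z|; falls back to Bonferroni if the
#'   multivariate-normal computation fails).
#' @return a `tap_fit` list: `spec`, `model` (the `lmerMod`), `effects`
#'   (data.frame: `effect`, `F`, `df1`, `df2`, `p`, `eta_p2`), `contrasts`
#'   (post-hoc table or `NULL`), `n_outliers_removed`, `outlier_log`.
#' @export
fit_lmm <- function(data, model = "max_speed", outlier_removal = TRUE,
                    outlier_cutoff = 2.5, posthoc = TRUE, adjust = "mvt") {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  for (v in c("participant_id", spec$response)) {
    if (!v %in% names(data)) stop_param("data lacks column '%s'", v)
  }
  outlier_log <- NULL
  n_removed <- 0L
  if (outlier_removal) {
    rem <- remove_outliers(data, spec, cutoff = outlier_cutoff)
    data <- rem$data
    outlier_log <- rem$removed
    n_removed <- rem$n_removed
  } else {
    data <- prepare_model_data(data, spec)
  }
  for (v in intersect(c("age_group", "finger", "sex", "time_bin"),
                      all.vars(spec$formula))) {
    if (nlevels(droplevels(data[[v]])) < 2L) {
      stop_param("factor '%s' has < 2 levels present", v)
    }
  }
  fit <- lmerTest::lmer(spec$formula, data = data, REML = TRUE)
  if (lme4::isSingular(fit)) {
    warning("singular random-effect fit (participant variance near 0)",
            call. = FALSE)
  }
  at <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  effects <- data.frame(effect = rownames(at),
                        F = at[["F value"]],
                        df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                        p = at[["Pr(>F)"]])
  effects$eta_p2 <- partial_eta_squared(effects$F, effects$df1, effects$df2)
  contrasts <- if (posthoc) posthoc_contrasts(fit, adjust = adjust)
  structure(list(spec = spec, model = fit, effects = effects,
                 contrasts = contrasts, n_outliers_removed = n_removed,
                 outlier_log = outlier_log, data = data),
            class = "tap_fit")
}

#' @export
print.tap_fit <- function(x, ...) {
  cat(sprintf("<tap_fit> %s model: %d observations, %d outlier(s) removed\n",
              x$spec$name, nrow(x$data), x$n_outliers_removed))
  eff <- x$effects
  cat("Type III fixed effects (Satterthwaite df):\n")
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-32s F(%g, %.2f) = %7.3f  p = %.4g  eta_p2 = %.3f\n",
                eff$effect[i], eff$df1[i], eff$df2[i], eff$F[i], eff$p[i],
                eff$eta_p2[i]))
  }
  if (!is.null(x$contrasts)) {
    cat("Post-hoc contrasts (single-step FWER adjustment):\n")
    for (i in seq_len(nrow(x$contrasts))) {
      co <- x$contrasts[i, ]
      cat(sprintf("  %-36s est = %7.3f  z = %6.2f  p_adj = %.4g\n",
                  co$contrast, co$estimate, co$z, co$p_adj))
    }
  }
  invisible(x)
}

#' Post-hoc contrasts of the age-group difference across fingers
#'
#' The six-contrast family suggested by the age-by-finger interaction: the
#' young-aged difference within each finger, and the pairwise differences
#' of that difference between fingers. Tests are asymptotic z statistics;
#' the family-wise error rate is controlled with the single-step max-|z|
#' multivariate-normal adjustment (Bonferroni fallback).
#'
#' @param model a fitted `lmerMod`/`lmerModLmerTest` containing `age_group`
#'   and `finger` fixed effects.
#' @param adjust `"mvt"` (default) or any adjustment accepted by emmeans.
#' @param contrasts optional named list of custom contrast coefficient
#'   vectors over the `age_group x finger` cell means (young/aged ordering
#'   within finger index, middle, little).
#' @return data.frame with `contrast`, `estimate`, `se`, `z`, `p_raw`,
#'   `p_adj`.
#' @export
posthoc_contrasts <- function(model, adjust = "mvt", contrasts = NULL) {
  emm <- emmeans::emmeans(model, ~ age_group * finger,
                          lmer.df = "asymptotic")
  grid <- as.data.frame(emm)[, c("age_group", "finger")]
  cell <- function(g, f) as.integer(grid$age_group == g & grid$finger == f)
  d_in <- function(f) cell("young", f) - cell("aged", f)
  if (is.null(contrasts)) {
    contrasts <- list(
      "young-aged | index" = d_in("index"),
      "young-aged | middle" = d_in("middle"),
      "young-aged | little" = d_in("little"),
      "(young-aged) index - middle" = d_in("index") - d_in("middle"),
      "(young-aged) index - little" = d_in("index") - d_in("little"),
      "(young-aged) middle - little" = d_in("middle") - d_in("little"))
  }
  run <- function(adj) {
    summary(emmeans::contrast(emm, method = contrasts, adjust = adj),
            infer = c(FALSE, TRUE))
  }
  res <- tryCatch(run(adjust), error = function(e) {
    warning("'", adjust, "' adjustment failed (", conditionMessage(e),
            "); using Bonferroni", call. = FALSE)
    run("bonferroni")
  })
  raw <- summary(emmeans::contrast(emm, method = contrasts, adjust = "none"))
  if (anyNA(res$estimate)) {
    stop_param("contrast '%s' is not estimable (rank-deficient)",
               res$contrast[which(is.na(res$estimate))[1L]])
  }
  zcol <- if ("z.ratio" %in% names(res)) "z.ratio" else "t.ratio"
  data.frame(contrast = as.character(res$contrast),
             estimate = res$estimate, se = res$SE,
             z = res[[zcol]],
             p_raw = raw$p.value,
             p_adj = pmax(res$p.value, raw$p.value))
}

#' Simulate a feature table with known effects
#'
#' Generates a balanced participant-by-finger table of maximal tapping
#' speeds from a linear mixed model with known fixed effects and a
#' participant random intercept. Used for type-I-error and effect-recovery
#' calibration of the model-fitting stack.
#'
#' @param n_young,n_aged participants per age group.
#' @param mu grand mean speed, Hz.
#' @param age_effect added for young participants, Hz.
#' @param finger_effect named vector of finger offsets, Hz.
#' @param interaction_effect extra young-participant advantage on the index
#'   finger, Hz (a pure age-by-finger interaction).
#' @param sex_effect added for males, Hz.
#' @param sd_participant SD of the participant random intercept, Hz.
#' @param sd_resid residual SD, Hz.
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `age_group`, `sex`, `finger`,
#'   `speed_max`.
#' @export
simulate_feature_table <- function(n_young = 30, n_aged = 30, mu = 5.8,
                                   age_effect = 0,
                                   finger_effect = c(index = 0.3,
                                                     middle = 0,
                                                     little = -0.5),
                                   interaction_effect = 0,
                                   sex_effect = 0,
                                   sd_participant = 0.5, sd_resid = 0.3,
                                   seed = 1L) {
  set.seed(seed)
  n <- n_young + n_aged
  ids <- sprintf("s%03d", seq_len(n))
  group <- rep(c("young", "aged"), c(n_young, n_aged))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  u <- stats::rnorm(n, 0, sd_participant)
  rows <- lapply(seq_len(n), function(i) {
    y <- mu + (group[i] == "young") * age_effect +
      finger_effect[FINGERS_TAPPING] +
      (group[i] == "young") * (FINGERS_TAPPING == "index") *
        interaction_effect +
      (sex[i] == "male") * sex_effect +
      u[i] + stats::rnorm(3L, 0, sd_resid)
    data.frame(participant_id = ids[i], age_group = group[i], sex = sex[i],
               finger = FINGERS_TAPPING, speed_max = unname(y))
  })
  do.call(rbind, rows)
}
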