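#' Negative-binomial and zero-inflated count models
#'
#' Fits EPVS count outcomes with a log link. Plain negative-binomial
#' (NB) regression estimates the dispersion by maximum likelihood; the
#' zero-inflated variant (ZINB) adds an intercept-only structural-zero
#' component, appropriate for within-lesion counts where a large share
#' of subjects have no EPVS inside lesions at all. Group contrasts are
#' reported as ratios of expected counts (`beta_exp`, the exponentiated
#' coefficient) with Wald 95% confidence intervals on the same scale.
#'
#' @param data data.frame with one row per subject.
#' @param outcome name of the nonnegative-integer count column.
#' @param predictors character vector of predictor columns (first factor
#'   is typically the group); entered additively.
#' @param family `"nb"` or `"zinb"`.
#' @param group optional name of the group factor column; when given,
#'   `ref_level` fixes its reference level.
#' @param ref_level reference level of the group factor.
#' @param interaction optional character pair `c(a, b)` adding `a * b`.
#' @param offset_log optional column whose log enters as an exposure
#'   offset (none by default).
#' @param family_id label attached to every term for FDR grouping.
#' @return An object of class `pvs_count_model`: list with `results`
#'   (data.frame: `term`, `estimate`, `se`, `beta_exp`, `ci_low`,
#'   `ci_high` on the `beta_exp` scale, `p_value`, `family_id`,
#'   `n_obs`, `converged`), `fit` (the underlying model object),
#'   `dispersion_alpha` and, for ZINB, `zero_inflation_pi`.
#' @export
fit_count_model <- function(data, outcome, predictors = "group",
                            family = c("nb", "zinb"), group = NULL,
                            ref_level = NULL, interaction = NULL,
                            offset_log = NULL,
                            family_id = NA_character_) {
  family <- match.arg(family)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome, call. = FALSE)
  if (any(y < 0) || any(y != round(y)))
    stop("count outcome must be nonnegative integers", call. = FALSE)
  if (all(y == 0)) {
    if (family == "nb")
      stop("all-zero outcome: NB model is degenerate; use ZINB",
           call. = FALSE)
    return(structure(list(results = NULL, fit = NULL,
                          dispersion_alpha = NA_real_,
                          zero_inflation_pi = 1, degenerate = TRUE),
                     class = "pvs_count_model"))
  }
  data <- relevel_group(data, group, ref_level)
  rhs <- paste(predictors, collapse = " + ")
  if (!is.null(interaction))
    rhs <- paste(rhs, "+", interaction[1], "*", interaction[2])
  if (!is.null(offset_log))
    rhs <- paste0(rhs, " + offset(log(", offset_log, "))")
  f <- as.formula(paste(outcome, "~", rhs))
  n_par <- ncol(stats::model.matrix(as.formula(paste("~", rhs)), data))
  if (nrow(data) <= n_par + 2L)
    stop("too few observations for ", n_par, " parameters", call. = FALSE)

  if (family == "nb") {
    converged <- TRUE
    fit <- withCallingHandlers(
      MASS::glm.nb(f, data = data,
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 200)),
      warning = function(w) {
        if (grepl("iteration limit|did not converge", conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    alpha <- 1 / fit$theta
    pi_zi <- NULL
  } else {
    fit <- glmmTMB::glmmTMB(f, data = data, ziformula = ~1,
                            family = glmmTMB::nbinom2())
    converged <- isTRUE(fit$sdr$pdHess)
    est <- glmmTMB::fixef(fit)$cond
    se <- sqrt(diag(vcov(fit)$cond))
    alpha <- 1 / glmmTMB::sigma(fit)
    pi_zi <- plogis(glmmTMB::fixef(fit)$zi[["(Intercept)"]])
  }
  z <- qnorm(0.975)
  res <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    beta_exp = exp(unname(est)),
    ci_low = exp(unname(est) - z * unname(se)),
    ci_high = exp(unname(est) + z * unname(se)),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se))),
    family_id = family_id, n_obs = nrow(data), converged = converged,
    stringsAsFactors = FALSE)
  structure(list(results = res, fit = fit, family = family,
                 dispersion_alpha = alpha, zero_inflation_pi = pi_zi,
                 degenerate = FALSE),
            class = "pvs_count_model")
}

#' Log-Gaussian model for EPVS or lesion volumes
#'
#' Volumes are right-skewed; the model takes the natural log of the
#' (ICV-normalized) volume and fits a Gaussian GLM. Coefficients are
#' reported as standardized betas: the log outcome and all continuous
#' predictors are z-scored before fitting, while binary and categorical
#' predictors stay as indicators, so a group coefficient is in pooled-SD
#' units of the log outcome. Rows with zero volume are excluded (the log
#' is undefined) and counted in the exclusion report; alternatively a
#' small offset of half the smallest positive observed volume can be
#' added via `zero_rule = "epsilon"`.
#'
#' @inheritParams fit_count_model
#' @param outcome name of the positive volume column.
#' @param zero_rule `"exclude"` (default) or `"epsilon"`.
#' @return An object of class `pvs_volume_model`: list with `results`
#'   (`term`, `std_beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `family_id`, `n_obs`, `converged`), `fit`, and `n_excluded_zero`.
#' @export
fit_log_volume_model <- function(data, outcome, predictors = "group",
                                 group = NULL, ref_level = NULL,
                                 interaction = NULL,
                                 zero_rule = c("exclude", "epsilon"),
                                 family_id = NA_character_) {
  zero_rule <- match.arg(zero_rule)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome, call. = FALSE)
  zero <- !is.finite(y) | y <= 0
  if (zero_rule == "epsilon" && any(!zero)) {
    eps <- min(y[!zero]) / 2
    y[zero] <- eps
    n_excluded <- 0L
  } else {
    data <- data[!zero, , drop = FALSE]
    y <- y[!zero]
    n_excluded <- sum(zero)
  }
  if (length(y) < 3L)
    stop("fewer than 3 positive-volume rows", call. = FALSE)
  data <- relevel_group(data, group, ref_level)
  data$.log_y <- as.numeric(scale(log(y)))
  for (p in unique(c(predictors, interaction))) {
    if (is.numeric(data[[p]]) && length(unique(data[[p]])) > 2L)
      data[[p]] <- as.numeric(scale(data[[p]]))
  }
  rhs <- paste(predictors, collapse = " + ")
  if (!is.null(interaction))
    rhs <- paste(rhs, "+", interaction[1], "*", interaction[2])
  fit <- lm(as.formula(paste(".log_y ~", rhs)), data = data)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  res <- data.frame(
    term = names(est), std_beta = unname(est), se = unname(se),
    ci_low = unname(est) - z * unname(se),
    ci_high = unname(est) + z * unname(se),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se))),
    family_id = family_id, n_obs = nrow(data), converged = TRUE,
    stringsAsFactors = FALSE)
  structure(list(results = res, fit = fit, n_excluded_zero = n_excluded),
            class = "pvs_volume_model")
}

relevel_group <- function(data, group, ref_level) {
  if (!is.null(group)) {
    data[[group]] <- factor(data[[group]])
    if (!is.null(ref_level))
      data[[group]] <- stats::relevel(data[[group]], ref = ref_level)
  }
  data
}

#' Interaction between lesion burden and group
#'
#' Convenience wrapper adding a `wml_log_volume x group` interaction to
#' a count or volume model, keeping the main effects. Requires at least
#' two group levels present in the data.
#'
#' @inheritParams fit_count_model
#' @param wml_col name of the log lesion-volume column.
#' @param outcome_type `"count"` or `"volume"`.
#' @param ... passed to the underlying fit function.
#' @return The fitted model object (`pvs_count_model` or
#'   `pvs_volume_model`) with interaction terms in `results`.
#' @export
interaction_model <- function(data, outcome, group, wml_col,
                              outcome_type = c("count", "volume"),
                              predictors = character(0), ...) {
  outcome_type <- match.arg(outcome_type)
  if (length(unique(data[[group]])) < 2L)
    stop("interaction inestimable with a single group", call. = FALSE)
  preds <- unique(c(group, wml_col, predictors))
  if (outcome_type == "count")
    fit_count_model(data, outcome, predictors = preds, group = group,
                    interaction = c(wml_col, group), ...)
  else
    fit_log_volume_model(data, outcome, predictors = preds, group = group,
                         interaction = c(wml_col, group), ...)
}

#' Wald contrasts between sequential disease stages
#'
#' For each adjacent pair in `stages` (e.g. CU-/CU+/MCI+/AD+), tests the
#' difference of the corresponding group coefficients: the estimate is
#' `beta_b - beta_a` (the reference level's coefficient being 0), its
#' variance `v_bb + v_aa - 2 v_ab`, equivalent to re-leveling the factor
#' and reading off the coefficient. For count models the contrast is
#' also reported as a ratio of expected counts.
#'
#' @param model a `pvs_count_model` or `pvs_volume_model`.
#' @param stages character vector of ordered group levels (>= 2), all
#'   present in the fitted model's group factor.
#' @param group name of the group column used in the fit.
#' @return data.frame with one row per adjacent pair: `contrast`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value` (and `beta_exp`
#'   scale columns for count models).
#' @export
sequential_contrasts <- function(model, stages, group = "group") {
  stopifnot(length(stages) >= 2L)
  is_count <- inherits(model, "pvs_count_model")
  fit <- model$fit
  if (is_count && identical(model$family, "zinb")) {
    b <- glmmTMB::fixef(fit)$cond
    V <- as.matrix(vcov(fit)$cond)
  } else {
    b <- coef(fit)
    V <- as.matrix(vcov(fit))
  }
  glev <- levels(stats::model.frame(fit)[[group]])
  missing_lev <- setdiff(stages, glev)
  if (length(missing_lev))
    stop("stage absent from model: ", paste(missing_lev, collapse = ", "),
         call. = FALSE)
  coef_of <- function(lev) {
    nm <- paste0(group, lev)
    if (lev == glev[1]) list(b = 0, i = NA_integer_)
    else list(b = b[[nm]], i = which(names(b) == nm))
  }
  out <- lapply(seq_len(length(stages) - 1L), function(k) {
    a <- coef_of(stages[k]); bb <- coef_of(stages[k + 1])
    est <- bb$b - a$b
    va <- if (is.na(a$i)) 0 else V[a$i, a$i]
    vb <- if (is.na(bb$i)) 0 else V[bb$i, bb$i]
    cab <- if (is.na(a$i) || is.na(bb$i)) 0 else V[a$i, bb$i]
    se <- sqrt(va + vb - 2 * cab)
    z <- qnorm(0.975)
    data.frame(contrast = paste(stages[k + 1], "vs", stages[k]),
               estimate = est, se = se,
               ci_low = est - z * se, ci_high = est + z * se,
               p_value = 2 * pnorm(-abs(est / se)))
  })
  out <- do.call(rbind, out)
  if (is_count) {
    out$beta_exp <- exp(out$estimate)
    out$beta_exp_ci_low <- exp(out$ci_low)
    out$beta_exp_ci_high <- exp(out$ci_high)
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment within one family of hypothesis tests: sort the m
#' p-values ascending, set `adj_i = min_{j >= i} (p_j * m / j)` capped at
#' 1, and return in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order; `adj >= p` elementwise.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Breusch-Pagan test for heteroscedasticity
#'
#' Regresses the squared residuals on the design; the Lagrange-multiplier
#' statistic is `n` times the auxiliary R-squared, referred to a
#' chi-squared distribution with as many degrees of freedom as design
#' columns.
#'
#' @param residuals numeric residual vector.
#' @param design numeric matrix (or data.frame) of regressors, without
#'   intercept; must have full column rank and `n > k + 1` rows.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
breusch_pagan <- function(residuals, design) {
  design <- as.matrix(design)
  n <- length(residuals)
  k <- ncol(design)
  if (nrow(design) != n) stop("residuals/design misaligned", call. = FALSE)
  if (n <= k + 1L) stop("need n > k + 1", call. = FALSE)
  if (qr(cbind(1, design))$rank < k + 1L)
    stop("rank-deficient design", call. = FALSE)
  u2 <- residuals^2
  tss <- sum((u2 - mean(u2))^2)
  if (tss <= 1e-12 * max(1, mean(u2)^2) * n)
    return(list(statistic = 0, df = k, p_value = 1))
  aux <- lm(u2 ~ design)
  r2 <- 1 - sum(resid(aux)^2) / tss
  stat <- n * r2
  list(statistic = stat, df = k,
       p_value = pchisq(stat, df = k, lower.tail = FALSE))
}

#' Qualitative effect-size label
#'
#' Conventions used for reporting: standardized betas are small below
#' 0.1 in magnitude, medium below 0.3, medium-large from 0.3 to below
#' 0.5, large from 0.5; count-ratio effects are labeled by direction
#' (ratio below / equal to / above 1).
#'
#' @param value numeric effect estimate.
#' @param scale `"std_beta"` or `"beta_exp"`.
#' @return Character label.
#' @export
effect_size_label <- function(value, scale = c("std_beta", "beta_exp")) {
  scale <- match.arg(scale)
  if (!is.finite(value)) stop("value must be finite", call. = FALSE)
  if (scale == "std_beta") {
    a <- abs(value)
    if (a < 0.1) "small"
    else if (a < 0.3) "medium"
    else if (a < 0.5) "medium-large"
    else "large"
  } else {
    if (value < 1) "decrease" else if (value == 1) "no change" else "increase"
  }
}
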