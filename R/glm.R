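#' Upper-tail F probability
#'
#' Two-tailed p-value of a group effect in a general linear model is the
#' upper-tail probability of its F statistic.
#'
#' @param f F statistic (non-negative, vectorised).
#' @param df1,df2 Numerator and denominator degrees of freedom (at least 1).
#' @return Probability in (0, 1].
#' @export
f_pvalue <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) {
    abort("degrees of freedom must be at least 1", class = "circsleep_malformed_input")
  }
  if (any(f < 0)) abort("F must be non-negative", class = "circsleep_malformed_input")
  pf(f, df1, df2, lower.tail = FALSE)
}

#' Partial eta squared from an F statistic
#'
#' For a single effect, partial eta squared is
#' `SS_effect / (SS_effect + SS_error) = F * df1 / (F * df1 + df2)`.
#' `effect_size_label()` applies the conventional thresholds 0.01 / 0.06 /
#' 0.14 for small / medium / large.
#'
#' @inheritParams f_pvalue
#' @return Numeric effect size in \[0, 1).
#' @export
partial_eta_squared <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

#' @rdname partial_eta_squared
#' @param eta_p2 Partial eta squared value(s).
#' @export
effect_size_label <- function(eta_p2) {
  dplyr::case_when(
    eta_p2 >= 0.14 ~ "large",
    eta_p2 >= 0.06 ~ "medium",
    eta_p2 >= 0.01 ~ "small",
    TRUE ~ "below_small"
  )
}

#' Covariate-adjusted two-group comparison for one outcome
#'
#' Fits ordinary least squares on `[intercept, group indicator, covariates]`
#' over complete cases and tests the group effect with the partial (type-III)
#' F comparing the full model to the model without the group column
#' (equivalently, since the group carries 1 df, the squared t of its
#' coefficient). Reported group descriptives are raw (unadjusted) means/SDs.
#'
#' @param data Data frame (typically profiles from [build_profiles()]).
#' @param outcome Name of the numeric outcome column.
#' @param group Name of a two-level factor column; the first level is the
#'   reference.
#' @param covariates Character vector of covariate column names (numeric or
#'   factor); default none, which reduces to classical one-way ANOVA.
#' @return A `circ_glm` object; see [tidy.circ_glm()] and
#'   [glance.circ_glm()]. Key fields: `F`, `df1`, `df_error`, `p`, `eta_p2`,
#'   `effect_label`, `descriptives`, `coefficients`.
#' @export
fit_group_model <- function(data, outcome, group, covariates = character()) {
  cols <- c(outcome, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")),
          class = "circsleep_malformed_input")
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  g <- d[[group]]
  if (!is.factor(g)) g <- factor(g)
  g <- droplevels(g)
  if (nlevels(g) != 2) {
    abort(paste0("group '", group, "' must have exactly two levels present (has ",
                 nlevels(g), ")"),
          class = "circsleep_degenerate_design")
  }
  d[[group]] <- g
  n <- nrow(d)
  y <- as.numeric(d[[outcome]])

  # design: intercept + 0/1 risk indicator + covariates
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- cbind(X, stats::setNames(as.numeric(g == levels(g)[2]), NULL))
  colnames(X)[2] <- paste0(group, levels(g)[2])
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) < 2) {
        abort(paste0("degenerate design: covariate '", cv, "' is constant"),
              class = "circsleep_degenerate_design")
      }
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(v)[-1])
      X <- cbind(X, mm)
    } else {
      if (stats::var(v) == 0) {
        abort(paste0("degenerate design: covariate '", cv, "' is constant"),
              class = "circsleep_degenerate_design")
      }
      X <- cbind(X, stats::setNames(matrix(as.numeric(v), ncol = 1,
                                           dimnames = list(NULL, cv)), NULL))
    }
  }
  p_cols <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p_cols) {
    drop_col <- colnames(X)[qrX$pivot[(qrX$rank + 1):p_cols]]
    abort(paste0("degenerate (singular) design; aliased column(s): ",
                 paste(drop_col, collapse = ", ")),
          class = "circsleep_degenerate_design")
  }
  df_error <- n - p_cols
  if (df_error < 1) {
    abort("not enough complete cases for the design",
          class = "circsleep_degenerate_design")
  }

  fit_full <- lm.fit(X, y)
  rss1 <- sum(fit_full$residuals^2)
  X0 <- X[, -2, drop = FALSE]
  fit_red <- lm.fit(X0, y)
  rss0 <- sum(fit_red$residuals^2)
  Fstat <- ((rss0 - rss1) / 1) / (rss1 / df_error)
  Fstat <- max(Fstat, 0)
  pval <- f_pvalue(Fstat, 1, df_error)
  eta <- partial_eta_squared(Fstat, 1, df_error)

  sigma2 <- rss1 / df_error
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  coefs <- tibble(
    term = colnames(X),
    estimate = unname(fit_full$coefficients),
    std.error = se,
    statistic = unname(fit_full$coefficients) / se,
    p.value = 2 * stats::pt(abs(unname(fit_full$coefficients) / se),
                            df_error, lower.tail = FALSE)
  )

  desc <- tibble(level = levels(g)) |>
    mutate(
      n = vapply(.data$level, function(l) sum(g == l), integer(1),
                 USE.NAMES = FALSE),
      mean = vapply(.data$level, function(l) mean(y[g == l]), numeric(1),
                    USE.NAMES = FALSE),
      sd = vapply(.data$level, function(l) stats::sd(y[g == l]), numeric(1),
                  USE.NAMES = FALSE)
    )
  if (any(desc$n < 2)) {
    abort("each group level needs at least 2 observations",
          class = "circsleep_degenerate_design")
  }

  structure(
    list(outcome = outcome, grouping = group, covariates = covariates,
         n = n, descriptives = desc, F = Fstat, df1 = 1L, df_error = df_error,
         p = pval, eta_p2 = eta, effect_label = effect_size_label(eta),
         coefficients = coefs, rss = rss1, sigma = sqrt(sigma2)),
    class = "circ_glm"
  )
}

#' @export
print.circ_glm <- function(x, ...) {
  cat("Two-group general linear model\n")
  cat("  outcome:  ", x$outcome, "\n  grouping: ", x$grouping,
      if (length(x$covariates)) paste0("\n  adjusted for: ",
                                       paste(x$covariates, collapse = ", ")),
      "\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4f, partial eta^2 = %.3f (%s)\n",
              x$df1, x$df_error, x$F, x$p, x$eta_p2, x$effect_label))
  invisible(x)
}

#' Tidy a fitted two-group model
#'
#' `tidy()` returns the per-term coefficient table; `glance()` the one-row
#' model summary (group F, dfs, p, partial eta squared, label).
#'
#' @param x A `circ_glm` object from [fit_group_model()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy circ_glm
#' @export
tidy.circ_glm <- function(x, ...) x$coefficients

#' @rdname tidy.circ_glm
#' @method glance circ_glm
#' @export
glance.circ_glm <- function(x, ...) {
  d <- x$descriptives
  tibble(
    grouping = x$grouping, outcome = x$outcome,
    level1 = d$level[1], n1 = d$n[1], m1 = d$mean[1], sd1 = d$sd[1],
    level2 = d$level[2], n2 = d$n[2], m2 = d$mean[2], sd2 = d$sd[2],
    F = x$F, df1 = x$df1, df_error = x$df_error, p = x$p,
    eta_p2 = x$eta_p2, effect_label = x$effect_label
  )
}

#' Run the full grid of circadian group comparisons
#'
#' Fits one covariate-adjusted model per circadian grouping and outcome
#' (4 x 5 = 20 by default), each on that grouping's available-case subset.
#' Rows whose design is degenerate (e.g. an empty group level) are emitted
#' with missing statistics and a warning rather than dropped. The
#' `interpret` flag marks rows whose partial eta squared reaches the medium
#' benchmark (0.06), the reporting rule used with small samples; no
#' multiple-testing correction is applied (`n_tests` records the count).
#'
#' @param profiles Profiles tibble ([build_profiles()]).
#' @param covariates Covariate columns (default sex, pubertal development,
#'   income band; use `c("sex", "pds_total")` for the two-covariate variant).
#' @param outcomes Named character vector mapping display names to profile
#'   columns.
#' @param groupings Grouping columns to test.
#' @return Tibble with one row per grouping x outcome, plus attribute
#'   `n_tests`.
#' @export
run_all_comparisons <- function(profiles,
                                covariates = c("sex", "pds_total", "income_band"),
                                outcomes = c(
                                  depression = "dass_depression",
                                  anxiety = "dass_anxiety",
                                  stress = "dass_stress",
                                  cognitive_reappraisal = "erq_reappraisal",
                                  expressive_suppression = "erq_suppression"),
                                groupings = c("phase_group", "alignment_group",
                                              "sjl_group", "chronotype_group")) {
  grid <- tidyr::expand_grid(grouping = groupings, outcome = names(outcomes))
  rows <- purrr::pmap(grid, function(grouping, outcome) {
    fit <- tryCatch(
      fit_group_model(profiles, outcomes[[outcome]], grouping, covariates),
      circsleep_degenerate_design = function(e) {
        warn(paste0("skipping statistics for ", grouping, " x ", outcome,
                    ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) {
      return(tibble(grouping = grouping, outcome = outcome,
                    level1 = NA_character_, n1 = NA_integer_, m1 = NA_real_,
                    sd1 = NA_real_, level2 = NA_character_, n2 = NA_integer_,
                    m2 = NA_real_, sd2 = NA_real_, F = NA_real_,
                    df1 = NA_integer_, df_error = NA_integer_, p = NA_real_,
                    eta_p2 = NA_real_, effect_label = NA_character_))
    }
    g <- glance(fit)
    g$outcome <- outcome
    g
  })
  out <- list_rbind(rows) |>
    mutate(interpret = !is.na(.data$eta_p2) & .data$eta_p2 >= 0.06)
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("circ_comparisons", class(out))
  out
}
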