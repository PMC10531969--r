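ELIGIBILITY_STEPS <- c("amputation", "under_18", "deceased",
                       "unknown_address", "insufficient_postop_images")

#' Eligibility filtering of a surgical cohort
#'
#' Applies the exclusion cascade — amputation, age under 18, deceased at
#' follow-up, unknown address, insufficient postoperative image quality —
#' either to patient-level records (logical flag columns) or to aggregate
#' counts, and returns an eligibility ledger.
#'
#' @param x either a data.frame with logical columns named after the
#'   exclusion steps (plus optionally `responded`), or a named numeric
#'   vector/list with `total_surgical`, the five step counts, and
#'   optionally `responders`.
#' @return An object of class `eligibility_ledger` with `total_surgical`,
#'   per-step `excluded` counts, `eligible` and `responders`.
#' @export
#' @examples
#' led <- apply_eligibility_filters(c(total_surgical = 766, amputation = 4,
#'   under_18 = 33, deceased = 74, unknown_address = 12,
#'   insufficient_postop_images = 6, responders = 362))
#' led$eligible        # 637
#' response_rate(led)  # 57
apply_eligibility_filters <- function(x) {
  if (is.data.frame(x)) {
    miss <- setdiff(ELIGIBILITY_STEPS, names(x))
    if (length(miss)) stop("records lack exclusion flags: ",
                           paste(miss, collapse = ", "))
    remaining <- rep(TRUE, nrow(x))
    excluded <- setNames(integer(length(ELIGIBILITY_STEPS)), ELIGIBILITY_STEPS)
    for (s in ELIGIBILITY_STEPS) {
      hit <- remaining & as.logical(x[[s]])
      excluded[s] <- sum(hit)
      remaining <- remaining & !hit
    }
    responders <- if ("responded" %in% names(x))
      sum(remaining & as.logical(x$responded)) else NA_integer_
    ledger <- list(total_surgical = nrow(x), excluded = excluded,
                   eligible = sum(remaining), responders = responders)
  } else {
    x <- unlist(x)
    if (!"total_surgical" %in% names(x)) stop("counts need 'total_surgical'")
    miss <- setdiff(ELIGIBILITY_STEPS, names(x))
    if (length(miss)) stop("counts lack exclusion steps: ",
                           paste(miss, collapse = ", "))
    excluded <- x[ELIGIBILITY_STEPS]
    ledger <- list(total_surgical = unname(x["total_surgical"]),
                   excluded = excluded,
                   eligible = unname(x["total_surgical"] - sum(excluded)),
                   responders = if ("responders" %in% names(x))
                     unname(x["responders"]) else NA_integer_)
  }
  if (ledger$eligible < 0) stop("exclusions exceed the surgical total")
  if (!is.na(ledger$responders) && ledger$responders > ledger$eligible)
    stop("responders exceed eligible patients")
  structure(ledger, class = "eligibility_ledger")
}

#' @export
print.eligibility_ledger <- function(x, ...) {
  cat("<eligibility_ledger> surgical", x$total_surgical, "\n")
  for (s in names(x$excluded))
    cat(sprintf("  - %-28s %d\n", s, x$excluded[[s]]))
  cat("  eligible", x$eligible)
  if (!is.na(x$responders))
    cat(";  responders", x$responders,
        sprintf("(%d%%)", response_rate(x)))
  cat("\n")
  invisible(x)
}

#' Response rate of an eligibility ledger
#' @param ledger An [apply_eligibility_filters()] result.
#' @return Response percentage, rounded to the nearest integer.
#' @export
response_rate <- function(ledger) {
  stopifnot(inherits(ledger, "eligibility_ledger"))
  if (is.na(ledger$responders)) stop("ledger has no responder count")
  if (ledger$eligible <= 0) stop("no eligible patients")
  round(100 * ledger$responders / ledger$eligible)
}

#' Summarize KOOS outcome by prognostic gap-area group
#'
#' @param cohort data.frame with a gap-area column and KOOS subscale
#'   columns.
#' @param gap_field name of the gap-area column (mm^2), default
#'   `"initial_gap_mm2"`.
#' @param subscales subscale columns to summarize.
#' @return data.frame with one row per group x subscale: `group`,
#'   `subscale`, `n`, `mean`, `sd` (mean is NA for empty groups).
#' @export
group_summary <- function(cohort, gap_field = "initial_gap_mm2",
                          subscales = KOOS_SUBSCALES) {
  if (!gap_field %in% names(cohort)) stop("no column '", gap_field, "'")
  grp <- assign_prognostic_group(cohort[[gap_field]])
  out <- expand.grid(group = levels(grp), subscale = subscales,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean <- NA_real_; out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- cohort[[out$subscale[r]]][grp == out$group[r]]
    v <- v[!is.na(v)]
    out$n[r] <- length(v)
    if (length(v) > 0) out$mean[r] <- mean(v)
    if (length(v) > 1) out$sd[r] <- sd(v)
  }
  out
}

#' One-way analysis of variance across groups
#'
#' Classical one-way fixed-effects ANOVA (equal-variance F test) of a
#' continuous outcome across groups, with per-group descriptives.
#'
#' @param values_by_group either a named list of numeric vectors, or a
#'   numeric vector (then `groups` is required).
#' @param groups optional grouping factor parallel to a numeric
#'   `values_by_group`.
#' @return An object of class `anova_result`: `F`, `df`, `p_value` and a
#'   `groups` data.frame (n, mean, sd).
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))$F  # 27
one_way_anova <- function(values_by_group, groups = NULL) {
  if (is.list(values_by_group)) {
    v <- unlist(values_by_group, use.names = FALSE)
    g <- rep(names(values_by_group) %||% seq_along(values_by_group),
             lengths(values_by_group))
  } else {
    if (is.null(groups)) stop("groups required for a numeric value vector")
    v <- values_by_group; g <- groups
  }
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- factor(g[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("ANOVA needs at least 2 non-empty groups")
  if (length(v) - nlevels(g) < 2) stop("ANOVA needs at least 2 residual df")
  fit <- aov(v ~ g)
  tab <- summary(fit)[[1]]
  # no between-group variation: define F = 0 (p = 1) even when the
  # within-group variance is also zero
  if (tab[1, "Sum Sq"] < 1e-12 * max(1, sum(v^2))) {
    tab[1, "F value"] <- 0
    tab[1, "Pr(>F)"] <- 1
  }
  desc <- data.frame(group = levels(g),
                     n = as.integer(table(g)),
                     mean = as.numeric(tapply(v, g, mean)),
                     sd = as.numeric(tapply(v, g, sd)))
  structure(list(F = tab[1, "F value"], df = c(tab[1, "Df"], tab[2, "Df"]),
                 p_value = tab[1, "Pr(>F)"], groups = desc),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Confounder-adjusted linear regression of outcome on gap area
#'
#' Ordinary least squares of a KOOS subscale on the 3D gap area scaled to
#' 100 mm^2 units, adjusted for the standard confounder set: age, sex, BMI,
#' smoking, AO/OTA classification (dummy-coded, 41-B1 reference),
#' complication, follow-up time, and — for the initial-displacement model
#' only — inadequate reduction on the postoperative radiograph (the
#' residual-displacement model omits it, as the residual gap area itself
#' measures reduction quality). Complete-case analysis; 95% confidence
#' intervals from the t distribution with residual df.
#'
#' @param cohort data.frame with the outcome, gap and confounder columns
#'   (`age`, `sex`, `bmi`, `smoking`, `ao_ota`, `complication`,
#'   `follow_up`, and `inadequate_reduction` for the initial model).
#' @param outcome KOOS subscale column name.
#' @param gap_field `"initial_gap_mm2"` or `"residual_gap_mm2"`.
#' @return An object of class `regression_result`: `terms` data.frame
#'   (term, estimate, conf_low, conf_high, p_value), `n`, `outcome`,
#'   `gap_field`, `note`, and the underlying `fit`.
#' @export
fit_ols <- function(cohort, outcome,
                    gap_field = c("initial_gap_mm2", "residual_gap_mm2")) {
  gap_field <- match.arg(gap_field)
  if (!outcome %in% names(cohort)) stop("no outcome column '", outcome, "'")
  confounders <- c("age", "sex", "bmi", "smoking", "ao_ota", "complication",
                   "follow_up")
  if (gap_field == "initial_gap_mm2")
    confounders <- append(confounders, "inadequate_reduction", after = 6)
  miss <- setdiff(c(gap_field, confounders), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  d <- data.frame(.outcome = cohort[[outcome]],
                  gap_per_100mm2 = cohort[[gap_field]] / 100)
  d$age <- cohort$age
  d$sex <- factor(cohort$sex, levels = c("male", "female"))
  d$bmi <- cohort$bmi
  d$smoking <- as.logical(cohort$smoking)
  d$ao_ota <- factor(cohort$ao_ota, levels = AO_OTA_CODES)
  d$complication <- as.logical(cohort$complication)
  if ("inadequate_reduction" %in% confounders)
    d$inadequate_reduction <- as.logical(cohort$inadequate_reduction)
  d$follow_up <- cohort$follow_up
  d <- d[complete.cases(d), , drop = FALSE]
  d$ao_ota <- droplevels(d$ao_ota)
  fit <- lm(.outcome ~ ., data = d)
  if (anyNA(coef(fit)))
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  ci <- confint(fit, level = 0.95)
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      conf_low = ci[, 1], conf_high = ci[, 2],
                      p_value = sm[, 4], row.names = NULL)
  structure(list(terms = terms, n = nrow(d), outcome = outcome,
                 gap_field = gap_field,
                 note = paste0("gap coefficient per 100 mm^2; reference ",
                               "levels: 41-B1, male, non-smoker, no ",
                               "complication, adequate reduction"),
                 fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result>", x$outcome, "~", x$gap_field,
      sprintf("(n = %d)\n", x$n))
  g <- x$terms[x$terms$term == "gap_per_100mm2", ]
  cat(sprintf("  gap area (per 100 mm^2): B = %.1f (%.1f to %.1f), p = %.3g\n",
              g$estimate, g$conf_low, g$conf_high, g$p_value))
  invisible(x)
}

#' Gap-area coefficient of a fitted model
#' @param result A [fit_ols()] result.
#' @return Named numeric: estimate, conf_low, conf_high, p_value.
#' @export
gap_coefficient <- function(result) {
  stopifnot(inherits(result, "regression_result"))
  g <- result$terms[result$terms$term == "gap_per_100mm2", ]
  c(estimate = g$estimate, conf_low = g$conf_low, conf_high = g$conf_high,
    p_value = g$p_value)
}

#' Responder vs nonresponder comparisons from summary statistics
#'
#' Welch two-sample t test for age computed from means, SDs and group
#' sizes, and a two-proportion chi-square test with continuity correction
#' for sex.
#'
#' @param responders,nonresponders lists with `n`, `age_mean`, `age_sd` and
#'   `n_female`.
#' @return List with `age` (t, df, p_value) and `sex` (chisq, df, p_value).
#' @export
nonresponse_tests <- function(responders, nonresponders) {
  r <- responders; nr <- nonresponders
  se2 <- r$age_sd^2 / r$n + nr$age_sd^2 / nr$n
  t <- (r$age_mean - nr$age_mean) / sqrt(se2)
  df <- se2^2 / ((r$age_sd^2 / r$n)^2 / (r$n - 1) +
                   (nr$age_sd^2 / nr$n)^2 / (nr$n - 1))
  p_age <- 2 * pt(-abs(t), df)
  pt_res <- prop.test(c(r$n_female, nr$n_female), c(r$n, nr$n), correct = TRUE)
  list(age = list(t = t, df = df, p_value = p_age),
       sex = list(chisq = unname(pt_res$statistic), df = unname(pt_res$parameter),
                  p_value = pt_res$p.value))
}
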