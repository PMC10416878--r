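#' Compare a per-slide layer summary across diagnosis groups
#'
#' One-way ANOVA F-test of a per-slide summary statistic (the median
#' layer number, or its standard deviation as a measure of thickness
#' variability) across diagnosis groups.
#'
#' @param cohort data.frame with columns `slide_id`, `diagnosis_group`
#'   and the chosen statistic (see [generate_cohort()] for the layout).
#' @param statistic `"median_layers"` or `"sd_layers"`.
#' @return object of class `"group_comparison"`: list with `statistic`,
#'   `groups` (per-group n/mean/median), `f_statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(cohort, statistic = c("median_layers",
                                                 "sd_layers")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("diagnosis_group", statistic) %in% names(cohort)))
  tab <- table(cohort$diagnosis_group)
  if (length(tab) < 2)
    stop("need at least 2 diagnosis groups", call. = FALSE)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("group(s) with fewer than 2 slides: ",
         paste(small, collapse = ", "), call. = FALSE)
  y <- cohort[[statistic]]
  g <- factor(cohort$diagnosis_group)
  # suppress lm's perfect-fit warning; degenerate cases are handled below
  fit <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ss_between <- fit$`Sum Sq`[1]
  ss_within <- fit$`Sum Sq`[2]
  f_stat <- fit$`F value`[1]
  p_val <- fit$`Pr(>F)`[1]
  # degenerate decompositions: no between-group signal is F = 0, p = 1
  # even when the within-group variance also vanishes; perfect separation
  # with zero within-group variance is F = Inf, p = 0
  if (ss_between <= .Machine$double.eps * max(1, sum(y^2))) {
    f_stat <- 0; p_val <- 1
  } else if (ss_within <= .Machine$double.eps * max(1, sum(y^2))) {
    f_stat <- Inf; p_val <- 0
  }
  per_group <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- y[g == lv]
    data.frame(group = lv, n = length(v), mean = mean(v),
               median = stats::median(v))
  }))
  structure(list(statistic = statistic,
                 groups = per_group,
                 f_statistic = f_stat,
                 df = c(fit$Df[1], fit$Df[2]),
                 p_value = p_val),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("one-way ANOVA on", x$statistic, "\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Median-split survival analysis of epithelial layer number
#'
#' Ranks slides by their median layer number, splits the cohort at its
#' median into equal low/high groups (sizes `floor(n/2)` and
#' `ceiling(n/2)`; ties broken by stable sort on `slide_id`), estimates
#' Kaplan-Meier progression-free survival curves per group, and fits a
#' Cox proportional-hazards model of the event on the group indicator
#' (Efron tie handling). Extra covariate columns can be included in the
#' Cox fit via `covariates`.
#'
#' @param cohort data.frame with `slide_id`, `median_layers`,
#'   `pfi_time`, `pfi_event` (0/1).
#' @param covariates optional character vector of extra cohort columns
#'   entered into the Cox model alongside the risk group.
#' @return object of class `"survival_report"`: list with
#'   `split_threshold`, `group_sizes`, `km` (data.frame of product-limit
#'   curves: group, time, n_risk, n_event, survival), `cox_coef`,
#'   `hazard_ratio`, `hr_ci` (95%), `p_wald`, `p_lrt`, and the fitted
#'   `cox_fit`.
#' @export
survival_split <- function(cohort, covariates = character()) {
  need <- c("slide_id", "median_layers", "pfi_time", "pfi_event")
  stopifnot(all(need %in% names(cohort)))
  if (any(cohort$pfi_time <= 0))
    stop("pfi_time must be positive", call. = FALSE)
  n <- nrow(cohort)
  ord <- order(cohort$median_layers, cohort$slide_id)
  cohort <- cohort[ord, , drop = FALSE]
  n_low <- floor(n / 2)
  cohort$risk_group <- factor(
    rep(c("low", "high"), c(n_low, n - n_low)),
    levels = c("low", "high"))
  threshold <- stats::median(cohort$median_layers)

  if (all(cohort$pfi_event == 0)) {
    warning("all subjects censored; survival comparison undefined",
            call. = FALSE)
    return(structure(list(split_threshold = threshold,
                          group_sizes = table(cohort$risk_group),
                          km = NULL, cox_coef = NA_real_,
                          hazard_ratio = NA_real_, hr_ci = c(NA, NA),
                          p_wald = NA_real_, p_lrt = NA_real_,
                          cox_fit = NULL, data = cohort),
                     class = "survival_report"))
  }

  sf <- survival::survfit(
    survival::Surv(pfi_time, pfi_event) ~ risk_group, data = cohort)
  strata_names <- sub("^risk_group=", "", rep(names(sf$strata), sf$strata))
  km <- data.frame(group = strata_names, time = sf$time,
                   n_risk = sf$n.risk, n_event = sf$n.event,
                   survival = sf$surv)

  fml <- stats::as.formula(paste(
    "survival::Surv(pfi_time, pfi_event) ~ risk_group",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  fit <- survival::coxph(fml, data = cohort, ties = "efron")
  sm <- summary(fit)
  structure(list(split_threshold = threshold,
                 group_sizes = table(cohort$risk_group),
                 km = km,
                 cox_coef = unname(stats::coef(fit)["risk_grouphigh"]),
                 hazard_ratio = unname(exp(stats::coef(fit)["risk_grouphigh"])),
                 hr_ci = unname(sm$conf.int["risk_grouphigh",
                                            c("lower .95", "upper .95")]),
                 p_wald = unname(sm$coefficients["risk_grouphigh",
                                                 "Pr(>|z|)"]),
                 p_lrt = unname(sm$logtest["pvalue"]),
                 cox_fit = fit,
                 data = cohort),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("median split at", x$split_threshold, "layers; group sizes:",
      paste(names(x$group_sizes), as.integer(x$group_sizes),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("Cox HR (high vs low) = %.3f [%.3f, %.3f], Wald p = %.4g, LRT p = %.4g\n",
              x$hazard_ratio, x$hr_ci[1], x$hr_ci[2], x$p_wald, x$p_lrt))
  invisible(x)
}
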