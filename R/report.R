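serialize_fit <- function(fit) {
  list(method = fit$method, n_obs = fit$n_obs, converged = fit$converged,
       n_iter = fit$n_iter, scale = fit$scale, terms = fit$terms)
}

serialize_stage <- function(stage, f = identity) {
  if (isTRUE(stage$skipped))
    list(skipped = TRUE, reason = stage$reason)
  else f(stage$value)
}

serialize_report <- function(r) {
  list(
    frequency_table = serialize_stage(r$frequency_table, function(v)
      list(categories = v$categories, subcategories = v$subcategories,
           total = v$total)),
    typicality = serialize_stage(r$typicality, unclass),
    metric_profiles = r$metric_profiles,
    clusters = serialize_stage(r$clusters, function(v)
      list(k_selected = v$k_selected, wcss_by_k = as.list(v$wcss_by_k),
           assignments = as.list(v$assignments),
           cluster_summary = v$cluster_summary,
           u_statistic = v$u_statistic, u_min = v$u_min,
           p_value = v$p_value)),
    logistic_fit = serialize_stage(r$logistic_fit, serialize_fit),
    ols_fit = serialize_stage(r$ols_fit, serialize_fit),
    huber_fit = serialize_stage(r$huber_fit, serialize_fit),
    icc = serialize_stage(r$icc, function(v)
      list(sigma2_between = v$sigma2_between, sigma2_within = v$sigma2_within,
           icc = v$icc, n_groups = v$n_groups, n_obs = v$n_obs,
           method = v$method, anova = v$anova, reml = v$reml)),
    provenance = r$provenance)
}

md_fit_table <- function(fit, title) {
  tt <- fit$terms
  c(sprintf("## %s", title),
    "",
    "| Predictor | Coefficient | Std. error | z-value | p-value | 95% CI (Lower, Upper) |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %.2f | %.2f | %.2f | %.3f | (%.2f, %.2f) |",
            tt$term, tt$estimate, tt$std_error, tt$z_value, tt$p_value,
            tt$ci_low, tt$ci_high),
    "")
}

md_stage <- function(stage, title, f) {
  if (isTRUE(stage$skipped))
    c(sprintf("## %s", title), "", sprintf("Skipped: %s", stage$reason), "")
  else f(stage$value)
}

#' Render an analysis report
#'
#' `"json"` gives a schema-stable, reparseable document (pretty-printed,
#' fixed numeric precision, no timestamps, so identical analyses render
#' byte-identically). `"markdown"` gives a human-readable report with a
#' frequency table over all seven categories and coefficient tables in the
#' Predictor / Coefficient / Std. error / z-value / p-value / 95\% CI layout
#' of published regression tables.
#'
#' @param r an `explor_report` from [analyze_dataset()] or [run_pipeline()].
#' @param format `"json"` or `"markdown"`.
#' @return A single character string.
#' @export
render_report <- function(r, format = c("json", "markdown")) {
  stopifnot(inherits(r, "explor_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(serialize_report(r), pretty = TRUE,
                                         auto_unbox = TRUE, digits = I(10),
                                         na = "null", null = "null")))
  }
  lines <- c("# Exploration Index analysis report", "")
  lines <- c(lines, md_stage(r$frequency_table, "Object use categories",
    function(v) {
      ct <- v$categories
      c("## Object use categories", "",
        "| Category | Bouts | Proportion of total (%) |", "|---|---|---|",
        sprintf("| %s | %d | %.1f |", ct$category, ct$count,
                ct$proportion_percent),
        sprintf("| TOTAL | %d | 100 |", v$total), "")
    }))
  lines <- c(lines, md_stage(r$typicality, "Typicality", function(v)
    c("## Typicality", "",
      sprintf("- typical: %d; atypical: %d (%.1f%%)", v$n_typical,
              v$n_atypical, v$pct_atypical),
      sprintf("- atypical split: %d omission, %d commission (%.1f%% of atypical)",
              v$n_omission, v$n_commission, v$pct_commission_of_atypical),
      sprintf("- atypical share of bouts at age <= %g: %.1f%%; above: %.1f%%",
              v$age_cut, v$young_atypical_pct, v$old_atypical_pct), "")))
  lines <- c(lines, md_stage(r$clusters, "Explorer clusters", function(v) {
    s <- v$cluster_summary
    c("## Explorer clusters", "",
      sprintf("Selected k = %d by the elbow method.", v$k_selected), "",
      "| Cluster | n | Mean | SD | Range |", "|---|---|---|---|---|",
      sprintf("| %s | %d | %.2f | %.2f | %.2f to %.2f |", s$cluster, s$size,
              s$mean, s$sd, s$min, s$max),
      if (!is.null(v$u_statistic))
        sprintf("\nMann-Whitney U (high orientation) = %g (U_min = %g), p = %.3g",
                v$u_statistic, v$u_min, v$p_value) else character(), "")
  }))
  lines <- c(lines, md_stage(r$logistic_fit,
                             "Logistic regression: atypical use vs. age",
                             function(v) md_fit_table(v,
                               "Logistic regression: atypical use vs. age")))
  lines <- c(lines, md_stage(r$ols_fit, "OLS regression: Exploration Index",
                             function(v) md_fit_table(v,
                               "OLS regression: Exploration Index")))
  lines <- c(lines, md_stage(r$huber_fit,
                             "Robust regression (Huber M-estimator): Exploration Index",
                             function(v) md_fit_table(v,
                               "Robust regression (Huber M-estimator): Exploration Index")))
  lines <- c(lines, md_stage(r$icc, "Maternal-ID variance components",
    function(v)
      c("## Maternal-ID variance components", "",
        sprintf("ICC = %.3f (%s; sigma2_between = %.3g, sigma2_within = %.3g; %d mothers)",
                v$icc, v$method, v$sigma2_between, v$sigma2_within,
                v$n_groups), "")))
  paste(lines, collapse = "\n")
}
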