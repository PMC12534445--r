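#' One-way random-intercept variance components and ICC
#'
#' Fits the one-way random-effects model
#' \eqn{y_{ij} = \mu + a_i + e_{ij}}, \eqn{a_i \sim N(0, \sigma^2_b)},
#' \eqn{e_{ij} \sim N(0, \sigma^2_w)}, by REML, profiling the within-group
#' variance and maximizing over the intraclass correlation
#' \eqn{\rho = \sigma^2_b / (\sigma^2_b + \sigma^2_w)} on \[0, 1\) by
#' one-dimensional optimization (closed-form profile likelihood handles
#' unbalanced group sizes). The method-of-moments (ANOVA) estimator is
#' computed alongside as a cross-check; on balanced designs with an interior
#' solution the two coincide. Negative component estimates are truncated at
#' zero.
#'
#' @param values numeric vector of scores.
#' @param group_ids grouping factor (e.g. maternal identity); at least two
#'   groups required.
#' @param method which estimator populates `sigma2_between`, `sigma2_within`
#'   and `icc`: `"reml"` (default) or `"anova"`. Both are always returned in
#'   the `reml` and `anova` sub-lists.
#' @return An object of class `explor_icc`: list with `sigma2_between`,
#'   `sigma2_within`, `icc`, `n_groups`, `n_obs`, `method`, and sub-lists
#'   `reml` and `anova` with each estimator's components.
#' @export
icc_one_way <- function(values, group_ids, method = c("reml", "anova")) {
  method <- match.arg(method)
  if (length(values) != length(group_ids))
    explor_error("values and group_ids must have equal length",
                 "explor_domain_error")
  g <- factor(group_ids)
  a <- nlevels(g)
  if (a < 2)
    explor_error("icc_one_way requires at least two groups",
                 "explor_domain_error")
  N <- length(values)
  ni <- as.numeric(table(g))
  si <- as.numeric(tapply(values, g, sum))
  S2 <- sum(values^2)
  Tot <- sum(values)
  SSB <- sum(si^2 / ni) - Tot^2 / N
  SSW <- S2 - sum(si^2 / ni)

  # ANOVA (method-of-moments) estimator for unbalanced one-way designs
  MSB <- SSB / (a - 1)
  MSW <- if (N > a) SSW / (N - a) else 0
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2w_anova <- MSW
  s2b_anova <- max(0, (MSB - MSW) / n0)
  icc_anova <- if (s2b_anova + s2w_anova > 0)
    s2b_anova / (s2b_anova + s2w_anova) else 0

  # REML: profile -2 log-likelihood in rho, lambda = rho / (1 - rho)
  prof <- function(rho) {
    lam <- rho / (1 - rho)
    d <- 1 + lam * ni
    A <- sum(ni / d)
    Q <- (S2 - lam * sum(si^2 / d)) - (sum(si / d))^2 / A
    s2w <- Q / (N - 1)
    if (s2w <= 0) return(Inf)
    (N - 1) * log(s2w) + sum(log(d)) + log(A)
  }
  if (SSW <= 1e-12 * max(1, S2) && SSB > 0) {
    # no within-group variance: perfect clustering
    s2w_reml <- 0; s2b_reml <- MSB / n0; icc_reml <- 1
  } else if (SSB + SSW <= 0 || stats::var(values) == 0) {
    s2w_reml <- 0; s2b_reml <- 0; icc_reml <- 0
  } else {
    opt <- stats::optimize(prof, interval = c(0, 1 - 1e-10), tol = 1e-12)
    # compare against the boundary rho = 0 explicitly
    rho <- if (prof(0) <= opt$objective) 0 else opt$minimum
    lam <- rho / (1 - rho)
    d <- 1 + lam * ni
    A <- sum(ni / d)
    Q <- (S2 - lam * sum(si^2 / d)) - (sum(si / d))^2 / A
    s2w_reml <- Q / (N - 1)
    s2b_reml <- lam * s2w_reml
    icc_reml <- rho
  }
  reml <- list(sigma2_between = s2b_reml, sigma2_within = s2w_reml,
               icc = icc_reml)
  anova <- list(sigma2_between = s2b_anova, sigma2_within = s2w_anova,
                icc = icc_anova)
  sel <- if (method == "reml") reml else anova
  structure(list(sigma2_between = sel$sigma2_between,
                 sigma2_within = sel$sigma2_within,
                 icc = min(1, max(0, sel$icc)),
                 n_groups = a, n_obs = N, method = method,
                 reml = reml, anova = anova),
            class = "explor_icc")
}

#' @export
print.explor_icc <- function(x, ...) {
  cat(sprintf(
    "<explor_icc> ICC = %.4f (%s) over %d groups, %d observations\n",
    x$icc, x$method, x$n_groups, x$n_obs))
  cat(sprintf("  sigma2_between = %.4g, sigma2_within = %.4g\n",
              x$sigma2_between, x$sigma2_within))
  invisible(x)
}
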