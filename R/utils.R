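# Small shared helpers.

# Round-half-up at `digits` decimal places (base round() is round-half-even;
# printed tables in the field round 41.79 -> 41.8 and 49.25 -> 49.3).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

new_model_fit <- function(term, estimate, std_error, n_obs, converged = TRUE,
                          n_iter = 0L, scale = NA_real_, method = "ols") {
  z <- ifelse(std_error > 0, estimate / std_error,
              ifelse(estimate == 0, 0, sign(estimate) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(0.975)
  fit <- list(
    terms = data.frame(term = term, estimate = estimate,
                       std_error = std_error, z_value = z, p_value = p,
                       ci_low = estimate - q * std_error,
                       ci_high = estimate + q * std_error,
                       stringsAsFactors = FALSE),
    n_obs = n_obs, converged = converged, n_iter = as.integer(n_iter),
    scale = scale, method = method)
  class(fit) <- "explor_fit"
  fit
}

#' @export
print.explor_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<explor_fit> method = %s, n = %d%s\n", x$method, x$n_obs,
              if (!x$converged) " (NOT converged)" else ""))
  tt <- x$terms
  out <- data.frame(
    Predictor = tt$term,
    Coefficient = round(tt$estimate, digits),
    `Std. error` = round(tt$std_error, digits),
    `z-value` = round(tt$z_value, digits),
    `p-value` = signif(tt$p_value, 3),
    `95% CI` = sprintf("(%.2f, %.2f)", tt$ci_low, tt$ci_high),
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.explor_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

check_design <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  if (length(y) != nrow(X))
    explor_error("length(y) must equal nrow(X)", "explor_domain_error")
  if (nrow(X) <= ncol(X))
    explor_error("need more observations than parameters",
                 "explor_domain_error")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    explor_error(paste("design matrix is rank deficient; collinear column(s):",
                       paste(dropped, collapse = ", ")),
                 "explor_rank_error")
  }
  X
}
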