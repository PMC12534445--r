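#' Category frequency table
#'
#' Counts bouts per ethogram category (and per subcategory where coded) with
#' proportions of the total as percentages rounded half-up to one decimal
#' place, mirroring the printed precision of published frequency tables.
#'
#' @param ds an `explor_dataset` with at least one bout.
#' @return An object of class `explor_freq`: list with `categories`
#'   (data.frame `category`, `count`, `proportion_percent`, all seven
#'   categories in canonical order), `subcategories` (data.frame
#'   `category`, `subcategory`, `count`) and `total`.
#' @export
category_frequencies <- function(ds) {
  stopifnot(inherits(ds, "explor_dataset"))
  bouts <- ds$bouts
  if (!nrow(bouts))
    explor_error("category_frequencies requires at least one bout",
                 "explor_domain_error")
  total <- nrow(bouts)
  cnt <- as.integer(table(factor(bouts$category, levels = OBJECT_CATEGORIES)))
  categories <- data.frame(category = OBJECT_CATEGORIES, count = cnt,
                           proportion_percent = round_half_up(100 * cnt / total, 1),
                           stringsAsFactors = FALSE)
  has_sub <- !is.na(bouts$subcategory)
  subs <- if (any(has_sub)) {
    agg <- stats::aggregate(list(count = bouts$bout_id[has_sub]),
                            by = list(category = bouts$category[has_sub],
                                      subcategory = bouts$subcategory[has_sub]),
                            FUN = length)
    agg <- agg[order(match(agg$category, OBJECT_CATEGORIES), agg$subcategory), ]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(category = character(), subcategory = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(categories = categories, subcategories = subs, total = total),
            class = "explor_freq")
}

#' @export
print.explor_freq <- function(x, ...) {
  cat(sprintf("<explor_freq> %d bouts\n", x$total))
  print(x$categories, row.names = FALSE)
  invisible(x)
}

#' Typical/atypical accounting with an age-class comparison
#'
#' Tallies typical vs. atypical bouts, splits the atypical bouts into
#' omission uses (attempts at an adult form missing key elements) and
#' commission uses (novel, modified or recontextualized uses), and compares
#' the atypical share between bouts by younger (age at bout `<= age_cut`)
#' and older (`> age_cut`) immatures. Percentages are rounded half-up to one
#' decimal place and recompute exactly from their integer numerators and
#' denominators.
#'
#' @param ds an `explor_dataset`.
#' @param age_cut age in years separating the young and old bout classes
#'   (default 4, boundary-inclusive for young).
#' @return An object of class `explor_typicality`: list with counts
#'   `n_typical`, `n_atypical`, `n_omission`, `n_commission`, percentages
#'   `pct_atypical`, `pct_commission_of_atypical` (NA when no atypical bouts),
#'   `young_atypical_pct`, `old_atypical_pct` (NA for an empty class), the
#'   class sizes `n_young`, `n_old`, and `age_cut`.
#' @export
typicality_breakdown <- function(ds, age_cut = 4.0) {
  stopifnot(inherits(ds, "explor_dataset"))
  bouts <- ds$bouts
  if (!nrow(bouts))
    explor_error("typicality_breakdown requires at least one bout",
                 "explor_domain_error")
  atyp <- bouts$typicality == "atypical"
  young <- bouts$age_at_bout <= age_cut
  n_atyp <- sum(atyp)
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else NA_real_
  structure(list(
    n_typical = sum(!atyp),
    n_atypical = n_atyp,
    n_omission = sum(bouts$atypical_mode == "omission", na.rm = TRUE),
    n_commission = sum(bouts$atypical_mode == "commission", na.rm = TRUE),
    pct_atypical = pct(n_atyp, nrow(bouts)),
    pct_commission_of_atypical =
      pct(sum(bouts$atypical_mode == "commission", na.rm = TRUE), n_atyp),
    young_atypical_pct = pct(sum(atyp & young), sum(young)),
    old_atypical_pct = pct(sum(atyp & !young), sum(!young)),
    n_young = sum(young), n_old = sum(!young), age_cut = age_cut),
    class = "explor_typicality")
}

#' @export
print.explor_typicality <- function(x, ...) {
  cat(sprintf("<explor_typicality> %d typical / %d atypical (%.1f%%)\n",
              x$n_typical, x$n_atypical, x$pct_atypical))
  cat(sprintf("  atypical: %d omission, %d commission (%.1f%% of atypical)\n",
              x$n_omission, x$n_commission, x$pct_commission_of_atypical))
  cat(sprintf("  atypical share: age <= %g: %.1f%%; age > %g: %.1f%%\n",
              x$age_cut, x$young_atypical_pct, x$age_cut, x$old_atypical_pct))
  invisible(x)
}

#' Logistic regression of atypical use on age
#'
#' Fits a logistic regression of bout typicality (atypical = 1, typical = 0)
#' on age by Newton-Raphson (see [logistic_fit()]). The default unit of
#' analysis is the bout, with age at bout as the continuous predictor; the
#' `"individual"` level aggregates each individual's bouts into a binomial
#' count of atypical uses with central age (mean bout age) as the predictor.
#'
#' @param ds an `explor_dataset`.
#' @param level `"bout"` (default) or `"individual"`.
#' @return An `explor_fit` with terms `(Intercept)` and `age`.
#' @export
atypicality_logistic <- function(ds, level = c("bout", "individual")) {
  level <- match.arg(level)
  stopifnot(inherits(ds, "explor_dataset"))
  bouts <- ds$bouts
  if (level == "bout") {
    y <- as.numeric(bouts$typicality == "atypical")
    if (sum(y) < 2 || sum(1 - y) < 2)
      explor_error("need at least 2 bouts in each outcome class",
                   "explor_domain_error")
    X <- cbind("(Intercept)" = 1, age = bouts$age_at_bout)
    logistic_fit(y, X)
  } else {
    prof <- compute_metrics(ds)
    successes <- round(prof$atypical_proportion * prof$total_bouts)
    X <- cbind("(Intercept)" = 1, age = prof$central_age)
    logistic_fit(successes / prof$total_bouts, X, weights = prof$total_bouts)
  }
}
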