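#' z-transform a vector of metric values
#'
#' Centers and scales to sample mean 0 and sample standard deviation 1
#' (denominator n - 1). A zero-variance input returns all zeros, so that a
#' degenerate metric contributes nothing to the composite index instead of
#' erroring.
#'
#' @param values numeric vector, length >= 2.
#' @param sd_type `"sample"` (default, n - 1 denominator) or `"population"`
#'   (n denominator).
#' @return Numeric vector of the same length.
#' @export
z_transform <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2)
    explor_error("z_transform requires at least two values",
                 "explor_domain_error")
  if (anyNA(values))
    explor_error("z_transform input contains missing values",
                 "explor_domain_error")
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((length(values) - 1) / length(values))
  if (!is.finite(s) || s == 0) return(rep(0, length(values)))
  (values - mean(values)) / s
}

#' Compute the five per-individual object-use metrics
#'
#' For every individual with at least one bout: (1) total number of bouts;
#' (2) category diversity, the number of distinct ethogram categories used;
#' (3) atypical proportion, atypical bouts over total bouts; (4) object-use
#' rate, bouts per observation hour; (5) age diversity, the number of
#' distinct integer age points (`floor(age_at_bout)`) at which bouts
#' occurred. Individuals without bouts are excluded, mirroring the study's
#' restriction to object-using subjects. `central_age` (mean bout age) and
#' `observation_hours` are carried along for downstream models.
#'
#' @param ds an `explor_dataset`.
#' @return data.frame with one row per profiled individual, ordered by
#'   `individual_id`.
#' @seealso [exploration_index()], [exploration_profiles()]
#' @export
compute_metrics <- function(ds) {
  stopifnot(inherits(ds, "explor_dataset"))
  bouts <- ds$bouts
  inds <- ds$individuals
  if (any(inds$observation_hours <= 0))
    explor_error("observation_hours must be positive", "explor_domain_error")
  used <- sort(unique(bouts$individual_id))
  inds <- inds[match(used, inds$individual_id), , drop = FALSE]
  by_id <- split(bouts, factor(bouts$individual_id, levels = used))
  prof <- data.frame(
    individual_id = used,
    total_bouts = vapply(by_id, nrow, integer(1)),
    category_diversity = vapply(by_id, function(d)
      length(unique(d$category)), integer(1)),
    atypical_proportion = vapply(by_id, function(d)
      mean(d$typicality == "atypical"), numeric(1)),
    observation_hours = inds$observation_hours,
    age_diversity = vapply(by_id, function(d)
      length(unique(floor(d$age_at_bout))), integer(1)),
    central_age = vapply(by_id, function(d) mean(d$age_at_bout), numeric(1)),
    stringsAsFactors = FALSE)
  prof$bout_rate <- prof$total_bouts / prof$observation_hours
  rownames(prof) <- NULL
  prof
}

metric_columns <- function(metric4 = c("rate", "hours")) {
  metric4 <- match.arg(metric4)
  c("total_bouts", "category_diversity", "atypical_proportion",
    if (metric4 == "rate") "bout_rate" else "observation_hours",
    "age_diversity")
}

#' Compute Exploration Indexes from metric profiles
#'
#' z-transforms each of the five metrics across individuals and sums the
#' z-scores into the composite Exploration Index. Equal weighting of the five
#' components is by construction; the z-transform absorbs each metric's scale
#' and location, so the index is invariant to affine rescaling of any raw
#' metric (e.g. recording hours in minutes).
#'
#' @param profiles data.frame from [compute_metrics()] (>= 2 rows).
#' @param metric4 which operationalization of the fourth metric to use:
#'   `"rate"` (bouts per observation hour, the default and the operational
#'   definition used throughout) or `"hours"` (raw observation hours, kept as
#'   a sensitivity switch).
#' @param sd_type passed to [z_transform()].
#' @return `profiles` with five `z_*` columns and an `exploration_index`
#'   column appended. The indexes sum to zero across individuals.
#' @export
exploration_index <- function(profiles, metric4 = c("rate", "hours"),
                              sd_type = c("sample", "population")) {
  metric4 <- match.arg(metric4)
  sd_type <- match.arg(sd_type)
  if (nrow(profiles) < 2)
    explor_error("exploration_index requires at least two profiles",
                 "explor_domain_error")
  cols <- metric_columns(metric4)
  zmat <- vapply(cols, function(cl) z_transform(profiles[[cl]], sd_type),
                 numeric(nrow(profiles)))
  colnames(zmat) <- paste0("z_", cols)
  out <- cbind(profiles, as.data.frame(zmat))
  out$exploration_index <- rowSums(zmat)
  out
}

#' One-call metric profiles with Exploration Indexes
#'
#' @inheritParams compute_metrics
#' @inheritParams exploration_index
#' @return See [exploration_index()].
#' @export
exploration_profiles <- function(ds, metric4 = c("rate", "hours"),
                                 sd_type = c("sample", "population")) {
  exploration_index(compute_metrics(ds), match.arg(metric4),
                    match.arg(sd_type))
}
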