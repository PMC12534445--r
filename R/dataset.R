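#' Object-use ethogram categories
#'
#' The closed seven-category ethogram for immature chimpanzee object use:
#' tool use, doll play, aggression, object games, locomotion aid, physical
#' stimulation, and play nest. Unknown categories are rejected on ingest
#' rather than coerced.
#'
#' @format Character vector of length 7.
#' @export
OBJECT_CATEGORIES <- c("tool", "doll", "aggression", "game",
                       "locomotion_aid", "physical_stimulation", "play_nest")

BOUT_COLUMNS <- c("bout_id", "individual_id", "age_at_bout", "category",
                  "subcategory", "typicality", "atypical_mode")
INDIVIDUAL_COLUMNS <- c("individual_id", "sex", "parity", "maternal_id",
                        "observation_hours", "life_stage")

explor_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "explor_error")))
}

#' Construct a validated object-use dataset
#'
#' Bundles a bout-level table and an individual-level table into a single
#' validated dataset object, the common currency of all downstream analyses.
#'
#' @param bouts data.frame with columns `bout_id`, `individual_id`,
#'   `age_at_bout` (decimal years), `category` (one of [OBJECT_CATEGORIES]),
#'   `subcategory` (optional, `NA` when absent), `typicality`
#'   (`"typical"`/`"atypical"`) and `atypical_mode` (`"omission"` or
#'   `"commission"`, required exactly when the bout is atypical).
#' @param individuals data.frame with columns `individual_id`, `sex`
#'   (`"female"`/`"male"`), `parity` (`"primiparous"`/`"multiparous"`,
#'   the mother's parity), `maternal_id`, `observation_hours` (> 0) and
#'   `life_stage` (`"infant"`/`"juvenile"`).
#'
#' @return An object of class `explor_dataset`: a list with elements `bouts`
#'   and `individuals` (clean data.frames).
#'
#' @details Validation enforces: unique `bout_id` and `individual_id`;
#' referential integrity (every bout's individual exists); ages within
#' \[0, 20\]; positive observation hours; the closed category set; and the
#' typicality coding rule that `atypical_mode` is present iff the bout is
#' atypical. Violations raise classed conditions (`explor_schema_error`,
#' `explor_integrity_error`, `explor_coding_error`, `explor_domain_error`)
#' citing the offending rows.
#'
#' @seealso [read_dataset()], [write_dataset()], [table1_fixture()]
#' @export
explor_dataset <- function(bouts, individuals) {
  bouts <- validate_bouts(bouts)
  individuals <- validate_individuals(individuals)
  unknown <- !(bouts$individual_id %in% individuals$individual_id)
  if (any(unknown)) {
    explor_error(sprintf(
      "bout rows %s reference unknown individual_id(s): %s",
      paste(which(unknown), collapse = ", "),
      paste(unique(bouts$individual_id[unknown]), collapse = ", ")),
      "explor_integrity_error")
  }
  structure(list(bouts = bouts, individuals = individuals),
            class = "explor_dataset")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    explor_error(sprintf("%s table is missing column(s): %s", what,
                         paste(missing, collapse = ", ")),
                 "explor_schema_error")
  }
}

check_enum <- function(x, levels, field, rows_label, optional = FALSE) {
  x <- tolower(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    explor_error(sprintf("invalid %s at %s row(s) %s: %s (expected one of %s)",
                         field, rows_label, paste(which(bad), collapse = ", "),
                         paste(unique(x[bad]), collapse = ", "),
                         paste(levels, collapse = "/")),
                 "explor_schema_error")
  }
  if (!optional && anyNA(x)) {
    explor_error(sprintf("missing %s at %s row(s) %s", field, rows_label,
                         paste(which(is.na(x)), collapse = ", ")),
                 "explor_schema_error")
  }
  x
}

validate_bouts <- function(bouts) {
  stopifnot(is.data.frame(bouts))
  require_columns(bouts, BOUT_COLUMNS, "bouts")
  bouts <- bouts[, BOUT_COLUMNS, drop = FALSE]
  rownames(bouts) <- NULL
  bouts$bout_id <- trimws(as.character(bouts$bout_id))
  bouts$individual_id <- trimws(as.character(bouts$individual_id))
  if (anyDuplicated(bouts$bout_id)) {
    explor_error(sprintf("duplicated bout_id(s): %s",
                         paste(unique(bouts$bout_id[duplicated(bouts$bout_id)]),
                               collapse = ", ")),
                 "explor_integrity_error")
  }
  bouts$age_at_bout <- suppressWarnings(as.numeric(bouts$age_at_bout))
  bad_age <- is.na(bouts$age_at_bout) | bouts$age_at_bout < 0 |
    bouts$age_at_bout > 20
  if (nrow(bouts) && any(bad_age)) {
    explor_error(sprintf("age_at_bout outside [0, 20] or missing at bout row(s) %s",
                         paste(which(bad_age), collapse = ", ")),
                 "explor_domain_error")
  }
  bouts$category <- check_enum(bouts$category, OBJECT_CATEGORIES,
                               "category", "bout")
  sub <- trimws(as.character(bouts$subcategory))
  sub[sub == ""] <- NA_character_
  bouts$subcategory <- sub
  bouts$typicality <- check_enum(bouts$typicality, c("typical", "atypical"),
                                 "typicality", "bout")
  bouts$atypical_mode <- check_enum(bouts$atypical_mode,
                                    c("omission", "commission"),
                                    "atypical_mode", "bout", optional = TRUE)
  miscoded <- xor(bouts$typicality == "atypical", !is.na(bouts$atypical_mode))
  if (nrow(bouts) && any(miscoded)) {
    explor_error(sprintf(
      "atypical_mode must be present exactly when typicality is atypical; bout row(s) %s",
      paste(which(miscoded), collapse = ", ")), "explor_coding_error")
  }
  bouts
}

validate_individuals <- function(individuals) {
  stopifnot(is.data.frame(individuals))
  require_columns(individuals, INDIVIDUAL_COLUMNS, "individuals")
  individuals <- individuals[, INDIVIDUAL_COLUMNS, drop = FALSE]
  rownames(individuals) <- NULL
  individuals$individual_id <- trimws(as.character(individuals$individual_id))
  individuals$maternal_id <- trimws(as.character(individuals$maternal_id))
  if (anyDuplicated(individuals$individual_id)) {
    explor_error(sprintf(
      "duplicated individual_id(s): %s",
      paste(unique(individuals$individual_id[
        duplicated(individuals$individual_id)]), collapse = ", ")),
      "explor_integrity_error")
  }
  individuals$sex <- check_enum(individuals$sex, c("female", "male"),
                                "sex", "individual")
  individuals$parity <- check_enum(individuals$parity,
                                   c("primiparous", "multiparous"),
                                   "parity", "individual")
  individuals$life_stage <- check_enum(individuals$life_stage,
                                       c("infant", "juvenile"),
                                       "life_stage", "individual")
  individuals$observation_hours <-
    suppressWarnings(as.numeric(individuals$observation_hours))
  bad <- is.na(individuals$observation_hours) |
    individuals$observation_hours <= 0
  if (any(bad)) {
    explor_error(sprintf("observation_hours must be > 0; individual row(s) %s",
                         paste(which(bad), collapse = ", ")),
                 "explor_domain_error")
  }
  individuals
}

#' Read a dataset from bout and individual CSV files
#'
#' Files are comma-separated UTF-8 with a header row naming the schema
#' columns (see [explor_dataset()]). Enumerated fields are parsed
#' case-insensitively; empty cells in the optional `subcategory` and
#' `atypical_mode` columns become `NA`. The result is fully validated, and
#' error messages cite row numbers of the offending file.
#'
#' @param bouts_path,individuals_path paths to the two CSV files.
#' @return An `explor_dataset`.
#' @export
read_dataset <- function(bouts_path, individuals_path) {
  for (p in c(bouts_path, individuals_path)) {
    if (!file.exists(p)) explor_error(paste("file not found:", p),
                                      "explor_io_error")
  }
  bouts <- utils::read.csv(bouts_path, colClasses = "character",
                           na.strings = "", strip.white = TRUE)
  individuals <- utils::read.csv(individuals_path, colClasses = "character",
                                 na.strings = "", strip.white = TRUE)
  if (is.null(bouts$subcategory) && all(BOUT_COLUMNS[-5] %in% names(bouts)))
    bouts$subcategory <- NA_character_
  if (is.null(bouts$atypical_mode) && all(BOUT_COLUMNS[-7] %in% names(bouts)))
    bouts$atypical_mode <- NA_character_
  explor_dataset(bouts, individuals)
}

#' Write a dataset to bout and individual CSV files
#'
#' Writes the two tables in the same dialect [read_dataset()] expects, so
#' that `read_dataset(write_dataset(ds))` reproduces `ds` field-for-field.
#' Missing optional values are written as empty cells, never as a literal
#' `"NA"`.
#'
#' @param ds an `explor_dataset`.
#' @param bouts_path,individuals_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, bouts_path, individuals_path) {
  stopifnot(inherits(ds, "explor_dataset"))
  for (p in c(bouts_path, individuals_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) explor_error(paste("directory does not exist:", dir),
                                       "explor_io_error")
  }
  utils::write.csv(ds$bouts, bouts_path, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(ds$individuals, individuals_path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(c(bouts_path, individuals_path))
}

#' @export
print.explor_dataset <- function(x, ...) {
  cat(sprintf("<explor_dataset> %d bouts by %d individuals\n",
              nrow(x$bouts), nrow(x$individuals)))
  tab <- table(factor(x$bouts$category, levels = OBJECT_CATEGORIES))
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  cat(sprintf("  typicality: %d typical / %d atypical\n",
              sum(x$bouts$typicality == "typical"),
              sum(x$bouts$typicality == "atypical")))
  invisible(x)
}
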