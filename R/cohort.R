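#' Construct a cohort of repeated measurement triplets
#'
#' Long-format container for a validation cohort: one row per
#' participant x occasion x instrument x nutrient measurement, with
#' participant covariates repeated on each row.  All model fitting operates
#' on natural-log-scale values; the `log_transformed` flag records whether
#' the transform has been applied, and [fit_model()] refuses cohorts where
#' it has not.
#'
#' @param data A data frame with columns `participant_id`, `occasion`
#'   (integer `1..J`), `instrument` (`"webq"`, `"recall"`, `"biomarker"`),
#'   `nutrient`, `value`, `sex` (0 man / 1 woman), `age` (years), `bmi`.
#'   Missing measurements are rows with `NA` value (or simply absent rows).
#' @param log_transformed Logical; `TRUE` if `value` is already on the
#'   natural-log scale.
#' @return A `cohort_measurements` object (a data frame).
#' @export
cohort_measurements <- function(data, log_transformed = FALSE) {
  req <- c("participant_id", "occasion", "instrument", "nutrient", "value",
           "sex", "age", "bmi")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("cohort data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(data$instrument %in% c("webq", "recall", "biomarker")))
    stop("instrument must be one of 'webq', 'recall', 'biomarker'",
         call. = FALSE)
  occ <- data$occasion
  if (any(!is.finite(occ)) || any(occ < 1) || any(occ != round(occ)))
    stop("occasion must be integers >= 1", call. = FALSE)
  bad <- is.infinite(data$value) | is.nan(data$value)
  if (any(bad))
    stop("non-finite measurement values for participant(s) ",
         paste(utils::head(unique(data$participant_id[bad]), 3),
               collapse = ", "), call. = FALSE)
  if (!all(data$sex %in% c(0, 1, NA)))
    stop("sex must be coded 0 (man) / 1 (woman)", call. = FALSE)
  data$occasion <- as.integer(data$occasion)
  structure(as.data.frame(data),
            log_transformed = isTRUE(log_transformed),
            class = c("cohort_measurements", "data.frame"))
}

#' @export
print.cohort_measurements <- function(x, ...) {
  cat(sprintf(
    "Validation cohort: %d participants, %d occasions, nutrients: %s\n",
    length(unique(x$participant_id)), max(x$occasion),
    paste(unique(x$nutrient), collapse = ", ")))
  cat(sprintf("  %d measurement rows (%d missing); log scale: %s\n",
              nrow(x), sum(is.na(x$value)),
              attr(x, "log_transformed")))
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Expects the long format written by [write_cohort()]: tab-separated
#' columns `participant_id`, `occasion`, `instrument`, `nutrient`, `value`,
#' `sex`, `age`, `bmi`, with `#`-prefixed header comment lines permitted.
#'
#' @param path File path.
#' @param log_transform If `TRUE` (default), values are assumed to be in
#'   natural units and are log-transformed on load; nonpositive values then
#'   raise an error.  Use `FALSE` for files that already store log values.
#' @param sep Field separator.
#' @return A [cohort_measurements()] object with `log_transformed = TRUE`
#'   when `log_transform` was applied.
#' @export
read_cohort <- function(path, log_transform = TRUE, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (log_transform) {
    if (any(df$value <= 0, na.rm = TRUE))
      stop("cannot log-transform nonpositive values in ", path, call. = FALSE)
    df$value <- log(df$value)
  }
  cohort_measurements(df, log_transformed = log_transform)
}

#' Write a cohort (or any data frame) as delimited text
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param header Optional character vector of comment lines (each written
#'   with a leading `# `), used by the simulator to embed the seed and
#'   scenario hash.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, header = NULL, sep = "\t") {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stack a cohort nutrient into the wide observation matrix
#'
#' Internal workhorse: returns the `n x 3J` matrix of log measurements in
#' the order `(webq 1..J, recall 1..J, biomarker 1..J)` that
#' [implied_moments()] describes, with `NA` for missing cells, plus one row
#' of covariates per participant.
#'
#' @param cohort A [cohort_measurements()] object.
#' @param nutrient Which nutrient to extract (required when the cohort
#'   holds several).
#' @param design A [design_spec()].
#' @return A list with `y` (matrix, rownames = participant ids) and
#'   `covariates` (data frame: `participant_id`, `sex`, `age`, `bmi`).
#' @keywords internal
#' @export
cohort_wide <- function(cohort, nutrient = NULL, design = design_spec()) {
  stopifnot(inherits(cohort, "cohort_measurements"))
  nut <- unique(cohort$nutrient)
  if (is.null(nutrient)) {
    if (length(nut) > 1L)
      stop("cohort holds several nutrients (", paste(nut, collapse = ", "),
           "); specify one", call. = FALSE)
    nutrient <- nut
  }
  d <- cohort[cohort$nutrient == nutrient, , drop = FALSE]
  if (!nrow(d)) stop("no rows for nutrient '", nutrient, "'", call. = FALSE)
  J <- design$n_occasions
  if (max(d$occasion) > J)
    stop("cohort has occasions beyond the design's J = ", J, call. = FALSE)
  ids <- unique(d$participant_id)
  nm <- c(paste0("webq", seq_len(J)), paste0("recall", seq_len(J)),
          paste0("biomarker", seq_len(J)))
  y <- matrix(NA_real_, length(ids), 3L * J, dimnames = list(ids, nm))
  col <- match(d$instrument, c("webq", "recall", "biomarker"))
  y[cbind(match(d$participant_id, ids), (col - 1L) * J + d$occasion)] <- d$value
  cov_rows <- d[!duplicated(d$participant_id),
                c("participant_id", "sex", "age", "bmi")]
  cov_rows <- cov_rows[match(ids, cov_rows$participant_id), ]
  rownames(cov_rows) <- NULL
  list(y = y, covariates = cov_rows)
}
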