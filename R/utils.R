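#' Round half away from zero
#'
#' Reporting-boundary rounding. Unlike [base::round()], which rounds half to
#' even, ties are rounded away from zero (0.5 -> 1), the convention used for
#' the package's printed tables. Internal aggregation never rounds; this is
#' applied only when writing report tables.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.5)       # 3
#' round_half_up(1.845, 2)  # 1.85 (note: subject to binary representation)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored just below a representable
  # half (e.g. 1.85 read back as 1.84999...) still round as printed
  z <- abs(x) * p
  z <- z * (1 + .Machine$double.eps * 4)
  sign(x) * floor(z + 0.5) / p
}

# classed aborts so callers can catch specific failure modes ------------------

pc_abort <- function(message, class, ...) {
  abort(message, class = c(class, "pc_error"), ...)
}

pc_validation_error <- function(message, ...) {
  pc_abort(message, class = "pc_validation_error", ...)
}

pc_io_error <- function(message, ...) {
  pc_abort(message, class = "pc_io_error", ...)
}

pc_no_data_error <- function(message, ...) {
  pc_abort(message, class = "pc_no_data_error", ...)
}

pc_zero_need_error <- function(message, ...) {
  pc_abort(message, class = "pc_zero_need_error", ...)
}

pc_zero_burden_error <- function(message, ...) {
  pc_abort(message, class = "pc_zero_burden_error", ...)
}

pc_zero_requirement_error <- function(message, ...) {
  pc_abort(message, class = "pc_zero_requirement_error", ...)
}

stopifnot_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pc_validation_error(sprintf(
      "table '%s' is missing required column(s): %s",
      table, paste(missing, collapse = ", ")
    ))
  }
}

# income groups and care levels are closed enumerations -----------------------

#' @rdname pc_levels
#' @export
pc_income_groups <- function() {
  c("low", "lower-middle", "upper-middle", "high")
}

#' Closed enumerations used throughout the pipeline
#'
#' `pc_care_levels()` returns the five care levels at which palliative-care
#' encounters are modelled; `pc_staff_categories()` the ten staff categories
#' for which full-time equivalents are computed; `pc_income_groups()` the four
#' World Bank income groups used for stratified reporting.
#'
#' @return character vector of the enumeration values, in canonical order.
#' @name pc_levels
#' @rdname pc_levels
#' @export
pc_care_levels <- function() {
  c("referral_hospital", "provincial_hospital", "district_hospital",
    "community_health_center", "home")
}

#' @rdname pc_levels
#' @export
pc_staff_categories <- function() {
  c("doctor", "nurse", "social_worker", "spiritual_counsellor",
    "psychologist_or_psychiatrist", "physical_therapist", "pharmacist",
    "community_health_worker", "clinical_support", "nonclinical_support")
}
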