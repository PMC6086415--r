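# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# days as integers internally; accept Date or integer-like input
.as_day <- function(x) {
  if (inherits(x, "Date")) as.integer(x) else as.integer(x)
}

.restore_day <- function(x, template) {
  if (inherits(template, "Date")) as.Date(x, origin = "1970-01-01") else x
}

# age in completed years at `on` for someone born on `birth` (Dates)
.completed_years <- function(birth, on) {
  b <- as.POSIXlt(birth)
  o <- as.POSIXlt(on)
  age <- o$year - b$year
  before_birthday <- (o$mon < b$mon) | (o$mon == b$mon & o$mday < b$mday)
  age - as.integer(before_birthday)
}

.month_year <- function(d) format(d, "%Y-%m")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_columns <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("`%s` is missing required column(s): %s", name,
           paste(miss, collapse = ", "))
  invisible(df)
}

#' Study NSAID groups
#'
#' The six mutually exclusive NSAID exposure groups modelled throughout the
#' package: the five common drugs studied individually plus the pooled
#' \code{other_nsaid} group. Aspirin is handled separately everywhere.
#'
#' @return Character vector of the six group labels.
#' @export
nsaid_groups <- function() {
  c("celecoxib", "diclofenac", "ibuprofen", "naproxen", "rofecoxib",
    "other_nsaid")
}

.is_nsaid <- function(drug) drug %in% nsaid_groups()
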