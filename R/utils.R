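`%||%` <- function(x, y) if (is.null(x)) y else x

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_tiss <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "tiss_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_string <- function(x, what) {
  if (!is_string(x)) stop_tiss(sprintf("%s must be a single string", what), "tiss_type_error")
  x
}

# Canonical ISO-8601 timestamp: "YYYY-MM-DDTHH:MM:SS". Accepts a space
# separator and a missing seconds field; anything else is rejected.
canonical_datetime <- function(x) {
  assert_string(x, "timestamp")
  x <- sub(" ", "T", x, fixed = TRUE)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}$", x)) x <- paste0(x, ":00")
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", x)) {
    stop_tiss(sprintf("not an ISO-8601 timestamp: '%s'", x), "tiss_value_error")
  }
  x
}

canonical_date <- function(x) {
  assert_string(x, "date")
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    stop_tiss(sprintf("not an ISO-8601 date: '%s'", x), "tiss_value_error")
  }
  x
}

# Canonical decimal parse for monetary amounts: strips thousands separators
# ("1,200.00" == "1200.00") and rounds half-to-even at 2 decimals.
canonical_amount <- function(x) {
  if (is.character(x)) x <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_tiss("monetary amount must parse as a decimal number", "tiss_value_error")
  }
  round(as.numeric(x), 2)
}

format_amount <- function(x) sprintf("%.2f", x)

num_to_str <- function(x) sprintf("%.15g", x)

compact <- function(x) x[!vapply(x, is.null, logical(1))]
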