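new_dv <- function(kind, fields) {
  structure(c(list(dv_type = kind), fields),
            class = c(paste0("tiss_", tolower(kind)), "tiss_dv"))
}

#' Data value constructors
#'
#' Leaf values recorded in ELEMENT nodes form a closed variant set. Type names
#' used in archetype definitions (`DV_TEXT`, `DV_DATE_TIME`, ...) map 1:1 onto
#' these constructors. Timestamps and dates are validated ISO-8601 strings and
#' canonicalized at construction; monetary amounts accept thousands separators
#' and are rounded half-to-even at two decimals.
#'
#' @param value the scalar payload (text, timestamp, date, or count).
#' @param code,terminology_id,display coded-text fields.
#' @param magnitude,units quantity fields.
#' @param amount,currency money fields; `currency` is a 3-letter code.
#' @param id,issuer,type identifier fields.
#' @return an object of class `tiss_dv`.
#' @examples
#' dv_money("1,200.00")$amount == dv_money(1200)$amount
#' @export
dv_text <- function(value) new_dv("DV_TEXT", list(value = assert_string(value, "value")))

#' @rdname dv_text
#' @export
dv_coded_text <- function(code, terminology_id, display = code) {
  new_dv("DV_CODED_TEXT", list(
    code = assert_string(code, "code"),
    terminology_id = assert_string(terminology_id, "terminology_id"),
    display = assert_string(display, "display")
  ))
}

#' @rdname dv_text
#' @export
dv_date_time <- function(value) new_dv("DV_DATE_TIME", list(value = canonical_datetime(value)))

#' @rdname dv_text
#' @export
dv_date <- function(value) new_dv("DV_DATE", list(value = canonical_date(value)))

#' @rdname dv_text
#' @export
dv_count <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value != trunc(value)) {
    stop_tiss("count must be a non-negative integer", "tiss_value_error")
  }
  new_dv("DV_COUNT", list(value = as.numeric(value)))
}

#' @rdname dv_text
#' @export
dv_quantity <- function(magnitude, units) {
  if (!is.numeric(magnitude) || length(magnitude) != 1L || is.na(magnitude)) {
    stop_tiss("magnitude must be a number", "tiss_value_error")
  }
  new_dv("DV_QUANTITY", list(magnitude = as.numeric(magnitude),
                             units = assert_string(units, "units")))
}

#' @rdname dv_text
#' @export
dv_money <- function(amount, currency = "BRL") {
  if (!is_string(currency) || !grepl("^[A-Z]{3}$", currency)) {
    stop_tiss("currency must be a 3-letter uppercase code", "tiss_value_error")
  }
  new_dv("DV_MONEY", list(amount = canonical_amount(amount), currency = currency))
}

#' @rdname dv_text
#' @export
dv_identifier <- function(id, issuer, type = "") {
  new_dv("DV_IDENTIFIER", list(
    id = assert_string(id, "id"),
    issuer = assert_string(issuer, "issuer"),
    type = if (is.null(type)) "" else assert_string(type, "type")
  ))
}

is_dv <- function(x) inherits(x, "tiss_dv")

dv_kind <- function(x) x$dv_type

#' @export
format.tiss_dv <- function(x, ...) {
  switch(x$dv_type,
    DV_TEXT = x$value,
    DV_CODED_TEXT = sprintf("%s::%s (%s)", x$terminology_id, x$code, x$display),
    DV_DATE_TIME = x$value,
    DV_DATE = x$value,
    DV_COUNT = num_to_str(x$value),
    DV_QUANTITY = paste(num_to_str(x$magnitude), x$units),
    DV_MONEY = paste(format_amount(x$amount), x$currency),
    DV_IDENTIFIER = sprintf("%s@%s", x$id, x$issuer)
  )
}

#' @export
print.tiss_dv <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$dv_type, format(x)))
  invisible(x)
}
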