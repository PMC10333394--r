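#' Parse a clock time to minutes since midnight
#'
#' @param x character vector of times in \code{"HH:MM"} form. Hours beyond 23
#'   are allowed so that times past midnight (e.g. a late PACU exit) can be
#'   represented as \code{"24:10"}.
#' @return numeric vector of minutes since midnight.
#' @examples
#' parse_hm("07:30")  # 450
#' @export
parse_hm <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed clock time(s): ", paste(x[bad], collapse = ", "))
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

#' Format minutes since midnight as "HH:MM"
#'
#' Minutes are rounded to the nearest whole minute. Hours are not wrapped at
#' 24, so a PACU exit after midnight prints as e.g. \code{"24:10"}.
#'
#' @param m numeric vector of minutes since midnight.
#' @return character vector.
#' @export
format_hm <- function(m) {
  m <- round(m)
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
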