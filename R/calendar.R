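#' Calendar conventions
#'
#' All series in the package are monthly with 0-based indices; month 0 is
#' January 2018. For queue timesteps a month is treated as exactly 4 weeks
#' (a 48-week year), so monthly capacity divides evenly into two 2-week
#' steps or four 1-week steps. Conversions between weeks and months use the
#' same convention throughout.
#'
#' @param label an ISO "YYYY-MM" string (or "YYYY", taken as January).
#' @return `month_index()` returns the 0-based month index; `month_label()`
#'   the ISO label of an index.
#' @examples
#' month_index("2020-01") # 24
#' month_label(48)        # "2022-01"
#' @export
month_index <- function(label) {
  if (is.numeric(label)) return(as.integer(label))
  parts <- strsplit(as.character(label), "-", fixed = TRUE)
  vapply(parts, function(p) {
    y <- as.integer(p[[1L]])
    m <- if (length(p) >= 2L) as.integer(p[[2L]]) else 1L
    if (is.na(y) || is.na(m) || m < 1L || m > 12L)
      stop("malformed month label", call. = FALSE)
    (y - 2018L) * 12L + (m - 1L)
  }, integer(1))
}

#' @rdname month_index
#' @param index 0-based month index.
#' @export
month_label <- function(index) {
  index <- as.integer(index)
  sprintf("%04d-%02d", 2018L + index %/% 12L, index %% 12L + 1L)
}

# year (e.g. 2020) of a 0-based month index
month_year <- function(index) 2018L + as.integer(index) %/% 12L

# weeks in one model month (4-week-month convention)
WEEKS_PER_MONTH <- 4L
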