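# Time-interval bin schemes. Two schemes are used in the study: paired
# analysis bins the collection-time difference Dt = t2 - t1, unpaired
# analysis bins each individual sample's time since death (tx_ToD) into 10
# groups. Bins are half-open [lo, hi): a boundary value belongs to the
# upper bin (12.0 h falls in "12-24 h").

#' Construct a time-interval bin scheme
#'
#' @param name `"paired_dt"` (9 bins over the t2 - t1 interval: 0-12, 12-24,
#'   24-36, 36-48, 48-72, 72-96, 96-120, 120-144, >144 h) or
#'   `"unpaired_tod"` (10 groups over time since death: 0-6 (group 1),
#'   6-12 (group 2), 12-24, 24-36, 36-48, 48-72, 72-96, 96-120, 120-144,
#'   >144 h (group 10)).
#' @return Object of class `pm_bin_scheme` with `name`, `edges` (strictly
#'   increasing, last edge `Inf`), `labels` and `group` numbers.
#' @export
#' @examples
#' bin_scheme("unpaired_tod")$labels
bin_scheme <- function(name = c("paired_dt", "unpaired_tod")) {
  name <- match.arg(name)
  edges <- switch(name,
    paired_dt = c(0, 12, 24, 36, 48, 72, 96, 120, 144, Inf),
    unpaired_tod = c(0, 6, 12, 24, 36, 48, 72, 96, 120, 144, Inf)
  )
  k <- length(edges) - 1L
  labels <- character(k)
  for (i in seq_len(k)) {
    labels[i] <- if (is.infinite(edges[i + 1L])) {
      paste0(">", edges[i], " h")
    } else {
      paste0(edges[i], "-", edges[i + 1L], " h")
    }
  }
  structure(
    list(name = name, edges = edges, labels = labels, group = seq_len(k)),
    class = "pm_bin_scheme"
  )
}

#' Assign hour values to scheme bins
#'
#' Half-open binning `[lo, hi)`: a value equal to a shared edge goes to the
#' upper bin (6.0 h is group 2 of the unpaired scheme), and the last bin is
#' open-ended.
#'
#' @param value_h Numeric vector of non-negative hours.
#' @param scheme A [bin_scheme()].
#' @return Factor of bin labels with levels in scheme order.
#' @export
#' @examples
#' assign_bin(c(5.9, 6, 500), bin_scheme("unpaired_tod"))
assign_bin <- function(value_h, scheme) {
  stopifnot(inherits(scheme, "pm_bin_scheme"))
  if (any(value_h < 0, na.rm = TRUE)) {
    stop("hour values must be non-negative", call. = FALSE)
  }
  idx <- findInterval(value_h, scheme$edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  factor(scheme$labels[idx], levels = scheme$labels)
}
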