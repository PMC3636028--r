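#' Population code
#'
#' Partition of input channels into groups, one group per abstract
#' multinomial variable, with exactly one channel per (group, value) pair.
#' The active channel of a group fires while its value is presented; a
#' silent group encodes a missing value.
#'
#' @param n_values Integer vector; `n_values[j]` is the number of values of
#'   variable `j`. Channels are laid out group by group, value by value, so
#'   channel of `(j, v)` is `sum(n_values[seq_len(j - 1)]) + v`.
#' @return An object of class `population_code` with fields:
#'   \describe{
#'     \item{n_groups}{number of variables `m`}
#'     \item{n_values}{values per group}
#'     \item{n_channels}{total channel count}
#'     \item{group_of}{group index per channel}
#'     \item{value_of}{value index per channel}
#'     \item{first_channel}{channel offset per group}
#'   }
#' @examples
#' code <- population_code(c(2, 3))
#' code$group_of
#' channel_for(code, 2, 3)
#' @export
population_code <- function(n_values) {
  n_values <- as.integer(n_values)
  stopifnot(length(n_values) >= 1L, all(n_values >= 1L))
  m <- length(n_values)
  first <- cumsum(c(0L, n_values[-m])) + 1L
  structure(
    list(
      n_groups = m,
      n_values = n_values,
      n_channels = sum(n_values),
      group_of = rep(seq_len(m), n_values),
      value_of = unlist(lapply(n_values, seq_len)),
      first_channel = first
    ),
    class = "population_code"
  )
}

#' Binary on/off pixel code
#'
#' Two channels per pixel (value 1 = "on", value 2 = "off"), the encoding
#' used for image inputs.
#'
#' @param n_pixels Number of pixels.
#' @return A [population_code()] with `n_pixels` binary groups.
#' @export
binary_code <- function(n_pixels) population_code(rep(2L, n_pixels))

#' @export
print.population_code <- function(x, ...) {
  cat(sprintf("<population_code> %d groups, %d channels (values per group: %s)\n",
              x$n_groups, x$n_channels,
              if (length(unique(x$n_values)) == 1L) as.character(x$n_values[1L])
              else paste(range(x$n_values), collapse = "-")))
  invisible(x)
}

#' Channel index of a (group, value) pair
#'
#' @param code A [population_code()].
#' @param group Group index (vectorized).
#' @param value Value index within the group (vectorized).
#' @return Integer channel indices.
#' @export
channel_for <- function(code, group, value) {
  stopifnot(all(group >= 1L), all(group <= code$n_groups))
  if (any(value < 1L | value > code$n_values[group])) {
    stop("value out of range for its group")
  }
  code$first_channel[group] + as.integer(value) - 1L
}

#' Channels belonging to one group
#'
#' @inheritParams channel_for
#' @return Integer vector of channel indices.
#' @export
group_channels <- function(code, group) {
  stopifnot(group >= 1L, group <= code$n_groups)
  seq.int(code$first_channel[group],
          length.out = code$n_values[group])
}

#' Evidence vectors
#'
#' An evidence vector assigns to each group either a value index or `NA`
#' (missing). Represented as a plain integer vector of length `n_groups`
#' with `NA` for missing groups; this helper only validates.
#'
#' @param values Integer vector (with `NA`s allowed) of length
#'   `code$n_groups`.
#' @param code A [population_code()].
#' @return The validated integer vector.
#' @export
evidence_vector <- function(values, code) {
  values <- as.integer(values)
  stopifnot(length(values) == code$n_groups)
  obs <- !is.na(values)
  if (any(values[obs] < 1L | values[obs] > code$n_values[obs])) {
    stop("evidence value out of range for its group")
  }
  values
}
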