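# Configurations and state indexing.
#
# A configuration assigns one value per node, either in spin form (-1/+1,
# used by MR and IMR) or Boolean form (0/1, used by NMR and INMR). The two
# forms are linked by the componentwise bijection 0 <-> -1, 1 <-> +1.
#
# Indexing convention (fixed, documented, stable): node 1 is the most
# significant bit, a high value (spin +1 / Boolean 1) maps to bit 1, and the
# index is the big-endian integer of the bit string, from 0 to 2^n - 1.
# The all-low configuration therefore has index 0.

#' Convert a configuration between spin and Boolean representations
#'
#' Componentwise bijection: Boolean 0 maps to spin -1 and Boolean 1 to spin
#' +1 (and back). Applying the conversion twice is the identity.
#'
#' @param values Integer vector in spin (-1/+1) or Boolean (0/1) form.
#' @param to Target representation, `"spin"` or `"boolean"`.
#' @return The converted vector.
#' @examples
#' convert_representation(c(0, 1, 0), "spin")
#' @export
convert_representation <- function(values, to = c("spin", "boolean")) {
  to <- match.arg(to)
  stopifnot(all(values %in% c(-1L, 0L, 1L)))
  if (to == "spin") ifelse(values > 0, 1L, -1L) else ifelse(values > 0, 1L, 0L)
}

config_bits <- function(values) as.integer(values > 0)

bits_to_values <- function(bits, representation) {
  if (representation == "spin") ifelse(bits > 0, 1L, -1L) else as.integer(bits)
}

#' Map a configuration to its state index (and back)
#'
#' Node 1 is the most significant position, a high value is bit 1, and the
#' index is the big-endian value of the bit string (0-based). The functions
#' are inverse bijections between configurations and `0:(2^n - 1)`.
#'
#' @param values Configuration vector (spin or Boolean).
#' @param index 0-based state index.
#' @param n Number of nodes.
#' @param representation `"spin"` or `"boolean"` for the reconstructed vector.
#' @return `state_to_index()`: an integer index; `index_to_state()`: a
#'   configuration vector.
#' @examples
#' state_to_index(c(1, -1))       # spin (+,-) -> 2
#' index_to_state(2, 2, "spin")
#' @export
state_to_index <- function(values) {
  n <- length(values)
  bits <- config_bits(values)
  sum(bits * 2^(n - seq_len(n)))
}

#' @rdname state_to_index
#' @export
index_to_state <- function(index, n, representation = c("spin", "boolean")) {
  representation <- match.arg(representation)
  stopifnot(index >= 0, index < 2^n)
  bits <- as.integer(bitwAnd(index %/% 2^((n - 1):0), 1))
  bits_to_values(bits, representation)
}

#' Parse and format configuration strings
#'
#' Configurations travel on the command line as strings over `{0,1}` or
#' `{+,-}` in node order; both are accepted for either representation.
#'
#' @param x A string such as `"0101"` or `"+-+-"`.
#' @param representation Output representation.
#' @return `parse_configuration()`: an integer vector;
#'   `format_configuration()`: a string.
#' @export
parse_configuration <- function(x, representation = c("spin", "boolean")) {
  representation <- match.arg(representation)
  chars <- strsplit(trimws(x), "")[[1]]
  bits <- ifelse(chars %in% c("1", "+"), 1L,
                 ifelse(chars %in% c("0", "-"), 0L, NA_integer_))
  if (anyNA(bits)) stop("configuration characters must be 0/1 or +/-", call. = FALSE)
  bits_to_values(bits, representation)
}

#' @rdname parse_configuration
#' @param values Configuration vector.
#' @export
format_configuration <- function(values, representation = NULL) {
  if (is.null(representation)) {
    representation <- if (any(values < 0)) "spin" else "boolean"
  }
  bits <- config_bits(values)
  if (representation == "spin") {
    paste(ifelse(bits > 0, "+", "-"), collapse = "")
  } else {
    paste(bits, collapse = "")
  }
}
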