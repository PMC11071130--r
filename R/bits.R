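#' Pack and unpack bit strings
#'
#' Bit streams are represented in R as character scalars over `"0"`/`"1"`.
#' On disk they are packed most-significant-bit first within each byte and
#' zero-padded to a byte boundary, so the bit count must be carried alongside
#' the bytes to invert the packing.
#'
#' @param bits Character scalar of `"0"`/`"1"` characters.
#' @param bytes Raw vector as produced by `pack_bits()`.
#' @param n_bits Number of leading bits of `bytes` that are payload.
#' @return `pack_bits()` a raw vector; `unpack_bits()` a bit string.
#' @examples
#' pack_bits("10000001")
#' unpack_bits(as.raw(c(0x81)), 8)
#' @export
pack_bits <- function(bits) {
  stopifnot(is.character(bits), length(bits) == 1L)
  cpp_pack_bits(bits)
}

#' @rdname pack_bits
#' @export
unpack_bits <- function(bytes, n_bits) {
  stopifnot(is.raw(bytes), length(n_bits) == 1L, n_bits >= 0)
  cpp_unpack_bits(bytes, as.double(n_bits))
}

# number of bits used in the final byte of a packed stream (0 for empty)
bit_tail <- function(n_bits) {
  if (n_bits == 0) return(0L)
  r <- n_bits %% 8L
  if (r == 0L) 8L else as.integer(r)
}
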