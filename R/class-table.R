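#' Color-class frequencies
#'
#' Counts how many k-mers carry each distinct color class. Classes are
#' returned in increasing numerical order, reading each bit string as a
#' C-bit integer with color 0 as the most significant bit.
#'
#' @param x A `color_matrix` or a character vector of class bit strings
#'   (one per k-mer).
#' @return Named integer vector: names are class bit strings (ascending),
#'   values their k-mer counts.
#' @export
class_frequencies <- function(x) {
  classes <- if (inherits(x, "color_matrix")) x$classes else x
  stopifnot(is.character(classes), length(classes) >= 1L)
  tab <- table(classes)
  out <- setNames(as.integer(tab), names(tab))
  out[order(names(out), method = "radix")]
}

#' Assign Huffman global IDs to color classes
#'
#' Builds a deterministic canonical Huffman code over the class frequencies:
#' more frequent classes receive shorter codewords, frequency ties are
#' broken toward the smaller numeric class value, and codewords are assigned
#' canonically (shorter codes first, then by class value). The same codes
#' are regenerated bit-for-bit from the (classes, frequencies) pair alone,
#' which is what decompression relies on. A single class (M = 1) receives
#' the empty codeword.
#'
#' @param freqs Named integer vector from [class_frequencies()].
#' @return Object of class `global_class_table`: list with `classes`
#'   (ascending), `freqs` and `codes` (aligned character vector, also named
#'   by class).
#' @export
assign_global_ids <- function(freqs) {
  stopifnot(is.numeric(freqs), !is.null(names(freqs)), length(freqs) >= 1L)
  ord <- order(names(freqs), method = "radix")
  classes <- names(freqs)[ord]
  f <- as.numeric(freqs)[ord]
  lens <- cpp_huffman_lengths(f)
  codes <- cpp_canonical_codes(lens)
  structure(
    list(classes = classes, freqs = as.integer(f),
         codes = setNames(as.character(codes), classes)),
    class = "global_class_table"
  )
}

#' @export
print.global_class_table <- function(x, ...) {
  cat("global class table: M =", length(x$classes), "classes,",
      "code lengths", min(nchar(x$codes)), "-", max(nchar(x$codes)), "bits\n")
  invisible(x)
}

#' Serialize / deserialize the global class table
#'
#' On disk the table is three pieces: a color encoding `delta` (the first
#' class verbatim in C bits, every later class as the ascending list of
#' color indices where it differs from its predecessor, each index in
#' ceiling(log2 C) bits, floored at 1 bit), a `boundary` bitvector of the
#' same length with a 1 wherever a class's encoding begins, and the
#' frequency list in sorted-class order. Those three suffice to reconstruct
#' the classes and regenerate identical Huffman codes.
#'
#' @param tab A `global_class_table`.
#' @param C Number of colors.
#' @return `serialize_global_table()`: object of class
#'   `global_table_serialization` with `delta`, `boundary` and `freq_list`.
#'   `deserialize_global_table()`: the reconstructed `global_class_table`.
#' @examples
#' tab <- assign_global_ids(c("010" = 2, "011" = 2, "111" = 3))
#' serialize_global_table(tab, 3)
#' @export
serialize_global_table <- function(tab, C) {
  stopifnot(inherits(tab, "global_class_table"))
  ser <- cpp_serialize_classes(tab$classes, as.integer(C))
  structure(
    list(delta = ser$delta, boundary = ser$boundary,
         freq_list = tab$freqs),
    class = "global_table_serialization"
  )
}

#' @rdname serialize_global_table
#' @param ser A `global_table_serialization`.
#' @export
deserialize_global_table <- function(ser, C) {
  stopifnot(inherits(ser, "global_table_serialization") || is.list(ser))
  classes <- cpp_deserialize_classes(ser$delta, ser$boundary, as.integer(C))
  if (length(ser$freq_list) != length(classes))
    stop("frequency list has ", length(ser$freq_list),
         " entries but ", length(classes), " classes were reconstructed",
         call. = FALSE)
  assign_global_ids(setNames(as.integer(ser$freq_list), classes))
}
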