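#' Rank index over a string set
#'
#' Maps each k-mer of the underlying set to its 0-based rank: the number of
#' k-mer windows strictly before its window, counting across simplitigs in
#' order. Lookups canonicalize nothing; use [rank_of()] which canonicalizes
#' the query and errors on absent k-mers.
#'
#' @param s An `spss` object.
#' @return Named integer vector: names are canonical k-mers, values ranks.
#' @export
build_rank_index <- function(s) {
  stopifnot(inherits(s, "spss"))
  win <- cpp_spss_kmers(s$simplitigs, s$k)$kmers
  if (anyDuplicated(win))
    stop("string set repeats a k-mer; rank index would not be bijective",
         call. = FALSE)
  setNames(seq_along(win) - 1L, win)
}

#' @rdname build_rank_index
#' @param index A rank index from `build_rank_index()`.
#' @param kmer A single k-mer (either orientation).
#' @export
rank_of <- function(index, kmer) {
  key <- canonicalize(kmer)
  r <- index[key]
  if (is.na(r)) stop("k-mer ", key, " is absent from the string set",
                     call. = FALSE)
  unname(r)
}

#' Color matrix in string-set order
#'
#' Emits one color vector per union k-mer, ordered by the k-mer's rank in
#' the string set. Color 0 is the leftmost character of each bit string and
#' the most significant bit when a vector is read as a C-bit integer; that
#' convention fixes the "increasing numerical order" sort of the class
#' table. Errors name the first k-mer on which `s` and the graph disagree.
#'
#' @param s An `spss` object covering exactly the union k-mers of `x`.
#' @param x A [cdbg] object, or a named character mapping from
#'   [union_with_classes()].
#' @return Object of class `color_matrix`: list with `kmers` and `classes`
#'   (parallel, rank order), `C`, `k`, `n_windows` (per simplitig) and
#'   `class_seqs` (per-simplitig class sequences, used by the codec).
#' @export
build_color_matrix <- function(s, x) {
  stopifnot(inherits(s, "spss"))
  mapping <- if (inherits(x, "cdbg")) union_with_classes(x) else x
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  cs <- cpp_class_sequences(s$simplitigs, s$k, names(mapping),
                            unname(mapping))
  win <- cpp_spss_kmers(s$simplitigs, s$k)
  structure(
    list(kmers = win$kmers,
         classes = unlist(cs, use.names = FALSE),
         C = nchar(mapping[[1L]]), k = s$k,
         n_windows = win$n_windows, class_seqs = cs),
    class = "color_matrix"
  )
}

#' @export
print.color_matrix <- function(x, ...) {
  cat("color matrix:", length(x$kmers), "k-mers x", x$C, "colors,",
      length(unique(x$classes)), "distinct classes\n")
  invisible(x)
}

#' Write a color matrix as tab-separated text
#'
#' One line per union k-mer in rank order: the k-mer, a tab, and its C-bit
#' color vector.
#'
#' @param m A `color_matrix`.
#' @param path Output path.
#' @export
write_color_matrix <- function(m, path) {
  stopifnot(inherits(m, "color_matrix"))
  writeLines(paste0(m$kmers, "\t", m$classes), path)
  invisible(path)
}
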