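#' Spectrum-preserving string set (simplitigs)
#'
#' An SPSS of a k-mer set is an ordered list of strings (simplitigs), each at
#' least `k` long, whose length-`k` windows canonicalize to every k-mer of
#' the set exactly once and to nothing else. The record order and window
#' offsets induce the global k-mer order used by the color matrix.
#'
#' @param simplitigs Character vector of DNA strings, each of length >= k.
#' @param k K-mer length.
#' @return An object of class `spss` with fields `simplitigs` and `k`.
#' @export
new_spss <- function(simplitigs, k) {
  simplitigs <- toupper(as.character(simplitigs))
  if (length(simplitigs) && any(nchar(simplitigs) < k))
    stop("every simplitig must be at least k characters long", call. = FALSE)
  structure(list(simplitigs = simplitigs, k = as.integer(k)), class = "spss")
}

#' @export
print.spss <- function(x, ...) {
  nw <- sum(nchar(x$simplitigs) - x$k + 1L)
  cat("spectrum-preserving string set: ", length(x$simplitigs),
      " simplitigs, ", nw, " k-mers (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Build simplitigs greedily
#'
#' Deterministic greedy construction: the lexicographically smallest unused
#' k-mer seeds a simplitig, which is extended base by base to the right and
#' then to the left; candidate bases are tried in `A`,`C`,`G`,`T` order and
#' an extension is admissible iff the new window's canonical form is still
#' unused. K-mers may therefore appear in either orientation inside a
#' simplitig; membership is always tested on the canonical form. The codec
#' downstream is correct for any valid SPSS; this builder merely fixes a
#' reproducible one.
#'
#' @param kmers Character vector of distinct canonical k-mers.
#' @param k K-mer length.
#' @return An [new_spss()] object; empty input gives an empty SPSS.
#' @examples
#' build_simplitigs(c("TCAAA", "CAAAA", "AAAAT"), 5)
#' @export
build_simplitigs <- function(kmers, k) {
  if (length(kmers) == 0L) return(new_spss(character(0), k))
  new_spss(cpp_build_simplitigs(kmers, as.integer(k)), k)
}

#' Validate a string set against a k-mer set
#'
#' Enumerates every window of every simplitig, canonicalizes it, and checks
#' the multiset against `kmers`: each k-mer must appear exactly once and no
#' foreign k-mer may appear.
#'
#' @param s An `spss` object.
#' @param kmers Character vector of canonical k-mers the set must cover.
#' @return A list with `pass` (logical) and the offending k-mers in
#'   `missing`, `duplicated` and `foreign`.
#' @export
validate_spss <- function(s, kmers) {
  stopifnot(inherits(s, "spss"))
  win <- if (length(s$simplitigs))
    cpp_spss_kmers(s$simplitigs, s$k)$kmers else character(0)
  dup <- unique(win[duplicated(win)])
  foreign <- setdiff(unique(win), kmers)
  missing <- setdiff(kmers, win)
  res <- list(pass = length(dup) == 0L && length(foreign) == 0L &&
                length(missing) == 0L,
              n_kmers = length(win),
              missing = missing, duplicated = dup, foreign = foreign)
  class(res) <- "spss_validation"
  res
}

#' @export
print.spss_validation <- function(x, ...) {
  cat(if (x$pass) "valid" else "INVALID",
      "string set over", x$n_kmers, "k-mer windows\n")
  if (length(x$missing))
    cat("  missing:", paste(head(x$missing, 5L), collapse = " "), "\n")
  if (length(x$duplicated))
    cat("  duplicated:", paste(head(x$duplicated, 5L), collapse = " "), "\n")
  if (length(x$foreign))
    cat("  foreign:", paste(head(x$foreign, 5L), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a string set as FASTA
#'
#' Records are named `simplitig_<index>` with 0-based indices; record order
#' is the simplitig order, so a read-back reproduces the same object.
#'
#' @param s An `spss` object.
#' @param path Output (or input) FASTA path.
#' @param k K-mer length expected on read.
#' @return `write_spss()` the path, invisibly; `read_spss()` an `spss`.
#' @export
write_spss <- function(s, path) {
  stopifnot(inherits(s, "spss"))
  x <- Biostrings::DNAStringSet(s$simplitigs)
  names(x) <- paste0("simplitig_", seq_along(s$simplitigs) - 1L)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_spss
#' @export
read_spss <- function(path, k) {
  seqs <- as.character(Biostrings::readDNAStringSet(path))
  if (length(seqs) && any(nchar(seqs) < k))
    stop("FASTA record shorter than k = ", k, " in ", path, call. = FALSE)
  new_spss(unname(seqs), k)
}
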