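#' Canonicalize k-mers
#'
#' A k-mer is canonical when it is the lexicographically smaller of itself
#' and its reverse complement; the canonical form represents both
#' orientations of a sequence. Lowercase input is uppercased first; any
#' character outside `A`,`C`,`G`,`T` is an error reporting its position.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length with each element canonical.
#' @examples
#' canonicalize(c("TCAAA", "TTTTT", "ACGT"))
#' @export
canonicalize <- function(x) {
  stopifnot(is.character(x))
  cpp_canonicalize(x)
}

#' Extract canonical k-mers from a sequence
#'
#' Slides a length-`k` window over `seq` and canonicalizes every window whose
#' characters are all `A`,`C`,`G`,`T`; windows touching any other character
#' (for example `N` in an assembly) contribute nothing. Multiplicities are
#' preserved and windows are returned in order of occurrence. A sequence
#' shorter than `k` yields an empty vector.
#'
#' @param seq A single DNA string.
#' @param k Window length, at least 2.
#' @return Character vector of canonical k-mers, one per valid window.
#' @examples
#' extract_kmers("TCAAAAT", 5)
#' @export
extract_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_extract_kmers(seq, as.integer(k))
}

# read sequences from a FASTA (or FASTQ) file as plain character strings;
# gzip-compressed files are handled by Biostrings transparently
read_sequences <- function(path) {
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("failed to parse ", fmt, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  as.character(seqs)
}

# one canonical k-mer per line; validated against k and deduplicated
read_kmer_list <- function(path, k) {
  lines <- readLines(path, warn = FALSE)
  lines <- toupper(trimws(lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) && any(nchar(lines) != k))
    stop("k-mer list '", path, "' contains entries of length != ", k,
         call. = FALSE)
  sort(unique(canonicalize(lines)), method = "radix")
}

#' Count canonical k-mers of one color
#'
#' Accumulates canonical k-mer counts over all listed FASTA files (a file
#' listed twice is counted twice) and keeps the k-mers whose total count is
#' at least `a`, the abundance threshold. This in-process counter stands in
#' for an external k-mer counter at desk scale.
#'
#' @param paths Character vector of FASTA file paths.
#' @param k K-mer length.
#' @param a Abundance threshold, at least 1.
#' @return Sorted character vector of canonical k-mers with count `>= a`.
#' @export
count_color <- function(paths, k, a = 1L) {
  stopifnot(length(paths) >= 1L)
  seqs <- unlist(lapply(paths, read_sequences), use.names = FALSE)
  cpp_count_kmers(seqs, as.integer(k), as.integer(a))
}

#' Construct a colored de Bruijn graph from in-memory k-mer sets
#'
#' @param colors List of character vectors, one per color, each a set of
#'   k-mers (canonicalized and deduplicated here).
#' @param k K-mer length shared by all sets.
#' @param abundance Abundance threshold the sets were built with (recorded,
#'   not re-applied).
#' @return An object of class `cdbg` with fields `k`, `C`, `abundance` and
#'   `colors` (list of sorted canonical k-mer vectors).
#' @examples
#' g <- cdbg(list(c("TCAAA", "CAAAA"), c("TCAAA")), k = 5)
#' g$C
#' @export
cdbg <- function(colors, k, abundance = 1L) {
  stopifnot(is.list(colors), length(colors) >= 1L, k >= 2)
  colors <- lapply(colors, function(s) {
    s <- as.character(s)
    if (length(s) && any(nchar(s) != k))
      stop("all k-mers must have length k = ", k, call. = FALSE)
    sort(unique(canonicalize(s)), method = "radix")
  })
  structure(
    list(k = as.integer(k), C = length(colors),
         abundance = as.integer(abundance), colors = colors),
    class = "cdbg"
  )
}

#' @export
print.cdbg <- function(x, ...) {
  cat("colored de Bruijn graph: C =", x$C, "colors, k =", x$k,
      ", abundance >=", x$abundance, "\n")
  cat("  per-color k-mer counts:",
      paste(vapply(x$colors, length, 0L), collapse = " "), "\n")
  invisible(x)
}

#' Load a colored de Bruijn graph from a manifest
#'
#' The manifest is a plain-text file with one color per line; each line lists
#' whitespace-separated input files and the 0-based line number is the color
#' index. Entries ending in `.kmers` are plain-text k-mer lists (one k-mer
#' per line, auto-canonicalized, abundance threshold not applied); all other
#' entries are FASTA (optionally gzip-compressed) counted through
#' [count_color()].
#'
#' @param manifest Path to the manifest file.
#' @param k K-mer length.
#' @param a Abundance threshold applied to FASTA-derived counts.
#' @return A [cdbg] object with `C` equal to the number of manifest lines.
#' @export
load_cdbg <- function(manifest, k, a = 1L) {
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  lines <- readLines(manifest, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("manifest lists no colors: ", manifest, call. = FALSE)
  base <- dirname(manifest)
  colors <- lapply(lines, function(line) {
    files <- strsplit(trimws(line), "\\s+")[[1]]
    # paths are taken relative to the manifest unless absolute
    files <- ifelse(file.exists(files), files, file.path(base, files))
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("manifest entry not found: ", missing[1L], call. = FALSE)
    is_list <- grepl("\\.kmers$", files, ignore.case = TRUE)
    km <- character(0)
    if (any(!is_list))
      km <- count_color(files[!is_list], k, a)
    if (any(is_list))
      km <- union(km, unlist(lapply(files[is_list], read_kmer_list, k = k)))
    km
  })
  cdbg(colors, k = k, abundance = a)
}

# union + per-k-mer membership bits over a list of sorted k-mer vectors
union_classes_from_sets <- function(sets) {
  u <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  cols <- lapply(sets, function(s) ifelse(u %in% s, "1", "0"))
  setNames(do.call(paste0, cols), u)
}

#' Union k-mer set with color classes
#'
#' Computes the union of all per-color k-mer sets and, for each union k-mer,
#' its color vector: a `C`-bit string whose i-th character (color 0 leftmost)
#' is `1` iff the k-mer belongs to color i. The color vector doubles as the
#' k-mer's color-class identity.
#'
#' @param x A [cdbg] object.
#' @return Named character vector: names are the union k-mers (ascending),
#'   values their color-vector bit strings.
#' @export
union_with_classes <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  union_classes_from_sets(x$colors)
}
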