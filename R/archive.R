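# On-disk container, format version 1.
#
#   magic "CDBGZIP1" | int32 LE: version, k, C, M, run_divisor,
#   n_simplitigs, n_kmers | 7 directory entries | payloads concatenated.
#
# Directory entry: name (8 bytes, space-padded) | codec int32 (0 raw,
# 1 DEFLATE) | raw_bytes int32 | tail_bits int32 (bits used in the final raw
# byte; with raw_bytes this recovers the exact bit length) | stored_bytes
# int32 | CRC32 of the raw payload (4 bytes, little-endian).
#
# Integer fields are unsigned 32-bit; the implementation caps them at
# 2^31 - 1 (desk scale).

ARCHIVE_MAGIC <- "CDBGZIP1"
ARCHIVE_VERSION <- 1L
SECTION_NAMES <- c("SPSSDATA", "DELTA", "BOUNDARY", "FREQS",
                   "META", "LOCAL", "MBITS")

index_width_r <- function(n) {
  w <- 0L
  v <- 1
  while (v < n) {
    v <- v * 2
    w <- w + 1L
  }
  max(1L, w)
}

#' Pack / unpack an archive section payload
#'
#' Codec 0 stores bytes verbatim; codec 1 applies DEFLATE (gzip). This
#' generic byte compressor is the archive's final space reducer; no queries
#' are ever run on the compressed sections, so nothing fancier is needed.
#'
#' @param raw Raw vector (the section's exact payload).
#' @param codec 0 or 1.
#' @return `pack_section()` the stored bytes; `unpack_section()` the
#'   original payload.
#' @export
pack_section <- function(raw, codec) {
  stopifnot(is.raw(raw))
  switch(as.character(codec),
         "0" = raw,
         "1" = memCompress(raw, type = "gzip"),
         stop("unknown codec id: ", codec, call. = FALSE))
}

#' @rdname pack_section
#' @param stored Raw vector as stored in the archive.
#' @export
unpack_section <- function(stored, codec) {
  stopifnot(is.raw(stored))
  switch(as.character(codec),
         "0" = stored,
         "1" = memDecompress(stored, type = "gzip"),
         stop("unknown codec id: ", codec, call. = FALSE))
}

crc32_bytes <- function(raw) {
  v <- cpp_crc32(raw)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

check_u31 <- function(x, what) {
  if (x > 2147483647) stop(what, " exceeds the 2^31-1 format limit",
                           call. = FALSE)
  as.integer(x)
}

# build a section record from a bit string or raw text
section_bits <- function(bits) {
  list(raw = pack_bits(bits), n_bits = nchar(bits))
}
section_text <- function(text) {
  raw <- charToRaw(text)
  list(raw = raw, n_bits = 8 * length(raw))
}

#' Compress a colored de Bruijn graph to an archive
#'
#' Runs the full pipeline: union k-mers with color classes, greedy simplitig
#' construction, color matrix in simplitig order, Huffman global class IDs,
#' delta/boundary class-table serialization, per-simplitig six-way mode
#' search, and section packing. Identical inputs and parameters produce
#' byte-identical archives.
#'
#' @param x A [cdbg] object.
#' @param path Output archive path.
#' @param run_divisor Power-of-two run-length divisor (default 16).
#' @return Invisibly, a list with the header fields and a `sections` data
#'   frame (name, codec, raw_bytes, raw_bits, stored_bytes) plus the
#'   per-simplitig mode choices.
#' @export
compress_cdbg <- function(x, path, run_divisor = 16L) {
  stopifnot(inherits(x, "cdbg"))
  run_divisor <- as.integer(run_divisor)
  mapping <- union_with_classes(x)
  if (length(mapping) == 0L)
    stop("the union k-mer set is empty; nothing to compress", call. = FALSE)
  s <- build_simplitigs(names(mapping), x$k)
  cm <- build_color_matrix(s, mapping)
  tab <- assign_global_ids(class_frequencies(cm))
  ser <- serialize_global_table(tab, x$C)
  M <- length(tab$classes)
  enc <- cpp_encode_choose_all(cm$class_seqs, tab$classes,
                               unname(tab$codes), cm$C, run_divisor)

  meta_bits <- paste0(ifelse(enc$use_local_id, "1", "0"),
                      c("00", "01", "10")[enc$max_dif + 1L])
  wM <- index_width_r(M)
  local_parts <- character(0)
  if (any(enc$use_local_id)) {
    local_parts <- vapply(which(enc$use_local_id), function(i) {
      entries <- enc$local[[i]]
      paste0(cpp_int_to_bits(length(entries) - 1L, wM),
             paste(tab$codes[entries], collapse = ""))
    }, character(1))
  }

  sections <- list(
    SPSSDATA = section_text(paste(s$simplitigs, collapse = "\n")),
    DELTA    = section_bits(ser$delta),
    BOUNDARY = section_bits(ser$boundary),
    FREQS    = section_text(paste(ser$freq_list, collapse = "\n")),
    META     = section_bits(paste(meta_bits, collapse = "")),
    LOCAL    = section_bits(paste(local_parts, collapse = "")),
    MBITS    = section_bits(paste(enc$m, collapse = ""))
  )

  header <- list(version = ARCHIVE_VERSION, k = x$k, C = x$C, M = M,
                 run_divisor = run_divisor,
                 n_simplitigs = length(s$simplitigs),
                 n_kmers = length(mapping))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(ARCHIVE_MAGIC), con)
  writeBin(vapply(header, check_u31, 0L, what = "header field"), con,
           size = 4L, endian = "little")
  stored <- list()
  info <- data.frame(name = SECTION_NAMES, codec = 0L, raw_bytes = 0L,
                     raw_bits = 0, stored_bytes = 0L)
  for (i in seq_along(SECTION_NAMES)) {
    sec <- sections[[SECTION_NAMES[i]]]
    packed <- pack_section(sec$raw, 1L)
    codec <- if (length(packed) < length(sec$raw)) 1L else 0L
    if (codec == 0L) packed <- sec$raw
    stored[[i]] <- packed
    info$codec[i] <- codec
    info$raw_bytes[i] <- length(sec$raw)
    info$raw_bits[i] <- sec$n_bits
    info$stored_bytes[i] <- length(packed)
    writeBin(charToRaw(sprintf("%-8s", SECTION_NAMES[i])), con)
    writeBin(c(codec, check_u31(length(sec$raw), "section size"),
               bit_tail(sec$n_bits),
               check_u31(length(packed), "section size")), con,
             size = 4L, endian = "little")
    writeBin(crc32_bytes(sec$raw), con)
  }
  for (p in stored) writeBin(p, con)

  invisible(c(header,
              list(path = path, sections = info,
                   max_dif = enc$max_dif, use_local_id = enc$use_local_id)))
}

# parse the container; errors on truncation, bad magic/version, CRC mismatch
read_archive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path, call. = FALSE)
  bytes <- readBin(path, raw(), file.size(path))
  pos <- 0L
  take <- function(n) {
    if (pos + n > length(bytes))
      stop("truncated archive: ", path, call. = FALSE)
    out <- bytes[seq_len(n) + pos]
    pos <<- pos + as.integer(n)
    out
  }
  ints <- function(n) readBin(take(4L * n), integer(), n, size = 4L,
                              endian = "little")
  if (rawToChar(take(8L)) != ARCHIVE_MAGIC)
    stop("not a cdbgzip archive (bad magic): ", path, call. = FALSE)
  h <- ints(7L)
  if (h[1] != ARCHIVE_VERSION)
    stop("unsupported archive format version ", h[1], call. = FALSE)
  header <- list(version = h[1], k = h[2], C = h[3], M = h[4],
                 run_divisor = h[5], n_simplitigs = h[6], n_kmers = h[7])
  dir <- vector("list", length(SECTION_NAMES))
  for (i in seq_along(SECTION_NAMES)) {
    name <- trimws(rawToChar(take(8L)))
    if (name != SECTION_NAMES[i])
      stop("unexpected section '", name, "' (wanted ", SECTION_NAMES[i], ")",
           call. = FALSE)
    v <- ints(4L)
    crc <- take(4L)
    dir[[i]] <- list(name = name, codec = v[1], raw_bytes = v[2],
                     tail_bits = v[3], stored_bytes = v[4], crc = crc)
  }
  sections <- list()
  for (i in seq_along(SECTION_NAMES)) {
    d <- dir[[i]]
    raw <- unpack_section(take(d$stored_bytes), d$codec)
    if (length(raw) != d$raw_bytes)
      stop("section ", d$name, " decompressed to ", length(raw),
           " bytes, expected ", d$raw_bytes, call. = FALSE)
    if (!identical(crc32_bytes(raw), d$crc))
      stop("CRC mismatch in section ", d$name, call. = FALSE)
    n_bits <- if (d$raw_bytes == 0L) 0 else 8 * (d$raw_bytes - 1) + d$tail_bits
    sections[[d$name]] <- list(raw = raw, n_bits = n_bits, codec = d$codec,
                               stored_bytes = d$stored_bytes)
  }
  list(header = header, sections = sections)
}

#' Decompress an archive
#'
#' Restores the string set and the exact k-mer-to-color-class mapping, in
#' string-set rank order. Optionally writes the string set as FASTA and the
#' color matrix as tab-separated text (`<kmer>\\t<C-bit class>` per line).
#'
#' @param path Archive produced by [compress_cdbg()].
#' @param spss_out Optional FASTA output path for the string set.
#' @param matrix_out Optional TSV output path for the color matrix.
#' @return List with `mapping` (named character: k-mer to class bit string,
#'   rank order), `kmers`, `classes`, `spss`, and the header fields `k`,
#'   `C`, `M`, `run_divisor`.
#' @export
decompress_cdbg <- function(path, spss_out = NULL, matrix_out = NULL) {
  a <- read_archive(path)
  h <- a$header
  sec <- a$sections

  simplitigs <- strsplit(rawToChar(sec$SPSSDATA$raw), "\n", fixed = TRUE)[[1]]
  if (length(simplitigs) != h$n_simplitigs)
    stop("archive holds ", length(simplitigs), " simplitigs, header says ",
         h$n_simplitigs, call. = FALSE)
  s <- new_spss(simplitigs, h$k)
  n_windows <- nchar(simplitigs) - h$k + 1L
  if (sum(n_windows) != h$n_kmers)
    stop("simplitig lengths disagree with the header k-mer count",
         call. = FALSE)

  ser <- structure(
    list(delta = unpack_bits(sec$DELTA$raw, sec$DELTA$n_bits),
         boundary = unpack_bits(sec$BOUNDARY$raw, sec$BOUNDARY$n_bits),
         freq_list = as.integer(strsplit(rawToChar(sec$FREQS$raw), "\n",
                                         fixed = TRUE)[[1]])),
    class = "global_table_serialization"
  )
  tab <- deserialize_global_table(ser, h$C)
  if (length(tab$classes) != h$M)
    stop("class table holds ", length(tab$classes),
         " classes, header says ", h$M, call. = FALSE)

  dec <- cpp_decode_all(unpack_bits(sec$MBITS$raw, sec$MBITS$n_bits),
                        unpack_bits(sec$META$raw, sec$META$n_bits),
                        unpack_bits(sec$LOCAL$raw, sec$LOCAL$n_bits),
                        as.integer(n_windows), tab$classes,
                        unname(tab$codes), h$C, h$run_divisor)
  if (dec$m_bits_consumed != sec$MBITS$n_bits)
    stop("m bitvector has trailing bits beyond the decoded k-mers",
         call. = FALSE)
  if (dec$local_bits_consumed != sec$LOCAL$n_bits)
    stop("local-table stream has trailing undecoded bits", call. = FALSE)

  kmers <- cpp_spss_kmers(simplitigs, h$k)$kmers
  mapping <- setNames(dec$classes, kmers)
  if (!is.null(spss_out)) write_spss(s, spss_out)
  if (!is.null(matrix_out))
    writeLines(paste0(kmers, "\t", dec$classes), matrix_out)
  list(mapping = mapping, kmers = kmers, classes = dec$classes, spss = s,
       k = h$k, C = h$C, M = h$M, run_divisor = h$run_divisor,
       max_dif = dec$max_dif, use_local_id = dec$use_local_id)
}

#' Verify an archive against its source graph
#'
#' Decompresses the archive and compares the recovered k-mer-to-class
#' mapping with [union_with_classes()] of `x`; exact equality is required.
#'
#' @param x The [cdbg] the archive was (supposedly) built from.
#' @param path Archive path.
#' @return List with `pass`, `n_kmers` and, on failure, `first_divergence`
#'   (k-mer, expected class, recovered class).
#' @export
verify_roundtrip <- function(x, path) {
  truth <- union_with_classes(x)
  d <- decompress_cdbg(path)
  res <- list(pass = TRUE, n_kmers = length(truth), first_divergence = NULL)
  class(res) <- "roundtrip_report"
  if (length(d$mapping) != length(truth)) {
    extra <- setdiff(d$kmers, names(truth))
    missing <- setdiff(names(truth), d$kmers)
    bad <- if (length(extra)) extra[1L] else missing[1L]
    res$pass <- FALSE
    res$first_divergence <- list(kmer = bad,
                                 expected = unname(truth[bad]),
                                 recovered = unname(d$mapping[bad]))
    return(res)
  }
  got <- unname(d$mapping)
  want <- unname(truth[d$kmers])
  bad <- which(is.na(want) | got != want)
  if (length(bad)) {
    i <- bad[1L]
    res$pass <- FALSE
    res$first_divergence <- list(kmer = d$kmers[i], expected = want[i],
                                 recovered = got[i])
  }
  res
}

#' @export
print.roundtrip_report <- function(x, ...) {
  if (x$pass) {
    cat("round trip OK over", x$n_kmers, "k-mers\n")
  } else {
    d <- x$first_divergence
    cat("ROUND TRIP FAILED at k-mer", d$kmer, ": expected",
        d$expected, "recovered", if (is.na(d$recovered)) "<absent>"
        else d$recovered, "\n")
  }
  invisible(x)
}

#' Archive statistics
#'
#' Per-section byte breakdown and the frequency of the six per-simplitig
#' compression modes.
#'
#' @param path Archive path.
#' @return List of class `cdbg_archive_stats` with `header`, `sections`
#'   (data frame) and `modes` (2 x 3 matrix, UseLocalID by maxDif).
#' @export
cdbg_stats <- function(path) {
  a <- read_archive(path)
  h <- a$header
  meta <- unpack_bits(a$sections$META$raw, a$sections$META$n_bits)
  S <- h$n_simplitigs
  ul <- substring(meta, 3 * seq_len(S) - 2, 3 * seq_len(S) - 2) == "1"
  d <- as.integer(substring(meta, 3 * seq_len(S) - 1,
                            3 * seq_len(S) - 1) == "1") * 2L +
    as.integer(substring(meta, 3 * seq_len(S), 3 * seq_len(S)) == "1")
  modes <- matrix(0L, 2, 3,
                  dimnames = list(c("UseLocalID=FALSE", "UseLocalID=TRUE"),
                                  paste0("maxDif=", 0:2)))
  for (i in seq_len(S))
    modes[ul[i] + 1L, d[i] + 1L] <- modes[ul[i] + 1L, d[i] + 1L] + 1L
  sections <- do.call(rbind, lapply(a$sections, function(s)
    data.frame(codec = s$codec, raw_bytes = length(s$raw),
               raw_bits = s$n_bits, stored_bytes = s$stored_bytes)))
  sections <- cbind(name = rownames(sections), sections)
  rownames(sections) <- NULL
  structure(list(header = h, sections = sections, modes = modes),
            class = "cdbg_archive_stats")
}

#' @export
print.cdbg_archive_stats <- function(x, ...) {
  h <- x$header
  cat("cdbgzip archive: k =", h$k, ", C =", h$C, ", M =", h$M,
      ",", h$n_simplitigs, "simplitigs,", h$n_kmers, "k-mers\n")
  print(x$sections, row.names = FALSE)
  cat("compression modes (simplitig counts):\n")
  print(x$modes)
  invisible(x)
}
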