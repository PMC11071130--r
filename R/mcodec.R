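#' Run-length quotient/remainder encoding
#'
#' A run length is split by the power-of-two `run_divisor` (default 16) into
#' a quotient, written in unary as that many `1`s terminated by a `0`, and a
#' remainder written in exactly log2(run_divisor) binary bits, most
#' significant first. `encode_run_length(21, 16)` is therefore `"100101"`:
#' quotient 1, remainder 5. A smaller divisor spends more bits on long runs,
#' a larger one on short runs.
#'
#' @param run_len Non-negative integer run length.
#' @param run_divisor Power of two, at least 2.
#' @return Bit string.
#' @export
encode_run_length <- function(run_len, run_divisor = 16L) {
  cpp_encode_run_length(as.double(run_len), as.integer(run_divisor))
}

#' @rdname encode_run_length
#' @param bits Bit string to read from.
#' @param pos 1-based position of the first bit of the field.
#' @return `decode_run_length()`: list with `value` (the run length) and
#'   `pos` (1-based position of the first unconsumed bit).
#' @export
decode_run_length <- function(bits, run_divisor = 16L, pos = 1L) {
  r <- cpp_decode_run_length(bits, as.double(pos - 1L),
                             as.integer(run_divisor))
  list(value = r$value, pos = r$pos + 1)
}

#' Differing color indices between two color vectors
#'
#' @param prev,cur Color-vector bit strings of equal length.
#' @return Ascending 0-based integer vector of positions where they differ;
#'   its length is the Hamming distance.
#' @export
diff_indices <- function(prev, cur) {
  cpp_diff_indices(prev, cur)
}

#' Encode one simplitig's class sequence
#'
#' Scans the simplitig's per-k-mer classes left to right and appends one of
#' four encodings to the m bitvector for each k-mer:
#'
#' * *Skip*: interior k-mer whose class equals both neighbours — nothing is
#'   appended.
#' * *Small class difference*: Hamming distance `0 < h <= max_dif` to the
#'   preceding k-mer — type `10`, an extra bit when `max_dif == 2` (1 iff
#'   `h == 2`), then the `h` differing color indices, each in
#'   ceiling(log2 C) bits.
#' * *End of run*: class equal to the preceding k-mer and either different
#'   from the successor or last — type `11` (`1` when `max_dif == 0`), then
#'   the run length (the number of consecutive same-class predecessors)
#'   via [encode_run_length()].
#' * *Store class ID*: otherwise — type `0`, then the class's Huffman global
#'   ID, or its fixed-width local ID when `use_local_id`.
#'
#' The first k-mer always stores its ID (it has no predecessor). With
#' `use_local_id` the local table lists the simplitig's distinct classes in
#' first-appearance order; a local ID takes ceiling(log2 l) bits (0 bits
#' when l = 1).
#'
#' @param class_seq Character vector of class bit strings, one per k-mer.
#' @param max_dif Maximum Hamming distance encoded as a difference (0-2).
#' @param use_local_id Whether class IDs are local to the simplitig.
#' @param table A `global_class_table` covering every class in `class_seq`.
#' @param run_divisor Power-of-two run-length divisor.
#' @return List with `m` (bit string), `local` (character vector of classes
#'   in first-appearance order; empty when `use_local_id` is `FALSE`) and
#'   `total_bits` (3 metadata bits + length of `m` + on-disk local-table
#'   bits).
#' @export
encode_simplitig <- function(class_seq, max_dif, use_local_id, table,
                             run_divisor = 16L) {
  stopifnot(inherits(table, "global_class_table"))
  cpp_encode_simplitig(class_seq, as.integer(max_dif),
                       isTRUE(use_local_id), table$classes,
                       unname(table$codes), as.integer(run_divisor))
}

#' Decode one simplitig's class sequence
#'
#' Exact inverse of [encode_simplitig()]. The decoder knows `n_kmers` (from
#' the simplitig's length in the string set) and reads type bits: with
#' `max_dif == 0`, `0` = store and `1` = run; otherwise `0` = store, `10` =
#' difference, `11` = run. A run marker emits its run-length many k-mers of
#' the current class — the skipped interior k-mers plus the closing one; the
#' run's opener was emitted by its own store/difference encoding. A run or
#' difference before any class, a run length of zero, an overshoot of
#' `n_kmers` or an exhausted bit stream is an error.
#'
#' @param bits Bit string holding the m vector (possibly concatenated with
#'   others).
#' @param max_dif,use_local_id The simplitig's metadata.
#' @param table A `global_class_table`.
#' @param local Character vector of local-table classes in first-appearance
#'   order (ignored unless `use_local_id`).
#' @param n_kmers Number of k-mers to emit.
#' @param C Number of colors.
#' @param run_divisor Power-of-two run-length divisor.
#' @param pos 1-based position of the first bit to read.
#' @return List with `classes` (length `n_kmers`) and `pos` (1-based first
#'   unconsumed bit).
#' @export
decode_simplitig <- function(bits, max_dif, use_local_id, table,
                             local = character(0), n_kmers, C,
                             run_divisor = 16L, pos = 1L) {
  stopifnot(inherits(table, "global_class_table"))
  r <- cpp_decode_simplitig(bits, as.double(pos - 1L), as.integer(max_dif),
                            isTRUE(use_local_id), table$classes,
                            unname(table$codes), as.character(local),
                            as.integer(n_kmers), as.integer(C),
                            as.integer(run_divisor))
  list(classes = r$classes, pos = r$pos + 1)
}

#' Six-way per-simplitig mode search
#'
#' Encodes the class sequence under all six (max_dif, use_local_id)
#' combinations and keeps the cheapest, counting 3 metadata bits, the m
#' vector, and the on-disk local table (ceiling(log2 M) bits for its size
#' plus the listed global IDs) when local IDs are used. Ties prefer the
#' smaller `max_dif`, then `use_local_id = FALSE`, so archives are
#' reproducible.
#'
#' @inheritParams encode_simplitig
#' @return List with the winning `max_dif`, `use_local_id`, `m`, `local`,
#'   `total_bits`, and `candidate_costs` (the six costs in search order).
#' @export
choose_encoding <- function(class_seq, table, run_divisor = 16L) {
  stopifnot(inherits(table, "global_class_table"))
  cpp_choose_encoding(class_seq, table$classes, unname(table$codes),
                      as.integer(run_divisor))
}
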