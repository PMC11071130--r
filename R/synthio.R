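#' Specification of a synthetic colored de Bruijn graph
#'
#' The generator emulates a collection of related genomes: `n_backbones`
#' random ancestral sequences are shared by the `C` colors; each color drops
#' a backbone with probability `dropout` (creating multi-color class
#' structure and long monochrome runs) and substitutes bases independently
#' with probability `mutation_rate` (creating rare-class k-mers and small
#' class differences). Defaults mirror a high-sharing, read-collection-like
#' regime: 9 colors, k = 31, light mutation, moderate dropout.
#'
#' @param C Number of colors (>= 1).
#' @param n_backbones Number of shared backbone sequences.
#' @param backbone_len Backbone length in bases (>= k).
#' @param mutation_rate Per-base substitution probability per color.
#' @param dropout Probability a backbone is absent from a color.
#' @param k K-mer length.
#' @param abundance Abundance threshold recorded for the readers.
#' @param seed Integer seed; everything the generator draws depends on it.
#' @return Object of class `synth_cdbg_spec`.
#' @export
synth_spec <- function(C = 9L, n_backbones = 5L, backbone_len = 2000L,
                       mutation_rate = 0.001, dropout = 0.2, k = 31L,
                       abundance = 1L, seed = 1L) {
  stopifnot(C >= 1, n_backbones >= 1, backbone_len >= k, k >= 2,
            mutation_rate >= 0, mutation_rate <= 1,
            dropout >= 0, dropout <= 1)
  structure(list(C = as.integer(C), n_backbones = as.integer(n_backbones),
                 backbone_len = as.integer(backbone_len),
                 mutation_rate = mutation_rate, dropout = dropout,
                 k = as.integer(k), abundance = as.integer(abundance),
                 seed = as.integer(seed)),
            class = "synth_cdbg_spec")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic colored de Bruijn graph with ground truth
#'
#' Writes one FASTA file per color, a manifest, and a truth table
#' (`<kmer>\\t<C-bit class>`) to `out_dir`. The ground-truth mapping is
#' computed by re-counting the emitted in-memory sequences (not by tracking
#' which bases mutated), so a mutated k-mer that collides with an existing
#' one is classified correctly by construction. Deterministic given the
#' spec's seed. A color that would end up with no sequence at all is an
#' error when `dropout == 1`; for `dropout < 1` one backbone is retained so
#' every color is non-empty.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest`, `fasta` (per-color paths), `truth_file`,
#'   `truth` (named character mapping) and `spec`.
#' @export
generate_cdbg <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_cdbg_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  backbones <- vapply(seq_len(spec$n_backbones),
                      function(i) random_dna(spec$backbone_len), "")
  fasta <- file.path(out_dir, sprintf("color_%d.fa", seq_len(spec$C) - 1L))
  color_seqs <- vector("list", spec$C)
  for (ci in seq_len(spec$C)) {
    keep <- stats::runif(spec$n_backbones) >= spec$dropout
    if (!any(keep)) {
      if (spec$dropout >= 1)
        stop("color ", ci - 1L, " has no sequences (dropout = 1); ",
             "an all-zero color is not representable", call. = FALSE)
      keep[sample.int(spec$n_backbones, 1L)] <- TRUE
    }
    seqs <- vapply(backbones[keep], mutate_seq, "",
                   rate = spec$mutation_rate, USE.NAMES = FALSE)
    color_seqs[[ci]] <- seqs
    writeLines(paste0(">seq_", seq_along(seqs) - 1L, "\n", seqs), fasta[ci])
  }
  manifest <- file.path(out_dir, "manifest.txt")
  writeLines(basename(fasta), manifest)

  sets <- lapply(color_seqs, cpp_count_kmers, k = spec$k, a = 1L)
  truth <- union_classes_from_sets(sets)
  truth_file <- file.path(out_dir, "truth.tsv")
  writeLines(paste0(names(truth), "\t", truth), truth_file)
  list(manifest = manifest, fasta = fasta, truth_file = truth_file,
       truth = truth, spec = spec)
}

#' Sharing statistics of a k-mer to class mapping
#'
#' @param mapping Named character vector (k-mer to class bit string).
#' @return List with `n_kmers`, `C`, `M` (distinct classes),
#'   `single_color_fraction` (share of k-mers present in exactly one
#'   color), and `mean_run_length` (mean length of maximal equal-class runs
#'   along a reference greedy string set of the mapping's k-mers).
#' @export
sharing_stats <- function(mapping) {
  stopifnot(is.character(mapping), length(mapping) >= 1L,
            !is.null(names(mapping)))
  k <- nchar(names(mapping)[1L])
  ones <- nchar(gsub("0", "", mapping, fixed = TRUE))
  s <- build_simplitigs(names(mapping), k)
  runs <- unlist(lapply(cpp_class_sequences(s$simplitigs, k, names(mapping),
                                            unname(mapping)),
                        function(cs) rle(cs)$lengths))
  list(n_kmers = length(mapping), C = nchar(mapping[[1L]]),
       M = length(unique(mapping)),
       single_color_fraction = mean(ones == 1L),
       mean_run_length = mean(runs))
}
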