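# Shared fixtures, all built in code.

# Three-color toy graph (k = 5): colors 1 and 2 extend color 0; the union
# has 7 k-mers in 3 distinct color classes.
toy_core <- c("TCAAA", "CAAAA", "AAAAT")
toy_cdbg <- function() {
  cdbg(list(toy_core,
            c(toy_core, "AAATT", "CAAAG", "AAATC", "AATCG"),
            c(toy_core, "AAATT", "CAAAG")),
       k = 5)
}
toy_mapping <- function() {
  c(TCAAA = "111", CAAAA = "111", AAAAT = "111",
    AAATT = "011", CAAAG = "011", AAATC = "010", AATCG = "010")
}

write_fasta <- function(seqs, path, names = paste0("seq", seq_along(seqs))) {
  writeLines(paste0(">", names, "\n", seqs), path)
  path
}

# manifest for one FASTA file per color
make_manifest <- function(color_seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- vapply(seq_along(color_seqs), function(i) {
    write_fasta(color_seqs[[i]], file.path(dir, sprintf("c%d.fa", i)))
  }, "")
  manifest <- file.path(dir, "manifest.txt")
  writeLines(basename(paths), manifest)
  manifest
}

# a global class table whose code assignment is easy to reason about
small_table <- function(freqs) {
  assign_global_ids(freqs)
}

# random class-vector pool of size m over C colors (distinct, none all-zero);
# m is capped at the 2^C - 1 distinct non-zero vectors that exist
rand_classes <- function(m, C) {
  m <- min(m, 2^C - 1)
  out <- character(0)
  while (length(out) < m) {
    cand <- do.call(paste0, lapply(seq_len(C), function(j)
      sample(c("0", "1"), m, replace = TRUE)))
    cand <- setdiff(unique(cand), c(strrep("0", C), out))
    out <- c(out, cand)
  }
  out[seq_len(m)]
}

# class sequence with run structure and occasional small differences,
# mimicking consecutive k-mers along a simplitig
rand_class_seq <- function(n, pool, p_stay = 0.6, p_diff = 0.2) {
  C <- nchar(pool[1])
  seq <- character(n)
  seq[1] <- sample(pool, 1)
  if (n == 1) return(seq)
  for (i in 2:n) {
    u <- stats::runif(1)
    if (u < p_stay) {
      seq[i] <- seq[i - 1]
    } else if (u < p_stay + p_diff) {
      h <- sample(1:2, 1)
      cls <- strsplit(seq[i - 1], "")[[1]]
      idx <- sample(C, min(h, C))
      cls[idx] <- ifelse(cls[idx] == "0", "1", "0")
      cand <- paste(cls, collapse = "")
      seq[i] <- if (cand == strrep("0", C)) seq[i - 1] else cand
    } else {
      seq[i] <- sample(pool, 1)
    }
  }
  seq
}

# frequency table covering every class used in a sequence (plus the pool)
table_for_seq <- function(seqs, pool) {
  cls <- unique(c(unlist(seqs), pool))
  freqs <- table(factor(unlist(seqs), levels = cls)) + 1
  assign_global_ids(setNames(as.integer(freqs), cls))
}
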