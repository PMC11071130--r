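test_that("section codecs round-trip and record exact lengths", {
  set.seed(71)
  x <- as.raw(sample(0:255, 300, TRUE))
  expect_identical(unpack_section(pack_section(x, 0), 0), x)
  expect_identical(unpack_section(pack_section(x, 1), 1), x)
  expect_identical(unpack_section(pack_section(raw(0), 1), 1), raw(0))
  expect_error(pack_section(x, 7), "unknown codec")
})

test_that("bit packing is MSB-first and inverts exactly", {
  expect_identical(pack_bits("10000001"), as.raw(0x81))
  expect_identical(pack_bits("101"), as.raw(0xA0)) # zero-padded
  set.seed(72)
  for (n in c(0, 1, 7, 8, 9, 63, 200)) {
    bits <- paste(sample(c("0", "1"), n, TRUE), collapse = "")
    expect_identical(unpack_bits(pack_bits(bits), n), bits)
  }
})

test_that("the toy graph compresses and decompresses losslessly", {
  g <- toy_cdbg()
  path <- withr::local_tempfile(fileext = ".cdbgc")
  res <- compress_cdbg(g, path)
  expect_equal(res$n_kmers, 7)
  expect_equal(res$M, 3)

  d <- decompress_cdbg(path)
  truth <- union_with_classes(g)
  expect_setequal(names(d$mapping), names(truth))
  expect_equal(unname(d$mapping[names(truth)]), unname(truth))
  expect_true(validate_spss(d$spss, names(truth))$pass)
  expect_true(verify_roundtrip(g, path)$pass)
})

test_that("identical inputs produce byte-identical archives", {
  g <- toy_cdbg()
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  compress_cdbg(g, p1)
  compress_cdbg(g, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
})

test_that("a single-color graph degenerates to one empty-code class", {
  set.seed(73)
  kmers <- unique(extract_kmers(paste(
    sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""), 9))
  g <- cdbg(list(kmers), k = 9)
  path <- withr::local_tempfile()
  res <- compress_cdbg(g, path)
  expect_equal(res$M, 1)
  # exact m cost: 1 bit for a lone k-mer, else store + one run encoding
  d <- decompress_cdbg(path)
  nw <- nchar(d$spss$simplitigs) - 9 + 1
  expected_bits <- sum(ifelse(nw == 1, 1, 2 + (nw - 1) %/% 16 + 1 + 4))
  expect_equal(res$sections$raw_bits[res$sections$name == "MBITS"],
               expected_bits)
  expect_true(verify_roundtrip(g, path)$pass)
})

test_that("corrupt or truncated archives fail loudly, never silently", {
  g <- toy_cdbg()
  path <- withr::local_tempfile()
  compress_cdbg(g, path)
  bytes <- readBin(path, raw(), file.size(path))

  trunc <- withr::local_tempfile()
  writeBin(bytes[1:(length(bytes) - 4)], trunc)
  expect_error(decompress_cdbg(trunc), "truncated|CRC|decompressed")

  junk <- withr::local_tempfile()
  writeBin(c(charToRaw("NOTANARC"), bytes[-(1:8)]), junk)
  expect_error(decompress_cdbg(junk), "magic")

  flip <- bytes
  flip[length(flip)] <- xor(flip[length(flip)], as.raw(1))
  bad <- withr::local_tempfile()
  writeBin(flip, bad)
  expect_error(decompress_cdbg(bad)) # CRC, codec or decode failure
})

test_that("verification pinpoints a class divergence", {
  g <- toy_cdbg()
  path <- withr::local_tempfile()
  compress_cdbg(g, path)
  # move AAATC from color 1 only into colors 0+1: union unchanged, class flips
  g2 <- cdbg(list(c(toy_core, "AAATC"),
                  c(toy_core, "AAATT", "CAAAG", "AAATC", "AATCG"),
                  c(toy_core, "AAATT", "CAAAG")), k = 5)
  rep <- verify_roundtrip(g2, path)
  expect_false(rep$pass)
  expect_equal(rep$first_divergence$kmer, "AAATC")
  expect_equal(rep$first_divergence$expected, "110")
  expect_equal(rep$first_divergence$recovered, "010")
})

test_that("synthetic graphs round-trip across color counts", {
  for (C in c(2, 9, 100)) {
    spec <- synth_spec(C = C, n_backbones = 3, backbone_len = 300,
                       mutation_rate = 0.01, dropout = 0.2, k = 21,
                       seed = 100 + C)
    out <- generate_cdbg(spec, withr::local_tempdir())
    g <- load_cdbg(out$manifest, k = 21)
    path <- withr::local_tempfile()
    compress_cdbg(g, path)
    d <- decompress_cdbg(path)
    expect_equal(length(d$mapping), length(out$truth))
    expect_equal(unname(d$mapping[names(out$truth)]), unname(out$truth))
  }
})

test_that("high-sharing graphs beat the naive matrix in raw color bits", {
  spec <- synth_spec(C = 9, n_backbones = 5, backbone_len = 1500,
                     mutation_rate = 0.001, dropout = 0.2, k = 31, seed = 77)
  out <- generate_cdbg(spec, withr::local_tempdir())
  g <- load_cdbg(out$manifest, k = 31)
  path <- withr::local_tempfile()
  res <- compress_cdbg(g, path)
  color_bits <- sum(res$sections$raw_bits[res$sections$name != "SPSSDATA"])
  expect_lt(color_bits, 9 * res$n_kmers)
})

test_that("archive statistics report sections and mode counts", {
  g <- toy_cdbg()
  path <- withr::local_tempfile()
  res <- compress_cdbg(g, path)
  st <- cdbg_stats(path)
  expect_equal(st$sections$name,
               c("SPSSDATA", "DELTA", "BOUNDARY", "FREQS",
                 "META", "LOCAL", "MBITS"))
  expect_equal(sum(st$modes), res$n_simplitigs)
  expect_equal(st$header$n_kmers, 7)
  # mode table agrees with the compressor's own choices
  for (i in seq_along(res$max_dif))
    expect_gte(st$modes[res$use_local_id[i] + 1, res$max_dif[i] + 1], 1)
})

test_that("decompression writes the string set and matrix on request", {
  g <- toy_cdbg()
  path <- withr::local_tempfile()
  compress_cdbg(g, path)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  d <- decompress_cdbg(path, spss_out = fa, matrix_out = tsv)
  expect_identical(read_spss(fa, 5), d$spss)
  lines <- readLines(tsv)
  expect_length(lines, 7)
  expect_identical(lines, paste0(d$kmers, "\t", d$classes))
})
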