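test_that("class frequencies count k-mers per distinct class in ascending class order", {
  cm <- build_color_matrix(new_spss(c("TCAAAATCG", "AAATT", "CAAAG"), 5),
                           toy_cdbg())
  f <- class_frequencies(cm)
  expect_equal(f, c("010" = 2L, "011" = 2L, "111" = 3L))
  expect_length(f, 3) # M = 3

  expect_equal(class_frequencies(rep("0110", 9)), c("0110" = 9L))
})

test_that("Huffman global IDs are optimal, canonical and deterministic", {
  tab <- assign_global_ids(c("111" = 3, "011" = 2, "010" = 2))
  expect_equal(nchar(tab$codes[c("111", "011", "010")]),
               c("111" = 1L, "011" = 2L, "010" = 2L))

  # single class: empty codeword
  tab1 <- assign_global_ids(c("10" = 5))
  expect_equal(unname(tab1$codes), "")

  # four equally frequent classes: balanced tree
  tab4 <- assign_global_ids(c("0001" = 2, "0010" = 2, "0100" = 2, "1000" = 2))
  expect_true(all(nchar(tab4$codes) == 2))
  expect_equal(anyDuplicated(tab4$codes), 0)

  # rebuilt from (classes, freqs) alone -> identical codes
  tab_re <- assign_global_ids(setNames(tab4$freqs, tab4$classes))
  expect_identical(tab_re$codes, tab4$codes)
})

test_that("codes form a prefix-free set", {
  set.seed(51)
  for (rep in 1:10) {
    C <- sample(2:10, 1)
    M <- sample(1:40, 1)
    classes <- rand_classes(M, C)
    tab <- assign_global_ids(setNames(sample(1:50, length(classes), TRUE),
                                      classes))
    codes <- sort(unname(tab$codes))
    if (length(codes) > 1)
      for (i in seq_len(length(codes) - 1))
        expect_false(startsWith(codes[i + 1], codes[i]))
  }
})

test_that("delta/boundary serialization matches the hand-worked layout", {
  tab <- assign_global_ids(c("010" = 2, "011" = 2, "111" = 3))
  ser <- serialize_global_table(tab, 3)
  # 010 verbatim, then index 2 ("10"), then index 0 ("00")
  expect_equal(ser$delta, "0101000")
  expect_equal(ser$boundary, "1001010")
  expect_equal(ser$freq_list, c(2L, 2L, 3L))

  ser1 <- serialize_global_table(assign_global_ids(c("111" = 7)), 3)
  expect_equal(ser1$delta, "111")
  expect_equal(ser1$boundary, "100")

  expect_identical(deserialize_global_table(ser, 3)$classes, tab$classes)
  expect_identical(deserialize_global_table(ser, 3)$codes, tab$codes)
})

test_that("serialization round-trips with bit-identical regenerated codes", {
  set.seed(52)
  for (rep in 1:25) {
    C <- sample(2:24, 1)
    M <- sample(1:60, 1)
    classes <- rand_classes(M, C)
    M <- length(classes)
    tab <- assign_global_ids(setNames(sample(1:200, M, TRUE), classes))
    ser <- serialize_global_table(tab, C)
    back <- deserialize_global_table(ser, C)
    expect_identical(back$classes, tab$classes)
    expect_identical(back$codes, tab$codes)
    expect_identical(back$freqs, tab$freqs)

    # |delta| identity: C bits + index_width * total Hamming distance
    w <- max(1, ceiling(log2(C)))
    h_sum <- if (M > 1) sum(vapply(2:M, function(i)
      length(diff_indices(tab$classes[i - 1], tab$classes[i])), 0L)) else 0
    expect_equal(nchar(ser$delta), C + w * h_sum)
    expect_equal(nchar(ser$boundary), nchar(ser$delta))
    expect_equal(sum(strsplit(ser$boundary, "")[[1]] == "1"), M)
  }
})

test_that("mean code length stays within one bit of the class entropy", {
  set.seed(53)
  for (rep in 1:10) {
    C <- sample(2:16, 1)
    M <- sample(2:50, 1)
    classes <- rand_classes(M, C)
    freqs <- setNames(sample(1:500, length(classes), TRUE), classes)
    tab <- assign_global_ids(freqs)
    p <- tab$freqs / sum(tab$freqs)
    H <- -sum(p * log2(p))
    L <- sum(p * nchar(tab$codes))
    expect_gte(L, H - 1e-9)
    expect_lt(L, H + 1)
  }
})

test_that("tampered serializations are rejected", {
  tab <- assign_global_ids(c("010" = 2, "011" = 2, "111" = 3))
  ser <- serialize_global_table(tab, 3)

  bad <- ser
  bad$boundary <- "1011010" # spurious extra boundary
  expect_error(deserialize_global_table(bad, 3),
               "index fields|ascending|exactly C bits")

  bad2 <- ser
  bad2$boundary <- substr(bad2$boundary, 1, 6)
  expect_error(deserialize_global_table(bad2, 3), "differ in length")

  bad3 <- ser
  bad3$freq_list <- c(2L, 3L)
  expect_error(deserialize_global_table(bad3, 3), "frequency list")
})
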