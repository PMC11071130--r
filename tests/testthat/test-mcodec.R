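# tables with hand-picked codewords (canonical assignment is by
# (length, class value), so class values pin the codes down)
tab_c0 <- small_table(c("01" = 3, "10" = 1))              # "01" -> "0"
tab_uv <- small_table(c("100000" = 2, "100100" = 1))      # u -> "0"
tab_c10 <- small_table(c("001" = 2, "011" = 1, "100" = 1)) # "011" -> "10"

test_that("run lengths split into unary quotient and binary remainder", {
  expect_equal(encode_run_length(21, 16), "100101")
  expect_equal(encode_run_length(1, 16), "00001")
  expect_equal(encode_run_length(16, 16), "100000")
  expect_equal(encode_run_length(0, 2), "00")

  expect_equal(decode_run_length("100101", 16)$value, 21)
  expect_equal(decode_run_length("00001", 16)$value, 1)

  for (n in c(0:128, sample(129:10000, 400), 9999, 10000)) {
    for (div in c(2, 16, 64)) {
      bits <- encode_run_length(n, div)
      dec <- decode_run_length(bits, div)
      expect_equal(dec$value, n)
      expect_equal(dec$pos, nchar(bits) + 1)
    }
  }
})

test_that("diff_indices lists differing colors ascending", {
  expect_equal(diff_indices("111", "011"), 0L)
  expect_length(diff_indices("010", "010"), 0)
  expect_equal(diff_indices("000000", "001001"), c(2L, 5L))
  expect_error(diff_indices("01", "011"), "differ in length")
})

test_that("encode_simplitig reproduces hand-simulated bit streams", {
  # store, skip, end-of-run (runLen = 2)
  e1 <- encode_simplitig(rep("01", 3), 0, FALSE, tab_c0)
  expect_equal(e1$m, paste0("00", "1", "00010"))
  expect_equal(e1$total_bits, 3 + 8)

  # store u, then a Hamming-1 difference at color index 3 (C = 6)
  e2 <- encode_simplitig(c("100000", "100100"), 1, FALSE, tab_uv)
  expect_equal(e2$m, "0010011")

  # a lone k-mer must store its ID
  e3 <- encode_simplitig("011", 0, FALSE, tab_c10)
  expect_equal(e3$m, "010")

  # the run-length example embedded in a real stream: 22 equal classes
  e4 <- encode_simplitig(rep("01", 22), 0, FALSE, tab_c0)
  expect_equal(e4$m, paste0("00", "1", "100101"))
})

test_that("decode_simplitig inverts the hand examples", {
  d1 <- decode_simplitig("00100010", 0, FALSE, tab_c0, n_kmers = 3, C = 2)
  expect_equal(d1$classes, rep("01", 3))
  expect_equal(d1$pos, 9)

  d2 <- decode_simplitig("0010011", 1, FALSE, tab_uv, n_kmers = 2, C = 6)
  expect_equal(d2$classes, c("100000", "100100"))

  # a run marker emits runLen k-mers of the current class
  d4 <- decode_simplitig("001100101", 0, FALSE, tab_c0, n_kmers = 22, C = 2)
  expect_equal(d4$classes, rep("01", 22))
})

test_that("malformed streams are rejected", {
  expect_error(decode_simplitig("00", 0, FALSE, tab_c0, n_kmers = 3, C = 2),
               "exhausted")
  # run marker before any class
  expect_error(decode_simplitig("1100101", 0, FALSE, tab_c0,
                                n_kmers = 21, C = 2), "before any class")
  # run overshooting the simplitig
  expect_error(decode_simplitig("001100101", 0, FALSE, tab_c0,
                                n_kmers = 3, C = 2), "overshoot")
})

test_that("decode inverts encode in all six modes on structured sequences", {
  set.seed(61)
  for (rep in 1:150) {
    C <- sample(2:12, 1)
    pool <- rand_classes(sample(1:5, 1), C)
    n <- sample(1:50, 1)
    cs <- rand_class_seq(n, pool)
    tab <- table_for_seq(list(cs), pool)
    for (d in 0:2) {
      for (l in c(FALSE, TRUE)) {
        enc <- encode_simplitig(cs, d, l, tab)
        dec <- decode_simplitig(enc$m, d, l, tab, local = enc$local,
                                n_kmers = n, C = C)
        expect_identical(dec$classes, cs)
        expect_equal(dec$pos, nchar(enc$m) + 1)
      }
    }
  }
})

test_that("edge cases round-trip: M = 1, single k-mer, boundary runs, h = 2", {
  tab1 <- small_table(c("1" = 4))
  for (cs in list("1", rep("1", 2), rep("1", 40))) {
    for (d in 0:2) for (l in c(FALSE, TRUE)) {
      enc <- encode_simplitig(cs, d, l, tab1)
      dec <- decode_simplitig(enc$m, d, l, tab1, local = enc$local,
                              n_kmers = length(cs), C = 1)
      expect_identical(dec$classes, cs)
    }
  }
  # alternating h=2 flips, runs touching both simplitig ends
  cs <- c("1100", "1100", "0011", "1100", "0011", "0011")
  tab <- table_for_seq(list(cs), c("1100", "0011"))
  for (d in 0:2) for (l in c(FALSE, TRUE)) {
    enc <- encode_simplitig(cs, d, l, tab)
    dec <- decode_simplitig(enc$m, d, l, tab, local = enc$local,
                            n_kmers = length(cs), C = 4)
    expect_identical(dec$classes, cs)
  }
})

test_that("total_bits accounts for metadata, m and the on-disk local table", {
  set.seed(62)
  for (rep in 1:30) {
    C <- sample(2:8, 1)
    pool <- rand_classes(sample(2:4, 1), C)
    cs <- rand_class_seq(sample(2:30, 1), pool)
    tab <- table_for_seq(list(cs), pool)
    M <- length(tab$classes)
    for (d in 0:2) for (l in c(FALSE, TRUE)) {
      enc <- encode_simplitig(cs, d, l, tab)
      local_bits <- if (l)
        max(1, ceiling(log2(M))) + sum(nchar(tab$codes[enc$local])) else 0
      expect_equal(enc$total_bits, 3 + nchar(enc$m) + local_bits)
      if (!l) expect_length(enc$local, 0)
    }
  }
})

test_that("choose_encoding returns the cheapest of the six modes", {
  # single-class simplitig: local table can only cost extra
  ch <- choose_encoding(rep("01", 5), tab_c0)
  expect_false(ch$use_local_id)
  expect_true(all(ch$total_bits <= ch$candidate_costs))

  # lone k-mer: full tie across modes resolves to maxDif 0, global IDs
  ch1 <- choose_encoding("011", tab_c10)
  expect_equal(ch1$max_dif, 0)
  expect_false(ch1$use_local_id)

  set.seed(63)
  for (rep in 1:40) {
    C <- sample(2:10, 1)
    pool <- rand_classes(sample(2:5, 1), C)
    cs <- rand_class_seq(sample(1:40, 1), pool, p_stay = 0.3, p_diff = 0.4)
    tab <- table_for_seq(list(cs), pool)
    ch <- choose_encoding(cs, tab)
    # oracle: enumerate the six candidates explicitly
    grid <- expand.grid(l = c(FALSE, TRUE), d = 0:2)
    costs <- mapply(function(d, l)
      encode_simplitig(cs, d, l, tab)$total_bits, grid$d, grid$l)
    expect_equal(ch$total_bits, min(costs))
    expect_equal(ch$candidate_costs, unname(costs))
    # deterministic tie-break: first minimum in (maxDif, useLocalID) order
    first <- which.min(costs)
    expect_equal(ch$max_dif, grid$d[first])
    expect_equal(ch$use_local_id, grid$l[first])
    # never worse than the maxDif=0 / global-ID baseline
    expect_lte(ch$total_bits, costs[1])
  }
})
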