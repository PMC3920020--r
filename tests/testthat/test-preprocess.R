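test_that("adapter trimming removes the longest exact suffix/prefix overlap", {
  expect_equal(trim_adapter("ACGTACGTTCGTAT", "TCGTATGCC"), "ACGTACGT")
  expect_equal(trim_adapter("ACGTACGTACGT", "TCGTATGCC"), "ACGTACGTACGT")
  # overlap below the minimum stays untouched
  expect_equal(trim_adapter("ACGTACGTTCGTA", "TCGTATGCC", min_overlap = 6),
               "ACGTACGTTCGTA")
  expect_error(trim_adapter("ACGT", ""), "non-empty")
})

test_that("adapter trimming agrees with a brute-force overlap oracle", {
  set.seed(11)
  adapter <- "TCGTATGCCGTCTTCTGCTTG"
  oracle_trim <- function(read, adapter, min_ov) {
    n <- nchar(read)
    for (ov in seq(min(n, nchar(adapter)), 1)) {
      if (ov < min_ov) break
      if (substr(read, n - ov + 1, n) == substr(adapter, 1, ov))
        return(substr(read, 1, n - ov))
    }
    read
  }
  for (i in 1:60) {
    ins <- rand_dna(sample(4:30, 1))
    read <- substr(paste0(ins, substr(adapter, 1, sample(0:21, 1))), 1, 36)
    expect_identical(trim_adapter(read, adapter, 6),
                     oracle_trim(read, adapter, 6))
  }
})

test_that("poly-N and homopolymer policy drops and trims as configured", {
  cfg <- preprocess_config()
  expect_equal(drop_polyN_and_homopolymers("ACGNNNNNAC", cfg)$reason, "poly_N")
  expect_equal(drop_polyN_and_homopolymers(strrep("A", 20), cfg)$reason,
               "homopolymer")
  v <- drop_polyN_and_homopolymers("ACGTACGTACGTACGTAC", cfg)
  expect_true(v$keep)
  expect_equal(v$sequence, "ACGTACGTACGTACGTAC")
  # trailing run above the cap is trimmed; a read that then collapses to a
  # single repeated base is dropped
  long_tail <- paste0("ACGTACGTAC", strrep("T", 12))
  expect_equal(drop_polyN_and_homopolymers(long_tail, cfg)$sequence,
               "ACGTACGTAC")
})

test_that("the low-count filter keeps exactly the reads at or above threshold and is monotone", {
  ur <- collapse_reads(list(
    root = c(rep("AAAACCCCGGGGTTTTAA", 1), rep("CCCCGGGGTTTTAAAACC", 4)),
    leaf = c(rep("AAAACCCCGGGGTTTTAA", 1), rep("GGGGTTTTAAAACCCCGG", 1)),
    flower = rep("AAAACCCCGGGGTTTTAA", 1),
    seed = character(0)))
  kept <- low_count_filter(ur, 4L)
  # 3 total across libraries -> removed; 4 -> kept (boundary)
  expect_false("AAAACCCCGGGGTTTTAA" %in% kept$sequence)
  expect_true("CCCCGGGGTTTTAAAACC" %in% kept$sequence)
  expect_equal(nrow(low_count_filter(ur, 1L)), nrow(ur))  # identity
  for (thr in 1:6) {
    a <- low_count_filter(ur, thr)
    b <- low_count_filter(ur, thr + 1L)
    expect_true(all(b$sequence %in% a$sequence))  # monotone
  }
})

test_that("contaminant removal is exact, full-length and strand-agnostic", {
  contam <- rand_dna(300, seed = 5)
  refs <- data.frame(id = "virus1", sequence = contam)
  inside <- substr(contam, 100, 120)
  inside_rc <- revcomp(substr(contam, 200, 220))
  mm <- inside
  substr(mm, 10, 10) <- ifelse(substr(mm, 10, 10) == "A", "C", "A")
  ur <- collapse_reads(list(root = c(inside, inside_rc, mm,
                                     rand_dna(21, seed = 6))))
  res <- remove_contaminants(ur, refs)
  expect_setequal(res$removed$sequence, c(inside, inside_rc))
  expect_true(all(res$removed$ref_id == "virus1"))
  # partition property
  expect_equal(sort(c(res$kept$sequence, res$removed$sequence)),
               sort(ur$sequence))
  expect_error(remove_contaminants(ur, refs[0, ]), "empty")
})

test_that("contaminant removal equals the exhaustive substring oracle", {
  set.seed(19)
  refs <- data.frame(id = c("c1", "c2"),
                     sequence = c(rand_dna(150), rand_dna(150)))
  reads <- c(
    replicate(10, rand_dna(20)),
    vapply(1:5, function(i) {
      s <- sample(130, 1); substr(refs$sequence[sample(2, 1)], s, s + 19)
    }, character(1)),
    vapply(1:5, function(i) {
      s <- sample(130, 1)
      revcomp(substr(refs$sequence[sample(2, 1)], s, s + 19))
    }, character(1)))
  ur <- collapse_reads(list(root = reads))
  res <- remove_contaminants(ur, refs)
  for (i in seq_len(nrow(ur))) {
    expect_equal(ur$sequence[i] %in% res$removed$sequence,
                 oracle_is_substring(ur$sequence[i], refs$sequence),
                 info = ur$sequence[i])
  }
})

test_that("the length histogram tallies unique and redundancy-weighted counts", {
  ur <- collapse_reads(list(
    root = c(rep(rand_dna(21, seed = 30), 10), rand_dna(24), rand_dna(24))))
  h <- length_histogram(ur)
  expect_equal(h$total_count[h$length == 21], 10)
  expect_equal(h$unique_count[h$length == 21], 1)
  expect_equal(h$total_count[h$length == 24], 2)
  expect_equal(h$unique_count[h$length == 24], 2)
  expect_equal(nrow(length_histogram(collapse_reads(list(root = character(0))))), 0)
})

test_that("a 60/40 length mixture yields the designed modal lengths", {
  set.seed(77)
  reads <- c(replicate(120, rand_dna(21)), replicate(80, rand_dna(24)))
  ur <- collapse_reads(list(root = reads))
  h <- length_histogram(ur)
  expect_equal(h$length[which.max(h$total_count)], 21)
  expect_equal(sum(h$total_count), 200)
})
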