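test_that("dot-bracket parsing builds a symmetric, legal partner map", {
  pt <- parse_dotbracket("GGGAAACCC", "(((...)))")
  expect_equal(pt$partner, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
  expect_error(parse_dotbracket("GGAC", "((.)"), "unbalanced")
  expect_error(parse_dotbracket("GGACC", "((.)"), "lengths differ")
  # G:C legal, A:C illegal
  expect_silent(parse_dotbracket("GAAAC", "(...)"))
  expect_error(parse_dotbracket("AAAAC", "(...)"), "illegal pair")
  # render is the parser's inverse
  db <- "((..((...))..((...))..))"
  expect_equal(render_dotbracket(parse_dotbracket(seq_for_db(db), db)), db)
})

test_that("pair tables reject pseudoknots and asymmetric maps", {
  expect_error(pair_table("GGAACC", c(5L, 6L, 0L, 0L, 1L, 2L)),
               "pseudoknot")
  expect_error(pair_table("GGAACC", c(6L, 0L, 0L, 0L, 0L, 2L)),
               "not symmetric")
})

test_that("builtin fold handles perfect complements, homopolymers and designed hairpins", {
  pt <- fold("GGGGGAAAACCCCC")
  expect_equal(render_dotbracket(pt), "(((((....)))))")
  expect_lt(pt$mfe, -8)
  pt2 <- fold("AAAAAAAAAA")
  expect_equal(sum(pt2$partner > 0), 0)
  expect_equal(pt2$mfe, 0)
  # designed 70-nt perfect hairpin: all 30 designed pairs recovered
  arm <- rand_dna(30, seed = 70)
  hp <- paste0(arm, "AACAACAACA", revcomp(arm))
  p <- fold(hp)
  expect_equal(sum(p$partner[1:30] == 71 - (1:30)), 30)
  expect_error(fold("ACGTACGT"), "too short")
})

test_that("partner involution and nesting hold for folds of random sequences", {
  set.seed(81)
  for (i in 1:10) {
    pt <- fold(rand_dna(sample(30:80, 1)))
    idx <- which(pt$partner > 0)
    expect_equal(pt$partner[pt$partner[idx]], idx)
    expect_silent(mirloom:::check_nested(pt$partner))
  }
})

test_that("hairpin metrics count loops, branches, bulges and mismatches", {
  m1 <- hairpin_metrics(parse_dotbracket(seq_for_db("(((...)))"),
                                         "(((...)))"))
  expect_equal(m1$terminal_loop_size, 3L)
  expect_equal(m1$branch_count, 0L)
  expect_equal(nrow(m1$bulges), 0)

  db2 <- "((..((...))..((...))..))"
  m2 <- hairpin_metrics(parse_dotbracket(seq_for_db(db2), db2))
  expect_equal(m2$branch_count, 2L)
  expect_equal(m2$loop_count, 2L)

  db3 <- "(((.(((...))))))"
  m3 <- hairpin_metrics(parse_dotbracket(seq_for_db(db3), db3))
  expect_equal(nrow(m3$bulges), 1)
  expect_equal(m3$bulges$side, 5L)
  expect_equal(m3$bulges$size, 1L)

  # symmetric 1:1 internal loop counts as a mismatch, not a bulge
  db4 <- "(((.(((...))).)))"
  m4 <- hairpin_metrics(parse_dotbracket(seq_for_db(db4), db4))
  expect_equal(nrow(m4$bulges), 0)
  expect_equal(length(m4$mismatch_positions), 1)

  m0 <- hairpin_metrics(parse_dotbracket("AAAAA", "....."))
  expect_equal(m0$n_pairs, 0L)
  expect_equal(nrow(m0$stems), 0)
})

test_that("core location rejects loop overlap and measures span metrics", {
  db <- paste0(strrep("(", 10), "....", strrep(")", 10))
  pt <- parse_dotbracket(seq_for_db(db), db)
  core <- locate_core(pt, c(2, 8))
  expect_false(core$rejected)
  expect_equal(core$bulge_count, 0L)
  expect_equal(core$unpaired_count, 0L)
  # one nt into the terminal loop -> rejection
  expect_equal(locate_core(pt, c(8, 11))$reason, "in_loop")
  # spanning a size-1 bulge
  db5 <- "((((.((((....))))))))"
  pt5 <- parse_dotbracket(seq_for_db(db5), db5)
  co5 <- locate_core(pt5, c(2, 8))
  expect_equal(co5$bulge_count, 1L)
  expect_equal(co5$max_bulge_size, 1L)
  expect_false(co5$contains_loop_or_branch)
})

test_that("star derivation gives 2-nt 3' overhangs and is an involution", {
  arm <- rand_dna(30, seed = 90)
  hp <- paste0(arm, "AACAACAACA", revcomp(arm))
  pt <- fold(hp)
  d <- derive_star(pt, c(5, 25))
  expect_equal(d$star, c(48, 68))
  expect_equal(derive_star(pt, d$star)$star, c(5, 25))
  expect_equal(d$star_sequence, substr(hp, 48, 68))
  # mature inside the loop has no duplex partners
  expect_error(derive_star(pt, c(31, 40)), "no_duplex")
})

test_that("precursor trimming keeps duplex +/- flank, clamps, and refolds stably", {
  arm <- rand_dna(40, seed = 91)
  hp100 <- paste0(arm, strrep("A", 20), revcomp(arm))  # L = 100
  pt <- fold(hp100)
  d <- derive_star(pt, c(15, 35))
  tr <- trim_precursor(pt, d, flank = 10)
  # outermost duplex pair is (15, partner(15)) = (15, 86): kept 5..96
  expect_equal(pt$partner[15], 86)
  expect_equal(tr$kept, c(5, 96))
  expect_equal(tr$sequence,
               substr(hp100, tr$kept[1], tr$kept[2]))
  expect_equal(tr$pair_table$backend, "builtin")
  # clamping: duplex near the ends leaves the sequence untrimmed
  arm2 <- rand_dna(30, seed = 92)
  hp70 <- paste0(arm2, "AACAACAACA", revcomp(arm2))
  pt70 <- fold(hp70)
  d70 <- derive_star(pt70, c(3, 23))
  tr70 <- trim_precursor(pt70, d70, flank = 10)
  expect_equal(tr70$kept, c(1, 70))
  # re-trimming the trimmed sequence is a no-op under a stable fold
  d_again <- derive_star(tr70$pair_table, c(3, 23))
  tr_again <- trim_precursor(tr70$pair_table, d_again, flank = 10)
  expect_equal(tr_again$sequence, tr70$sequence)
})

test_that("dot-bracket files round-trip including the energy annotation", {
  pts <- list(h1 = fold("GGGGGAAAACCCCC"),
              h2 = parse_dotbracket("GGGAAACCC", "(((...)))", mfe = -3.2))
  path <- tempfile(fileext = ".db")
  write_dotbracket_file(pts, path)
  back <- read_dotbracket_file(path)
  expect_equal(names(back), c("h1", "h2"))
  expect_equal(back$h1$partner, pts$h1$partner)
  expect_equal(back$h1$mfe, pts$h1$mfe, tolerance = 0.01)
  expect_equal(back$h2$mfe, -3.2, tolerance = 0.01)
})

test_that("connect-table files are parsed into pair tables", {
  ct <- tempfile(fileext = ".ct")
  writeLines(c(
    "9 dG = -3.20 h1",
    "1 G 0 2 9 1", "2 G 1 3 8 2", "3 G 2 4 7 3",
    "4 A 3 5 0 4", "5 A 4 6 0 5", "6 A 5 7 0 6",
    "7 C 6 8 3 7", "8 C 7 9 2 8", "9 C 8 0 1 9"), ct)
  pt <- read_ct_file(ct)
  expect_equal(pt$partner, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
  expect_equal(pt$mfe, -3.2)
})
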