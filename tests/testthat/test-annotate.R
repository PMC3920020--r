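test_that("sense-perfect coding matches are strand-specific", {
  est <- data.frame(id = "PC1", sequence = rand_dna(200, seed = 3))
  inside <- substr(est$sequence, 50, 70)
  hit <- match_sense_perfect(inside, est)
  expect_equal(hit$ref_id, "PC1")
  expect_equal(c(hit$start, hit$end), c(50, 70))
  # antisense-only occurrence returns nothing
  expect_null(match_sense_perfect(revcomp(inside), est))
  expect_null(match_sense_perfect(rand_dna(21, seed = 4), est))
})

test_that("k-edit placement agrees with the base-R edit-distance oracle", {
  set.seed(23)
  for (i in 1:25) {
    ref <- rand_dna(60)
    read <- if (i %% 2 == 0) {
      # plant a mutated copy
      s <- sample(35, 1)
      r <- substr(ref, s, s + 19)
      pos <- sample(20, sample(0:3, 1))
      for (p in pos) substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      r
    } else rand_dna(20)
    h <- match_with_edits(read, ref, max_edits = 30L, gapped = TRUE)
    expect_equal(h$edits, oracle_min_edits(read, ref), info = read)
  }
})

test_that("edit caps and the gapped flag are honoured", {
  ref <- rand_dna(80, seed = 9)
  read <- substr(ref, 20, 40)
  expect_equal(match_with_edits(read, ref)$edits, 0)
  r3 <- read
  for (p in c(3, 9, 15)) substr(r3, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(r3, p, p))[1]
  h <- match_with_edits(r3, ref, max_edits = 3, gapped = FALSE)
  expect_equal(h$mismatches, 3)
  expect_equal(h$gaps, 0)
  # 2 substitutions + 2 gaps = 4 edits > 3 -> no hit
  r4 <- paste0(substr(r3, 1, 5), substr(r3, 8, 21), "CA")
  h4 <- match_with_edits(r4, ref, max_edits = 3, gapped = TRUE)
  if (!is.null(h4)) expect_lte(h4$edits, 3)
  # reverse-strand placement is found and reported on plus coordinates
  hrc <- match_with_edits(revcomp(read), ref, max_edits = 0)
  expect_equal(hrc$strand, "-")
  expect_equal(c(hrc$start, hrc$end), c(20, 40))
})

test_that("the cascade assigns exactly one category with fixed precedence", {
  coding <- data.frame(id = "PC1", sequence = rand_dna(120, seed = 31))
  noncod <- data.frame(id = "NC1", sequence = rand_dna(120, seed = 32))
  struct <- reference_set("structural_rna", "tRNA1",
                          rand_dna(120, seed = 33), "tRNA")
  mirref <- reference_set("known_mirna", "ath-miR156a",
                          rand_dna(21, seed = 34), "miR156")

  r_coding <- substr(coding$sequence, 10, 30)        # also = miRNA? no
  r_nc <- substr(noncod$sequence, 40, 60)
  r_trna <- substr(struct$sequence, 50, 71)
  r_trna_mm <- r_trna
  substr(r_trna_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                     substr(r_trna_mm, 5, 5))[1]
  substr(r_trna_mm, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                       substr(r_trna_mm, 12, 12))[1]
  r_mir <- mirref$sequence
  r_none <- rand_dna(21, seed = 35)

  ur <- collapse_reads(list(root = c(r_coding, r_nc, r_trna_mm, r_mir,
                                     r_none)))
  ann <- classify_reads(ur, coding, noncod, struct, mirref)
  got <- setNames(ann$category, ur$sequence[match(ann$read_id, ur$read_id)])
  expect_equal(unname(got[r_coding]), "protein_coding")
  expect_equal(unname(got[r_nc]), "noncoding_est")
  # 2 mismatches from a tRNA beats the miRNA step by cascade order
  expect_equal(unname(got[r_trna_mm]), "tRNA")
  expect_equal(unname(got[r_mir]), "miRNA")
  expect_equal(unname(got[r_none]), "unmatched")
  expect_equal(ann$family[ann$category == "miRNA"], "miR156")
  # exactly one category each, and categories exhaust the read set
  expect_equal(nrow(ann), nrow(ur))
  expect_true(all(ann$category %in% mirloom:::CATEGORIES))
})

test_that("coding-EST precedence beats a simultaneous miRNA match", {
  seqr <- rand_dna(21, seed = 55)
  coding <- data.frame(id = "PC1",
                       sequence = paste0(rand_dna(30, seed = 56), seqr,
                                         rand_dna(30)))
  mirref <- reference_set("known_mirna", "osa-miR399", seqr, "miR399")
  ur <- collapse_reads(list(root = seqr))
  ann <- classify_reads(ur, coding,
                        data.frame(id = character(), sequence = character()),
                        mirref[0, ], mirref)
  expect_equal(ann$category, "protein_coding")
})

test_that("family labels collapse species prefixes and variant suffixes", {
  expect_equal(mirna_family_label(c("ath-miR156a", "osa-miR156b")),
               c("miR156", "miR156"))
  expect_equal(mirna_family_label("miR-466"), "miR-466")
  expect_equal(mirna_family_label("ppt-miR319c"), "miR319")
  expect_warning(out <- mirna_family_label("weird99"), "unparsable")
  expect_equal(out, "weird99")
})

test_that("family aggregation sums member reads per library", {
  seq1 <- rand_dna(21, seed = 61); seq2 <- rand_dna(21, seed = 62)
  mirref <- reference_set("known_mirna", c("ath-miR156a", "osa-miR156b"),
                          c(seq1, seq2), c("miR156", "miR156"))
  empty_est <- data.frame(id = character(), sequence = character())
  ur <- collapse_reads(list(root = c(rep(seq1, 3), rep(seq2, 2)),
                            leaf = rep(seq1, 5)))
  ann <- classify_reads(ur, empty_est, empty_est, mirref[0, ], mirref)
  fam <- aggregate_families(ann, ur)
  expect_equal(nrow(fam), 1)
  expect_equal(fam$family, "miR156")
  expect_equal(fam$root, 5L)
  expect_equal(fam$leaf, 5L)
  expect_equal(fam$root_unique, 2L)
  expect_equal(fam$leaf_unique, 1L)
  expect_equal(nrow(aggregate_families(ann[0, ], ur)), 0)
})
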