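test_that("a perfect antisense site is found with zero mismatches", {
  mir <- rand_dna(21, seed = 301)
  tr <- data.frame(id = "T1",
                   sequence = paste0(rand_dna(80, seed = 302), revcomp(mir),
                                     rand_dna(80)))
  sites <- complementarity_scan(mir, tr, mirna_id = "miRx")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$mismatches, 0)
  expect_equal(sites$align_length, 21)
  expect_equal(c(sites$start, sites$end), c(81, 101))
  expect_true(sites$covers_2_12)
})

test_that("G:U wobble counts as a mismatch and short alignments are rejected", {
  mir <- paste0("TT", rand_dna(19, seed = 303))
  site <- revcomp(mir)
  # oppose miRNA position 5 with a G:U wobble (miRNA U opposite site G
  # instead of A) plus 3 true mismatches -> 4 mismatches, rejected
  mir_gu <- mir
  substr(mir_gu, 5, 5) <- "T"
  site_gu <- site
  substr(site_gu, 17, 17) <- "G"   # opposite miRNA position 5
  for (p in c(3, 8, 14)) {
    q <- 21 - p + 1
    cur_m <- substr(mir_gu, p, p)
    wc <- c(A = "T", C = "G", G = "C", T = "A")[[cur_m]]
    bad <- setdiff(c("A", "C", "G", "T"), c(wc, "G"))[1]
    substr(site_gu, q, q) <- bad
  }
  tr <- data.frame(id = "T1", sequence = paste0(rand_dna(30, seed = 304),
                                                site_gu, rand_dna(30)))
  expect_equal(nrow(complementarity_scan(mir_gu, tr)), 0)
  # complementary over positions 1-16 only (length 16 < 17) -> rejected;
  # the bases opposite miRNA positions 17-21 are set to the miRNA base
  # itself (never its Watson-Crick partner) so no chance extension exists
  mirc <- strsplit(mir, "")[[1]]
  left <- paste0(rand_dna(35, seed = 305),
                 paste(mirc[21:17], collapse = ""))
  tr16 <- data.frame(id = "T2",
                     sequence = paste0(left, revcomp(substr(mir, 1, 16)),
                                       rand_dna(40)))
  expect_equal(nrow(complementarity_scan(mir, tr16)), 0)
})

test_that("the scan equals the exhaustive all-offset oracle on random transcripts", {
  set.seed(310)
  for (rep in 1:6) {
    mir <- rand_dna(21)
    base <- rand_dna(500)
    # implant one perfect site and one 2-mismatch site
    s1 <- revcomp(mir)
    s2 <- s1
    for (p in c(4, 10)) substr(s2, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(s2, p, p))[1]
    tseq <- paste0(substr(base, 1, 150), s1, substr(base, 151, 300), s2,
                   substr(base, 301, 500))
    tr <- data.frame(id = "T", sequence = tseq)
    got <- complementarity_scan(mir, tr)
    got <- got[order(got$start), , drop = FALSE]
    want <- oracle_best_sites(oracle_target_scan(mir, tseq))
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$mismatches, want$mm)
  }
})

test_that("every reported site satisfies the three published criteria", {
  set.seed(311)
  for (rep in 1:4) {
    mir <- rand_dna(sample(20:24, 1))
    tr <- data.frame(id = "T", sequence = paste0(rand_dna(120), revcomp(mir),
                                                 rand_dna(120)))
    sites <- complementarity_scan(mir, tr)
    expect_true(all(sites$mismatches <= 3))
    expect_true(all(sites$covers_2_12))
    expect_true(all(sites$align_length > 16))
  }
})

test_that("homology transfer joins best hits under the e-value cutoff", {
  bh <- data.frame(est_id = c("E1", "E1", "E2", "E3"),
                   gene_id = c("AT3G11440.1", "AT1G01010.1", "AT3G11440.1",
                               "AT2G22840.1"),
                   evalue = c(1e-45, 1e-10, 1e-20, 1e-60))
  kt <- data.frame(family = c("miR159", "miR396"),
                   gene_id = c("AT3G11440.1", "AT2G22840.1"))
  out <- homology_transfer(bh, kt, mirnas_present = c("miR159", "miR396"))
  # E1 best hit passes and is a miR159 target; E2 fails the cutoff;
  # E3 joins miR396
  expect_equal(out$est_id, c("E1", "E3"))
  expect_equal(out$family, c("miR159", "miR396"))
  # family absent from the libraries is excluded
  out2 <- homology_transfer(bh, kt, mirnas_present = "miR396")
  expect_equal(out2$family, "miR396")
  expect_error(homology_transfer(bh[, 1:2], kt, "miR159"), "columns")
})

test_that("method merging flags method1/method2/both correctly", {
  sites <- data.frame(mirna_id = c("miR159", "miR528"),
                      transcript_id = c("E1", "E9"))
  transfers <- data.frame(est_id = c("E1", "E3"),
                          family = c("miR159", "miR396"),
                          gene_id = "g", evalue = 1e-40)
  merged <- merge_methods(sites, transfers)
  both <- merged[merged$family == "miR159" & merged$transcript_id == "E1", ]
  expect_true(both$both)
  m1only <- merged[merged$family == "miR528", ]
  expect_true(m1only$method1 && !m1only$method2)
  m2only <- merged[merged$family == "miR396", ]
  expect_true(m2only$method2 && !m2only$method1)
  # disjoint inputs concatenate
  expect_equal(nrow(merged), 3)
})

test_that("dual-site transcripts are detected with sites in coordinate order", {
  mir <- rand_dna(21, seed = 320)
  site <- revcomp(mir)
  tas <- data.frame(id = "TAS3",
                    sequence = paste0(rand_dna(50, seed = 321), site,
                                      rand_dna(150), site,
                                      rand_dna(50)))
  one <- data.frame(id = "ONE",
                    sequence = paste0(rand_dna(50, seed = 322), site,
                                      rand_dna(50)))
  hits <- detect_dual_site_transcripts(mir, rbind(tas, one))
  expect_equal(names(hits), "TAS3")
  expect_equal(nrow(hits$TAS3), 2)
  expect_true(all(diff(hits$TAS3$start) > 0))
  # two overlapping windows of one physical site merge to a single site
  expect_equal(nrow(complementarity_scan(mir, one)), 1)
})
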