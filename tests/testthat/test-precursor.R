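test_that("an exact linear training set is fitted with zero residual SD", {
  tr <- data.frame(length = c(60, 80, 100, 120, 140),
                   mfe = c(-20, -30, -40, -50, -60))
  reg <- fit_mfe_regression(tr)
  expect_equal(reg$slope, -0.5)
  expect_equal(reg$intercept, 10)
  expect_equal(reg$residual_sd, 0)
  expect_error(fit_mfe_regression(tr[1:2, ]), "insufficient_training")
  expect_error(fit_mfe_regression(data.frame(length = c(80, 80, 80),
                                             mfe = c(-1, -2, -3))),
               "insufficient_training")
  # degenerate interval still contains the fitted line
  expect_equal(mfe_within_pi(reg, 90, -35), "inside")
  expect_equal(mfe_within_pi(reg, 90, -20), "outside")
})

test_that("the prediction interval matches predict.lm and widens away from the mean length", {
  set.seed(101)
  tr <- data.frame(length = seq(60, 200, length.out = 40))
  tr$mfe <- -5 - 0.45 * tr$length + rnorm(40, sd = 4)
  reg <- fit_mfe_regression(tr)
  fit <- lm(mfe ~ length, data = tr)
  newl <- c(55, 90, 130, 210)
  ours <- mfe_prediction_interval(reg, newl)
  ref <- predict(fit, newdata = data.frame(length = newl),
                 interval = "prediction", level = 0.95)
  expect_equal(ours$lower, unname(ref[, "lwr"]), tolerance = 1e-8)
  expect_equal(ours$upper, unname(ref[, "upr"]), tolerance = 1e-8)
  widths <- ours$upper - ours$lower
  dist <- abs(newl - reg$mean_length)
  expect_equal(order(widths), order(dist))
  expect_equal(mfe_within_pi(reg, 100, reg$intercept + reg$slope * 100),
               "inside")
  expect_equal(mfe_within_pi(reg, 100, 1e6), "outside")
})

test_that("simulated regression parameters are recovered within three standard errors", {
  set.seed(103)
  a <- -4; b <- -0.5; sd <- 3
  tr <- data.frame(length = runif(200, 60, 200))
  tr$mfe <- a + b * tr$length + rnorm(200, sd = sd)
  reg <- fit_mfe_regression(tr)
  se_b <- sd / sqrt(reg$sxx)
  se_a <- sd * sqrt(1 / reg$n + reg$mean_length^2 / reg$sxx)
  expect_lt(abs(reg$slope - b), 3 * se_b)
  expect_lt(abs(reg$intercept - a), 3 * se_a)
})

test_that("composition-preserving shuffles keep the residue multiset and are seeded", {
  s <- "AACG"
  sh <- shuffle_preserving_composition(s, 7)
  expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_equal(shuffle_preserving_composition(s, 7),
               shuffle_preserving_composition(s, 7))
  expect_equal(shuffle_preserving_composition("A", 1), "A")
  long <- rand_dna(100, seed = 5)
  expect_equal(sort(strsplit(shuffle_preserving_composition(long, 9),
                             "")[[1]]),
               sort(strsplit(long, "")[[1]]))
})

test_that("candidate generation places matures on both strands of non-coding ESTs only", {
  reg <- shared_reg()
  hp <- make_hairpin_est(rand_dna(21, seed = 120), seed = 121)
  mature <- substr(hp$sequence, hp$mature_span[1], hp$mature_span[2])
  # implant on the reverse strand: candidate generated on the reverse
  # complement
  ests <- data.frame(id = c("NCfwd", "NCrev"),
                     sequence = c(hp$sequence, revcomp(hp$sequence)))
  cands <- generate_candidates(
    data.frame(read_id = "r1", sequence = mature), ests,
    mode = "conserved_match")
  strands <- vapply(cands, function(cc) paste(cc$est_id, cc$strand),
                    character(1))
  expect_true("NCfwd +" %in% strands)
  expect_true("NCrev -" %in% strands)
  # a mature absent from every EST yields nothing
  expect_length(generate_candidates(
    data.frame(read_id = "r2", sequence = rand_dna(21, seed = 122)),
    ests, mode = "conserved_match"), 0)
})

test_that("overlapping duplicate placements keep the highest-count mature read", {
  hp <- make_hairpin_est(rand_dna(21, seed = 130), seed = 131)
  mature <- substr(hp$sequence, hp$mature_span[1], hp$mature_span[2])
  shifted <- substr(hp$sequence, hp$mature_span[1] + 1,
                    hp$mature_span[2] + 1)
  ests <- data.frame(id = "NC1", sequence = hp$sequence)
  cands <- generate_candidates(
    data.frame(read_id = c("low", "high"),
               sequence = c(mature, shifted), count = c(2L, 9L)),
    ests, mode = "conserved_match")
  ids <- vapply(cands, `[[`, character(1), "mature_read_id")
  expect_true("high" %in% ids)
  expect_false("low" %in% ids)
})

test_that("the filter cascade passes clean hairpins and reports first failures", {
  reg <- shared_reg()
  thr <- filter_thresholds()
  hp <- make_hairpin_est(rand_dna(21, seed = 140), seed = 141,
                         thresholds = thr, reg = reg)
  cand <- mirloom:::build_candidate("e1", "+", hp$sequence, hp$mature_span,
                                    "r1", 1L, "novel", 10L, 25)
  v <- evaluate_candidate(cand, thr, reg)
  expect_true(v$pass)
  expect_true(all(v$checks))
  # an impossibly tight loop threshold flips the verdict at that rule
  thr_tight <- filter_thresholds(max_loop = 2L)
  v2 <- evaluate_candidate(cand, thr_tight, reg)
  expect_false(v2$pass)
  expect_equal(v2$first_fail, "loop_size")
  # backend mismatch between fold and regression is refused
  reg_ext <- fit_mfe_regression(
    data.frame(length = c(60, 90, 120), mfe = c(-20, -35, -50)),
    backend = "external")
  expect_error(evaluate_candidate(cand, thr, reg_ext), "backend")
})

test_that("the core-length unpaired allowance applies the published staircase", {
  expect_equal(default_mismatch_allowance(c(15, 17, 18, 19, 20, 21, 40)),
               c(1L, 1L, 2L, 3L, 4L, 5L, 5L))
  # constructed duplexes: core of 17 bp with 2 unpaired fails rule 8;
  # 19 bp with 3 unpaired passes it, with 4 fails rule 6/8
  mk <- function(db, span) {
    pt <- parse_dotbracket(seq_for_db(db), db)
    locate_core(pt, span)
  }
  # helix 20 with two 1:1 mismatches inside the span: 17 paired + 2 unpaired
  db <- paste0(strrep("(", 6), ".", strrep("(", 6), ".", strrep("(", 7),
               "....", strrep(")", 7), ".", strrep(")", 6), ".",
               strrep(")", 6))
  co <- mk(db, c(1, 19))
  expect_equal(co$length_bp, 17L)
  expect_equal(co$unpaired_count, 2L)
  expect_gt(co$unpaired_count, default_mismatch_allowance(co$length_bp))
  co19 <- mk(db, c(1, 21))  # 19 paired + 2 unpaired
  expect_equal(co19$length_bp, 19L)
  expect_lte(co19$unpaired_count, default_mismatch_allowance(co19$length_bp))
})

test_that("the shuffle benchmark separates designed hairpins from their permutations", {
  reg <- shared_reg()
  thr <- filter_thresholds()
  pos <- do.call(rbind, lapply(1:8, function(i) {
    h <- make_hairpin_est(rand_dna(21, seed = 150 + i), seed = 160 + i,
                          thresholds = thr, reg = reg)
    data.frame(sequence = h$sequence, mature_start = h$mature_span[1],
               mature_end = h$mature_span[2])
  }))
  bm <- benchmark_precursor_filter(pos, seed = 99, thresholds = thr,
                                   reg = reg)
  expect_equal(bm$sensitivity, 1.0)
  expect_gte(bm$specificity, 0.95)
  expect_equal(nrow(bm$audit), 2 * nrow(pos))
  expect_true(all(bm$audit$pass[bm$audit$class == "pos"]))
})
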