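# Precursor prediction: candidate generation from non-coding ESTs, the
# MFE-vs-length prediction-interval filter, the structural filter cascade,
# and the shuffle-based sensitivity/specificity benchmark.

#' Default structural filter thresholds
#'
#' The printed defaults of the filter cascade: terminal loop <= 15 nt,
#' branches <= 6, core bulges <= 1 of size <= 2, continuous unpaired <= 4,
#' no loop/branch inside the core, and a core-length-dependent cap on
#' unpaired residues (<=17 bp: 1; 18: 2; 19: 3; 20: 4; >20: 5).
#'
#' @param max_loop,max_branches,max_core_bulges,max_core_bulge_size,max_continuous_unpaired scalar caps.
#' @param mismatch_allowance function core length_bp -> max unpaired count.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_loop = 15L, max_branches = 6L,
                              max_core_bulges = 1L, max_core_bulge_size = 2L,
                              max_continuous_unpaired = 4L,
                              mismatch_allowance = default_mismatch_allowance) {
  stopifnot(max_loop > 0, max_branches > 0, max_core_bulges >= 0)
  structure(list(max_loop = as.integer(max_loop),
                 max_branches = as.integer(max_branches),
                 max_core_bulges = as.integer(max_core_bulges),
                 max_core_bulge_size = as.integer(max_core_bulge_size),
                 max_continuous_unpaired = as.integer(max_continuous_unpaired),
                 mismatch_allowance = mismatch_allowance),
            class = "filter_thresholds")
}

#' Core-length-dependent unpaired-residue allowance
#' @param length_bp base pairs in the core region.
#' @return maximum allowed unpaired residues in the core.
#' @export
default_mismatch_allowance <- function(length_bp) {
  ifelse(length_bp <= 17, 1L,
         ifelse(length_bp == 18, 2L,
                ifelse(length_bp == 19, 3L,
                       ifelse(length_bp == 20, 4L, 5L))))
}

#' Fit the MFE-on-length regression used by the prediction-interval filter
#'
#' Ordinary least squares of MFE on sequence length over a training set of
#' trusted hairpins, retaining everything needed for a two-sided prediction
#' interval at a new length. Training and scoring must use the same folding
#' backend.
#'
#' @param training data.frame with columns `length` and `mfe` (>= 3 rows,
#'   lengths not all equal).
#' @param confidence prediction-interval confidence (default 0.95).
#' @param backend folding backend the energies came from.
#' @return an `mfe_regression` object.
#' @export
fit_mfe_regression <- function(training, confidence = 0.95,
                               backend = "builtin") {
  if (nrow(training) < 3)
    stop("insufficient_training: need at least 3 (length, mfe) pairs")
  if (length(unique(training$length)) < 2)
    stop("insufficient_training: lengths have zero variance")
  fit <- lm(mfe ~ length, data = training)
  n <- nrow(training)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = n,
                 residual_sd = sqrt(sum(fit$residuals^2) / (n - 2)),
                 mean_length = mean(training$length),
                 sxx = sum((training$length - mean(training$length))^2),
                 confidence = confidence,
                 t_quantile = qt(1 - (1 - confidence) / 2, df = n - 2),
                 backend = backend),
            class = "mfe_regression")
}

#' Prediction-interval bounds at a given length
#' @param reg an `mfe_regression`.
#' @param length sequence length(s).
#' @param epsilon widening applied when the training residual SD is zero.
#' @return data.frame with `fit`, `lower`, `upper`.
#' @export
mfe_prediction_interval <- function(reg, length, epsilon = 1e-6) {
  fit <- reg$intercept + reg$slope * length
  sd <- max(reg$residual_sd, 0)
  half <- reg$t_quantile * sd *
    sqrt(1 + 1 / reg$n + (length - reg$mean_length)^2 / reg$sxx)
  half <- pmax(half, epsilon)
  data.frame(fit = fit, lower = fit - half, upper = fit + half)
}

#' Is an observed MFE inside the prediction interval at its length?
#' @param reg an `mfe_regression`.
#' @param length sequence length.
#' @param mfe observed energy (same backend as training).
#' @param epsilon degenerate-interval widening.
#' @return `"inside"` or `"outside"`.
#' @export
mfe_within_pi <- function(reg, length, mfe, epsilon = 1e-6) {
  pi <- mfe_prediction_interval(reg, length, epsilon)
  ifelse(mfe >= pi$lower & mfe <= pi$upper, "inside", "outside")
}

#' Generate precursor candidates by placing mature reads on non-coding ESTs
#'
#' For every qualifying (mature, EST, strand) placement -- perfect match for
#' modes `conserved_match` and `novel`, up to `max_edits` edits for mode
#' `est_vs_mirbase` -- the EST strand carrying the mature in sense
#' orientation is folded, the core located, the star derived, and the
#' precursor trimmed to the duplex +/- `flank` and refolded.
#'
#' @param mature_set data.frame with `read_id`, `sequence`, optional `count`
#'   (used to deduplicate overlapping placements: highest count wins).
#' @param noncoding_ests data.frame (`id`, `sequence`).
#' @param mode `"conserved_match"`, `"est_vs_mirbase"` or `"novel"`.
#' @param max_edits edit cap for `est_vs_mirbase` mode.
#' @param flank trim flank in nt.
#' @param temperature folding temperature metadata.
#' @return list of `precursor_candidate` objects (pre-filter; failed
#'   locate/derive steps are retained with a `status` explaining why).
#' @export
generate_candidates <- function(mature_set, noncoding_ests,
                                mode = c("conserved_match", "est_vs_mirbase",
                                         "novel"),
                                max_edits = 3L, flank = 10L,
                                temperature = 25) {
  mode <- match.arg(mode)
  out <- list()
  counts <- if ("count" %in% names(mature_set)) mature_set$count else
    rep(1L, nrow(mature_set))
  est_fw <- canon_dna(noncoding_ests$sequence)
  est_rc <- if (nrow(noncoding_ests)) revcomp(est_fw) else character(0)
  for (m in seq_len(nrow(mature_set))) {
    mat <- canon_dna(mature_set$sequence[m])
    for (k in seq_len(nrow(noncoding_ests))) {
      for (strand in c("+", "-")) {
        target <- if (strand == "+") est_fw[k] else est_rc[k]
        spans <- if (mode == "est_vs_mirbase") {
          h <- .fit_align_cpp(mat, target, TRUE)
          if (!is.na(h$edits) && h$edits <= max_edits)
            list(c(h$start, h$end)) else list()
        } else {
          pos <- gregexpr(mat, target, fixed = TRUE)[[1]]
          if (pos[1] == -1) list() else
            lapply(as.integer(pos), function(p) c(p, p + nchar(mat) - 1L))
        }
        for (span in spans) {
          cand <- build_candidate(
            est_id = noncoding_ests$id[k], strand = strand,
            target_seq = target, mature_span = span,
            mature_read_id = mature_set$read_id[m],
            mature_count = counts[m], mode = mode,
            flank = flank, temperature = temperature)
          out[[length(out) + 1]] <- cand
        }
      }
    }
  }
  dedupe_candidates(out)
}

# fold, locate, derive, trim for one placement
build_candidate <- function(est_id, strand, target_seq, mature_span,
                            mature_read_id, mature_count, mode, flank,
                            temperature) {
  cand <- structure(list(
    est_id = est_id, strand = strand,
    mature_read_id = mature_read_id, mature_count = mature_count,
    mature_span = mature_span, provenance = mode,
    full_pt = NULL, trimmed_sequence = NA_character_, pair_table = NULL,
    duplex = NULL, core = NULL, mfe = NA_real_, trimmed_span = NULL,
    status = "ok"), class = "precursor_candidate")
  if (nchar(target_seq) < 10) { cand$status <- "too_short"; return(cand) }
  pt <- fold(target_seq, temperature = temperature)
  cand$full_pt <- pt
  core0 <- locate_core(pt, mature_span)
  if (isTRUE(core0$rejected)) { cand$status <- "in_loop"; return(cand) }
  dup <- tryCatch(derive_star(pt, mature_span), error = function(e) e)
  if (inherits(dup, "error")) { cand$status <- "no_duplex"; return(cand) }
  tr <- trim_precursor(pt, dup, flank = flank)
  cand$trimmed_sequence <- tr$sequence
  cand$pair_table <- tr$pair_table
  cand$mfe <- tr$pair_table$mfe
  cand$trimmed_span <- tr$kept
  # remap the mature into trimmed coordinates and re-derive on the refold
  ms <- mature_span - tr$offset
  ms[1] <- max(1L, ms[1]); ms[2] <- min(nchar(tr$sequence), ms[2])
  cand$mature_span_trimmed <- ms
  core <- locate_core(tr$pair_table, ms)
  if (isTRUE(core$rejected)) { cand$status <- "in_loop"; return(cand) }
  cand$core <- core
  dup2 <- tryCatch(derive_star(tr$pair_table, ms), error = function(e) e)
  if (inherits(dup2, "error")) { cand$status <- "no_duplex"; return(cand) }
  cand$duplex <- dup2
  cand
}

# overlapping placements on the same EST: keep the highest-count mature read
dedupe_candidates <- function(cands) {
  if (length(cands) <= 1) return(cands)
  keep <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    if (!keep[i]) next
    for (j in seq_along(cands)) {
      if (i == j || !keep[j] || !keep[i]) next
      a <- cands[[i]]; b <- cands[[j]]
      if (a$est_id != b$est_id || a$strand != b$strand) next
      if (a$mature_span[1] <= b$mature_span[2] &&
          b$mature_span[1] <= a$mature_span[2]) {
        drop <- if (a$mature_count >= b$mature_count) j else i
        keep[drop] <- FALSE
      }
    }
  }
  cands[keep]
}

#' Evaluate a precursor candidate against the filter cascade
#'
#' Ordered checks: (1) mature in stem not loop (and a derivable duplex);
#' (2) trimmed MFE inside the prediction interval; (3) terminal loop of the
#' mature arm <= max_loop; (4) branches <= max_branches; (5) core bulges
#' <= max and bulge size <= max; (6) continuous unpaired <= max; (7) no
#' loop/branch inside the core; (8) core unpaired count <= allowance(core
#' length). The verdict records the first failing rule.
#'
#' @param cand a `precursor_candidate`.
#' @param thr a [filter_thresholds()].
#' @param reg an [fit_mfe_regression()] result (same backend as the fold).
#' @return list(`pass` logical, `first_fail` rule label or NA, `checks`
#'   named logical vector).
#' @export
evaluate_candidate <- function(cand, thr = filter_thresholds(), reg) {
  checks <- c(mature_in_stem = FALSE, mfe_in_pi = FALSE, loop_size = FALSE,
              branch_count = FALSE, core_bulges = FALSE,
              continuous_unpaired = FALSE, no_loop_in_core = FALSE,
              unpaired_allowance = FALSE)
  fail <- function(rule) list(pass = FALSE, first_fail = rule,
                              checks = checks)
  if (cand$status != "ok" || is.null(cand$core) || is.null(cand$duplex))
    return(fail("mature_in_stem"))
  checks["mature_in_stem"] <- TRUE
  pt <- cand$pair_table
  if (!identical(pt$backend, reg$backend))
    stop("fold backend (", pt$backend, ") differs from regression backend (",
         reg$backend, ")")
  if (mfe_within_pi(reg, nchar(cand$trimmed_sequence), cand$mfe) != "inside")
    return(fail("mfe_in_pi"))
  checks["mfe_in_pi"] <- TRUE
  tl <- arm_terminal_loop(pt, cand$mature_span_trimmed[1]:
                            cand$mature_span_trimmed[2])
  if (is.na(tl) || tl > thr$max_loop) return(fail("loop_size"))
  checks["loop_size"] <- TRUE
  hm <- hairpin_metrics(pt)
  if (hm$branch_count > thr$max_branches) return(fail("branch_count"))
  checks["branch_count"] <- TRUE
  core <- cand$core
  if (core$bulge_count > thr$max_core_bulges ||
      core$max_bulge_size > thr$max_core_bulge_size)
    return(fail("core_bulges"))
  checks["core_bulges"] <- TRUE
  if (core$max_continuous_unpaired > thr$max_continuous_unpaired)
    return(fail("continuous_unpaired"))
  checks["continuous_unpaired"] <- TRUE
  if (core$contains_loop_or_branch) return(fail("no_loop_in_core"))
  checks["no_loop_in_core"] <- TRUE
  if (core$unpaired_count > thr$mismatch_allowance(core$length_bp))
    return(fail("unpaired_allowance"))
  checks["unpaired_allowance"] <- TRUE
  list(pass = TRUE, first_fail = NA_character_, checks = checks)
}

#' Composition-preserving sequence shuffle
#'
#' Uniform random permutation of the residues: the nucleotide multiset is
#' identical to the input's. Deterministic for a given seed.
#'
#' @param sequence sequence to permute.
#' @param seed integer seed.
#' @return permuted sequence.
#' @export
shuffle_preserving_composition <- function(sequence, seed) {
  ch <- strsplit(sequence, "")[[1]]
  if (length(ch) <= 1) return(sequence)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  paste(sample(ch), collapse = "")
}

#' Shuffle-based sensitivity/specificity benchmark of the filter cascade
#'
#' For each positive (pre-miRNA sequence + mature span) one
#' composition-preserving shuffle is generated as its negative (evaluated at
#' the same mature coordinates). Sensitivity = passed positives / positives;
#' specificity = rejected negatives / negatives.
#'
#' @param positives data.frame with `sequence`, `mature_start`, `mature_end`.
#' @param seed integer seed for the shuffles.
#' @param thresholds a [filter_thresholds()].
#' @param reg an `mfe_regression` (builtin backend).
#' @param flank trim flank.
#' @return list(`sensitivity`, `specificity`, `audit` data.frame with one
#'   row per record: id, class, pass, first_fail).
#' @export
benchmark_precursor_filter <- function(positives, seed,
                                       thresholds = filter_thresholds(),
                                       reg, flank = 10L) {
  stopifnot(nrow(positives) > 0)
  eval_one <- function(seqs, starts, ends, cls) {
    res <- lapply(seq_along(seqs), function(i) {
      cand <- build_candidate(est_id = sprintf("%s%03d", cls, i),
                              strand = "+", target_seq = canon_dna(seqs[i]),
                              mature_span = c(starts[i], ends[i]),
                              mature_read_id = NA_character_,
                              mature_count = 1L, mode = "benchmark",
                              flank = flank, temperature = 25)
      v <- evaluate_candidate(cand, thresholds, reg)
      data.frame(id = cand$est_id, class = cls, pass = v$pass,
                 first_fail = ifelse(is.na(v$first_fail), "",
                                     v$first_fail),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  pos <- eval_one(positives$sequence, positives$mature_start,
                  positives$mature_end, "pos")
  shuffled <- vapply(seq_len(nrow(positives)), function(i)
    shuffle_preserving_composition(canon_dna(positives$sequence[i]),
                                   seed + i), character(1))
  neg <- eval_one(shuffled, positives$mature_start, positives$mature_end,
                  "neg")
  audit <- rbind(pos, neg)
  list(sensitivity = mean(pos$pass),
       specificity = mean(!neg$pass),
       audit = audit)
}
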