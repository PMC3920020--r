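# Novel miRNA identification: perfect placements of unannotated reads on
# non-coding ESTs, the full precursor filter cascade, and mandatory
# miRNA-star read evidence in the libraries.

#' Generate and filter novel-miRNA precursor candidates
#'
#' Reads classified `unmatched` or `noncoding_est` are placed on non-coding
#' ESTs (perfect matches only) and run through the precursor filter cascade.
#'
#' @param unmatched_reads `unique_reads` subset to consider (the caller
#'   selects the unmatched/non-coding reads).
#' @param noncoding_ests data.frame (`id`, `sequence`).
#' @param thresholds a [filter_thresholds()].
#' @param reg an `mfe_regression` (builtin backend).
#' @param mature_len_range allowed mature length range (default 20-24 nt).
#' @param flank trim flank.
#' @return list of passing `precursor_candidate`s (verdict attached as
#'   attribute `verdict`).
#' @export
find_novel_candidates <- function(unmatched_reads, noncoding_ests,
                                  thresholds = filter_thresholds(), reg,
                                  mature_len_range = c(20L, 24L),
                                  flank = 10L) {
  len <- nchar(unmatched_reads$sequence)
  sel <- len >= mature_len_range[1] & len <= mature_len_range[2]
  mature_set <- data.frame(read_id = unmatched_reads$read_id[sel],
                           sequence = unmatched_reads$sequence[sel],
                           count = unmatched_reads$total[sel],
                           stringsAsFactors = FALSE)
  if (nrow(mature_set) == 0) return(list())
  cands <- generate_candidates(mature_set, noncoding_ests, mode = "novel",
                               flank = flank)
  out <- list()
  for (cand in cands) {
    v <- evaluate_candidate(cand, thresholds, reg)
    if (v$pass) {
      attr(cand, "verdict") <- v
      out[[length(out) + 1]] <- cand
    }
  }
  out
}

#' Search the libraries for miRNA-star read evidence of a candidate
#'
#' Derives the star span of the candidate's duplex and looks for a library
#' read exactly equal to the star sequence, or (with `max_star_shift` > 0)
#' equal to the star span extended/shortened by up to that many nt at either
#' end. The highest-total-count matching read wins.
#'
#' @param candidate a passing `precursor_candidate`.
#' @param reads the post-filter `unique_reads` set.
#' @param max_star_shift per-end coordinate tolerance (default 0 = exact).
#' @return list(read_id, sequence, total, star_span) or NULL.
#' @export
star_evidence <- function(candidate, reads, max_star_shift = 0L) {
  if (is.null(candidate$duplex)) return(NULL)
  star <- candidate$duplex$star
  seqlen <- nchar(candidate$trimmed_sequence)
  shifts <- -max_star_shift:max_star_shift
  best <- NULL
  for (d1 in shifts) for (d2 in shifts) {
    s <- star[1] + d1; e <- star[2] + d2
    if (s < 1 || e > seqlen || s >= e) next
    star_seq <- substr(candidate$trimmed_sequence, s, e)
    hit <- which(reads$sequence == star_seq)
    for (h in hit) {
      if (is.null(best) || reads$total[h] > best$total)
        best <- list(read_id = reads$read_id[h],
                     sequence = reads$sequence[h],
                     total = reads$total[h], star_span = c(s, e))
    }
  }
  best
}

#' Call novel miRNAs: filtered candidates with mandatory star evidence
#'
#' @param unmatched_reads `unique_reads` considered as candidate matures.
#' @param all_reads the full post-filter `unique_reads` (searched for stars).
#' @param noncoding_ests data.frame (`id`, `sequence`).
#' @param thresholds,reg,mature_len_range,flank as in
#'   [find_novel_candidates()].
#' @param max_star_shift star-search tolerance.
#' @return data.frame, one row per novel miRNA: `mirna_id`, `read_id`,
#'   `arm`, `mature_sequence` (RNA), `size`, `est_id`, `precursor_length`,
#'   `mfe`, `star_read_id`, `star_sequence` (RNA), `five_prime_base`.
#' @export
call_novel_mirnas <- function(unmatched_reads, all_reads, noncoding_ests,
                              thresholds = filter_thresholds(), reg,
                              mature_len_range = c(20L, 24L), flank = 10L,
                              max_star_shift = 0L) {
  cands <- find_novel_candidates(unmatched_reads, noncoding_ests,
                                 thresholds, reg, mature_len_range, flank)
  rows <- list()
  for (cand in cands) {
    star <- star_evidence(cand, all_reads, max_star_shift)
    if (is.null(star)) next                     # Meyers-style hard filter
    arm <- candidate_arm(cand)
    mat_seq <- substr(cand$trimmed_sequence, cand$mature_span_trimmed[1],
                      cand$mature_span_trimmed[2])
    rows[[length(rows) + 1]] <- data.frame(
      read_id = cand$mature_read_id,
      arm = arm,
      mature_sequence = to_rna(mat_seq),
      size = nchar(mat_seq),
      est_id = cand$est_id, strand = cand$strand,
      precursor_length = nchar(cand$trimmed_sequence),
      mfe = cand$mfe,
      star_read_id = star$read_id,
      star_sequence = to_rna(star$sequence),
      five_prime_base = substr(to_rna(mat_seq), 1, 1),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), read_id = character(),
                      arm = character(), mature_sequence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # a perfect inverted repeat places the same read on both EST strands;
  # report one call per (read, EST) locus
  out <- out[!duplicated(out[, c("read_id", "est_id", "mature_sequence")]),
             , drop = FALSE]
  out$mirna_id <- sprintf("nov-miR%d-%s", seq_len(nrow(out)), out$arm)
  out[, c("mirna_id", setdiff(names(out), "mirna_id")), drop = FALSE]
}

# which arm of the hairpin carries the mature read?
candidate_arm <- function(cand) {
  pt <- cand$pair_table
  span <- cand$mature_span_trimmed[1]:cand$mature_span_trimmed[2]
  paired <- span[pt$partner[span] > 0]
  if (!length(paired)) return(NA_character_)
  if (mean(pt$partner[paired] > paired) >= 0.5) "5p" else "3p"
}

#' Fraction of mature miRNAs starting with uridine
#'
#' Counts distinct matures (deduplicated by read id) whose first base is
#' U (or T in DNA lettering).
#'
#' @param mirnas data.frame with `read_id` and `mature_sequence`, or a
#'   character vector of mature sequences.
#' @return c(count_U, total).
#' @export
five_prime_U_fraction <- function(mirnas) {
  if (is.data.frame(mirnas)) {
    keep <- !duplicated(mirnas$read_id)
    seqs <- mirnas$mature_sequence[keep]
  } else seqs <- mirnas
  if (!length(seqs)) return(c(count_U = 0L, total = 0L))
  first <- toupper(substr(seqs, 1, 1))
  c(count_U = sum(first %in% c("U", "T")), total = length(seqs))
}
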