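# Preprocessing ahead of annotation: 3' adapter trimming, poly-N exclusion,
# homopolymer handling, length selection, low-count filtering, contaminant
# removal. Every step partitions its input into kept + dropped (with reasons)
# so the attrition accounting is exact.

#' Preprocessing configuration
#'
#' @param adapter_3prime 3' adapter sequence (DNA or RNA lettering).
#' @param min_len,max_len post-trim insert length range kept (gel range).
#' @param min_total_count unique reads with a total count below this are
#'   removed (low-count filter).
#' @param min_adapter_overlap minimum exact read-suffix / adapter-prefix
#'   overlap for trimming.
#' @param max_tail_run trailing single-nucleotide runs longer than this are
#'   trimmed off the 3' end.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(adapter_3prime = "TCGTATGCCGTCTTCTGCTTG",
                              min_len = 18L, max_len = 30L,
                              min_total_count = 4L,
                              min_adapter_overlap = 6L,
                              max_tail_run = 8L) {
  stopifnot(min_len <= max_len, min_total_count >= 1, min_adapter_overlap >= 1)
  structure(list(adapter_3prime = canon_dna(adapter_3prime),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_total_count = as.integer(min_total_count),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_tail_run = as.integer(max_tail_run)),
            class = "preprocess_config")
}

#' Trim an exact 3' adapter match from a read
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, provided the overlap is at least `min_overlap`; unchanged
#' otherwise. If the adapter prefix occurs inside the read (full adapter
#' start within the read), everything from that point on is removed.
#'
#' @param read read sequence.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum overlap length.
#' @return trimmed read (possibly unchanged, possibly empty).
#' @export
trim_adapter <- function(read, adapter, min_overlap = 6L) {
  if (nchar(adapter) == 0) stop("adapter must be non-empty")
  read <- canon_dna(read); adapter <- canon_dna(adapter)
  n <- nchar(read)
  max_ov <- min(n, nchar(adapter))
  for (ov in rev(seq_len(max_ov))) {
    if (ov < min_overlap) break
    if (substr(read, n - ov + 1, n) == substr(adapter, 1, ov))
      return(substr(read, 1, n - ov))
  }
  read
}

#' Drop or trim reads with poly-N segments or homopolymer runs
#'
#' Reads containing any N are dropped (`poly_N`); reads that are one repeated
#' base are dropped (`homopolymer`); a trailing single-base run longer than
#' `cfg$max_tail_run` is trimmed.
#'
#' @param read read sequence (post adapter trimming).
#' @param cfg a [preprocess_config()].
#' @return list with `keep` (logical), `sequence` (if kept) and `reason`
#'   (if dropped).
#' @export
drop_polyN_and_homopolymers <- function(read, cfg = preprocess_config()) {
  read <- canon_dna(read)
  if (grepl("N", read, fixed = TRUE))
    return(list(keep = FALSE, reason = "poly_N"))
  if (nchar(read) > 0 && grepl("^(.)\\1*$", read))
    return(list(keep = FALSE, reason = "homopolymer"))
  m <- regmatches(read, regexpr("(.)\\1*$", read))[[1]]
  if (length(m) && nchar(m) > cfg$max_tail_run)
    read <- substr(read, 1, nchar(read) - nchar(m))
  if (nchar(read) > 0 && grepl("^(.)\\1*$", read))
    return(list(keep = FALSE, reason = "homopolymer"))
  list(keep = TRUE, sequence = read)
}

#' Remove unique reads below a total-count threshold
#'
#' Retains exactly the reads with `total >= min_total_count`; counts are
#' untouched. Monotone: raising the threshold never adds reads.
#'
#' @param reads a `unique_reads` data.frame.
#' @param min_total_count threshold (>= 1).
#' @return filtered `unique_reads`.
#' @export
low_count_filter <- function(reads, min_total_count = 4L) {
  stopifnot(min_total_count >= 1)
  keep <- reads$total >= min_total_count
  as_unique_reads(reads[keep, , drop = FALSE], read_libraries(reads))
}

#' Remove reads matching contaminant references exactly
#'
#' A read is removed iff its full-length sequence occurs exactly (100%
#' identity over the whole read) as a substring of any contaminant reference,
#' on either strand. Removal is not strand-specific.
#'
#' @param reads a `unique_reads` data.frame.
#' @param refs a reference set data.frame (columns `id`, `sequence`), e.g.
#'   from [reference_set()] with kind `"contaminant"`.
#' @return list with `kept` (`unique_reads`) and `removed` (data.frame with
#'   `read_id`, `sequence`, `ref_id`).
#' @export
remove_contaminants <- function(reads, refs) {
  if (nrow(refs) == 0) stop("contaminant reference set is empty")
  ref_seqs <- canon_dna(refs$sequence)
  both <- c(ref_seqs, revcomp(ref_seqs))
  ref_ids <- rep(refs$id, 2)
  hit_ref <- rep(NA_character_, nrow(reads))
  for (k in seq_along(both)) {
    todo <- is.na(hit_ref)
    if (!any(todo)) break
    hit <- grepl_fixed_vec(reads$sequence[todo], both[k])
    hit_ref[todo][hit] <- ref_ids[k]
  }
  removed <- !is.na(hit_ref)
  list(kept = as_unique_reads(reads[!removed, , drop = FALSE],
                              read_libraries(reads)),
       removed = data.frame(read_id = reads$read_id[removed],
                            sequence = reads$sequence[removed],
                            ref_id = hit_ref[removed],
                            stringsAsFactors = FALSE))
}

# vectorised adapter trimming: longest read-suffix / adapter-prefix exact
# overlap (>= min_overlap) removed; same contract as trim_adapter()
trim_adapter_vec <- function(reads, adapter, min_overlap) {
  if (!length(reads)) return(reads)
  n <- nchar(reads)
  done <- logical(length(reads))
  out <- reads
  max_ov <- min(nchar(adapter), max(n))
  if (max_ov < min_overlap) return(out)
  for (ov in seq(max_ov, min_overlap)) {
    idx <- !done & n >= ov
    if (!any(idx)) next
    hit <- substr(reads[idx], n[idx] - ov + 1, n[idx]) ==
      substr(adapter, 1, ov)
    w <- which(idx)[hit]
    out[w] <- substr(reads[w], 1, n[w] - ov)
    done[w] <- TRUE
  }
  out
}

# vectorised "pattern x occurs in subject" for many patterns, one subject
grepl_fixed_vec <- function(patterns, subject) {
  if (length(patterns) == 0) return(logical(0))
  vapply(patterns, function(p) grepl(p, subject, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

#' Read-length histogram of a unique-read set
#'
#' @param reads a `unique_reads` data.frame.
#' @return data.frame with `length`, `unique_count` and redundancy-weighted
#'   `total_count`, one row per observed length.
#' @export
length_histogram <- function(reads) {
  if (nrow(reads) == 0)
    return(data.frame(length = integer(), unique_count = integer(),
                      total_count = integer()))
  len <- nchar(reads$sequence)
  agg <- aggregate(cbind(unique_count = rep(1L, length(len)),
                         total_count = reads$total),
                   by = list(length = len), FUN = sum)
  agg[order(agg$length), , drop = FALSE]
}

#' Run the full preprocessing stage on raw per-library reads
#'
#' Order: adapter trim, poly-N / homopolymer policy, length selection,
#' collapse to unique reads, low-count filter, contaminant removal.
#'
#' @param reads_per_library named list: library -> character vector of raw
#'   read sequences.
#' @param cfg a [preprocess_config()].
#' @param contaminants optional contaminant reference set data.frame.
#' @return list: `reads` (`unique_reads` after all filters), `audit`
#'   (per-stage unique/total counts), `dropped` (drop-reason table),
#'   `contaminant_hits`.
#' @export
preprocess_libraries <- function(reads_per_library, cfg = preprocess_config(),
                                 contaminants = NULL) {
  trimmed <- lapply(reads_per_library, function(rs) {
    rs <- trim_adapter_vec(canon_dna(rs), cfg$adapter_3prime,
                           cfg$min_adapter_overlap)
    reasons <- rep(NA_character_, length(rs))
    reasons[grepl("N", rs, fixed = TRUE)] <- "poly_N"
    homo <- is.na(reasons) & nchar(rs) > 0 & grepl("^(.)\\1*$", rs)
    reasons[homo] <- "homopolymer"
    # trim trailing mononucleotide runs longer than the configured cap
    todo <- is.na(reasons)
    m <- regexpr("(.)\\1*$", rs[todo])
    runlen <- attr(m, "match.length")
    cut <- runlen > cfg$max_tail_run
    rs[todo][cut] <- substr(rs[todo][cut], 1,
                            nchar(rs[todo][cut]) - runlen[cut])
    homo2 <- is.na(reasons) & nchar(rs) > 0 & grepl("^(.)\\1*$", rs)
    reasons[homo2] <- "homopolymer"
    n <- nchar(rs)
    reasons[is.na(reasons) & (n < cfg$min_len | n > cfg$max_len)] <- "length"
    list(kept = rs[is.na(reasons)], reasons = reasons[!is.na(reasons)])
  })
  dropped <- data.frame(
    library = rep(names(trimmed), vapply(trimmed, function(x)
      length(x$reasons), integer(1))),
    reason = unlist(lapply(trimmed, `[[`, "reasons"), use.names = FALSE),
    stringsAsFactors = FALSE)
  collapsed <- collapse_reads(lapply(trimmed, `[[`, "kept"))
  audit <- data.frame(stage = "collapsed",
                      unique = nrow(collapsed), total = sum(collapsed$total))
  filtered <- low_count_filter(collapsed, cfg$min_total_count)
  audit <- rbind(audit, data.frame(stage = "low_count_filtered",
                                   unique = nrow(filtered),
                                   total = sum(filtered$total)))
  hits <- data.frame(read_id = character(), sequence = character(),
                     ref_id = character(), stringsAsFactors = FALSE)
  if (!is.null(contaminants) && nrow(contaminants) > 0) {
    dec <- remove_contaminants(filtered, contaminants)
    filtered <- dec$kept
    hits <- dec$removed
    audit <- rbind(audit, data.frame(stage = "contaminant_removed",
                                     unique = nrow(filtered),
                                     total = sum(filtered$total)))
  }
  list(reads = filtered, audit = audit, dropped = dropped,
       contaminant_hits = hits)
}
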