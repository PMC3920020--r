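# miRNA target prediction.
#
# Method 1: ungapped antisense complementarity on the transcript sense
# strand; only Watson-Crick pairs count as matches (G:U wobble = mismatch);
# a qualifying site covers miRNA positions 2-12, has alignment length > 16
# and at most 3 mismatches.
# Method 2: homology transfer through best protein-level hits to a model
# organism joined against its known target list.

WC_MATCH <- c(A = "T", C = "G", G = "C", T = "A")

#' Scan transcripts for complementarity-based miRNA target sites
#'
#' Enumerates every ungapped window: the aligned miRNA sub-interval must
#' contain positions 2-12 (1-based from the miRNA 5' end), span at least
#' `min_len` nt, and oppose the transcript with at most `max_mismatches`
#' non-Watson-Crick oppositions. Overlapping qualifying windows on one
#' transcript are merged to the best (fewest mismatches, then longest, then
#' leftmost).
#'
#' @param mirna mature miRNA sequence, 5'->3' (>= 13 nt).
#' @param transcripts data.frame (`id`, `sequence`) -- sense strands.
#' @param max_mismatches mismatch cap (default 3).
#' @param min_len minimum alignment length (default 17, i.e. "over 16").
#' @param max_mismatches_seed optional stricter cap inside positions 2-12.
#' @param mirna_id label carried into the result.
#' @return data.frame of sites: `mirna_id`, `transcript_id`, `start`, `end`
#'   (1-based transcript span), `align_length`, `mismatches`,
#'   `mirna_from`, `mirna_to`, `covers_2_12`, `mirna_align`, `site_align`,
#'   `marks`.
#' @export
complementarity_scan <- function(mirna, transcripts, max_mismatches = 3L,
                                 min_len = 17L, max_mismatches_seed = NULL,
                                 mirna_id = "miRNA") {
  mirna <- canon_dna(mirna)
  m <- nchar(mirna)
  if (m < 13) stop("miRNA too short (< 13 nt) for the positions-2-12 rule")
  mir_ch <- strsplit(mirna, "")[[1]]
  sites <- list()
  for (t in seq_len(nrow(transcripts))) {
    seq <- canon_dna(transcripts$sequence[t])
    n <- nchar(seq)
    tr_ch <- strsplit(seq, "")[[1]]
    hits <- list()
    # windows: miRNA sub-interval [a, b] with a <= 2, b >= 12, length >= min_len
    for (a in 1:2) {
      b_min <- max(12, a + min_len - 1)
      if (b_min > m) next
      for (b in b_min:m) {
        w <- b - a + 1
        if (w < min_len || w > n) next
        # transcript window opposing miRNA[a..b]: antiparallel, so miRNA
        # position a pairs the window's 3' end
        for (start in seq_len(n - w + 1)) {
          win <- tr_ch[start:(start + w - 1)]
          # reverse to oppose miRNA 5'->3'
          opp <- rev(win)
          mm_all <- WC_MATCH[mir_ch[a:b]] != opp
          # a local ungapped alignment never ends on a mismatch: trimming a
          # terminal mismatch always improves it, so such windows are not
          # reportable alignments
          if (mm_all[1] || mm_all[w]) next
          mm <- sum(mm_all)
          if (mm > max_mismatches) next
          if (!is.null(max_mismatches_seed)) {
            seedpos <- (2:12) - a + 1
            if (sum(mm_all[seedpos]) > max_mismatches_seed) next
          }
          hits[[length(hits) + 1]] <-
            list(start = start, end = start + w - 1, a = a, b = b, mm = mm)
        }
      }
    }
    if (!length(hits)) next
    merged <- merge_overlapping_hits(hits)
    for (h in merged) {
      win <- tr_ch[h$start:h$end]
      opp <- rev(win)
      mir_part <- mir_ch[h$a:h$b]
      marks <- ifelse(WC_MATCH[mir_part] == opp, "|", " ")
      sites[[length(sites) + 1]] <- data.frame(
        mirna_id = mirna_id, transcript_id = transcripts$id[t],
        start = h$start, end = h$end,
        align_length = h$end - h$start + 1L, mismatches = h$mm,
        mirna_from = h$a, mirna_to = h$b,
        covers_2_12 = h$a <= 2 && h$b >= 12,
        mirna_align = to_rna(paste(mir_part, collapse = "")),
        site_align = to_rna(paste(opp, collapse = "")),
        marks = paste(marks, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(sites))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      align_length = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, sites)
}

# keep the best window in each group of mutually overlapping hits
merge_overlapping_hits <- function(hits) {
  ord <- order(vapply(hits, function(h) as.numeric(h$start), numeric(1)))
  hits <- hits[ord]
  groups <- list()
  cur <- list(hits[[1]])
  cur_end <- hits[[1]]$end
  for (h in hits[-1]) {
    if (h$start <= cur_end) {
      cur[[length(cur) + 1]] <- h
      cur_end <- max(cur_end, h$end)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- list(h); cur_end <- h$end
    }
  }
  groups[[length(groups) + 1]] <- cur
  lapply(groups, function(g) {
    score <- vapply(g, function(h)
      h$mm * 1e6 - (h$end - h$start + 1) * 1e3 + h$start, numeric(1))
    g[[which.min(score)]]
  })
}

#' Homology-transfer target prediction
#'
#' Joins each EST's best protein-level model-organism hit (passing the
#' e-value cutoff) with a table of that organism's known miRNA targets,
#' restricted to miRNA families present in the libraries.
#'
#' @param est_besthit data.frame: `est_id`, `gene_id`, `evalue`.
#' @param known_targets data.frame: `family`, `gene_id`.
#' @param mirnas_present character vector of observed family labels.
#' @param evalue_cutoff default 1e-30.
#' @return data.frame: `est_id`, `family`, `gene_id`, `evalue`.
#' @export
homology_transfer <- function(est_besthit, known_targets, mirnas_present,
                              evalue_cutoff = 1e-30) {
  need1 <- c("est_id", "gene_id", "evalue")
  need2 <- c("family", "gene_id")
  if (!all(need1 %in% names(est_besthit)))
    stop("est_besthit must have columns: ", paste(need1, collapse = ", "))
  if (!all(need2 %in% names(known_targets)))
    stop("known_targets must have columns: ", paste(need2, collapse = ", "))
  if (any(est_besthit$evalue < 0)) stop("e-values must be >= 0")
  # best hit per EST: smallest e-value, ties by input order
  bh <- est_besthit[order(est_besthit$evalue), , drop = FALSE]
  bh <- bh[!duplicated(bh$est_id), , drop = FALSE]
  bh <- bh[bh$evalue <= evalue_cutoff, , drop = FALSE]
  hit <- merge(bh, known_targets, by = "gene_id")
  hit <- hit[hit$family %in% mirnas_present, , drop = FALSE]
  out <- hit[, c("est_id", "family", "gene_id", "evalue"), drop = FALSE]
  rownames(out) <- NULL
  out[order(out$family, out$est_id), , drop = FALSE]
}

#' Merge complementarity and homology-transfer target predictions
#'
#' @param sites data.frame from [complementarity_scan()] (needs a `family`
#'   column or `mirna_id` used as family).
#' @param transfers data.frame from [homology_transfer()].
#' @return data.frame keyed by (family, transcript) with logical `method1`,
#'   `method2` and `both` flags.
#' @export
merge_methods <- function(sites, transfers) {
  m1 <- if (nrow(sites)) {
    fam <- if ("family" %in% names(sites)) sites$family else sites$mirna_id
    unique(data.frame(family = fam, transcript_id = sites$transcript_id,
                      stringsAsFactors = FALSE))
  } else data.frame(family = character(), transcript_id = character(),
                    stringsAsFactors = FALSE)
  m2 <- if (nrow(transfers))
    unique(data.frame(family = transfers$family,
                      transcript_id = transfers$est_id,
                      stringsAsFactors = FALSE))
  else data.frame(family = character(), transcript_id = character(),
                  stringsAsFactors = FALSE)
  all <- unique(rbind(m1, m2))
  if (nrow(all) == 0) {
    all$method1 <- logical(); all$method2 <- logical(); all$both <- logical()
    return(all)
  }
  key <- function(df) paste(df$family, df$transcript_id)
  all$method1 <- key(all) %in% key(m1)
  all$method2 <- key(all) %in% key(m2)
  all$both <- all$method1 & all$method2
  rownames(all) <- NULL
  all[order(all$family, all$transcript_id), , drop = FALSE]
}

#' Detect transcripts carrying multiple target sites for one miRNA
#'
#' Reports transcripts with at least `min_sites` non-overlapping qualifying
#' sites (overlapping windows have already been merged by the scan), in
#' coordinate order -- the hallmark of TAS-like transcripts with dual
#' sites flanking an siRNA-producing region.
#'
#' @param mirna mature miRNA sequence.
#' @param transcripts data.frame (`id`, `sequence`).
#' @param min_sites minimum site count (default 2).
#' @param ... passed to [complementarity_scan()].
#' @return named list: transcript id -> site data.frame.
#' @export
detect_dual_site_transcripts <- function(mirna, transcripts, min_sites = 2L,
                                         ...) {
  sites <- complementarity_scan(mirna, transcripts, ...)
  if (!nrow(sites)) return(list())
  out <- list()
  for (id in unique(sites$transcript_id)) {
    sub <- sites[sites$transcript_id == id, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) >= min_sites) out[[id]] <- sub
  }
  out
}
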