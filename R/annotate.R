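# The fixed-order classification cascade. Every unique read that survives
# preprocessing is assigned exactly one category:
#   1. sense-perfect hit to a protein-coding EST      -> protein_coding
#   2. perfect hit to a non-coding EST (either strand) is recorded, read
#      continues through the cascade
#   3. structural-RNA hit within max_edits (gapped)   -> rRNA/tRNA/snRNA/
#                                                        snoRNA/other_sRNA
#   4. known-miRNA hit within max_mismatches (ungapped) -> miRNA (family)
#   5. read with a recorded non-coding hit and no class -> noncoding_est
#   6. otherwise                                       -> unmatched

STRUCTURAL_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "other_sRNA")
CATEGORIES <- c("protein_coding", "noncoding_est", STRUCTURAL_CLASSES,
                "miRNA", "unmatched")

#' Build a labelled reference set
#'
#' @param kind one of `"contaminant"`, `"structural_rna"`, `"known_mirna"`.
#' @param id,sequence record ids and sequences.
#' @param family family labels; required (non-empty) for structural RNA and
#'   known-miRNA sets. For structural RNA the family must be one of the five
#'   structural classes (rRNA, tRNA, snRNA, snoRNA, other_sRNA).
#' @return data.frame (`id`, `family`, `sequence`) with attribute `kind`.
#' @export
reference_set <- function(kind, id, sequence, family = NA_character_) {
  kind <- match.arg(kind, c("contaminant", "structural_rna", "known_mirna"))
  family <- rep_len(family, length(id))
  if (kind %in% c("structural_rna", "known_mirna") &&
      any(is.na(family) | family == ""))
    stop("family labels required for ", kind, " reference set")
  if (kind == "structural_rna" && !all(family %in% STRUCTURAL_CLASSES))
    stop("structural families must be one of: ",
         paste(STRUCTURAL_CLASSES, collapse = ", "))
  df <- data.frame(id = id, family = family,
                   sequence = canon_dna(sequence, id),
                   stringsAsFactors = FALSE)
  attr(df, "kind") <- kind
  df
}

#' Alignment parameters for the cascade
#'
#' Edit thresholds drive the internal exact/k-edit search; the BLAST-style
#' scores (+5/-4, word size 4 -- the miRBase web-search settings) are kept
#' only for interoperability with external tabular alignment files.
#'
#' @param max_mismatches_mirbase ungapped mismatch cap for the known-miRNA
#'   step.
#' @param max_edits_structural gaps+mismatches cap for the structural-RNA
#'   step.
#' @param match,mismatch,word_size BLAST-compatible scoring metadata.
#' @return an `align_params` list.
#' @export
align_params <- function(max_mismatches_mirbase = 3L,
                         max_edits_structural = 3L,
                         match = 5L, mismatch = -4L, word_size = 4L) {
  stopifnot(max_mismatches_mirbase >= 0, max_edits_structural >= 0)
  structure(list(max_mismatches_mirbase = as.integer(max_mismatches_mirbase),
                 max_edits_structural = as.integer(max_edits_structural),
                 match = match, mismatch = mismatch, word_size = word_size),
            class = "align_params")
}

#' Sense-strand perfect match of a read against coding ESTs
#'
#' Strand-specific: a hit requires the read to occur full-length, exactly,
#' on the stored (coding) strand. Antisense-only occurrences return no hit.
#'
#' @param read read sequence.
#' @param ests data.frame of protein-coding ESTs (`id`, `sequence`).
#' @return list(ref_id, strand, start, end) or NULL.
#' @export
match_sense_perfect <- function(read, ests) {
  read <- canon_dna(read)
  for (i in seq_len(nrow(ests))) {
    p <- regexpr(read, ests$sequence[i], fixed = TRUE)
    if (p > 0)
      return(list(ref_id = ests$id[i], strand = "+",
                  start = as.integer(p), end = as.integer(p) + nchar(read) - 1L))
  }
  NULL
}

#' Best semi-global placement of a read within a reference
#'
#' Places the full read inside `ref` (both strands), minimising edits
#' (substitutions plus indels when `gapped`, substitutions only otherwise).
#' Returns NULL unless the best placement has `edits <= max_edits`.
#'
#' @param read read sequence.
#' @param ref reference sequence.
#' @param max_edits maximum allowed edits.
#' @param gapped allow indels?
#' @param both_strands also scan the reverse complement of the reference?
#' @return list(edits, mismatches, gaps, start, end, strand) or NULL.
#'   Coordinates are 1-based on the stored strand of `ref`.
#' @export
match_with_edits <- function(read, ref, max_edits = 3L, gapped = TRUE,
                             both_strands = TRUE) {
  read <- canon_dna(read); ref <- canon_dna(ref)
  fw <- .fit_align_cpp(read, ref, gapped)
  best <- NULL
  if (!is.na(fw$edits) && fw$edits <= max_edits) {
    fw$strand <- "+"; best <- fw
  }
  if (both_strands) {
    rv <- .fit_align_cpp(read, revcomp(ref), gapped)
    if (!is.na(rv$edits) && rv$edits <= max_edits &&
        (is.null(best) || rv$edits < best$edits ||
         (rv$edits == best$edits && rv$mismatches < best$mismatches))) {
      n <- nchar(ref)
      rv$strand <- "-"
      tmp <- rv$start
      rv$start <- n - rv$end + 1L
      rv$end <- n - tmp + 1L
      best <- rv
    }
  }
  best
}

# strand-aware best placement with a precomputed reverse complement
# (avoids rebuilding the reverse complement for every read x ref pair)
fit_align_both <- function(read, ref, ref_rc, max_edits, gapped) {
  fw <- .fit_align_cpp(read, ref, gapped)
  best <- NULL
  if (!is.na(fw$edits) && fw$edits <= max_edits) { fw$strand <- "+"; best <- fw }
  rv <- .fit_align_cpp(read, ref_rc, gapped)
  if (!is.na(rv$edits) && rv$edits <= max_edits &&
      (is.null(best) || rv$edits < best$edits ||
       (rv$edits == best$edits && rv$mismatches < best$mismatches))) {
    n <- nchar(ref)
    rv$strand <- "-"
    tmp <- rv$start
    rv$start <- n - rv$end + 1L
    rv$end <- n - tmp + 1L
    best <- rv
  }
  best
}

# best hit of a read across a reference set; ties broken by fewest
# mismatches then reference order
best_ref_hit <- function(read, refs, max_edits, gapped,
                         refs_rc = revcomp(refs$sequence)) {
  best <- NULL; best_i <- NA_integer_
  for (i in seq_len(nrow(refs))) {
    h <- fit_align_both(read, refs$sequence[i], refs_rc[i],
                        max_edits = max_edits, gapped = gapped)
    if (is.null(h)) next
    if (is.null(best) || h$edits < best$edits ||
        (h$edits == best$edits && h$mismatches < best$mismatches)) {
      best <- h; best_i <- i
    }
  }
  if (is.null(best)) return(NULL)
  c(best, list(ref_id = refs$id[best_i], family = refs$family[best_i]))
}

#' Classify unique reads through the annotation cascade
#'
#' @param reads a `unique_reads` data.frame.
#' @param coding_ests,noncoding_ests EST data.frames (`id`, `sequence`).
#' @param structural_refs [reference_set()] of kind `structural_rna`.
#' @param mirna_refs [reference_set()] of kind `known_mirna`.
#' @param params an [align_params()].
#' @return data.frame with one row per read: `read_id`, `category`, `family`,
#'   `ref_id`, `strand`, `pos`, `mismatches`, `gaps`, `noncoding_hit`
#'   (id of a perfectly matching non-coding EST, or NA).
#' @export
classify_reads <- function(reads, coding_ests, noncoding_ests,
                           structural_refs, mirna_refs,
                           params = align_params()) {
  for (nm in c("coding_ests", "noncoding_ests", "structural_refs",
               "mirna_refs")) {
    obj <- get(nm)
    if (is.null(obj)) stop("missing reference set: ", nm)
  }
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id,
                    category = rep("unmatched", n),
                    family = NA_character_, ref_id = NA_character_,
                    strand = NA_character_, pos = NA_integer_,
                    mismatches = NA_integer_, gaps = NA_integer_,
                    noncoding_hit = NA_character_,
                    noncoding_strand = NA_character_,
                    noncoding_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  nc_rc <- if (nrow(noncoding_ests)) revcomp(noncoding_ests$sequence) else
    character(0)
  struct_rc <- if (nrow(structural_refs)) revcomp(structural_refs$sequence)
    else character(0)
  mirna_rc <- if (nrow(mirna_refs)) revcomp(mirna_refs$sequence) else
    character(0)
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    # 1. sense-perfect coding hit
    hit <- if (nrow(coding_ests)) match_sense_perfect(s, coding_ests) else NULL
    if (!is.null(hit)) {
      out$category[i] <- "protein_coding"
      out$ref_id[i] <- hit$ref_id; out$strand[i] <- hit$strand
      out$pos[i] <- hit$start; out$mismatches[i] <- 0L; out$gaps[i] <- 0L
      next
    }
    # 2. record perfect non-coding hit (either strand); read continues
    for (k in seq_len(nrow(noncoding_ests))) {
      p <- regexpr(s, noncoding_ests$sequence[k], fixed = TRUE)
      if (p > 0) {
        out$noncoding_hit[i] <- noncoding_ests$id[k]
        out$noncoding_strand[i] <- "+"
        out$noncoding_pos[i] <- as.integer(p)
        break
      }
      p <- regexpr(s, nc_rc[k], fixed = TRUE)
      if (p > 0) {
        out$noncoding_hit[i] <- noncoding_ests$id[k]
        out$noncoding_strand[i] <- "-"
        out$noncoding_pos[i] <-
          nchar(noncoding_ests$sequence[k]) - (as.integer(p) + nchar(s) - 1L) + 1L
        break
      }
    }
    # 3. structural RNA (gapped, <= max_edits)
    if (nrow(structural_refs)) {
      h <- best_ref_hit(s, structural_refs, params$max_edits_structural,
                        gapped = TRUE, refs_rc = struct_rc)
      if (!is.null(h)) {
        out$category[i] <- h$family   # family IS the structural class
        out$family[i] <- h$family; out$ref_id[i] <- h$ref_id
        out$strand[i] <- h$strand; out$pos[i] <- h$start
        out$mismatches[i] <- h$mismatches; out$gaps[i] <- h$gaps
        next
      }
    }
    # 4. known miRNA (ungapped, <= max mismatches)
    if (nrow(mirna_refs)) {
      h <- best_ref_hit(s, mirna_refs, params$max_mismatches_mirbase,
                        gapped = FALSE, refs_rc = mirna_rc)
      if (!is.null(h)) {
        out$category[i] <- "miRNA"
        out$family[i] <- mirna_family_label(h$family)
        out$ref_id[i] <- h$ref_id; out$strand[i] <- h$strand
        out$pos[i] <- h$start
        out$mismatches[i] <- h$mismatches; out$gaps[i] <- h$gaps
        next
      }
    }
    # 5./6. non-coding EST or unmatched
    if (!is.na(out$noncoding_hit[i])) out$category[i] <- "noncoding_est"
  }
  out
}

#' Collapse a reference miRNA name to its family label
#'
#' Strips the species prefix and trailing letter/number variants:
#' `ath-miR156a` -> `miR156`, `osa-miR156b` -> `miR156`, `miR-466` stays.
#' Unparsable names are returned as-is with a warning.
#'
#' @param name character vector of reference names (or family labels).
#' @return family labels.
#' @export
mirna_family_label <- function(name) {
  x <- sub("^[A-Za-z]{3,4}-(?=miR|MIR)", "", name, perl = TRUE)
  fam <- regmatches(x, regexpr("^(miR|MIR)-?[0-9]+", x))
  out <- character(length(x))
  ok <- vapply(seq_along(x), function(i)
    length(regmatches(x[i], regexpr("^(miR|MIR)-?[0-9]+", x[i]))) > 0,
    logical(1))
  out[ok] <- regmatches(x[ok], regexpr("^(miR|MIR)-?[0-9]+", x[ok]))
  if (any(!ok)) {
    warning("unparsable miRNA name(s): ",
            paste(unique(x[!ok]), collapse = ", "))
    out[!ok] <- x[!ok]
  }
  sub("^MIR", "miR", out)
}

#' Aggregate miRNA-annotated reads into family counts
#'
#' @param records output of [classify_reads()].
#' @param reads the `unique_reads` the records describe.
#' @param merge_map optional named character vector pooling families
#'   (e.g. `c(miR157 = "miR156")`).
#' @return data.frame: `family`, per-library total counts, per-library
#'   unique-read counts (`<lib>_unique`), and `total`.
#' @export
aggregate_families <- function(records, reads, merge_map = NULL) {
  libs <- read_libraries(reads)
  sel <- records$category == "miRNA"
  if (!any(sel))
    return(data.frame(family = character(), stringsAsFactors = FALSE))
  fam <- records$family[sel]
  if (!is.null(merge_map)) {
    m <- match(fam, names(merge_map))
    fam[!is.na(m)] <- merge_map[m[!is.na(m)]]
  }
  idx <- match(records$read_id[sel], reads$read_id)
  counts <- as.matrix(as.data.frame(reads)[idx, libs, drop = FALSE])
  totals <- rowsum(counts, fam)
  uniques <- rowsum((counts > 0) + 0L, fam)
  out <- data.frame(family = rownames(totals), stringsAsFactors = FALSE)
  for (lib in libs) out[[lib]] <- as.integer(totals[, lib])
  for (lib in libs) out[[paste0(lib, "_unique")]] <- as.integer(uniques[, lib])
  out$total <- as.integer(rowSums(totals))
  out[order(-out$total, out$family), , drop = FALSE]
}

#' Table-style category summary of an annotation
#'
#' @param records output of [classify_reads()].
#' @param reads the matching `unique_reads`.
#' @return data.frame: category x (per-library total, per-library unique).
#' @export
category_summary <- function(records, reads) {
  libs <- read_libraries(reads)
  idx <- match(records$read_id, reads$read_id)
  counts <- as.matrix(as.data.frame(reads)[idx, libs, drop = FALSE])
  cat <- factor(records$category, levels = CATEGORIES)
  totals <- rowsum(counts, cat)
  uniques <- rowsum((counts > 0) + 0L, cat)
  out <- data.frame(category = rownames(totals), stringsAsFactors = FALSE)
  for (lib in libs) {
    out[[paste0(lib, "_total")]] <- as.integer(totals[, lib])
    out[[paste0(lib, "_unique")]] <- as.integer(uniques[, lib])
  }
  out
}
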