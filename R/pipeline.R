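# End-to-end orchestration: preprocess -> annotate -> precursors -> novel
# -> targets -> expression, with per-stage attrition accounting. Outputs are
# pure functions of (inputs, config, seed).

#' Run the full small-RNA analysis pipeline
#'
#' @param reads named list of per-library raw read vectors, or a named
#'   vector of FASTQ paths.
#' @param coding_ests,noncoding_ests EST data.frames (`id`, `sequence`).
#' @param mirna_refs,structural_refs [reference_set()]s.
#' @param contaminants contaminant data.frame (`id`, `sequence`) or NULL.
#' @param preprocess a [preprocess_config()].
#' @param params an [align_params()].
#' @param thresholds a [filter_thresholds()].
#' @param reg an `mfe_regression` for the builtin backend (default
#'   [default_mfe_regression()]).
#' @param min_fold fold-change threshold for the clustering subset.
#' @param out_dir optional directory; when given, every stage table is
#'   written as TSV.
#' @return list: `reads` (post-filter `unique_reads`), `attrition`,
#'   `annotation`, `categories`, `families`, `rpm`, `spm`, `clustering`
#'   (hclust or NULL), `precursors` (candidate verdict table), `novel`,
#'   `targets`.
#' @export
run_pipeline <- function(reads, coding_ests, noncoding_ests, mirna_refs,
                         structural_refs, contaminants = NULL,
                         preprocess = preprocess_config(),
                         params = align_params(),
                         thresholds = filter_thresholds(),
                         reg = default_mfe_regression(),
                         min_fold = 4.0, out_dir = NULL) {
  if (is.character(reads))
    reads <- lapply(reads, function(p) read_sequences(p)$sequence)
  raw_totals <- vapply(reads, length, integer(1))

  pre <- preprocess_libraries(reads, preprocess, contaminants)
  ur <- pre$reads
  libs <- read_libraries(ur)

  ann <- classify_reads(ur, coding_ests, noncoding_ests, structural_refs,
                        mirna_refs, params)
  cats <- category_summary(ann, ur)
  fams <- aggregate_families(ann, ur)

  lib_totals <- setNames(vapply(libs, function(l)
    sum(as.data.frame(ur)[[l]]), numeric(1)), libs)
  rpmat <- if (nrow(fams)) rpm_matrix(fams, lib_totals) else
    matrix(numeric(0), 0, length(libs), dimnames = list(NULL, libs))
  spmat <- if (nrow(rpmat)) spm(rpmat) else rpmat
  sel <- if (nrow(rpmat) >= 2) fold_change_select(rpmat, min_fold) else rpmat
  clustering <- if (nrow(sel) >= 2) hclust_centroid(log2_rpm(sel)) else NULL

  # conserved precursors: miRNA-annotated reads placed on non-coding ESTs
  mir_rows <- ann$category == "miRNA"
  mature_set <- data.frame(read_id = ann$read_id[mir_rows],
                           sequence = ur$sequence[match(ann$read_id[mir_rows],
                                                        ur$read_id)],
                           count = ur$total[match(ann$read_id[mir_rows],
                                                  ur$read_id)],
                           stringsAsFactors = FALSE)
  prec_tab <- data.frame()
  if (nrow(mature_set)) {
    cands <- generate_candidates(mature_set, noncoding_ests,
                                 mode = "conserved_match")
    rows <- lapply(cands, function(cand) {
      v <- evaluate_candidate(cand, thresholds, reg)
      data.frame(est_id = cand$est_id, strand = cand$strand,
                 read_id = cand$mature_read_id,
                 family = ann$family[match(cand$mature_read_id,
                                           ann$read_id)],
                 mature_start = cand$mature_span[1],
                 mature_end = cand$mature_span[2],
                 precursor_length = ifelse(is.na(cand$trimmed_sequence),
                                           NA_integer_,
                                           nchar(cand$trimmed_sequence)),
                 mfe = cand$mfe, pass = v$pass,
                 first_fail = ifelse(is.na(v$first_fail), "",
                                     v$first_fail),
                 stringsAsFactors = FALSE)
    })
    prec_tab <- do.call(rbind, rows)
  }

  # novel miRNAs from unmatched / non-coding reads, star evidence mandatory
  novel_rows <- ann$category %in% c("unmatched", "noncoding_est")
  novel_reads <- as_unique_reads(
    as.data.frame(ur)[match(ann$read_id[novel_rows], ur$read_id), ,
                      drop = FALSE], libs)
  novel <- call_novel_mirnas(novel_reads, ur, noncoding_ests, thresholds,
                             reg)

  # targets of identified miRNAs on coding ESTs (method 1)
  mir_seqs <- c(
    setNames(mature_set$sequence,
             ann$family[match(mature_set$read_id, ann$read_id)]),
    if (nrow(novel)) setNames(chartr("Uu", "Tt", novel$mature_sequence),
                              novel$mirna_id) else character(0))
  mir_seqs <- mir_seqs[!duplicated(mir_seqs)]
  targets <- do.call(rbind, c(
    list(complementarity_scan("AAAAAAAAAAAAAAAAAAAAA",
                              coding_ests[0, , drop = FALSE])),
    lapply(seq_along(mir_seqs), function(i)
      complementarity_scan(mir_seqs[i], coding_ests,
                           mirna_id = names(mir_seqs)[i]))))

  attrition <- rbind(
    data.frame(stage = "raw", unique = NA_integer_,
               total = sum(raw_totals)),
    pre$audit)

  out <- list(reads = ur, attrition = attrition, annotation = ann,
              categories = cats, families = fams, rpm = rpmat, spm = spmat,
              clustering = clustering, precursors = prec_tab, novel = novel,
              targets = targets, library_totals = lib_totals)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(as.data.frame(df), file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(out$attrition, "attrition.tsv")
  wt(out$annotation, "annotation.tsv")
  wt(out$categories, "categories.tsv")
  wt(out$families, "families.tsv")
  if (nrow(out$rpm)) {
    wt(data.frame(family = rownames(out$rpm), out$rpm), "family_rpm.tsv")
    wt(data.frame(family = rownames(out$spm), out$spm), "family_spm.tsv")
  }
  if (nrow(out$precursors)) wt(out$precursors, "precursors.tsv")
  if (nrow(out$novel)) wt(out$novel, "novel_mirnas.tsv")
  if (nrow(out$targets)) wt(out$targets, "targets.tsv")
  write_count_matrix(out$reads, file.path(out_dir, "unique_reads.tsv"))
  if (!is.null(out$clustering) &&
      requireNamespace("ape", quietly = TRUE)) {
    writeLines(dendrogram_newick(out$clustering),
               file.path(out_dir, "dendrogram.nwk"))
  }
  invisible(out_dir)
}
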