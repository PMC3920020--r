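# Core sequence I/O and read collapsing.
#
# Internal canonical alphabet is DNA (A/C/G/T/N): U is accepted on input and
# converted to T; RNA-facing reports convert back with to_rna(). Coordinates
# are 1-based inclusive everywhere a user sees them.

#' Canonicalise a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Any character outside A/C/G/T/N is an
#' error naming the offending record.
#'
#' @param x character vector of sequences.
#' @param ids optional record ids used in error messages.
#' @return character vector over A/C/G/T/N.
#' @export
canon_dna <- function(x, ids = NULL) {
  out <- chartr("u", "t", x)
  out <- toupper(out)
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    stop("illegal character in sequence of record ", lab)
  }
  out
}

#' Convert a DNA-canonical sequence to RNA lettering (T -> U)
#' @param x character vector.
#' @return character vector with U in place of T.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

#' Reverse complement (DNA alphabet, N self-complementary)
#' @param x character vector of sequences.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Thin wrapper over Biostrings that returns plain (id, sequence) records in
#' file order, with sequences canonicalised to the internal DNA alphabet
#' (U stored as T, N retained).
#'
#' @param path file path.
#' @param format `"FASTA"` or `"FASTQ"` (case-insensitive). Defaults from the
#'   file extension (`.fq`/`.fastq` imply FASTQ).
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "FASTQ" else "FASTA"
  }
  format <- toupper(format)
  if (!format %in% c("FASTA", "FASTQ")) stop("unknown format: ", format)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = tolower(format)),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (length(seqs) == 0)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  data.frame(id = ids, sequence = canon_dna(seqs, ids),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse raw reads into unique reads with per-library counts
#'
#' Identical full-length sequences are merged into one unique read; reads
#' differing in even one nucleotide (or in length) stay distinct. Counts are
#' recorded per library and summed into `total`.
#'
#' @param reads_per_library named list: library name -> character vector of
#'   read sequences.
#' @return a `unique_reads` data.frame with columns `read_id`, `sequence`,
#'   one integer column per library, and `total`; ordered by decreasing total
#'   then sequence, with deterministic ids `sr000001, ...`.
#' @export
collapse_reads <- function(reads_per_library) {
  libs <- names(reads_per_library)
  if (anyDuplicated(libs)) stop("library names must be distinct")
  if (length(libs) == 0)
    return(as_unique_reads(data.frame(read_id = character(),
                                      sequence = character(),
                                      total = integer(),
                                      stringsAsFactors = FALSE),
                           character()))
  seqs <- unique(unlist(lapply(reads_per_library, canon_dna), use.names = FALSE))
  if (is.null(seqs)) seqs <- character()
  counts <- matrix(0L, nrow = length(seqs), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (lib in libs) {
    tab <- table(canon_dna(reads_per_library[[lib]]))
    if (length(tab)) counts[match(names(tab), seqs), lib] <- as.integer(tab)
  }
  total <- as.integer(rowSums(counts))
  ord <- order(-total, seqs)
  df <- data.frame(read_id = sprintf("sr%06d", seq_along(seqs)),
                   sequence = seqs[ord], stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts[ord, , drop = FALSE]))
  df$total <- total[ord]
  as_unique_reads(df, libs)
}

#' Mark a data.frame as a unique-read set
#' @param df data.frame with `read_id`, `sequence`, per-library counts, `total`.
#' @param libraries library column names.
#' @return the same data.frame with class `unique_reads`.
#' @export
as_unique_reads <- function(df, libraries) {
  stopifnot(all(c("read_id", "sequence", "total", libraries) %in% names(df)))
  if (anyDuplicated(df$sequence)) stop("duplicate sequences in unique-read set")
  rownames(df) <- NULL
  attr(df, "libraries") <- libraries
  class(df) <- c("unique_reads", "data.frame")
  df
}

#' Library column names of a unique-read set
#' @param reads a `unique_reads` data.frame.
#' @return character vector of library names.
#' @export
read_libraries <- function(reads) attr(reads, "libraries")

#' Write a unique-read count matrix as TSV
#'
#' Columns: read_id, sequence, one integer column per library, total.
#' `read_count_matrix()` reproduces the set exactly (round-trip identity).
#'
#' @param reads a `unique_reads` data.frame.
#' @param path output file.
#' @export
write_count_matrix <- function(reads, path) {
  if (length(read_libraries(reads)) == 0) stop("no libraries in read set")
  write.table(as.data.frame(reads), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @return `read_count_matrix()` returns the `unique_reads` data.frame.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = NA)
  need <- c("read_id", "sequence", "total")
  if (!all(need %in% names(df))) stop("count matrix missing columns")
  libs <- setdiff(names(df), need)
  if (length(libs) == 0) stop("count matrix has no library columns")
  for (lib in c(libs, "total")) df[[lib]] <- as.integer(df[[lib]])
  if (anyDuplicated(df$sequence)) stop("duplicate sequence rows in count matrix")
  as_unique_reads(df, libs)
}

#' Write records to a FASTA file
#' @param ids record ids.
#' @param seqs sequences.
#' @param path output file.
#' @param rna if TRUE, write RNA lettering (T -> U).
#' @export
write_fasta <- function(ids, seqs, path, rna = FALSE) {
  if (rna) seqs <- to_rna(seqs)
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
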