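# Deterministic synthetic-data generator.
#
# Emulates the study design: four strand-specific tissue libraries (root,
# leaf, flower, seed) of 18-30 nt inserts sequenced with a 3' adapter, drawn
# from ESTs that carry implanted miRNA hairpins, plus degraded-mRNA,
# structural-RNA, contaminant and noise reads. Every dataset is a pure
# function of its config (seed included) and ships its own truth table.

SIM_LIBRARIES <- c("root", "leaf", "flower", "seed")

# run code under a local, seeded RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions at test scale: four tissue
#' libraries, 18-30 nt gel window, total-count filter at 4, log-normal
#' abundance with strong tissue multipliers (reproducing the several-orders-
#' of-magnitude RPM spread of real family tables).
#'
#' @param seed master seed; every derived quantity is a function of it.
#' @param n_coding_ests,n_noncoding_ests plain EST counts.
#' @param n_conserved,n_novel implanted hairpin counts by provenance.
#' @param n_decoys composition-preserving shuffles of implanted hairpin ESTs
#'   added as additional non-coding ESTs.
#' @param mature_len mature miRNA length (nt).
#' @param loop_range,ext_range hairpin terminal-loop and arm-extension size
#'   ranges (nt).
#' @param flank_range random flank length range around the hairpin (nt).
#' @param est_len_range plain EST length range (nt).
#' @param base_count median per-library count of an implanted miRNA.
#' @param abundance_sdlog log-normal spread of counts.
#' @param tissue_boost multiplier applied in an entity's home tissue.
#' @param min_implant_count guaranteed minimum total count for implanted
#'   mature and star reads (the expression-evidence floor).
#' @param n_background_reads per-library count of degraded/structural/noise
#'   reads.
#' @param contaminant_fraction fraction of background reads drawn from the
#'   contaminant genome.
#' @param substitution_error_rate per-base substitution probability.
#' @param adapter 3' adapter appended to inserts.
#' @param read_length emitted read length (insert + adapter prefix).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_coding_ests = 6L, n_noncoding_ests = 6L,
                       n_conserved = 4L, n_novel = 4L, n_decoys = 3L,
                       mature_len = 21L,
                       loop_range = c(6L, 12L), ext_range = c(4L, 8L),
                       flank_range = c(12L, 25L),
                       est_len_range = c(150L, 400L),
                       base_count = 20, abundance_sdlog = 1.0,
                       tissue_boost = 50,
                       min_implant_count = 4L,
                       n_background_reads = 300L,
                       contaminant_fraction = 0.05,
                       substitution_error_rate = 0.001,
                       adapter = "TCGTATGCCGTCTTCTGCTTG",
                       read_length = 36L) {
  stopifnot(contaminant_fraction >= 0, contaminant_fraction <= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Construct an EST with an implanted miRNA hairpin
#'
#' Builds flank5 + (ext5 | mature | ext3) + loop + revcomp(arm5) + flank3: a
#' perfect stem whose 5' arm carries the mature. The builtin folder is used
#' to verify that the designed duplex forms, the core locates cleanly and
#' (when `reg` is given) the trimmed candidate passes the full filter
#' cascade; flanks and loop are re-drawn (deterministically) until
#' verification succeeds.
#'
#' @param mature mature sequence (20-24 nt).
#' @param seed integer seed.
#' @param loop_len terminal loop size (>= 4).
#' @param ext5,ext3 extra stem base pairs beyond the mature on each side.
#' @param flank5,flank3 unstructured flank lengths.
#' @param thresholds,reg optional filter cascade to verify against.
#' @param max_tries redraw budget.
#' @return list: `sequence`, `mature_span`, `star_span`, `star_sequence`
#'   (spans on the EST, 1-based; star from the builtin fold of the EST),
#'   `hairpin_span`.
#' @export
make_hairpin_est <- function(mature, seed, loop_len = 8L, ext5 = 5L,
                             ext3 = 5L, flank5 = 15L, flank3 = 15L,
                             thresholds = NULL, reg = NULL,
                             max_tries = 200L) {
  mature <- canon_dna(mature)
  if (nchar(mature) < 20 || nchar(mature) > 24)
    stop("mature length must be 20-24 nt")
  if (loop_len < 3) stop("impossible geometry: loop < 3 nt")
  for (try in seq_len(max_tries)) {
    built <- with_seed(seed * 1000L + try, {
      arm5 <- paste0(random_dna(ext5), mature, random_dna(ext3))
      loop <- random_dna(loop_len)
      est <- paste0(random_dna(flank5), arm5, loop, revcomp(arm5),
                    random_dna(flank3))
      mstart <- flank5 + ext5 + 1L
      list(est = est, mature_span = c(mstart, mstart + nchar(mature) - 1L),
           hairpin_span = c(flank5 + 1L,
                            flank5 + 2L * nchar(arm5) + loop_len))
    })
    ok <- tryCatch({
      pt <- fold(built$est)
      core <- locate_core(pt, built$mature_span)
      if (isTRUE(core$rejected)) stop("core in loop")
      dup <- derive_star(pt, built$mature_span)
      if (!is.null(thresholds)) {
        if (is.null(reg)) stop("reg required when thresholds given")
        cand <- build_candidate("est", "+", built$est, built$mature_span,
                                NA_character_, 1L, "synthetic", 10L, 25)
        v <- evaluate_candidate(cand, thresholds, reg)
        if (!v$pass) stop("candidate fails: ", v$first_fail)
        dup_t <- cand$duplex
        star_seq <- substr(cand$trimmed_sequence, dup_t$star[1],
                           dup_t$star[2])
        star_span <- dup_t$star + cand$trimmed_span[1] - 1L
      } else {
        star_seq <- dup$star_sequence
        star_span <- dup$star
      }
      list(sequence = built$est, mature_span = built$mature_span,
           star_span = star_span, star_sequence = star_seq,
           hairpin_span = built$hairpin_span)
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
  stop("could not build a verifiable hairpin EST in ", max_tries, " tries")
}

#' Training hairpins for the MFE regression
#'
#' Generates clean stem-loops across a range of lengths, folds each with the
#' builtin backend and returns the (length, mfe) table used to train the
#' prediction-interval filter. Training and scoring thereby share a backend.
#'
#' @param n number of hairpins.
#' @param seed integer seed.
#' @param arm_range stem arm length range (nt).
#' @param loop_range terminal loop range (nt).
#' @param flank flank length added each side (mirrors trimmed candidates).
#' @return data.frame `length`, `mfe`.
#' @export
mfe_training_hairpins <- function(n = 60L, seed = 42L,
                                  arm_range = c(18L, 45L),
                                  loop_range = c(4L, 15L), flank = 10L) {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      arm_len <- sample(arm_range[1]:arm_range[2], 1)
      loop_len <- sample(loop_range[1]:loop_range[2], 1)
      # GC varies across hairpins so the interval reflects the real
      # composition-driven spread of stem energies at a given length
      arm <- random_dna(arm_len, gc = runif(1, 0.35, 0.65))
      seqn <- paste0(random_dna(flank), arm, random_dna(loop_len),
                     revcomp(arm), random_dna(flank))
      pt <- fold(seqn)
      data.frame(length = nchar(seqn), mfe = pt$mfe)
    })
    do.call(rbind, rows)
  })
}

#' Default prediction-interval regression for the builtin fold backend
#' @param seed training-set seed (default 42).
#' @param n training hairpins (default 60).
#' @return an `mfe_regression` (backend `"builtin"`).
#' @export
default_mfe_regression <- function(seed = 42L, n = 60L) {
  fit_mfe_regression(mfe_training_hairpins(n = n, seed = seed),
                     backend = "builtin")
}

#' Simulate a complete study dataset
#'
#' Builds reference sets (known miRNAs, structural RNAs, a contaminant
#' genome), coding and non-coding ESTs with implanted conserved and novel
#' miRNA hairpins, shuffled decoy ESTs, and four tissue read libraries, all
#' deterministically from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param reg optional `mfe_regression` used to verify that implanted
#'   hairpins pass the filter cascade (defaults to
#'   [default_mfe_regression()]).
#' @return list: `coding_ests`, `noncoding_ests`, `mirna_refs`,
#'   `structural_refs`, `contaminants`, `raw_reads` (named list of
#'   per-library read vectors, adapters appended), `truth` (implant table),
#'   `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), reg = NULL) {
  if (is.null(reg)) reg <- default_mfe_regression()
  thr <- filter_thresholds()
  n_implants <- cfg$n_conserved + cfg$n_novel

  refs <- with_seed(cfg$seed + 1L, {
    # known-miRNA reference: conserved matures (5' U bias) + extra families;
    # realized mature GC is kept in the mid band ([1/3, 2/3], as for the
    # regression training population) so implanted stems share the
    # training energy-length relation
    draw_mature <- function() {
      repeat {
        s <- paste0(if (runif(1) < 0.8) "T" else sample(c("A", "C", "G"), 1),
                    random_dna(cfg$mature_len - 1L))
        gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
        if (gc >= 1 / 3 && gc <= 2 / 3) return(s)
      }
    }
    matures <- vapply(seq_len(n_implants), function(i) draw_mature(),
                      character(1))
    extra <- vapply(seq_len(4), function(i)
      paste0("T", random_dna(cfg$mature_len - 1L)), character(1))
    mirna_refs <- reference_set(
      "known_mirna",
      id = c(sprintf("ath-miR%d%s", 150 + seq_len(cfg$n_conserved), "a"),
             sprintf("osa-miR%d", 800 + seq_len(4))),
      sequence = c(matures[seq_len(cfg$n_conserved)], extra),
      family = c(sprintf("miR%d", 150 + seq_len(cfg$n_conserved)),
                 sprintf("miR%d", 800 + seq_len(4))))
    structural_refs <- reference_set(
      "structural_rna",
      id = c("rRNA_5S", "tRNA_Ala", "snoRNA_U3"),
      sequence = c(random_dna(220), random_dna(180), random_dna(160)),
      family = c("rRNA", "tRNA", "snoRNA"))
    contaminants <- data.frame(id = "chloroplast_frag",
                               sequence = random_dna(1500),
                               stringsAsFactors = FALSE)
    list(matures = matures, mirna_refs = mirna_refs,
         structural_refs = structural_refs, contaminants = contaminants)
  })

  # implanted hairpin ESTs (conserved first, then novel)
  implants <- lapply(seq_len(n_implants), function(i) {
    geom <- with_seed(cfg$seed + 100L + i, list(
      loop = sample(cfg$loop_range[1]:cfg$loop_range[2], 1),
      ext5 = sample(cfg$ext_range[1]:cfg$ext_range[2], 1),
      ext3 = sample(cfg$ext_range[1]:cfg$ext_range[2], 1),
      fl5 = sample(cfg$flank_range[1]:cfg$flank_range[2], 1),
      fl3 = sample(cfg$flank_range[1]:cfg$flank_range[2], 1)))
    hp <- make_hairpin_est(refs$matures[i], seed = cfg$seed + 200L + i,
                           loop_len = geom$loop, ext5 = geom$ext5,
                           ext3 = geom$ext3, flank5 = geom$fl5,
                           flank3 = geom$fl3, thresholds = thr, reg = reg)
    hp
  })

  plain <- with_seed(cfg$seed + 2L, {
    coding <- data.frame(
      id = sprintf("PC%05d", seq_len(cfg$n_coding_ests)),
      sequence = vapply(seq_len(cfg$n_coding_ests), function(i)
        random_dna(sample(cfg$est_len_range[1]:cfg$est_len_range[2], 1)),
        character(1)),
      stringsAsFactors = FALSE)
    noncoding_plain <- vapply(seq_len(cfg$n_noncoding_ests), function(i)
      random_dna(sample(cfg$est_len_range[1]:cfg$est_len_range[2], 1)),
      character(1))
    list(coding = coding, noncoding_plain = noncoding_plain)
  })

  decoys <- vapply(seq_len(cfg$n_decoys), function(i)
    shuffle_preserving_composition(
      implants[[((i - 1L) %% n_implants) + 1L]]$sequence,
      cfg$seed + 300L + i), character(1))

  noncoding_ests <- data.frame(
    id = c(sprintf("NC%05d", seq_along(plain$noncoding_plain)),
           sprintf("HP%05d", seq_len(n_implants)),
           sprintf("DC%05d", seq_along(decoys))),
    sequence = c(plain$noncoding_plain,
                 vapply(implants, `[[`, character(1), "sequence"),
                 decoys),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    implant_id = sprintf("impl%02d", seq_len(n_implants)),
    provenance = rep(c("conserved", "novel"),
                     c(cfg$n_conserved, cfg$n_novel)),
    family = c(sprintf("miR%d", 150 + seq_len(cfg$n_conserved)),
               rep(NA_character_, cfg$n_novel)),
    est_id = sprintf("HP%05d", seq_len(n_implants)),
    mature_sequence = vapply(implants, function(h)
      substr(h$sequence, h$mature_span[1], h$mature_span[2]), character(1)),
    star_sequence = vapply(implants, `[[`, character(1), "star_sequence"),
    mature_start = vapply(implants, function(h) h$mature_span[1], integer(1)),
    mature_end = vapply(implants, function(h) h$mature_span[2], integer(1)),
    home_tissue = SIM_LIBRARIES[((seq_len(n_implants) - 1L) %% 4L) + 1L],
    stringsAsFactors = FALSE)

  libs <- make_read_libraries(cfg, truth,
                              coding_ests = plain$coding,
                              structural_refs = refs$structural_refs,
                              contaminants = refs$contaminants,
                              decoy_ests = noncoding_ests[
                                startsWith(noncoding_ests$id, "DC"), ,
                                drop = FALSE])

  list(coding_ests = plain$coding, noncoding_ests = noncoding_ests,
       mirna_refs = refs$mirna_refs, structural_refs = refs$structural_refs,
       contaminants = refs$contaminants,
       raw_reads = libs$raw_reads, truth = cbind(truth, libs$truth_counts),
       config = cfg)
}

#' Sample per-library reads for a simulated dataset
#'
#' Counts for implanted matures and stars follow a log-normal abundance
#' model with a home-tissue multiplier and a guaranteed minimum total;
#' background reads are degraded coding-EST fragments, structural-RNA
#' fragments, contaminant fragments, decoy-locus reads and random noise.
#' Substitution errors are injected at the configured rate, and the adapter
#' is appended (reads padded to `cfg$read_length`).
#'
#' @param cfg a [sim_config()].
#' @param truth implant truth table (see [simulate_dataset()]).
#' @param coding_ests,structural_refs,contaminants,decoy_ests reference
#'   tables the background reads are drawn from.
#' @return list: `raw_reads` (named list per library), `truth_counts`
#'   (per-library true mature/star count columns).
#' @export
make_read_libraries <- function(cfg, truth, coding_ests, structural_refs,
                                contaminants, decoy_ests) {
  with_seed(cfg$seed + 3L, {
    raw <- setNames(vector("list", length(SIM_LIBRARIES)), SIM_LIBRARIES)
    for (lib in SIM_LIBRARIES) raw[[lib]] <- character(0)

    draw_counts <- function(home) {
      cts <- round(rlnorm(4, meanlog = log(cfg$base_count),
                          sdlog = cfg$abundance_sdlog))
      cts[SIM_LIBRARIES == home] <- cts[SIM_LIBRARIES == home] *
        cfg$tissue_boost
      cts <- pmax(cts, 0)
      if (sum(cts) < cfg$min_implant_count) {
        deficit <- cfg$min_implant_count - sum(cts)
        cts[SIM_LIBRARIES == home] <- cts[SIM_LIBRARIES == home] + deficit
      }
      as.integer(cts)
    }

    n_imp <- nrow(truth)
    mature_counts <- matrix(0L, n_imp, 4,
                            dimnames = list(NULL, SIM_LIBRARIES))
    star_counts <- mature_counts
    for (i in seq_len(n_imp)) {
      mature_counts[i, ] <- draw_counts(truth$home_tissue[i])
      sc <- round(draw_counts(truth$home_tissue[i]) * 0.2)
      if (sum(sc) < cfg$min_implant_count)
        sc[SIM_LIBRARIES == truth$home_tissue[i]] <-
          sc[SIM_LIBRARIES == truth$home_tissue[i]] +
          (cfg$min_implant_count - sum(sc))
      star_counts[i, ] <- as.integer(sc)
      for (lib in SIM_LIBRARIES) {
        raw[[lib]] <- c(raw[[lib]],
                        rep(truth$mature_sequence[i], mature_counts[i, lib]),
                        rep(truth$star_sequence[i], star_counts[i, lib]))
      }
    }

    frag <- function(seqs, k) {
      src <- seqs[sample.int(length(seqs), k, replace = TRUE)]
      vapply(src, function(s) {
        len <- sample(18:28, 1)
        if (nchar(s) <= len) return(s)
        st <- sample.int(nchar(s) - len, 1)
        substr(s, st, st + len - 1L)
      }, character(1), USE.NAMES = FALSE)
    }

    for (lib in SIM_LIBRARIES) {
      n_bg <- cfg$n_background_reads
      n_cont <- rbinom(1, n_bg, cfg$contaminant_fraction)
      n_rest <- n_bg - n_cont
      n_deg <- round(n_rest * 0.45)
      n_struct <- round(n_rest * 0.35)
      n_decoy <- round(n_rest * 0.10)
      n_noise <- n_rest - n_deg - n_struct - n_decoy
      bg <- c(
        frag(coding_ests$sequence, n_deg),
        frag(structural_refs$sequence, n_struct),
        # contaminant fragments come from either strand
        vapply(frag(contaminants$sequence, n_cont), function(s)
          if (runif(1) < 0.5) revcomp(s) else s, character(1),
          USE.NAMES = FALSE),
        if (nrow(decoy_ests)) frag(decoy_ests$sequence, n_decoy)
        else character(0),
        vapply(seq_len(n_noise), function(i) random_dna(sample(18:28, 1)),
               character(1)))
      # background fragments are sampled ~4x so they survive the low-count
      # filter at realistic rates
      bg <- rep(bg, each = 4)
      raw[[lib]] <- c(raw[[lib]], bg)
    }

    # substitution errors + adapter + pad to fixed read length
    mutate <- function(reads) {
      if (cfg$substitution_error_rate <= 0) return(reads)
      vapply(reads, function(r) {
        ch <- strsplit(r, "")[[1]]
        hit <- runif(length(ch)) < cfg$substitution_error_rate
        if (any(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    for (lib in SIM_LIBRARIES) {
      inserts <- mutate(raw[[lib]])
      reads <- paste0(inserts, cfg$adapter)
      raw[[lib]] <- substr(reads, 1, cfg$read_length)
      raw[[lib]] <- sample(raw[[lib]])  # shuffle read order
    }

    tc <- as.data.frame(mature_counts)
    names(tc) <- paste0("mature_", SIM_LIBRARIES)
    sc <- as.data.frame(star_counts)
    names(sc) <- paste0("star_", SIM_LIBRARIES)
    list(raw_reads = raw, truth_counts = cbind(tc, sc))
  })
}

#' Write simulated libraries as FASTQ files
#' @param raw_reads named list of per-library read vectors.
#' @param dir output directory.
#' @return named vector of file paths.
#' @export
write_fastq_libraries <- function(raw_reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(names(raw_reads), ".fastq")),
                    names(raw_reads))
  for (lib in names(raw_reads)) {
    reads <- raw_reads[[lib]]
    con <- file(paths[lib], "w")
    for (i in seq_along(reads)) {
      writeLines(c(sprintf("@%s_%06d", lib, i), reads[i], "+",
                   strrep("I", nchar(reads[i]))), con)
    }
    close(con)
  }
  paths
}

#' Packaged in-paper table fixtures
#'
#' Machine-readable copies of the published summary tables shipped with the
#' package: per-library processing totals, category distribution, top-30
#' family RPM values (with the tissue-specificity flags), the 74 conserved
#' precursor rows, and the 24 novel-miRNA rows.
#'
#' @return named list of data.frames: `processing`, `categories`,
#'   `family_rpm`, `precursors`, `novel`.
#' @export
packaged_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "mirloom",
                                  mustWork = TRUE)
  list(processing = read.delim(path("processing_totals.tsv")),
       categories = read.delim(path("category_distribution.tsv")),
       family_rpm = read.delim(path("family_rpm_top30.tsv")),
       precursors = read.delim(path("conserved_precursors.tsv")),
       novel = read.delim(path("novel_mirnas.tsv")))
}
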