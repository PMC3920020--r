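# Secondary-structure representation and hairpin analytics.
#
# A pair_table holds the (RNA) sequence, the dot-bracket string, a symmetric
# partner map, and the structure's energy. Structures are nested (no
# pseudoknots) by construction. Legal pairs: A:U, G:C, G:U.
#
# Terminology used throughout (the field often conflates these):
#   mismatch = symmetric 1:1 internal loop (one unpaired base opposite one);
#   bulge    = unpaired run on one strand only (larger internal loops are
#              counted as bulges of their larger side);
#   continuous unpaired = longest run of unpaired residues in a span,
#              regardless of which side the opposite strand bulges.

#' Construct a pair table
#'
#' @param sequence nucleotide sequence (stored as given; compared in DNA
#'   space internally).
#' @param partner integer vector, 1-based partner position or 0 if unpaired.
#' @param mfe structure energy (kcal/mol under the producing backend's model).
#' @param backend identifier of the producing backend (`"builtin"`,
#'   `"external"`); energies from different backends are not comparable.
#' @param fold_temperature folding temperature in degrees Celsius (metadata).
#' @param validate check symmetry, nesting and pair legality.
#' @return a `pair_table` object.
#' @export
pair_table <- function(sequence, partner, mfe = NA_real_,
                       backend = "external", fold_temperature = 25,
                       validate = TRUE) {
  n <- nchar(sequence)
  partner <- as.integer(partner)
  stopifnot(length(partner) == n)
  if (validate && n > 0) {
    idx <- which(partner > 0)
    if (any(partner[idx] < 1 | partner[idx] > n))
      stop("partner index out of range")
    if (!all(partner[partner[idx]] == idx))
      stop("partner map is not symmetric")
    sdna <- strsplit(canon_dna(sequence), "")[[1]]
    for (i in idx[idx < partner[idx]]) {
      if (!is_legal_pair(sdna[i], sdna[partner[i]]))
        stop("illegal pair ", sdna[i], ":", sdna[partner[i]],
             " at positions ", i, ",", partner[i])
    }
    check_nested(partner)
  }
  structure(list(sequence = sequence, partner = partner, mfe = mfe,
                 backend = backend, fold_temperature = fold_temperature),
            class = "pair_table")
}

is_legal_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

check_nested <- function(partner) {
  stack <- integer(0)
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j > i) stack <- c(stack, i)
    else if (j > 0 && j < i) {
      if (length(stack) == 0 || stack[length(stack)] != j)
        stop("structure contains a pseudoknot (crossing pairs)")
      stack <- stack[-length(stack)]
    }
  }
  invisible(TRUE)
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table:", nchar(x$sequence), "nt,",
      sum(x$partner > 0) / 2, "pairs, mfe", x$mfe,
      paste0("(", x$backend, ")"), "\n")
  cat(" ", to_rna(x$sequence), "\n ", render_dotbracket(x), "\n")
  invisible(x)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param sequence the nucleotide sequence.
#' @param dotbracket matched-parenthesis structure string of equal length.
#' @param mfe optional energy to attach.
#' @param backend backend label for the attached energy.
#' @return a `pair_table`.
#' @export
parse_dotbracket <- function(sequence, dotbracket, mfe = NA_real_,
                             backend = "external") {
  n <- nchar(sequence)
  if (nchar(dotbracket) != n)
    stop("sequence and structure lengths differ (", n, " vs ",
         nchar(dotbracket), ")")
  ch <- strsplit(dotbracket, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("dot-bracket may only contain '(', ')' and '.'")
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0)
        stop("unbalanced dot-bracket: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack) > 0)
    stop("unbalanced dot-bracket: unmatched '(' at position ",
         stack[length(stack)])
  pair_table(sequence, partner, mfe = mfe, backend = backend)
}

#' Render a pair table as a dot-bracket string
#' @param pt a `pair_table`.
#' @return dot-bracket string.
#' @export
render_dotbracket <- function(pt) {
  ch <- rep(".", length(pt$partner))
  ch[pt$partner > seq_along(pt$partner)] <- "("
  ch[pt$partner > 0 & pt$partner < seq_along(pt$partner)] <- ")"
  paste(ch, collapse = "")
}

#' Predict the secondary structure of a sequence
#'
#' The builtin backend computes the minimum-energy nested structure under a
#' simple stacking-energy model (documented in the package vignette): legal
#' pairs A:U (2), G:C (3), G:U (1); each stack of adjacent pairs contributes
#' minus the mean strength of its two pairs; each pair costs +0.25 so
#' isolated pairs never form; hairpin loops need >= 3 unpaired bases.
#' Energies are deterministic and comparable only within this backend.
#'
#' @param sequence nucleotide sequence (length >= 10 for the builtin
#'   backend).
#' @param temperature folding temperature metadata (degrees C). The builtin
#'   model is temperature-independent; the value is recorded for audit.
#' @param backend `"builtin"` or a parsed external structure (see
#'   [read_dotbracket_file()]).
#' @return a `pair_table` with `mfe` set.
#' @export
fold <- function(sequence, temperature = 25, backend = "builtin") {
  if (backend != "builtin")
    stop("fold() only provides the builtin backend; parse external ",
         "structures with read_dotbracket_file() or read_ct_file()")
  if (nchar(sequence) < 10) stop("sequence too short to fold (< 10 nt)")
  res <- .fold_cpp(canon_dna(sequence))
  pair_table(sequence, res$partner, mfe = res$mfe, backend = "builtin",
             fold_temperature = temperature, validate = FALSE)
}

#' Read a Vienna-style dot-bracket file
#'
#' Three logical lines per record: `>header`, sequence, structure with an
#' optional trailing `(energy)`.
#'
#' @param path file path.
#' @return named list of `pair_table`s.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop("expected '>' header at line ", i, " of ", path)
    if (i + 2 > length(lines))
      stop("truncated record at end of ", path)
    id <- sub("^>\\s*", "", lines[i])
    seq <- gsub("\\s", "", lines[i + 1])
    struct_line <- lines[i + 2]
    m <- regmatches(struct_line,
                    regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", struct_line))
    mfe <- NA_real_
    if (length(m)) {
      mfe <- as.numeric(gsub("[()\\s]", "", m))
      struct_line <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", struct_line)
    }
    out[[id]] <- parse_dotbracket(seq, gsub("\\s", "", struct_line), mfe = mfe)
    i <- i + 3
  }
  out
}

#' Write pair tables to a Vienna-style dot-bracket file
#' @param pts named list of `pair_table`s.
#' @param path output file.
#' @export
write_dotbracket_file <- function(pts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pts)) {
    pt <- pts[[id]]
    writeLines(c(paste0(">", id), to_rna(pt$sequence),
                 paste0(render_dotbracket(pt),
                        if (!is.na(pt$mfe)) sprintf(" (%.2f)", pt$mfe) else "")),
               con)
  }
  invisible(path)
}

#' Read a connect-table (.ct) structure file
#'
#' Adapter for Mfold-style output. Only the first structure in the file is
#' read.
#'
#' @param path file path.
#' @return a `pair_table` (energy parsed from the header when present).
#' @export
read_ct_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty .ct file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1])
  mfe <- NA_real_
  if (grepl("dG", lines[1])) {
    v <- regmatches(lines[1],
                    regexpr("dG\\s*=\\s*-?[0-9.]+", lines[1]))
    if (length(v)) mfe <- as.numeric(sub("dG\\s*=\\s*", "", v))
  }
  body <- lines[2:(1 + n)]
  fields <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), `[`, 1:6))
  seq <- paste(fields[, 2], collapse = "")
  partner <- as.integer(fields[, 5])
  pair_table(seq, partner, mfe = mfe, backend = "external")
}

# ---- loop decomposition -----------------------------------------------------

# For every position, identify its structural context:
#   "stem" (paired), "exterior", "hairpin", "multiloop", or "interior"
# (bulge / internal-loop between two helices). Internal helper shared by the
# metric functions below.
loop_contexts <- function(pt) {
  n <- length(pt$partner)
  p <- pt$partner
  ctx <- rep(NA_character_, n)
  ctx[p > 0] <- "stem"
  # enclosing pair for each position
  encl <- integer(n)  # index i of enclosing pair (i, p[i]) with i < p[i]
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (p[i] > i) { encl[i] <- if (length(stack)) stack[length(stack)] else 0L
                    stack <- c(stack, i) }
    else if (p[i] > 0 && p[i] < i) { stack <- stack[-length(stack)]
      encl[i] <- if (length(stack)) stack[length(stack)] else 0L }
    else encl[i] <- if (length(stack)) stack[length(stack)] else 0L
  }
  # classify each loop (region directly inside a pair)
  pairs5 <- which(p > seq_len(n))
  loop_type <- setNames(rep(NA_character_, length(pairs5)),
                        as.character(pairs5))
  for (i in pairs5) {
    j <- p[i]
    k <- i + 1
    children <- 0L
    unpaired <- 0L
    while (k < j) {
      if (p[k] > k) { children <- children + 1L; k <- p[k] + 1L }
      else { unpaired <- unpaired + 1L; k <- k + 1L }
    }
    loop_type[as.character(i)] <-
      if (children == 0L) "hairpin" else if (children == 1L) "interior"
      else "multiloop"
  }
  unp <- which(p == 0)
  for (i in unp) {
    ctx[i] <- if (encl[i] == 0L) "exterior" else
      loop_type[as.character(encl[i])]
  }
  list(context = ctx, enclosing = encl, loop_type = loop_type)
}

#' Hairpin metrics of a pair table
#'
#' @param pt a `pair_table`.
#' @return a `hairpin_metrics` list: `loops` (data.frame of hairpin loops:
#'   closing pair and size), `terminal_loop_size` (size of the single hairpin
#'   loop, or of the largest when the structure is branched), `branch_count`
#'   (helices emanating from multiloops beyond the entering helix, summed),
#'   `loop_count`, `stems` (helix segments start5/end5/start3/end3),
#'   `bulges` (side, start, size), `mismatch_positions` (5' positions of
#'   symmetric 1:1 internal loops), `n_pairs`.
#' @export
hairpin_metrics <- function(pt) {
  n <- length(pt$partner)
  p <- pt$partner
  lc <- loop_contexts(pt)
  pairs5 <- which(p > seq_len(n))
  # hairpin loops
  hp <- pairs5[lc$loop_type[as.character(pairs5)] == "hairpin"]
  loops <- data.frame(close5 = hp, close3 = p[hp],
                      size = p[hp] - hp - 1L)
  # branch count: per multiloop, number of child helices
  branch_count <- 0L
  ml <- pairs5[lc$loop_type[as.character(pairs5)] == "multiloop"]
  for (i in ml) {
    j <- p[i]; k <- i + 1; children <- 0L
    while (k < j) { if (p[k] > k) { children <- children + 1L; k <- p[k] + 1L }
                    else k <- k + 1L }
    branch_count <- branch_count + children
  }
  # exterior-level branches beyond the first also count as branching
  ext_helices <- sum(lc$enclosing[pairs5] == 0L)
  if (ext_helices > 1L) branch_count <- branch_count + (ext_helices - 1L)
  # helix segments: maximal runs of stacked pairs
  stems <- list()
  used <- rep(FALSE, n)
  for (i in pairs5) {
    if (used[i]) next
    s5 <- i; e5 <- i
    while (e5 + 1 <= n && p[e5 + 1] == p[e5] - 1 && p[e5 + 1] > e5 + 1) {
      e5 <- e5 + 1; used[e5] <- TRUE
    }
    used[i] <- TRUE
    stems[[length(stems) + 1]] <-
      c(start5 = s5, end5 = e5, start3 = p[e5], end3 = p[s5])
  }
  stems <- if (length(stems)) as.data.frame(do.call(rbind, stems)) else
    data.frame(start5 = integer(), end5 = integer(), start3 = integer(),
               end3 = integer())
  # bulges and 1:1 mismatches from interior loops
  bulges <- list()
  mism <- integer(0)
  il <- pairs5[lc$loop_type[as.character(pairs5)] == "interior"]
  for (i in il) {
    j <- p[i]
    k <- i + 1
    while (p[k] == 0) k <- k + 1      # child helix 5' start
    g5 <- k - i - 1L                  # unpaired on 5' side
    g3 <- j - p[k] - 1L               # unpaired on 3' side
    if (g5 == 1L && g3 == 1L) mism <- c(mism, i + 1L)
    else if (g5 > 0L && g3 == 0L)
      bulges[[length(bulges) + 1]] <- c(side = 5L, start = i + 1L, size = g5)
    else if (g3 > 0L && g5 == 0L)
      bulges[[length(bulges) + 1]] <- c(side = 3L, start = p[k] + 1L, size = g3)
    else if (g5 > 0L && g3 > 0L)      # larger internal loop: larger side
      bulges[[length(bulges) + 1]] <-
        c(side = if (g5 >= g3) 5L else 3L,
          start = if (g5 >= g3) i + 1L else p[k] + 1L,
          size = max(g5, g3))
  }
  bulges <- if (length(bulges)) as.data.frame(do.call(rbind, bulges)) else
    data.frame(side = integer(), start = integer(), size = integer())
  structure(list(
    loops = loops,
    terminal_loop_size = if (nrow(loops)) max(loops$size) else 0L,
    branch_count = branch_count,
    loop_count = nrow(loops),
    stems = stems, bulges = bulges, mismatch_positions = mism,
    n_pairs = length(pairs5)), class = "hairpin_metrics")
}

# size of the hairpin loop terminating the helix that contains `pos`
# (walk inward through bulges/interior loops; NA if a multiloop intervenes)
arm_terminal_loop <- function(pt, span) {
  p <- pt$partner
  paired <- span[p[span] > 0]
  if (!length(paired)) return(NA_integer_)
  lc <- loop_contexts(pt)
  # innermost pair of the span's helix path: largest i with partner > i
  # (5' arm) or smallest i with partner < i (3' arm)
  on5 <- p[paired] > paired
  i <- if (any(on5)) max(paired[on5]) else min(paired[!on5])
  if (p[i] < i) i <- p[i]
  repeat {
    lt <- lc$loop_type[as.character(i)]
    if (is.na(lt)) return(NA_integer_)
    if (lt == "hairpin") return(p[i] - i - 1L)
    if (lt == "multiloop") return(NA_integer_)
    # interior: descend to the single child helix
    k <- i + 1
    while (pt$partner[k] == 0) k <- k + 1
    i <- k
  }
}

#' Locate the core region of a mature placement within a structure
#'
#' The core region is the stem segment whose residues align with the mature
#' small RNA. The placement is rejected when any mature residue lies in a
#' hairpin loop or outside the folded stem (exterior), mirroring the rule
#' that a mature miRNA must sit in the stem, not the loop.
#'
#' @param pt a `pair_table`.
#' @param mature_span integer c(start, end), 1-based inclusive.
#' @return a `core_region` list (`span`, `length_bp`, `bulge_count`,
#'   `max_bulge_size`, `max_continuous_unpaired`, `unpaired_count`,
#'   `contains_loop_or_branch`) or a rejection list
#'   `list(rejected = TRUE, reason = "in_loop")`.
#' @export
locate_core <- function(pt, mature_span) {
  n <- length(pt$partner)
  s <- mature_span[1]; e <- mature_span[2]
  if (s < 1 || e > n || s > e) stop("mature span outside sequence")
  span <- s:e
  lc <- loop_contexts(pt)
  ctx <- lc$context[span]
  if (any(ctx %in% c("hairpin", "exterior")) || all(pt$partner[span] == 0))
    return(list(rejected = TRUE, reason = "in_loop"))
  p <- pt$partner
  paired <- span[p[span] > 0]
  unpaired_runs <- rle(p[span] == 0)
  max_run <- if (any(unpaired_runs$values))
    max(unpaired_runs$lengths[unpaired_runs$values]) else 0L
  # partner monotonicity: within one duplex arm, partners strictly decrease
  part <- p[paired]
  monotone <- all(diff(part) < 0)
  pairs_inside <- any(part %in% span)    # mature pairs with itself
  in_multiloop <- any(ctx == "multiloop")
  # bulges/mismatches restricted to the span: examine unpaired runs between
  # consecutive paired residues
  bulge_count <- 0L; max_bulge <- 0L; mismatches <- 0L
  if (length(paired) >= 2 && monotone && !pairs_inside) {
    for (k in seq_len(length(paired) - 1)) {
      a <- paired[k]; b <- paired[k + 1]
      g5 <- b - a - 1L              # unpaired on mature side
      g3 <- p[a] - p[b] - 1L        # unpaired on star side
      if (g5 == 0L && g3 == 0L) next
      if (g5 == 1L && g3 == 1L) { mismatches <- mismatches + 1L; next }
      bulge_count <- bulge_count + 1L
      max_bulge <- max(max_bulge, max(g5, g3))
    }
  }
  list(rejected = FALSE,
       span = c(s, e),
       length_bp = length(paired),
       bulge_count = bulge_count,
       max_bulge_size = max_bulge,
       max_continuous_unpaired = max_run,
       unpaired_count = sum(p[span] == 0),
       contains_loop_or_branch = in_multiloop || !monotone || pairs_inside)
}

#' Derive the miRNA* span of a mature placement (2-nt 3' overhangs)
#'
#' The star strand is the duplex partner of the mature, shifted so both
#' strands carry the canonical 2-nt 3' overhang: star_start =
#' partner(mature_end - 2), star_end = partner(mature_start) + 2. Positions
#' without partners are resolved by extrapolating from the nearest paired
#' neighbour within the mature span.
#'
#' @param pt a `pair_table`.
#' @param mature_span integer c(start, end).
#' @return a `duplex` list: `mature`, `star` (both c(start, end)),
#'   `star_sequence` (5'->3'), `overhang_3prime = 2`.
#' @export
derive_star <- function(pt, mature_span) {
  n <- length(pt$partner)
  p <- pt$partner
  s <- mature_span[1]; e <- mature_span[2]
  span <- s:e
  paired <- span[p[span] > 0]
  if (length(paired) < 2) stop("no_duplex: mature arm has too few partners")
  proj <- function(x) {
    if (x >= 1 && x <= n && p[x] > 0) return(p[x])
    d <- abs(paired - x)
    q <- paired[which.min(d)]
    est <- p[q] - (x - q)  # partners run antiparallel

    max(1L, min(n, as.integer(est)))
  }
  a <- proj(e - 2L)
  b <- proj(s) + 2L
  b <- max(1L, min(n, as.integer(b)))
  star <- sort(c(a, b))
  if (star[1] >= s && star[2] <= e)
    stop("no_duplex: derived star coincides with the mature span")
  star_seq <- substr(pt$sequence, star[1], star[2])
  # star is read 5'->3'; if the star lies 5' of the mature it is already
  # 5'->3' in sequence coordinates (both arms are on the same strand)
  list(mature = c(s, e), star = star, star_sequence = star_seq,
       overhang_3prime = 2L)
}

#' Trim a precursor to the duplex plus flanking nucleotides and refold
#'
#' Keeps `[outermost duplex 5' pair - flank, outermost 3' pair + flank]`
#' (clamped to the sequence) and refolds the kept subsequence with the
#' builtin backend, recomputing the energy.
#'
#' @param pt a `pair_table` of the full sequence.
#' @param duplex a duplex from [derive_star()].
#' @param flank nucleotides kept outside the terminal duplex pair.
#' @return list: `sequence` (kept subsequence), `pair_table` (refolded),
#'   `offset` (0-based shift: full coordinate = trimmed + offset),
#'   `kept` c(start, end) on the input.
#' @export
trim_precursor <- function(pt, duplex, flank = 10L) {
  p <- pt$partner
  n <- length(p)
  dpos <- c(duplex$mature[1]:duplex$mature[2],
            duplex$star[1]:duplex$star[2])
  dpos <- dpos[dpos >= 1 & dpos <= n]
  paired <- dpos[p[dpos] > 0 & p[dpos] %in% dpos]
  if (!length(paired)) paired <- dpos[p[dpos] > 0]
  if (!length(paired)) stop("duplex has no paired residues")
  lo <- min(paired); hi <- max(p[paired], paired)
  start <- max(1L, lo - as.integer(flank))
  end <- min(n, hi + as.integer(flank))
  subseq <- substr(pt$sequence, start, end)
  refolded <- fold(subseq, temperature = pt$fold_temperature)
  list(sequence = subseq, pair_table = refolded,
       offset = start - 1L, kept = c(start, end))
}
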