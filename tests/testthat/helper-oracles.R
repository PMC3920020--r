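# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (exhaustive enumeration, base-R edit distance,
# greedy recomputation) so it shares no code path with the implementation.

# a sequence compatible with an arbitrary dot-bracket string: G on "(",
# C on ")", A on "."
seq_for_db <- function(db) {
  ch <- strsplit(db, "")[[1]]
  paste(ifelse(ch == "(", "G", ifelse(ch == ")", "C", "A")), collapse = "")
}

# min edits placing the whole read inside ref: min over all substrings,
# via base R adist (Levenshtein), both strands
oracle_min_edits <- function(read, ref) {
  best <- Inf
  for (s in c(ref, mirloom::revcomp(ref))) {
    n <- nchar(s)
    for (i in seq_len(n)) {
      for (j in i:n) {
        d <- utils::adist(read, substr(s, i, j))[1, 1]
        if (d < best) best <- d
      }
    }
  }
  best
}

# exhaustive substring scan for contaminant matching (both strands)
oracle_is_substring <- function(read, refs) {
  any(vapply(refs, function(r)
    grepl(read, r, fixed = TRUE) ||
      grepl(read, mirloom::revcomp(r), fixed = TRUE), logical(1)))
}

# exhaustive complementarity scan: every offset x every window containing
# miRNA positions 2-12 with length >= min_len; Watson-Crick only
oracle_target_scan <- function(mirna, transcript, max_mm = 3, min_len = 17) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mir <- strsplit(mirna, "")[[1]]
  tr <- strsplit(transcript, "")[[1]]
  m <- length(mir); n <- length(tr)
  hits <- list()
  for (a in 1:2) for (b in 12:m) {
    w <- b - a + 1
    if (w < min_len || w > n) next
    for (start in 1:(n - w + 1)) {
      window <- tr[start:(start + w - 1)]
      mm <- 0
      for (k in 0:(w - 1)) {
        # miRNA position a+k opposes window position w-k (antiparallel)
        if (comp[[mir[a + k]]] != window[w - k]) mm <- mm + 1
      }
      ends_match <- comp[[mir[a]]] == window[w] &&
        comp[[mir[b]]] == window[1]
      if (ends_match && mm <= max_mm)
        hits[[length(hits) + 1]] <-
          data.frame(start = start, end = start + w - 1, mm = mm,
                     len = w)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# best qualifying window per overlapping group (fewest mm, longest,
# leftmost), mirroring the reporting convention
oracle_best_sites <- function(hits) {
  if (is.null(hits)) return(NULL)
  hits <- hits[order(hits$start), , drop = FALSE]
  groups <- list(); cur <- hits[1, , drop = FALSE]; cur_end <- hits$end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$start[i] <= cur_end) {
      cur <- rbind(cur, hits[i, ]); cur_end <- max(cur_end, hits$end[i])
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- hits[i, , drop = FALSE]; cur_end <- hits$end[i]
    }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(g) {
    g <- g[order(g$mm, -g$len, g$start), , drop = FALSE]
    g[1, , drop = FALSE]
  }))
}

# greedy centroid-linkage agglomeration: at each step merge the two
# clusters with the closest (Euclidean) centroids; returns merge heights
oracle_centroid_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); bd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ci <- colMeans(m[clusters[[i]], , drop = FALSE])
      cj <- colMeans(m[clusters[[j]], , drop = FALSE])
      d <- sqrt(sum((ci - cj)^2))
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# enumerate every nested structure (legal pairs, hairpin loop >= 3) of a
# short sequence and score each under the documented stacking model;
# returns the optimum energy
oracle_fold_mfe <- function(seq) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  n <- length(s)
  strength <- function(a, b) {
    ab <- paste0(a, b)
    if (ab %in% c("GC", "CG")) 3 else if (ab %in% c("AT", "TA")) 2 else
      if (ab %in% c("GT", "TG")) 1 else 0
  }
  # all pair sets on region [i, j], as lists of rbind-able c(i, j)
  enum <- function(i, j) {
    if (j - i < 4) return(list(list()))
    out <- enum(i + 1, j)                     # i unpaired
    for (k in (i + 4):j) {
      if (strength(s[i], s[k]) == 0) next
      inner <- enum(i + 1, k - 1)
      rest <- if (k < j) enum(k + 1, j) else list(list())
      for (a in inner) for (b in rest)
        out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
    }
    out
  }
  score <- function(pairs) {
    if (!length(pairs)) return(0)
    e <- 0.25 * length(pairs)
    pm <- do.call(rbind, pairs)
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1]; j <- pm[r, 2]
      inner <- which(pm[, 1] == i + 1 & pm[, 2] == j - 1)
      if (length(inner))
        e <- e - (strength(s[i], s[j]) +
                    strength(s[i + 1], s[j - 1])) / 2
    }
    e
  }
  min(vapply(enum(1, n), score, numeric(1)))
}

# deterministic random DNA for tests
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one shared prediction-interval regression for the whole suite (the
# builtin-backend default); computed once at load
shared_reg <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- mirloom::default_mfe_regression()
    reg
  }
})
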