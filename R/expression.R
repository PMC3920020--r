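# Expression profiling: RPM normalisation, the tissue-specificity measure
# (SPM), family shares, fold-change selection, centroid-linkage clustering
# and summary statistics.

#' Reads-per-million normalisation
#' @param count raw read count(s).
#' @param library_total total reads in the library (> 0).
#' @return count / library_total * 1e6.
#' @export
rpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("empty_library: total must be > 0")
  count / library_total * 1e6
}

#' Per-library RPM matrix for family counts
#' @param families output of [aggregate_families()].
#' @param library_totals named vector of per-library totals.
#' @return matrix (family x library) of RPM values.
#' @export
rpm_matrix <- function(families, library_totals) {
  libs <- names(library_totals)
  m <- as.matrix(families[, libs, drop = FALSE])
  rownames(m) <- families$family
  sweep(m, 2, library_totals, "/") * 1e6
}

#' Tissue-specificity measure (SPM) of an expression profile
#'
#' `cosine` variant: spm_i = x_i / ||x||_2, the cosine between the profile
#' and the idealised one-tissue unit vector. `squared` variant: spm_i =
#' x_i^2 / ||x||_2^2. Both are scale-invariant and map one-hot profiles to
#' one-hot SPM. An all-zero profile returns all zeros with a warning.
#'
#' @param profile non-negative RPM vector (one entry per library), or a
#'   matrix (rows = entities).
#' @param method `"cosine"` (default) or `"squared"`.
#' @return vector (or matrix) of SPM values in `[0, 1]`.
#' @export
spm <- function(profile, method = c("cosine", "squared")) {
  method <- match.arg(method)
  if (is.matrix(profile) || is.data.frame(profile)) {
    m <- as.matrix(profile)
    return(t(apply(m, 1, spm, method = method)))
  }
  x <- as.numeric(profile)
  if (any(x < 0)) stop("SPM requires non-negative expression values")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) {
    warning("all-zero profile: SPM undefined, returning zeros")
    return(setNames(rep(0, length(x)), names(profile)))
  }
  out <- if (method == "cosine") x / nrm else x^2 / nrm^2
  setNames(out, names(profile))
}

#' Family share of total miRNA expression
#' @param family_rpm family RPM (scalar or vector).
#' @param total_mirna_rpm total miRNA RPM in the same library.
#' @param digits decimals in the reported percentage (default 1).
#' @return percentage(s), rounded to `digits`.
#' @export
family_share <- function(family_rpm, total_mirna_rpm, digits = 1) {
  if (any(total_mirna_rpm <= 0)) stop("total miRNA RPM must be > 0")
  round(100 * family_rpm / total_mirna_rpm, digits)
}

#' Select entities by max/min fold change across libraries
#'
#' Fold change = max RPM / min RPM across libraries, with a pseudo-count
#' substituted for zero minima. Boundary inclusive ("at least").
#'
#' @param profiles matrix (entities x libraries) of RPM values.
#' @param min_fold threshold (>= 1), default 4.
#' @param pseudo pseudo-count for zeros (default 0.01 RPM).
#' @return the selected sub-matrix (possibly 0 rows).
#' @export
fold_change_select <- function(profiles, min_fold = 4.0, pseudo = 0.01) {
  stopifnot(min_fold >= 1)
  m <- pmax(as.matrix(profiles), pseudo)
  fc <- apply(m, 1, max) / apply(m, 1, min)
  profiles[fc >= min_fold, , drop = FALSE]
}

#' Log2 transform of an RPM matrix with pseudo-count
#' @param profiles RPM matrix.
#' @param pseudo pseudo-count substituted before the log (default 0.01).
#' @return log2 matrix.
#' @export
log2_rpm <- function(profiles, pseudo = 0.01) {
  log2(pmax(as.matrix(profiles), pseudo))
}

#' Centroid-linkage hierarchical clustering of expression profiles
#'
#' Agglomerative clustering under the Euclidean metric with centroid
#' linkage: at each step the two clusters whose centroids are closest are
#' merged; reported heights are the Euclidean centroid distances.
#' (Internally `stats::hclust(method = "centroid")` on squared distances,
#' whose Lance-Williams update reproduces true centroid distances; heights
#' are square-rooted back to the Euclidean scale.)
#'
#' @param profiles numeric matrix (>= 2 rows; typically log2 RPM).
#' @return an `hclust` object with Euclidean-scale heights.
#' @export
hclust_centroid <- function(profiles) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 profiles to cluster")
  if (any(!is.finite(m))) stop("non-finite values in profile matrix")
  hc <- hclust(dist(m)^2, method = "centroid")
  hc$height <- sqrt(pmax(hc$height, 0))
  hc$method <- "centroid (euclidean heights)"
  hc
}

#' Export a dendrogram as a Newick string
#' @param hc an `hclust` object.
#' @return Newick tree string.
#' @export
dendrogram_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc))
}

#' Min/max/mean summary of a numeric column, with optional predicate count
#' @param x numeric vector (non-empty).
#' @param predicate optional function returning a logical per element.
#' @param digits decimals for the mean (default: unrounded).
#' @return list(min, max, mean, n, predicate_count).
#' @export
summarize_column <- function(x, predicate = NULL, digits = NULL) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty column")
  mean_x <- mean(x)
  if (!is.null(digits)) mean_x <- round(mean_x, digits)
  list(min = min(x), max = max(x), mean = mean_x, n = length(x),
       predicate_count = if (is.null(predicate)) NA_integer_ else
         sum(predicate(x)))
}
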