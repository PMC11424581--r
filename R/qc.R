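#' @include AllClasses.R
NULL

#' Per-cell quality-control metrics
#'
#' Computes the four QC covariates used for outlier filtering: fraction of
#' counts on mitochondrial genes, fraction on ribosomal genes, number of
#' detected features and total counts. Cells with zero total counts are
#' flagged for unconditional removal.
#'
#' @param m A \linkS4class{CellMatrix}.
#' @param mito_prefix gene-symbol prefix of mitochondrial genes (species
#'   dialect is the caller's choice, e.g. \code{"mt-"} mouse, \code{"MT-"}
#'   human).
#' @param ribo_prefixes prefixes of ribosomal protein genes.
#' @return data.frame (rownames = barcodes) with columns \code{pct_mito},
#'   \code{pct_ribo}, \code{n_features}, \code{n_counts}, \code{empty}.
#' @export
computeQCMetrics <- function(m, mito_prefix = "mt-",
                             ribo_prefixes = c("Rps", "Rpl")) {
  cnt <- SummarizedExperiment::assay(m, "counts")
  total <- Matrix::colSums(cnt)
  is_mito <- startsWith(rownames(cnt), mito_prefix)
  is_ribo <- Reduce(`|`, lapply(ribo_prefixes, startsWith, x = rownames(cnt)))
  if (!any(is_mito))
    .log("warn", "no gene matches mitochondrial prefix '", mito_prefix,
         "'; pct_mito is all zero")
  if (!any(is_ribo))
    .log("warn", "no gene matches any ribosomal prefix; pct_ribo is all zero")
  safe_frac <- function(part) ifelse(total > 0, part / total, 0)
  data.frame(
    pct_mito = safe_frac(Matrix::colSums(cnt[is_mito, , drop = FALSE])),
    pct_ribo = safe_frac(Matrix::colSums(cnt[is_ribo, , drop = FALSE])),
    n_features = Matrix::colSums(cnt > 0),
    n_counts = total,
    empty = total == 0,
    row.names = colnames(cnt))
}

# keep cells within median +/- nmads * MAD; an all-identical metric carries
# no information and passes every cell (degenerate rule, logged). With a
# zero MAD but non-identical values the band collapses onto the median.
.mad_keep <- function(x, nmads, upper_only = FALSE) {
  if (diff(range(x)) <= 1e-10 * max(1, abs(stats::median(x)))) {
    .log("info", "all-identical QC criterion; it passes all cells")
    return(rep(TRUE, length(x)))
  }
  med <- stats::median(x)
  md <- stats::mad(x)  # 1.4826 normal-consistency constant
  if (md == 0)
    .log("info", "MAD = 0 on a non-constant QC criterion; ",
         "only median-valued cells pass it")
  if (upper_only) x <= med + nmads * md
  else abs(x - med) <= nmads * md
}

#' MAD-based outlier filtering of cells
#'
#' A cell is kept when it passes every criterion: mitochondrial fraction at
#' most \code{nmads} MADs above the median (one-sided; low mitochondrial
#' content is never a damage signal), ribosomal fraction, log10 feature
#' count and log10 total count each within \code{nmads} MADs of their
#' medians, and the residual of the least-squares fit of log10(features) on
#' log10(counts) within \code{nmads} MADs of the median residual. Cells
#' with zero counts are removed unconditionally. A criterion whose MAD is
#' zero passes all cells (degenerate rule, logged).
#'
#' @param qc data.frame from [computeQCMetrics()] (at least 3 cells).
#' @param nmads MAD multiplier, default 3.
#' @return Character vector of kept cell barcodes.
#' @export
madFilter <- function(qc, nmads = 3) {
  if (nrow(qc) < 3L) stop("MAD filtering needs at least 3 cells")
  qc2 <- qc[!qc$empty, , drop = FALSE]
  lf <- log10(qc2$n_features)
  lc <- log10(qc2$n_counts)
  resid <- stats::residuals(stats::lm(lf ~ lc))
  keep <- .mad_keep(qc2$pct_mito, nmads, upper_only = TRUE) &
    .mad_keep(qc2$pct_ribo, nmads) &
    .mad_keep(lf, nmads) &
    .mad_keep(lc, nmads) &
    .mad_keep(resid, nmads)
  rownames(qc2)[keep]
}

#' Calinski-Harabasz index of a clustering
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' \eqn{[B/(k-1)] / [W/(n-k)]}, where B is the size-weighted squared
#' distance of cluster centroids to the grand centroid and W the pooled
#' within-cluster sum of squares. A clustering of singletons (W = 0) scores
#' \code{Inf}, ranking above every finite score.
#'
#' @param embedding n_cells x d numeric matrix.
#' @param labels cluster assignment of each row.
#' @return Numeric score (possibly \code{Inf}).
#' @examples
#' calinskiHarabasz(cbind(c(0, 1, 10, 11)), c("a", "a", "b", "b"))  # 200
#' @export
calinskiHarabasz <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  n <- nrow(embedding)
  k <- length(unique(labels))
  if (k < 2L || k >= n)
    stop("invalid clustering candidate: need 2 <= k < n (k = ", k,
         ", n = ", n, ")")
  grand <- colMeans(embedding)
  W <- 0
  B <- 0
  for (cl in unique(labels)) {
    rows <- embedding[labels == cl, , drop = FALSE]
    cen <- colMeans(rows)
    W <- W + sum(sweep(rows, 2, cen)^2)
    B <- B + nrow(rows) * sum((cen - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the best clustering candidate
#'
#' Scores each candidate labelling with the Calinski-Harabasz index and
#' keeps the highest (ties broken by fewer clusters, then candidate order).
#' If the winning candidate has more than \code{max_clusters} clusters the
#' supplied fallback partition is returned instead. Candidates with a
#' single cluster or all-singleton clusters are invalid and skipped.
#'
#' @param embedding n_cells x d numeric matrix.
#' @param candidates named list of label vectors (names act as resolution
#'   tags).
#' @param max_clusters cluster-count ceiling, default 30.
#' @param fallback label vector used when the winner exceeds the ceiling.
#' @return The chosen label vector, with attributes \code{tag} (resolution
#'   tag or \code{"fallback"}), \code{score} (its CH index, \code{NA} for
#'   the fallback) and \code{fallback} (logical).
#' @export
selectClustering <- function(embedding, candidates, max_clusters = 30,
                             fallback) {
  if (!length(candidates)) stop("no clustering candidate supplied")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  ch <- vapply(candidates, function(lab)
    tryCatch(calinskiHarabasz(embedding, lab), error = function(e) NA_real_),
    numeric(1))
  if (all(is.na(ch))) stop("no valid clustering candidate")
  nclust <- vapply(candidates, function(lab) length(unique(lab)), integer(1))
  ok <- which(!is.na(ch))
  best <- ok[order(-ch[ok], nclust[ok], seq_along(ok))][1]
  if (nclust[best] > max_clusters) {
    .log("info", "best candidate has ", nclust[best], " clusters (> ",
         max_clusters, "); using fallback partition")
    return(structure(fallback, tag = "fallback", score = NA_real_,
                     fallback = TRUE))
  }
  structure(candidates[[best]], tag = names(candidates)[best],
            score = ch[[best]], fallback = FALSE)
}
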