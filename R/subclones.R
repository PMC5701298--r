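#' Parameters for subclonal SCNA detection
#'
#' @param min_nonzero_elements a bin must have at least this many cells
#'   with nonzero copy number to be considered (default 3).
#' @param variance_threshold keep bins whose across-cell variance is
#'   strictly greater than this (default 0.5).
#' @param n_pcs number of leading principal components mined for candidate
#'   bins (default 6).
#' @param contribution_multiplier within each PC, a bin is collected when
#'   its squared-loading contribution is at least this multiple of the
#'   average contribution (1/number of retained bins); 1 is the usual
#'   "above-average contribution" criterion of PCA contribution plots.
#' @param min_event_span minimum genomic span of a subclonal event in bp
#'   (default 1.5 Mb).
#' @param gap_tolerance number of missing bins allowed inside one event run
#'   (default 1).
#' @param k_range candidate cluster numbers for PAM.
#' @export
subclone_params <- function(min_nonzero_elements = 3L,
                            variance_threshold = 0.5,
                            n_pcs = 6L, contribution_multiplier = 1,
                            min_event_span = 1.5e6, gap_tolerance = 1L,
                            k_range = 2:10) {
  stopifnot(n_pcs >= 1, min_event_span > 0, contribution_multiplier > 0)
  list(min_nonzero_elements = as.integer(min_nonzero_elements),
       variance_threshold = variance_threshold, n_pcs = as.integer(n_pcs),
       contribution_multiplier = contribution_multiplier,
       min_event_span = min_event_span,
       gap_tolerance = as.integer(gap_tolerance), k_range = k_range)
}

#' Ward hierarchical clustering of copy-number profiles
#'
#' Euclidean distances between cell rows, `ward.D` linkage, cut at `k`.
#' Deterministic given input order.
#'
#' @param matrix cells x bins numeric matrix (integer copy-number states).
#' @param k number of clusters to cut at.
#' @return list(hclust = dendrogram, labels = named cluster ids)
#' @export
hierarchical_cluster <- function(matrix, k = 2L) {
  if (nrow(matrix) < 2L) stop("need >= 2 cells")
  if (all(apply(matrix, 2, stats::var) == 0)) {
    warning("constant matrix: single cluster")
    return(list(hclust = NULL,
                labels = stats::setNames(rep(1L, nrow(matrix)),
                                         rownames(matrix))))
  }
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "ward.D")
  labels <- stats::cutree(hc, k = min(k, nrow(matrix)))
  list(hclust = hc, labels = labels)
}

#' Choose the number of clusters with PAM and average silhouette width
#'
#' Runs partition-around-medoids at each k in `k_range` and picks the k
#' with the largest average silhouette width, mirroring the `pamk`
#' approach. Degenerate inputs (<= 2 cells) return k = 1 with a warning.
#'
#' @param matrix cells x bins numeric matrix.
#' @param params a [subclone_params()] list.
#' @return list(k, labels, silhouette = named per-k average widths,
#'   low_confidence = TRUE when the best silhouette is weak (< 0.25))
#' @export
pam_choose_k <- function(matrix, params = subclone_params()) {
  n <- nrow(matrix)
  if (n <= 2L) {
    warning("too few cells for PAM: returning k = 1")
    return(list(k = 1L, labels = stats::setNames(rep(1L, n),
                                                 rownames(matrix)),
                silhouette = NULL, low_confidence = TRUE))
  }
  ks <- params$k_range[params$k_range < n]
  sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- cluster::pam(matrix, k = ks[i], metric = "euclidean",
                        do.swap = TRUE)
    fits[[i]] <- fit
    sil[i] <- fit$silinfo$avg.width
  }
  best <- which.max(sil)
  list(k = ks[best], labels = fits[[best]]$clustering, silhouette = sil,
       low_confidence = max(sil, na.rm = TRUE) < 0.25)
}

#' Candidate subclonal bins via variance filtering and PCA
#'
#' Reproduces the bin-mining procedure: drop bins with all elements zero
#' and bins with fewer than `min_nonzero_elements` nonzero entries; keep
#' bins whose across-cell variance exceeds `variance_threshold`; run a
#' centered (unscaled) PCA on the retained cells x bins matrix; collect, on
#' each of the first `n_pcs` components, the bins whose squared-loading
#' contribution is at least `contribution_multiplier` times the average
#' contribution, and take the union.
#'
#' @param matrix cells x bins matrix of integer copy-number states, tumor
#'   cells only.
#' @param params a [subclone_params()] list.
#' @return list(candidate_bins = integer bin indices (into the full grid),
#'   variance_bins = indices passing the variance filter, loadings = PCA
#'   rotation of retained bins)
#' @export
pca_candidate_bins <- function(matrix, params = subclone_params()) {
  nz <- colSums(matrix != 0)
  keep1 <- nz >= params$min_nonzero_elements & nz > 0
  v <- apply(matrix, 2, stats::var)
  keepv <- keep1 & v > params$variance_threshold
  variance_bins <- which(keepv)
  if (length(variance_bins) < 2L) {
    if (length(variance_bins) == 0L)
      warning("no bins pass the variance filter: empty candidate set")
    return(list(candidate_bins = variance_bins,
                variance_bins = variance_bins, loadings = NULL))
  }
  sub <- matrix[, variance_bins, drop = FALSE]
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  npc <- min(params$n_pcs, ncol(pc$rotation))
  cand <- logical(length(variance_bins))
  avg <- 1 / length(variance_bins)
  for (j in seq_len(npc)) {
    contrib <- pc$rotation[, j]^2  # columns have unit norm
    cand <- cand | contrib >= params$contribution_multiplier * avg - 1e-12
  }
  list(candidate_bins = variance_bins[cand], variance_bins = variance_bins,
       loadings = pc$rotation[, seq_len(npc), drop = FALSE])
}

#' Keep only candidate runs spanning large events
#'
#' Groups candidate bins into maximal runs of genomically adjacent bins on
#' one chromosome (allowing up to `gap_tolerance` missing bins inside a
#' run) and keeps runs whose genomic span is at least `min_event_span`
#' (default 1.5 Mb, inclusive). Automates the "manual selection" of large
#' subclonal events reproducibly.
#'
#' @param candidate_bins integer bin indices into `grid`.
#' @param grid the `bin_grid`.
#' @param params a [subclone_params()] list.
#' @return list(selected_bins = surviving indices, events = data.frame
#'   (chrom, start, end, n_bins))
#' @export
select_large_events <- function(candidate_bins, grid,
                                params = subclone_params()) {
  events <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), n_bins = integer(0),
                       stringsAsFactors = FALSE)
  if (length(candidate_bins) == 0L)
    return(list(selected_bins = integer(0), events = events))
  b <- sort(unique(candidate_bins))
  selected <- integer(0)
  runs <- split(b, cumsum(c(TRUE, diff(b) > params$gap_tolerance + 1L |
                              grid$chrom[b[-1]] != grid$chrom[b[-length(b)]])))
  for (r in runs) {
    span <- grid$end[max(r)] - grid$start[min(r)]
    if (span >= params$min_event_span) {
      selected <- c(selected, r)
      events <- rbind(events, data.frame(
        chrom = grid$chrom[min(r)], start = grid$start[min(r)],
        end = grid$end[max(r)], n_bins = length(r),
        stringsAsFactors = FALSE))
    }
  }
  list(selected_bins = selected, events = events)
}

#' Cluster cells on subclonal event bins and report subpopulations
#'
#' Restricts the cells x bins matrix to the selected subclonal bins, runs
#' Ward hierarchical clustering and PAM model selection, and reports
#' cluster labels, the chosen k, subpopulation frequencies and (optionally)
#' an agreement table against labels from large-scale copy-number
#' clustering.
#'
#' @param matrix full cells x bins matrix (tumor cells).
#' @param selected_bins bin indices from [select_large_events()].
#' @param params a [subclone_params()] list.
#' @param compare_labels optional named cluster labels to cross-tabulate.
#' @return list of class `subclone_result`
#' @export
assign_subclones <- function(matrix, selected_bins,
                             params = subclone_params(),
                             compare_labels = NULL) {
  n <- nrow(matrix)
  if (length(selected_bins) == 0L) {
    warning("empty selected_bins: all cells in one subclone")
    labels <- stats::setNames(rep(1L, n), rownames(matrix))
    return(structure(list(labels = labels, k = 1L,
                          frequencies = c(`1` = 1),
                          silhouette = NULL, agreement = NULL,
                          selected_bins = selected_bins),
                     class = "subclone_result"))
  }
  sub <- matrix[, selected_bins, drop = FALSE]
  pk <- pam_choose_k(sub, params)
  hc <- hierarchical_cluster(sub, k = pk$k)
  agreement <- NULL
  if (!is.null(compare_labels))
    agreement <- table(subclonal = pk$labels,
                       large_scale = compare_labels[names(pk$labels)])
  structure(list(labels = pk$labels, k = pk$k,
                 frequencies = subpopulation_frequencies(pk$labels)$fraction,
                 silhouette = pk$silhouette,
                 hclust = hc$hclust, agreement = agreement,
                 selected_bins = selected_bins,
                 low_confidence = pk$low_confidence),
            class = "subclone_result")
}

#' @export
print.subclone_result <- function(x, ...) {
  cat(sprintf("subclone_result: k = %d over %d cells, %d event bins\n",
              x$k, length(x$labels), length(x$selected_bins)))
  pct <- subpopulation_frequencies(x$labels)$percent
  cat("  frequencies:", paste(sprintf("%s: %d%%", names(pct), pct),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Subpopulation frequencies from cluster labels
#'
#' Percent is rounded to the nearest integer for reporting (6 and 29 cells
#' of 35 give 17% and 83%); exact fractions are retained.
#'
#' @param labels vector of cluster labels (>= 1 cell).
#' @return list(counts, fraction, percent)
#' @export
subpopulation_frequencies <- function(labels) {
  if (length(labels) == 0L) stop("need at least one labeled cell")
  counts <- table(labels)
  fraction <- as.numeric(counts) / length(labels)
  names(fraction) <- names(counts)
  list(counts = counts, fraction = fraction,
       percent = stats::setNames(as.integer(round(100 * fraction)),
                                 names(counts)))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, ~0 means chance-level agreement.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
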