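#' Copy-number profile container
#'
#' Holds the control-normalized depth ratio (1.0 = diploid), its log2, the
#' inferred integer copy-number state and the MAPD quality score for one
#' single cell or bulk sample, aligned to a shared [build_genome()] grid.
#' @keywords internal
new_cn_profile <- function(sample_id, grid, ratio, masked) {
  structure(list(sample_id = sample_id, grid = grid, ratio = ratio,
                 log2_ratio = log2(ratio), cn_state = NULL,
                 masked = masked, mapd = NA_real_),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile '%s': %d bins (%d masked), MAPD %s\n",
              x$sample_id, length(x$ratio), sum(x$masked),
              ifelse(is.na(x$mapd), "not computed", sprintf("%.4f", x$mapd))))
  invisible(x)
}

#' Normalize binned read depth against a matched control
#'
#' Forms per-bin depth ratios `(raw_b / sum(raw)) / (control_b /
#' sum(control))`, masks bins where the control has fewer than
#' `min_control_count` reads, and rescales so the median unmasked autosomal
#' ratio is 1.0 (diploid baseline). The matched-blood control removes
#' shared mappability/GC structure from the tumor signal.
#'
#' @param raw integer vector of per-bin counts for the sample.
#' @param control per-bin counts (or expectations) of the matched control.
#' @param grid the shared `bin_grid`.
#' @param sample_id sample name.
#' @param min_control_count bins with control below this are masked.
#' @return a `cn_profile` with `ratio` and `log2_ratio` filled.
#' @export
normalize_depth <- function(raw, control, grid, sample_id = "sample",
                            min_control_count = 10) {
  if (length(raw) != nrow(grid) || length(control) != nrow(grid))
    stop("raw/control length does not match bin grid")
  if (all(raw == 0)) stop("all-zero raw counts")
  masked <- control < min_control_count
  if (mean(!masked) < 0.95)
    warning("control under min_control_count in >5% of bins")
  ratio <- (raw / sum(raw)) / (control / sum(control))
  ratio[masked] <- NA_real_
  auto <- grid$chrom %in% setdiff(unique(grid$chrom), c("chrX", "chrY", "X", "Y"))
  med <- stats::median(ratio[auto & !masked], na.rm = TRUE)
  if (!is.finite(med) || med <= 0) med <- stats::median(ratio, na.rm = TRUE)
  ratio <- ratio / med
  new_cn_profile(sample_id, grid, ratio, masked)
}

#' Median of absolute pairwise differences (MAPD)
#'
#' Quality metric for amplified single-cell profiles: the median absolute
#' difference between log2 ratios of consecutive bins, taken within
#' chromosomes so chromosome junctions do not contribute. Masked bins are
#' skipped. Insensitive to long-range copy-number structure; sensitive to
#' bin-to-bin technical noise.
#'
#' @param profile a `cn_profile` (or numeric vector of log2 ratios when
#'   `chrom` is supplied).
#' @param chrom optional chromosome labels when `profile` is a bare vector.
#' @return nonnegative scalar
#' @export
mapd <- function(profile, chrom = NULL) {
  if (inherits(profile, "cn_profile")) {
    lr <- profile$log2_ratio
    lr[profile$masked] <- NA_real_
    chrom <- profile$grid$chrom
  } else lr <- profile
  if (is.null(chrom)) chrom <- rep("chr", length(lr))
  if (sum(!is.na(lr)) < 2) stop("need at least 2 unmasked bins")
  diffs <- unlist(lapply(split(lr, factor(chrom, unique(chrom))), function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) abs(diff(v)) else numeric(0)
  }), use.names = FALSE)
  stats::median(diffs)
}

#' Attach MAPD to a profile
#' @param profile a `cn_profile`
#' @return the profile with `$mapd` filled
#' @export
add_mapd <- function(profile) {
  profile$mapd <- mapd(profile)
  profile
}

#' Pipeline parameters for copy-number profiling
#'
#' @param mapd_threshold cells with MAPD strictly below this pass QC.
#' @param max_cn largest integer copy-number state for the HMM.
#' @param hmm_transition_stay probability of remaining in the same state
#'   between adjacent bins.
#' @param hmm_emission_sd emission standard deviation on the ratio scale;
#'   `NULL` (default) estimates it robustly from consecutive-bin
#'   differences of each profile.
#' @param min_control_count minimum control reads for an unmasked bin.
#' @export
pipeline_params <- function(mapd_threshold = 0.25, max_cn = 8L,
                            hmm_transition_stay = 0.995,
                            hmm_emission_sd = NULL,
                            min_control_count = 10) {
  stopifnot(mapd_threshold > 0, max_cn >= 2,
            hmm_transition_stay > 0, hmm_transition_stay < 1)
  list(mapd_threshold = mapd_threshold, max_cn = as.integer(max_cn),
       hmm_transition_stay = hmm_transition_stay,
       hmm_emission_sd = hmm_emission_sd,
       min_control_count = min_control_count)
}

# Viterbi decoding over integer copy-number states with Gaussian emissions
# on the ratio scale (state s emits around s/2). Log-space, vectorized over
# states per bin.
viterbi_cn <- function(ratio, max_cn, stay, sd) {
  states <- 0:max_cn
  mu <- states / 2
  n <- length(ratio)
  ns <- length(states)
  log_trans <- matrix(log((1 - stay) / (ns - 1)), ns, ns)
  diag(log_trans) <- log(stay)
  # state-0 emissions: a small positive mean avoids a zero-width component
  mu[1] <- 0.05
  emit <- function(x) stats::dnorm(x, mean = mu, sd = sd, log = TRUE)
  delta <- matrix(-Inf, n, ns)
  psi <- matrix(0L, n, ns)
  delta[1, ] <- log(1 / ns) + emit(ratio[1])
  for (t in 2:n) {
    cand <- delta[t - 1, ] + log_trans   # ns x ns: from row, to col
    best <- max.col(t(cand), ties.method = "first")
    psi[t, ] <- best
    delta[t, ] <- cand[cbind(best, seq_len(ns))] + emit(ratio[t])
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states[path]
}

#' Infer integer copy number with a hidden Markov model
#'
#' Viterbi decoding over states 0..`max_cn` with Gaussian emissions centered
#' at state/2 on the ratio scale; transitions are uniform off-diagonal with
#' a high stay probability, so single-bin outliers are smoothed while
#' multi-bin events are kept. The emission standard deviation is estimated
#' robustly from consecutive-bin differences (`mad(diff)/sqrt(2)`), i.e.
#' from within-segment noise. Masked bins inherit the nearest unmasked
#' state. Chromosomes are decoded independently.
#'
#' @param profile a `cn_profile` with ratios present.
#' @param params a [pipeline_params()] list.
#' @return the profile with `cn_state` filled.
#' @export
infer_copy_number <- function(profile, params = pipeline_params()) {
  ratio <- profile$ratio
  if (length(ratio) == 0L) stop("empty profile")
  ok <- !is.na(ratio)
  if (!any(ok)) stop("all bins masked")
  sd_est <- params$hmm_emission_sd
  if (is.null(sd_est)) {
    d <- diff(ratio[ok])
    sd_est <- max(stats::mad(d) / sqrt(2), 0.02)
  }
  cn <- rep(NA_integer_, length(ratio))
  for (chr in unique(profile$grid$chrom)) {
    idx <- which(profile$grid$chrom == chr & ok)
    if (length(idx) == 0L) next
    if (length(idx) == 1L) {
      cn[idx] <- max(0L, min(params$max_cn, round(2 * ratio[idx])))
      next
    }
    cn[idx] <- viterbi_cn(ratio[idx], params$max_cn,
                          params$hmm_transition_stay, sd_est)
  }
  # masked bins take the nearest decoded state
  nas <- which(is.na(cn))
  if (length(nas) && any(!is.na(cn))) {
    filled <- which(!is.na(cn))
    for (i in nas) cn[i] <- cn[filled[which.min(abs(filled - i))]]
  }
  profile$cn_state <- as.integer(cn)
  profile
}

#' Partition cells by MAPD quality control
#'
#' A cell passes iff its MAPD is strictly less than `mapd_threshold`
#' (default 0.25). The returned partition is exhaustive and disjoint.
#'
#' @param cells list of `cn_profile` objects (MAPD computed on the fly if
#'   missing).
#' @param params a [pipeline_params()] list.
#' @return list(pass = , fail = ) of profiles, plus a `qc` data.frame.
#' @export
qc_filter <- function(cells, params = pipeline_params()) {
  cells <- lapply(cells, function(p) if (is.na(p$mapd)) add_mapd(p) else p)
  m <- vapply(cells, `[[`, numeric(1), "mapd")
  pass <- m < params$mapd_threshold
  qc <- data.frame(cell_id = vapply(cells, `[[`, character(1), "sample_id"),
                   mapd = m, pass = pass, stringsAsFactors = FALSE)
  list(pass = cells[pass], fail = cells[!pass], qc = qc)
}

#' Consensus copy-number profile of a cell set
#'
#' Per-bin median of integer copy-number states across cells; even-count
#' ties take the lower middle value so the consensus stays integer. Stands
#' in for the profile of the clone the cells were drawn from.
#'
#' @param cells non-empty list of `cn_profile` with `cn_state` filled.
#' @return a `cn_profile` whose `cn_state` is the consensus (ratio set to
#'   cn/2).
#' @export
consensus_profile <- function(cells) {
  if (length(cells) == 0L) stop("empty cell set")
  grid <- cells[[1]]$grid
  for (p in cells)
    if (!same_grid(grid, p$grid)) stop("cells not on a shared grid")
  mat <- vapply(cells, `[[`, integer(nrow(grid)), "cn_state")
  mat <- matrix(mat, nrow = nrow(grid))
  cons <- apply(mat, 1, function(v) sort(v)[ceiling(length(v) / 2)])
  out <- new_cn_profile("consensus", grid, cons / 2,
                        masked = rep(FALSE, nrow(grid)))
  out$cn_state <- as.integer(cons)
  out
}

#' Pairwise Pearson similarity of profiles
#'
#' Correlates the per-bin values (ratio by default, or cn_state) of each
#' pair of profiles over bins unmasked in both. Constant profiles have
#' undefined correlation and are masked with a warning.
#'
#' @param profiles list of `cn_profile` (>= 2) on a shared grid.
#' @param use `"ratio"` or `"cn_state"`.
#' @return list(matrix = symmetric correlation matrix with unit diagonal,
#'   mean = mean over the off-diagonal upper triangle)
#' @export
profile_similarity <- function(profiles, use = c("ratio", "cn_state")) {
  use <- match.arg(use)
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  vals <- vapply(profiles, function(p) {
    v <- if (use == "ratio") p$ratio else as.numeric(p$cn_state)
    v[p$masked] <- NA_real_
    v
  }, numeric(length(profiles[[1]]$ratio)))
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    warning("constant profile(s): correlations involving them are NA")
  cm <- suppressWarnings(
    stats::cor(vals, use = "pairwise.complete.obs", method = "pearson"))
  dimnames(cm) <- list(ids, ids)
  diag(cm) <- 1
  ut <- cm[upper.tri(cm)]
  list(matrix = cm, mean = mean(ut, na.rm = TRUE))
}
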