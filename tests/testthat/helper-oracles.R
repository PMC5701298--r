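# Independent brute-force oracles. These deliberately re-derive each rule
# from scratch (set algebra, all-pairs scans, enumeration) so the package
# implementation is checked against a second, dumber path.

oracle_bin_count <- function(genome_spec, bin_size) {
  total <- 0
  for (len in genome_spec) total <- total + ceiling(len / bin_size)
  total
}

# replay events along the root-to-leaf path of each clone
oracle_clone_profiles <- function(grid, clone_tree, event_list) {
  path_to <- function(cl) {
    p <- character(0)
    while (!is.na(cl)) { p <- c(cl, p); cl <- clone_tree[[cl]] }
    p
  }
  out <- matrix(2L, length(clone_tree), nrow(grid),
                dimnames = list(names(clone_tree), NULL))
  for (cl in names(clone_tree)) {
    prof <- rep(2L, nrow(grid))
    for (anc in path_to(cl)) {
      ev <- event_list[event_list$clone == anc, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        w <- grid$end - grid$start
        ov <- pmin(grid$end, ev$end[i]) - pmax(grid$start, ev$start[i])
        hit <- grid$chrom == ev$chrom[i] & ov >= 0.5 * w
        prof[hit] <- ev$cn[i]
      }
    }
    out[cl, ] <- prof
  }
  out
}

# per-(variant, region) set intersection of two long call lists
oracle_consensus <- function(calls_a, calls_b) {
  ka <- paste(calls_a$key, calls_a$region)
  kb <- paste(calls_b$key, calls_b$region)
  intersect(ka, kb)
}

# all-pairs O(n^2) spacing filter: drop both members of any same-chromosome
# pair closer than min_spacing
oracle_spacing_drop <- function(chrom, pos, min_spacing = 15) {
  n <- length(pos)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && chrom[i] == chrom[j] && abs(pos[i] - pos[j]) < min_spacing)
      drop[i] <- TRUE
  }
  drop
}

# rule replay for the low-VAF rescue over all (variant, region) pairs
oracle_rescue <- function(consensus, present_a, present_b, vaf, thr = 0.2) {
  out <- consensus
  for (i in seq_len(nrow(consensus))) {
    if (!any(consensus[i, ])) next
    for (j in seq_len(ncol(consensus))) {
      one_caller <- (present_a[i, j] + present_b[i, j]) == 1
      if (!consensus[i, j] && one_caller && !is.na(vaf[i, j]) &&
          vaf[i, j] > thr)
        out[i, j] <- TRUE
    }
  }
  out
}

oracle_categories <- function(presence) {
  apply(presence, 1, function(row) {
    n <- sum(row)
    if (n == ncol(presence)) "ubiquitous" else if (n > 1) "shared"
    else "private"
  })
}

# lookup-table spectrum oracle over all 12 substitutions
oracle_spectrum_class <- function(ref, alt) {
  lut <- c("C>A" = "C>A", "C>G" = "C>G", "C>T" = "C>T",
           "T>A" = "T>A", "T>C" = "T>C", "T>G" = "T>G",
           "G>T" = "C>A", "G>C" = "C>G", "G>A" = "C>T",
           "A>T" = "T>A", "A>G" = "T>C", "A>C" = "T>G")
  unname(lut[paste0(ref, ">", alt)])
}

# exhaustive hypergeometric enumeration for a 2x2 Fisher two-sided p
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1)),
    numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n) scan run-length oracle for large-event selection (gap tolerance g)
oracle_large_runs <- function(bins, grid, min_span, gap = 1L) {
  b <- sort(unique(bins))
  if (!length(b)) return(integer(0))
  runs <- list(b[1])
  for (x in b[-1]) {
    last <- runs[[length(runs)]]
    prev <- last[length(last)]
    if (x - prev <= gap + 1L && grid$chrom[x] == grid$chrom[prev])
      runs[[length(runs)]] <- c(last, x)
    else runs[[length(runs) + 1L]] <- x
  }
  keep <- integer(0)
  for (r in runs)
    if (grid$end[max(r)] - grid$start[min(r)] >= min_span)
      keep <- c(keep, r)
  keep
}
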