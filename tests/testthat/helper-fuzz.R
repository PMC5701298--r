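# fuzzed caller-table generators shared by module and acceptance tests

# random caller tables for fuzzing; returns tables plus long call lists
fuzz_callers <- function(n = 100, regions = c("A", "B", "C"), seed = 1,
                         p_call = 0.4) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  tab0 <- data.frame(
    CHROM = sample(c("chr1", "chr2"), n, replace = TRUE),
    POS = sample(1e6, n), REF = ref,
    ALT = vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1)),
    GENE = sprintf("G%d", seq_len(n)), EFFECT = "nonsynonymous",
    QUAL = sample(20:60, n, replace = TRUE), stringsAsFactors = FALSE)
  tab0 <- tab0[!duplicated(paste(tab0$CHROM, tab0$POS)), ]
  mk <- function(caller) {
    tab <- tab0
    for (r in regions) {
      v <- round(runif(nrow(tab), 0.05, 0.6), 3)
      v[runif(nrow(tab)) > p_call] <- NA
      tab[[paste0("vaf_", r)]] <- v
    }
    tab$CALLER <- caller
    tab[rowSums(!is.na(tab[paste0("vaf_", regions)])) > 0, ]
  }
  list(a = mk("callerA"), b = mk("callerB"))
}

long_calls <- function(tab, regions) {
  key <- paste(tab$CHROM, tab$POS, tab$REF, tab$ALT, sep = ":")
  do.call(rbind, lapply(regions, function(r) {
    ok <- !is.na(tab[[paste0("vaf_", r)]])
    data.frame(key = key[ok], region = r, stringsAsFactors = FALSE)
  }))
}
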