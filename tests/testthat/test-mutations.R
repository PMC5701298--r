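test_that("consensus is per-(variant, region) caller intersection", {
  regions <- c("A", "B", "C")
  tabs <- fuzz_callers(500, regions, seed = 5)
  mc <- consensus_calls(tabs$a, tabs$b)
  got <- long_calls_from <- which(mc$consensus, arr.ind = TRUE)
  got <- paste(rownames(mc$consensus)[got[, 1]], regions[got[, 2]])
  want <- oracle_consensus(long_calls(tabs$a, regions),
                           long_calls(tabs$b, regions))
  expect_setequal(got, want)
  # every retained variant is a consensus call somewhere
  expect_true(all(rowSums(mc$consensus) > 0))
  # a variant called by only one caller everywhere is excluded entirely
  only_a <- setdiff(variant_keys <- paste(tabs$a$CHROM, tabs$a$POS,
                                          tabs$a$REF, tabs$a$ALT, sep = ":"),
                    paste(tabs$b$CHROM, tabs$b$POS, tabs$b$REF, tabs$b$ALT,
                          sep = ":"))
  expect_length(intersect(only_a, mc$variants$key), 0)

  bad <- tabs$a; bad$POS[1] <- 0
  expect_error(consensus_calls(bad, tabs$b), "coordinate")
  bad2 <- tabs$b; names(bad2)[names(bad2) == "vaf_A"] <- "vaf_Z"
  expect_error(consensus_calls(tabs$a, bad2), "naming")
})

simple_calls <- function(qual, chrom, pos, regions = "A",
                         present = NULL, vaf = 0.3) {
  n <- length(pos)
  tab <- data.frame(CHROM = chrom, POS = pos,
                    REF = rep("C", n), ALT = rep("T", n),
                    GENE = sprintf("G%d", seq_len(n)),
                    EFFECT = "nonsynonymous", QUAL = qual,
                    stringsAsFactors = FALSE)
  for (r in regions) tab[[paste0("vaf_", r)]] <- vaf
  tab$CALLER <- "x"
  tab
}

no_blood <- data.frame(CHROM = character(0), POS = numeric(0),
                       REF = character(0), ALT = character(0))

test_that("quality and spacing filters cut at the stated boundaries", {
  tab <- simple_calls(qual = c(29, 30, 50, 50, 50, 50), chrom = "chr1",
                      pos = c(1000, 2000, 3100, 3110, 5000, 5015))
  mc <- consensus_calls(tab, tab)
  f <- apply_quality_filters(mc, no_blood)
  # qual 29 dropped, 30 kept; pair at distance 10 dropped (both), 15 kept
  expect_setequal(f$variants$POS, c(2000, 5000, 5015))
  expect_error(apply_quality_filters(mc, NULL), "blood")
  # germline subtraction by exact allele-aware key
  blood <- data.frame(CHROM = "chr1", POS = 2000, REF = "C", ALT = "T")
  f2 <- apply_quality_filters(mc, blood)
  expect_setequal(f2$variants$POS, c(5000, 5015))
  # idempotence
  f3 <- apply_quality_filters(f2, blood)
  expect_equal(f3$variants, f2$variants)
})

test_that("spacing filter equals the all-pairs brute-force oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 200
    pos <- sample(5000, n)
    # plant some near-pairs
    pos[1:20] <- pos[21:40] + sample(c(-14:-1, 1:14), 20, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos <- abs(pos) + 1
    tab <- simple_calls(qual = rep(50, n), chrom = chrom, pos = pos)
    tab <- tab[!duplicated(paste(chrom, pos)), ]
    mc <- consensus_calls(tab, tab)
    f <- apply_quality_filters(mc, no_blood)
    drop <- oracle_spacing_drop(mc$variants$CHROM, mc$variants$POS)
    expect_setequal(f$variants$key, mc$variants$key[!drop])
  }
})

test_that("low-VAF rescue is strict at 0.2 and consensus-anchored", {
  mk <- function(vaf_a_in_A) {
    a <- simple_calls(50, "chr1", 100)
    a$vaf_A <- vaf_a_in_A; a$vaf_B <- 0.4
    b <- simple_calls(50, "chr1", 100)
    b$vaf_A <- NA_real_; b$vaf_B <- 0.4
    consensus_calls(a[c(names(a)[1:7], "vaf_A", "vaf_B", "CALLER")],
                    b[c(names(b)[1:7], "vaf_A", "vaf_B", "CALLER")])
  }
  r1 <- rescue_low_vaf(mk(0.25))
  expect_true(all(r1$presence[1, c("A", "B")]))
  expect_true(r1$rescued[1, "A"])
  r2 <- rescue_low_vaf(mk(0.20))  # boundary: 0.20 is not > 0.2
  expect_false(r2$presence[1, "A"])
  expect_true(r2$presence[1, "B"])
})

test_that("rescue equals the rule-replay oracle and is monotone", {
  for (seed in 1:5) {
    tabs <- fuzz_callers(200, seed = seed, p_call = 0.5)
    mc <- consensus_calls(tabs$a, tabs$b)
    got <- rescue_low_vaf(mc)
    want <- oracle_rescue(mc$consensus, mc$present_a, mc$present_b, mc$vaf)
    expect_equal(unname(got$presence), unname(want))
    # raising the threshold never increases presence
    stricter <- rescue_low_vaf(mc, vaf_threshold = 0.4)
    expect_true(all(got$presence >= stricter$presence))
  }
})

test_that("indel merging unions tables and deduplicates by max quality", {
  tabs <- fuzz_callers(100, seed = 3)
  mc <- rescue_low_vaf(consensus_calls(tabs$a, tabs$b))
  mm0 <- merge_indels(mc, NULL)
  expect_equal(nrow(mm0$presence), nrow(mc$presence))

  ind <- data.frame(CHROM = "chr9", POS = 777, REF = "A", ALT = "AT",
                    GENE = "IND1", EFFECT = "indel", QUAL = 55,
                    vaf_A = NA, vaf_B = NA, vaf_C = 0.3, CALLER = "callerA",
                    stringsAsFactors = FALSE)
  mm1 <- merge_indels(mc, ind)
  expect_equal(nrow(mm1$presence), nrow(mc$presence) + 1L)
  k <- "chr9:777:A:AT"
  expect_equal(unname(mm1$presence[k, ]), c(FALSE, FALSE, TRUE))
  expect_true(mm1$variants$is_indel[mm1$variants$key == k])

  # duplicate key keeps the max-quality record, cardinality by set oracle
  dup <- mc$variants[1, ]
  ind2 <- data.frame(CHROM = dup$CHROM, POS = dup$POS, REF = dup$REF,
                     ALT = dup$ALT, GENE = dup$GENE, EFFECT = "indel",
                     QUAL = 99, vaf_A = 0.2, vaf_B = NA, vaf_C = NA,
                     CALLER = "callerA", stringsAsFactors = FALSE)
  mm2 <- merge_indels(mc, rbind(ind, ind2))
  expect_equal(nrow(mm2$presence),
               length(union(mc$variants$key, c(k, dup$key))))
  expect_equal(mm2$variants$QUAL[mm2$variants$key == dup$key], 99)
})

test_that("categorization matches the count oracle and partitions", {
  for (seed in 1:4) {
    set.seed(seed)
    n_reg <- sample(2:6, 1)
    pres <- matrix(runif(1000 * n_reg) < 0.4, 1000, n_reg,
                   dimnames = list(sprintf("v%d", 1:1000), LETTERS[1:n_reg]))
    pres <- pres[rowSums(pres) > 0, ]
    mm <- structure(list(presence = pres,
                         variants = data.frame(key = rownames(pres))),
                    class = "mutation_matrix")
    mm <- categorize_mutations(mm)
    expect_equal(unname(mm$category), unname(oracle_categories(pres)))
    # exactly one label each; counts sum to matrix size
    expect_equal(sum(table(mm$category)), nrow(pres))
  }
  # the shared worked example: present in B, C, D of regions A-E
  pres <- matrix(c(FALSE, TRUE, TRUE, TRUE, FALSE), 1,
                 dimnames = list("PDE11A", LETTERS[1:5]))
  mm <- structure(list(presence = pres,
                       variants = data.frame(key = "PDE11A")),
                  class = "mutation_matrix")
  expect_equal(unname(categorize_mutations(mm)$category), "shared")
  # private and single-region degenerate case
  pres2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1)
  mm2 <- structure(list(presence = pres2,
                        variants = data.frame(key = "x")),
                   class = "mutation_matrix")
  expect_equal(unname(categorize_mutations(mm2)$category), "private")
  mm3 <- structure(list(presence = matrix(TRUE, 2, 1),
                        variants = data.frame(key = c("x", "y"))),
                   class = "mutation_matrix")
  expect_equal(unname(categorize_mutations(mm3)$category),
               c("ubiquitous", "ubiquitous"))
  mm4 <- structure(list(presence = matrix(FALSE, 1, 3),
                        variants = data.frame(key = "z")),
                   class = "mutation_matrix")
  expect_error(categorize_mutations(mm4), "all-false")
})

test_that("mutation spectrum collapses to pyrimidine context", {
  v <- data.frame(REF = "G", ALT = "A", is_indel = FALSE)
  expect_equal(unname(mutation_spectrum(v)[1, ]),
               c(0L, 0L, 1L, 0L, 0L, 0L))
  # empty set -> all-zero vector
  expect_equal(sum(mutation_spectrum(data.frame(REF = character(0),
                                                ALT = character(0)))), 0L)
  # 600 random substitutions vs the lookup-table oracle; conservation
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 600, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  counts <- mutation_spectrum(data.frame(REF = ref, ALT = alt))
  want <- table(factor(oracle_spectrum_class(ref, alt),
                       levels = colnames(counts)))
  expect_equal(unname(counts[1, ]), as.integer(want))
  expect_equal(sum(counts), 600L)
  expect_warning(mutation_spectrum(data.frame(REF = c("C", "N"),
                                              ALT = c("A", "T"))),
                 "non-ACGT")
})

test_that("spectrum tests match closed forms and enumeration", {
  f <- spectrum_test(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "fisher")
  expect_equal(f$p.value, 1.0)
  c2 <- spectrum_test(rbind(c(10, 20, 30), c(10, 20, 30)), "chi2")
  expect_equal(unname(c2$statistic), 0)
  expect_equal(c2$p.value, 1)
  # random small 2x2 tables vs exhaustive hypergeometric enumeration
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- spectrum_test(tab, "fisher")$p.value
    expect_equal(got, oracle_fisher_2x2(tab), tolerance = 1e-10)
  }
  expect_warning(spectrum_test(rbind(c(0, 0), c(1, 2)), "chi2"),
                 "zero-margin")
})

test_that("end-to-end catalog recovers simulated region presence", {
  cfg <- small_config(seed = 17, caller_fn_rate = 0.15)
  sim <- simulate_dataset(cfg)
  mm <- build_mutation_catalog(sim$mutations$caller_a,
                               sim$mutations$caller_b,
                               blood = sim$mutations$blood,
                               indels = sim$mutations$indels)
  # no germline variant survives subtraction
  expect_length(intersect(mm$variants$key,
                          paste(sim$mutations$blood$CHROM,
                                sim$mutations$blood$POS,
                                sim$mutations$blood$REF,
                                sim$mutations$blood$ALT, sep = ":")), 0)
  # category of recovered somatic variants matches simulated truth
  common <- intersect(mm$variants$key, sim$mutations$spec$variant)
  expect_gt(length(common), 30)
  truth_cat <- sim$mutations$spec$category[
    match(common, sim$mutations$spec$variant)]
  agree <- mean(mm$category[common] == truth_cat)
  expect_gt(agree, 0.85)
})
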