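test_that("plant_events realizes clone profiles along the tree", {
  grid <- build_genome(small_genome())
  cfg0 <- small_config(event_list = NULL)
  prof0 <- plant_events(grid, cfg0)
  expect_true(all(prof0 == 2L))

  cfg <- small_config()
  prof <- plant_events(grid, cfg)
  # child inherits the parent's chr1 gain and adds its own chr2 event
  chr1_ev <- which(grid$chrom == "chr1" & grid$start >= 10e6 &
                     grid$end <= 40e6)
  expect_true(all(prof["cloneA", chr1_ev] == 3L))
  expect_true(all(prof["cloneB", chr1_ev] == 3L))
  chr2_ev <- which(grid$chrom == "chr2" & grid$start >= 20e6 &
                     grid$end <= 30e6)
  expect_true(all(prof["cloneA", chr2_ev] == 2L))
  expect_true(all(prof["cloneB", chr2_ev] == 4L))
  expect_true(all(prof["diploid", ] == 2L))
})

test_that("nested events match the root-to-leaf path-replay oracle", {
  grid <- build_genome(c(chr1 = 20e6, chr2 = 20e6), bin_size = 1e6)
  tree <- c(r = NA, m = "r", l = "m")
  ev <- data.frame(
    clone = c("r", "m", "m", "l"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0, 5e6, 2e6, 10e6),
    end = c(10e6, 8e6, 6e6, 16e6),
    cn = c(3L, 1L, 4L, 0L), stringsAsFactors = FALSE)
  cfg <- sim_config(genome_spec = c(chr1 = 20e6, chr2 = 20e6),
                    bin_size = 1e6, clone_tree = tree, event_list = ev,
                    clone_fractions_per_region = list(A = c(r = 1, m = 0, l = 0)))
  got <- plant_events(grid, cfg)
  want <- oracle_clone_profiles(grid, tree, ev)
  expect_equal(got[rownames(want), ], want)
})

test_that("conflicting events on one clone/bin are rejected", {
  grid <- build_genome(c(chr1 = 10e6), bin_size = 1e6)
  ev <- data.frame(clone = c("cloneA", "cloneA"), chrom = "chr1",
                   start = c(0, 2e6), end = c(5e6, 7e6), cn = c(3L, 4L))
  cfg <- small_config(genome_spec = c(chr1 = 10e6), event_list = ev)
  expect_error(plant_events(grid, cfg), "conflicting")
})

test_that("simulation is deterministic and conserves cells", {
  cfg <- small_config(seed = 11)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$truth$cell_assignments),
               sum(cfg$n_cells_per_region))
  expect_equal(anyDuplicated(s1$truth$cell_assignments$cell_id), 0L)
  # different seed changes the draw
  s3 <- simulate_dataset(small_config(seed = 12))
  expect_false(identical(s1$depths$counts, s3$depths$counts))
})

test_that("depth noise hits the target MAPD and the Poisson limit", {
  # calibration: 52 diploid cells at target 0.20 land within +-0.05
  cfg <- small_config(seed = 1, n_cells_per_region = 13,
                      diploid_cell_fraction = 1)
  sim <- simulate_dataset(cfg)
  m <- vapply(colnames(sim$depths$counts), function(cid)
    mapd(normalize_depth(sim$depths$counts[, cid], sim$depths$control,
                         sim$grid, cid)), numeric(1))
  expect_gt(mean(m), 0.15)
  expect_lt(mean(m), 0.25)

  # dispersion -> 0 at high depth on a diploid genome: ratios ~ 1, tiny MAPD
  cfg0 <- small_config(seed = 2, target_mapd = NULL, depth_dispersion = 0,
                       depth_mean = 20000, wave_sd = 0,
                       diploid_cell_fraction = 1, n_cells_per_region = 1)
  sim0 <- simulate_dataset(cfg0)
  p <- normalize_depth(sim0$depths$counts[, 1], sim0$depths$control,
                       sim0$grid)
  expect_lt(max(abs(p$log2_ratio)), 0.1)
  expect_lt(mapd(p), 0.02)

  expect_error(simulate_cell_depths(sim$truth,
                                    small_config(target_mapd = -1)),
               "target_mapd")
})

test_that("a CN=4 segment doubles the expected depth", {
  cfg <- small_config(seed = 3, wave_sd = 0.02, diploid_cell_fraction = 0,
                      n_cells_per_region = 10,
                      clone_fractions_per_region = list(
                        A = c(cloneA = 0, cloneB = 1, cloneC = 0)))
  sim <- simulate_dataset(cfg)
  seg <- which(sim$grid$chrom == "chr2" & sim$grid$start >= 20e6 &
                 sim$grid$end <= 30e6)
  counts <- sim$depths$counts[seg, ]
  est <- mean(counts)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(est - 200), 3 * se + 200 * 0.01)  # 3 SE plus wave bias slack
})

test_that("mean realized MAPD is monotone in target_mapd", {
  realized <- vapply(c(0.15, 0.25, 0.35), function(tm) {
    cfg <- small_config(seed = 5, target_mapd = tm, n_cells_per_region = 5,
                        diploid_cell_fraction = 1)
    sim <- simulate_dataset(cfg)
    mean(vapply(colnames(sim$depths$counts), function(cid)
      mapd(normalize_depth(sim$depths$counts[, cid], sim$depths$control,
                           sim$grid, cid)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(realized) > 0))
})

test_that("bulk regions are clone mixtures (chi-square goodness of fit)", {
  cfg <- small_config(seed = 7)
  sim <- simulate_dataset(cfg)
  for (r in colnames(sim$bulk$counts)) {
    o <- sim$bulk$counts[, r]; e <- sim$bulk$expected[, r]
    stat <- sum((o - e)^2 / e)
    p <- stats::pchisq(stat, df = length(o), lower.tail = FALSE)
    expect_gt(p, 0.01)
  }
})

test_that("noise-free mutation calls equal ground truth", {
  cfg <- small_config(seed = 9, caller_fn_rate = 0, ado_rate = 0,
                      assay_fail_rate = 0, n_germline = 0, n_indels = 0)
  sim <- simulate_dataset(cfg)
  mut <- sim$mutations
  pa <- !is.na(as.matrix(mut$caller_a[grep("^vaf_", names(mut$caller_a))]))
  rownames(pa) <- variant_keys <- paste(mut$caller_a$CHROM, mut$caller_a$POS,
                                        mut$caller_a$REF, mut$caller_a$ALT,
                                        sep = ":")
  pb <- !is.na(as.matrix(mut$caller_b[grep("^vaf_", names(mut$caller_b))]))
  expect_equal(unname(pa), unname(pb))
  expect_equal(unname(pa),
               unname(mut$truth_presence[mut$spec$variant %in% variant_keys, ,
                                         drop = FALSE]))
  # assays reflect truth exactly when ado and failure are off
  tru <- mut$mutation_truth[cbind(match(mut$assays$variant,
                                        rownames(mut$mutation_truth)),
                                  match(mut$assays$cell_id,
                                        colnames(mut$mutation_truth)))]
  expect_equal(mut$assays$outcome == "present", tru)
})

test_that("ubiquitous variant VAF follows the purity closed form", {
  # all tumor clones carry it, purity 0.5 -> VAF 0.5 * 0.5 = 0.25
  cfg <- small_config(seed = 10, diploid_contamination = 0.5)
  sim <- simulate_dataset(cfg)
  ubi <- sim$mutations$spec$category == "ubiquitous"
  expect_true(all(abs(sim$mutations$vaf_true[ubi, ] - 0.25) < 1e-12))
})

test_that("caller miss fraction matches the binomial rate", {
  cfg <- small_config(seed = 2, caller_fn_rate = 0.3, n_mut_root = 1000,
                      n_mut_per_clone = 0, n_germline = 0, n_indels = 0)
  sim <- simulate_dataset(cfg)
  mut <- sim$mutations
  for (tab in list(mut$caller_a, mut$caller_b)) {
    called <- matrix(FALSE, nrow(mut$truth_presence),
                     ncol(mut$truth_presence),
                     dimnames = dimnames(mut$truth_presence))
    k <- paste(tab$CHROM, tab$POS, tab$REF, tab$ALT, sep = ":")
    called[match(k, rownames(called)), ] <-
      !is.na(as.matrix(tab[grep("^vaf_", names(tab))]))
    n <- sum(mut$truth_presence)
    miss <- sum(mut$truth_presence & !called) / n
    ci <- 0.3 + c(-1, 1) * 1.96 * sqrt(0.3 * 0.7 / n)
    expect_gt(miss, ci[1]); expect_lt(miss, ci[2])
  }
})

test_that("config invariants are enforced", {
  expect_error(sim_config(clone_fractions_per_region =
                            list(A = c(cloneA = 0.5, cloneB = 0.2,
                                       cloneC = 0))),
               "sum")
  expect_error(small_config(event_list = data.frame(
    clone = "cloneA", chrom = "chr1", start = 0, end = 99e6, cn = 3L)),
    "bounds")
  expect_error(small_config(ado_rate = 1.2), "rates")
  expect_error(sim_config(bin_size = -5), "bin_size")
  bad_spec <- data.frame(variant = "v1", chrom = "chr1", pos = 100,
                         ref = "A", alt = "T", gene = "G1",
                         effect = "nonsynonymous", carriers = "")
  cfg <- small_config(mutation_spec = bad_spec)
  sim_truth <- list(cell_assignments = data.frame(
    cell_id = "A1", region = "A", clone = "cloneA"))
  expect_error(simulate_mutation_calls(sim_truth, cfg), "no clone")
})
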