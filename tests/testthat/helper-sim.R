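# shared small-world fixtures, built in code at test time

small_genome <- function() c(chr1 = 60e6, chr2 = 60e6, chr3 = 60e6)

small_events <- function() data.frame(
  clone = c("cloneA", "cloneB"), chrom = c("chr1", "chr2"),
  start = c(10e6, 20e6), end = c(40e6, 30e6), cn = c(3L, 4L),
  stringsAsFactors = FALSE)

small_config <- function(seed = 1L, ...) {
  args <- list(genome_spec = small_genome(), event_list = small_events(),
               depth_mean = 100, target_mapd = 0.2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# a noise-free profile with given per-bin ratios on a toy grid
toy_profile <- function(ratio, chrom = NULL, sample_id = "toy") {
  n <- length(ratio)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  lens <- vapply(split(chrom, factor(chrom, unique(chrom))), length,
                 integer(1)) * 5e5
  grid <- build_genome(lens)
  p <- scith:::new_cn_profile(sample_id, grid, ratio,
                              masked = rep(FALSE, n))
  p
}

# cells x bins matrix with a planted subclonal CN event
planted_matrix <- function(n_cells = 35, n_bins = 120, event_bins = 41:50,
                           carriers = 1:14, cn = 4L, noise_rate = 0,
                           seed = 1) {
  set.seed(seed)
  m <- matrix(2L, n_cells, n_bins,
              dimnames = list(sprintf("c%02d", 1:n_cells), NULL))
  m[carriers, event_bins] <- cn
  if (noise_rate > 0) {
    flip <- matrix(runif(length(m)) < noise_rate, n_cells, n_bins)
    m[flip] <- m[flip] + sample(c(-1L, 1L), sum(flip), replace = TRUE)
    m[m < 0] <- 0L
  }
  m
}
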