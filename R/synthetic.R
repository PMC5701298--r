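#' Simulation configuration
#'
#' Builds and validates the full specification of a synthetic multi-region /
#' single-cell dataset: genome and bin size, a small clone tree with integer
#' copy-number events, per-region clone mixtures with diploid contamination,
#' single-cell depth noise calibrated to a target MAPD, a mutation catalog
#' with ubiquitous/shared/private structure, caller false negatives and
#' allelic dropout in single-cell validation assays.
#'
#' Defaults emulate the study design the package targets: 4 regions with
#' ~10 sorted cells each, ~500 kb bins, tumor purity around 0.5, depth of
#' about 60 reads per bin (roughly 0.3x coverage at 500 kb and 150 bp
#' paired reads), and target MAPD 0.20 (below the 0.25 QC cut).
#'
#' @param genome_spec named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param clone_tree named character vector mapping clone -> parent clone;
#'   the root has parent `NA`. Clone names must not include `"diploid"`.
#' @param event_list data.frame with columns `clone`, `chrom`, `start`,
#'   `end`, `cn` (integer copy number planted on that clone).
#' @param clone_fractions_per_region named list: region -> named numeric of
#'   tumor-clone fractions summing to 1.
#' @param diploid_contamination fraction of diploid (non-tumor) genome in
#'   each bulk region; scalar or named per-region vector.
#' @param diploid_cell_fraction probability that a sorted single cell is a
#'   normal diploid cell rather than a tumor cell.
#' @param depth_mean expected reads per full-width bin for a diploid state
#'   in single cells.
#' @param region_depth_mean expected reads per bin for bulk regions.
#' @param depth_dispersion negative-binomial overdispersion alpha
#'   (variance = mu + alpha*mu^2); 0 means Poisson. Ignored when
#'   `target_mapd` is given.
#' @param target_mapd calibrate single-cell noise so realized MAPD of
#'   log2-ratio profiles is close to this value; `NULL` to use
#'   `depth_dispersion` directly.
#' @param wave_sd standard deviation of the cell-specific lognormal
#'   amplification wave (smooth along the genome; mimics WGA nonuniformity).
#' @param n_cells_per_region named integer vector (or scalar) of sorted
#'   cells per region.
#' @param mutation_spec data.frame with columns `variant`, `carriers`
#'   (comma-separated clone names forming a connected subtree); `NULL` for
#'   an auto-generated catalog.
#' @param n_mut_root,n_mut_per_clone sizes of the auto-generated catalog:
#'   variants on the root (ubiquitous) and on each non-root clone.
#' @param n_germline number of germline variants (present in blood and all
#'   regions at VAF ~0.5) planted to exercise germline subtraction.
#' @param n_indels number of somatic indels reported by caller A only.
#' @param caller_fn_rate probability that one caller misses a truly present
#'   variant in one region.
#' @param ado_rate probability that a truly present mutation reads as absent
#'   in a single-cell validation assay (allelic dropout).
#' @param assay_fail_rate probability a single-cell assay fails outright.
#' @param seed master seed; all stage-level streams are derived from it.
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(genome_spec = default_genome(),
                       bin_size = 500000L,
                       clone_tree = c(cloneA = NA, cloneB = "cloneA",
                                      cloneC = "cloneB"),
                       event_list = default_events(),
                       clone_fractions_per_region = NULL,
                       diploid_contamination = 0.5,
                       diploid_cell_fraction = 0.3,
                       depth_mean = 60,
                       region_depth_mean = 500,
                       depth_dispersion = 0,
                       target_mapd = 0.20,
                       wave_sd = 0.05,
                       n_cells_per_region = 10L,
                       mutation_spec = NULL,
                       n_mut_root = 40L,
                       n_mut_per_clone = 15L,
                       n_germline = 20L,
                       n_indels = 8L,
                       caller_fn_rate = 0.05,
                       ado_rate = 0.2,
                       assay_fail_rate = 0.05,
                       seed = 1L) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (any(genome_spec <= 0)) stop("zero-length chromosome")
  clones <- names(clone_tree)
  if ("diploid" %in% clones) stop("'diploid' is a reserved clone name")
  root <- clones[is.na(clone_tree)]
  if (length(root) != 1L) stop("clone_tree must have exactly one root")
  if (!all(stats::na.omit(clone_tree) %in% clones))
    stop("clone_tree parent refers to unknown clone")

  if (is.null(clone_fractions_per_region)) {
    # default mixtures give the catalog ubiquitous/shared/private structure:
    # the root is everywhere, cloneB only in B-D, cloneC only in D
    regions <- c("A", "B", "C", "D")
    frac <- list(A = c(cloneB = 0, cloneC = 0),
                 B = c(cloneB = 0.25, cloneC = 0),
                 C = c(cloneB = 0.4, cloneC = 0),
                 D = c(cloneB = 0.3, cloneC = 0.3))
    clone_fractions_per_region <- lapply(regions, function(r) {
      f <- stats::setNames(rep(0, length(clones)), clones)
      shared <- intersect(names(frac[[r]]), clones)
      f[shared] <- frac[[r]][shared]
      f[root] <- f[root] + (1 - sum(f))
      f
    })
    names(clone_fractions_per_region) <- regions
  }
  regions <- names(clone_fractions_per_region)
  for (r in regions) {
    f <- clone_fractions_per_region[[r]]
    if (abs(sum(f) - 1) > 1e-9)
      stop(sprintf("clone fractions in region %s sum to %g, not 1", r, sum(f)))
    if (!all(names(f) %in% clones)) stop("fraction for unknown clone")
    if (any(f < 0)) stop("negative clone fraction")
  }
  if (length(diploid_contamination) == 1L)
    diploid_contamination <- stats::setNames(
      rep(diploid_contamination, length(regions)), regions)
  rates <- c(diploid_contamination, diploid_cell_fraction, caller_fn_rate,
             ado_rate, assay_fail_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(target_mapd) && target_mapd <= 0)
    stop("target_mapd must be > 0")

  if (!is.null(event_list) && nrow(event_list)) {
    if (!all(event_list$clone %in% clones)) stop("event on unknown clone")
    lens <- genome_spec[event_list$chrom]
    if (any(is.na(lens))) stop("event on unknown chromosome")
    if (any(event_list$start < 0 | event_list$end > lens |
            event_list$start >= event_list$end))
      stop("event outside chromosome bounds")
    if (any(event_list$cn < 0 | event_list$cn != round(event_list$cn)))
      stop("event cn must be a nonnegative integer")
  }
  if (length(n_cells_per_region) == 1L)
    n_cells_per_region <- stats::setNames(
      rep(as.integer(n_cells_per_region), length(regions)), regions)

  cfg <- list(genome_spec = genome_spec, bin_size = bin_size,
              clone_tree = clone_tree, event_list = event_list,
              clone_fractions_per_region = clone_fractions_per_region,
              diploid_contamination = diploid_contamination,
              diploid_cell_fraction = diploid_cell_fraction,
              depth_mean = depth_mean, region_depth_mean = region_depth_mean,
              depth_dispersion = depth_dispersion, target_mapd = target_mapd,
              wave_sd = wave_sd, n_cells_per_region = n_cells_per_region,
              mutation_spec = mutation_spec, n_mut_root = n_mut_root,
              n_mut_per_clone = n_mut_per_clone,
              n_germline = n_germline, n_indels = n_indels,
              caller_fn_rate = caller_fn_rate, ado_rate = ado_rate,
              assay_fail_rate = assay_fail_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' hg19-style chromosome lengths (autosomes + X), bp
#'
#' Used as the default simulated genome so bin counts land in the same
#' regime as real ~500 kb tilings of the human genome.
#' @export
default_genome <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516,
    chr12 = 133851895, chr13 = 115169878, chr14 = 107349540,
    chr15 = 102531392, chr16 = 90354753, chr17 = 81195210,
    chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560)
}

#' Default clonal + subclonal event set
#'
#' Clonal gains/losses shared by the whole tumor (on the root clone) plus
#' one multi-Mb subclonal event on the child clone, echoing the common
#' colorectal pattern of chr20q gain and chr18q loss.
#' @export
default_events <- function() {
  data.frame(
    clone = c("cloneA", "cloneA", "cloneA", "cloneB"),
    chrom = c("chr20", "chr18", "chr8", "chr3"),
    start = c(30e6, 40e6, 100e6, 120e6),
    end   = c(63e6, 78e6, 146e6, 160e6),
    cn    = c(3L, 1L, 3L, 4L),
    stringsAsFactors = FALSE)
}

# deterministic child seed streams (below 2^31)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + k * 12347) %% 2147483629)
}

clone_order <- function(clone_tree) {
  ord <- character(0)
  remaining <- names(clone_tree)
  while (length(remaining)) {
    ready <- remaining[is.na(clone_tree[remaining]) |
                         clone_tree[remaining] %in% ord]
    if (!length(ready)) stop("clone_tree contains a cycle")
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord
}

#' Realize clone copy-number profiles on a bin grid
#'
#' Each child clone inherits its parent's per-bin profile, then applies its
#' own events. A bin takes an event's copy number when the event covers at
#' least half of the bin. Two events of the same clone hitting the same bin
#' with different copy numbers are rejected.
#'
#' @param grid a `bin_grid`
#' @param config a `sim_config`
#' @return integer matrix clones x bins; a `diploid` row (all 2) is included
#' @export
plant_events <- function(grid, config) {
  clones <- clone_order(config$clone_tree)
  profiles <- matrix(2L, nrow = length(clones) + 1L, ncol = nrow(grid),
                     dimnames = list(c("diploid", clones), NULL))
  ev <- config$event_list
  for (cl in clones) {
    parent <- config$clone_tree[[cl]]
    profiles[cl, ] <- if (is.na(parent)) 2L else profiles[parent, ]
    if (is.null(ev) || !nrow(ev)) next
    own <- ev[ev$clone == cl, , drop = FALSE]
    touched <- integer(0)
    for (i in seq_len(nrow(own))) {
      idx <- bins_for_interval(grid, own$chrom[i], own$start[i], own$end[i])
      clash <- intersect(idx, touched)
      if (length(clash) &&
          any(profiles[cl, clash] != own$cn[i]))
        stop(sprintf("conflicting events on clone %s", cl))
      profiles[cl, idx] <- as.integer(own$cn[i])
      touched <- union(touched, idx)
    }
  }
  profiles
}

#' Assign sorted cells to clones
#'
#' Each region contributes `n_cells_per_region` cells; a cell is diploid
#' with probability `diploid_cell_fraction`, otherwise a tumor clone drawn
#' from the region's clone fractions.
#' @keywords internal
assign_cells <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  regions <- names(config$clone_fractions_per_region)
  rows <- lapply(regions, function(r) {
    n <- config$n_cells_per_region[[r]]
    clone <- character(n)
    for (i in seq_len(n)) {
      if (stats::runif(1) < config$diploid_cell_fraction) clone[i] <- "diploid"
      else {
        f <- config$clone_fractions_per_region[[r]]
        clone[i] <- sample(names(f), 1L, prob = f)
      }
    }
    data.frame(cell_id = sprintf("%s%d", r, seq_len(n)), region = r,
               clone = clone, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# NB size parameter calibrated so that log2-ratio MAPD ~= target.
# MAPD of iid noise = sigma * sqrt(2) * qnorm(0.75); delta method maps the
# required log2 sd to a count-scale variance at the diploid mean.
calibrate_nb_size <- function(depth_mean, target_mapd) {
  sigma <- target_mapd / (sqrt(2) * stats::qnorm(0.75))
  var_needed <- (sigma * log(2) * depth_mean)^2
  if (var_needed <= depth_mean) return(Inf)  # Poisson floor
  depth_mean^2 / (var_needed - depth_mean)
}

rcounts <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate single-cell binned read depths
#'
#' Per-bin counts are negative binomial with mean proportional to the
#' cell's clone copy number, times a smooth cell-specific lognormal wave
#' that mimics whole-genome-amplification nonuniformity. Overdispersion is
#' calibrated so the realized MAPD of control-normalized log2-ratio
#' profiles is close to `target_mapd`. A noise-free diploid expectation
#' vector (`control`) is also returned.
#'
#' @param truth list with `clone_profiles` (from [plant_events()]) and
#'   `cell_assignments` (from the dataset simulator)
#' @param config a `sim_config`
#' @param grid the `bin_grid`
#' @return list(counts = bins x cells integer matrix, control = numeric,
#'   nb_size = calibrated NB size)
#' @export
simulate_cell_depths <- function(truth, config, grid) {
  if (!is.null(config$target_mapd) && config$target_mapd <= 0)
    stop("target_mapd must be > 0")
  set.seed(child_seed(config$seed, 2L))
  widths <- bin_widths(grid) / config$bin_size
  size <- if (!is.null(config$target_mapd))
    calibrate_nb_size(config$depth_mean, config$target_mapd)
  else if (config$depth_dispersion <= 0) Inf
  else 1 / config$depth_dispersion

  cells <- truth$cell_assignments
  nb <- nrow(grid)
  counts <- matrix(0L, nrow = nb, ncol = nrow(cells),
                   dimnames = list(NULL, cells$cell_id))
  period <- max(20, round(nb / 30))
  for (j in seq_len(nrow(cells))) {
    cn <- truth$clone_profiles[cells$clone[j], ]
    amp <- stats::rnorm(1, 0, config$wave_sd)
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- exp(amp * sin(2 * pi * seq_len(nb) / period + phase))
    mu <- config$depth_mean * widths * (cn / 2) * wave
    counts[, j] <- rcounts(nb, mu, size)
  }
  control <- config$depth_mean * widths
  list(counts = counts, control = control, nb_size = size)
}

#' Simulate bulk region depths as clone mixtures
#'
#' Expected depth per bin mixes tumor-clone copy numbers by region fractions
#' and adds diploid contamination; counts are Poisson (bulk libraries are
#' far less dispersed than amplified single cells).
#'
#' @inheritParams simulate_cell_depths
#' @return list(counts = bins x regions matrix, expected = same shape)
#' @export
simulate_region_depths <- function(truth, config, grid) {
  set.seed(child_seed(config$seed, 3L))
  widths <- bin_widths(grid) / config$bin_size
  regions <- names(config$clone_fractions_per_region)
  nb <- nrow(grid)
  expected <- counts <- matrix(0, nrow = nb, ncol = length(regions),
                               dimnames = list(NULL, regions))
  for (r in regions) {
    f <- config$clone_fractions_per_region[[r]]
    contam <- config$diploid_contamination[[r]]
    mix_cn <- rep(0, nb)
    for (cl in names(f))
      mix_cn <- mix_cn + f[[cl]] * truth$clone_profiles[cl, ]
    mix_cn <- (1 - contam) * mix_cn + contam * 2
    expected[, r] <- config$region_depth_mean * widths * mix_cn / 2
    counts[, r] <- stats::rpois(nb, expected[, r])
  }
  list(counts = counts, expected = expected)
}

subtree_clones <- function(clone_tree, top) {
  out <- top
  repeat {
    more <- names(clone_tree)[clone_tree %in% out & !(names(clone_tree) %in% out)]
    if (!length(more)) return(out)
    out <- c(out, more)
  }
}

#' Auto-generate a mutation catalog on the clone tree
#'
#' Root variants are carried by every tumor clone (ubiquitous); each
#' non-root clone gets variants carried by its own subtree, producing
#' shared/private structure through the region clone mixtures.
#' @keywords internal
make_mutation_spec <- function(config) {
  set.seed(child_seed(config$seed, 4L))
  clones <- clone_order(config$clone_tree)
  root <- clones[1L]
  carriers <- c(
    rep(paste(subtree_clones(config$clone_tree, root), collapse = ","),
        config$n_mut_root),
    unlist(lapply(setdiff(clones, root), function(cl)
      rep(paste(subtree_clones(config$clone_tree, cl), collapse = ","),
          config$n_mut_per_clone))))
  n <- length(carriers)
  chroms <- names(config$genome_spec)
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- vapply(chrom, function(ch)
    floor(stats::runif(1, 1, config$genome_spec[[ch]])), numeric(1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(variant = sprintf("v%03d", seq_len(n)), chrom = chrom,
             pos = pos, ref = ref, alt = alt,
             gene = sprintf("GENE%03d", seq_len(n)),
             effect = sample(c("nonsynonymous", "synonymous"), n,
                             replace = TRUE, prob = c(0.8, 0.2)),
             carriers = carriers, stringsAsFactors = FALSE)
}

#' Simulate dual-caller mutation tables and single-cell validation assays
#'
#' Per-region true VAF is the carrier-clone fraction times 0.5 (heterozygous)
#' times tumor purity, plus small Gaussian noise. Each caller independently
#' misses a truly present (variant, region) with `caller_fn_rate`.
#' Single-cell assay outcomes flip present -> absent with `ado_rate` and
#' fail outright with `assay_fail_rate`.
#'
#' @param truth list with `cell_assignments`
#' @param config a `sim_config`
#' @return list(caller_a, caller_b = call tables; truth_presence = variant x
#'   region logical; vaf_true = variant x region numeric; mutation_truth =
#'   variant x cell logical; assays = long data.frame of assay outcomes;
#'   spec = the mutation catalog with derived categories)
#' @export
simulate_mutation_calls <- function(truth, config) {
  spec <- config$mutation_spec
  if (is.null(spec)) spec <- make_mutation_spec(config)
  if (any(!nzchar(spec$carriers)))
    stop("variant assigned to no clone")
  set.seed(child_seed(config$seed, 5L))
  regions <- names(config$clone_fractions_per_region)
  nv <- nrow(spec)
  # key variants the same way the catalog does, so panels and assays join
  spec$variant <- paste(spec$chrom, spec$pos, spec$ref, spec$alt, sep = ":")
  carriers <- strsplit(spec$carriers, ",", fixed = TRUE)
  all_clones <- names(config$clone_tree)
  if (!all(unlist(carriers) %in% all_clones))
    stop("variant carried by unknown clone")

  vaf_true <- matrix(0, nv, length(regions),
                     dimnames = list(spec$variant, regions))
  for (r in regions) {
    f <- config$clone_fractions_per_region[[r]]
    purity <- 1 - config$diploid_contamination[[r]]
    for (i in seq_len(nv)) {
      cf <- sum(f[intersect(names(f), carriers[[i]])])
      vaf_true[i, r] <- cf * 0.5 * purity
    }
  }
  truth_presence <- vaf_true > 0

  make_caller <- function(name) {
    vaf_obs <- pmin(pmax(vaf_true +
      stats::rnorm(length(vaf_true), 0, 0.02) * (vaf_true > 0), 0), 1)
    called <- truth_presence &
      matrix(stats::runif(length(vaf_true)) >= config$caller_fn_rate,
             nv, length(regions))
    vaf_obs[!called] <- NA_real_
    tab <- data.frame(CHROM = spec$chrom, POS = spec$pos, REF = spec$ref,
                      ALT = spec$alt, GENE = spec$gene, EFFECT = spec$effect,
                      QUAL = round(stats::runif(nv, 30, 60)),
                      stringsAsFactors = FALSE)
    for (r in regions) tab[[paste0("vaf_", r)]] <- vaf_obs[, r]
    tab$CALLER <- name
    tab[rowSums(!is.na(vaf_obs)) > 0, , drop = FALSE]
  }
  caller_a <- make_caller("callerA")
  caller_b <- make_caller("callerB")

  bases <- c("A", "C", "G", "T")
  rand_sites <- function(n, prefix) {
    chrom <- sample(names(config$genome_spec), n, replace = TRUE)
    ref <- sample(bases, n, replace = TRUE)
    data.frame(CHROM = chrom,
               POS = vapply(chrom, function(ch)
                 floor(stats::runif(1, 1, config$genome_spec[[ch]])),
                 numeric(1)),
               REF = ref,
               ALT = vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                            character(1)),
               GENE = sprintf("%s%03d", prefix, seq_len(n)),
               EFFECT = "other",
               QUAL = round(stats::runif(n, 30, 60)),
               stringsAsFactors = FALSE)
  }

  # germline variants: VAF ~0.5 in blood and every region, called by both
  blood <- NULL
  if (config$n_germline > 0) {
    gl <- rand_sites(config$n_germline, "GERM")
    gl$EFFECT <- "synonymous"
    for (r in regions)
      gl[[paste0("vaf_", r)]] <-
        pmin(pmax(stats::rnorm(config$n_germline, 0.5, 0.03), 0), 1)
    gla <- gl; gla$CALLER <- "callerA"
    glb <- gl; glb$CALLER <- "callerB"
    glb[paste0("vaf_", regions)] <- gl[paste0("vaf_", regions)] +
      stats::rnorm(config$n_germline * length(regions), 0, 0.01)
    caller_a <- rbind(caller_a, gla[names(caller_a)])
    caller_b <- rbind(caller_b, glb[names(caller_b)])
    blood <- gl[, c("CHROM", "POS", "REF", "ALT")]
    blood$vaf_blood <- gl[[paste0("vaf_", regions[1])]]
  }

  # somatic indels (single-caller, germline-subtracted upstream)
  indels <- NULL
  if (config$n_indels > 0) {
    ind <- rand_sites(config$n_indels, "INDL")
    ind$EFFECT <- "indel"
    ins <- stats::runif(config$n_indels) < 0.5
    ind$ALT[ins] <- paste0(ind$REF[ins], "A")
    ind$REF[!ins] <- paste0(ind$REF[!ins], "T")
    carr_idx <- sample(seq_along(carriers), config$n_indels, replace = TRUE)
    for (r in regions) {
      f <- config$clone_fractions_per_region[[r]]
      purity <- 1 - config$diploid_contamination[[r]]
      v <- vapply(carr_idx, function(i)
        sum(f[intersect(names(f), carriers[[i]])]) * 0.5 * purity, numeric(1))
      v[v == 0] <- NA_real_
      ind[[paste0("vaf_", r)]] <- v
    }
    ind$CALLER <- "callerA"
    indels <- ind[rowSums(!is.na(ind[paste0("vaf_", regions)])) > 0, ,
                  drop = FALSE]
  }

  cells <- truth$cell_assignments
  mutation_truth <- matrix(FALSE, nv, nrow(cells),
                           dimnames = list(spec$variant, cells$cell_id))
  for (j in seq_len(nrow(cells)))
    mutation_truth[, j] <- vapply(carriers, function(cc)
      cells$clone[j] %in% cc, logical(1))

  # derived region-level category for ground truth
  n_reg <- rowSums(truth_presence)
  spec$category <- ifelse(n_reg == length(regions), "ubiquitous",
                          ifelse(n_reg > 1, "shared", "private"))

  assays <- expand.grid(cell_id = cells$cell_id, variant = spec$variant,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tru <- mutation_truth[cbind(match(assays$variant, spec$variant),
                              match(assays$cell_id, cells$cell_id))]
  u <- stats::runif(nrow(assays))
  outcome <- ifelse(tru, ifelse(u < config$ado_rate, "absent", "present"),
                    "absent")
  failed <- stats::runif(nrow(assays)) < config$assay_fail_rate
  outcome[failed] <- "failed"
  assays$outcome <- outcome

  list(caller_a = caller_a, caller_b = caller_b, blood = blood,
       indels = indels, truth_presence = truth_presence,
       vaf_true = vaf_true, mutation_truth = mutation_truth,
       assays = assays, spec = spec)
}

#' Simulate a complete ground-truth dataset
#'
#' Runs the whole generator: bin grid, clone profiles, cell assignments,
#' single-cell and bulk depths, dual-caller mutation tables and validation
#' assays. The returned object carries full ground truth for
#' parameter-recovery tests.
#'
#' @param config a `sim_config`
#' @return list of class `scith_sim` with elements `grid`, `truth`
#'   (clone_profiles, cell_assignments, region_compositions), `depths`,
#'   `bulk`, `mutations`, `config`
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- build_genome(config$genome_spec, config$bin_size)
  clone_profiles <- plant_events(grid, config)
  cell_assignments <- assign_cells(config)
  truth <- list(clone_profiles = clone_profiles,
                cell_assignments = cell_assignments,
                region_compositions = config$clone_fractions_per_region)
  depths <- simulate_cell_depths(truth, config, grid)
  bulk <- simulate_region_depths(truth, config, grid)
  mutations <- simulate_mutation_calls(truth, config)
  truth$mutation_truth <- mutations$mutation_truth
  structure(list(grid = grid, truth = truth, depths = depths, bulk = bulk,
                 mutations = mutations, config = config),
            class = "scith_sim")
}

#' @export
print.scith_sim <- function(x, ...) {
  cat(sprintf(
    "scith_sim: %d bins, %d clones, %d regions, %d cells, %d variants\n",
    nrow(x$grid), nrow(x$truth$clone_profiles) - 1L,
    length(x$config$clone_fractions_per_region),
    nrow(x$truth$cell_assignments), nrow(x$mutations$spec)))
  invisible(x)
}
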