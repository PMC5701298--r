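#' Genome bin grid
#'
#' A `bin_grid` is an ordered, non-overlapping tiling of a genome into
#' fixed-width bins (0-based, half-open coordinates). All depth profiles,
#' copy-number profiles and bin-level statistics in this package are aligned
#' to one shared grid. The last bin of each chromosome may be shorter than
#' `bin_size` when the chromosome length is not an exact multiple.
#'
#' @param genome_spec named numeric vector of chromosome lengths in bp, or a
#'   list of `(name, length)` pairs. Order is preserved as `chrom_order`.
#' @param bin_size bin width in bp (default 500 kb).
#' @return A data.frame of class `bin_grid` with columns `chrom`, `start`,
#'   `end` and attribute `chrom_order`.
#' @examples
#' grid <- build_genome(c(chr1 = 3e6), bin_size = 5e5)
#' nrow(grid)  # 6
#' @export
build_genome <- function(genome_spec, bin_size = 500000L) {
  if (is.list(genome_spec)) {
    nm <- vapply(genome_spec, function(x) as.character(x[[1]]), character(1))
    genome_spec <- stats::setNames(
      vapply(genome_spec, function(x) as.numeric(x[[2]]), numeric(1)), nm)
  }
  if (length(genome_spec) == 0L)
    stop("genome_spec must be non-empty")
  if (is.null(names(genome_spec)) || any(!nzchar(names(genome_spec))))
    stop("genome_spec chromosomes must be named")
  if (any(genome_spec <= 0))
    stop("zero- or negative-length chromosome in genome_spec")
  if (length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")

  pieces <- lapply(names(genome_spec), function(chr) {
    len <- genome_spec[[chr]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "chrom_order") <- names(genome_spec)
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins over %d chromosome(s), bin size %s bp\n",
              nrow(x), length(attr(x, "chrom_order")),
              format(attr(x, "bin_size"), big.mark = ",")))
  invisible(x)
}

#' Check that two objects share the same bin grid
#' @keywords internal
same_grid <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$start == b$start) && all(a$end == b$end)
}

#' Bin widths in bp
#' @keywords internal
bin_widths <- function(grid) grid$end - grid$start

#' Map a genomic interval to the bin indices it covers by at least half a bin
#'
#' A bin takes an event if the overlap between event and bin is >= 50% of
#' the bin's width.
#' @keywords internal
bins_for_interval <- function(grid, chrom, start, end) {
  idx <- which(grid$chrom == chrom)
  if (length(idx) == 0L) return(integer(0))
  ov <- pmin(grid$end[idx], end) - pmax(grid$start[idx], start)
  keep <- ov >= 0.5 * bin_widths(grid)[idx]
  idx[keep]
}

#' Read a bin grid from a BED file
#'
#' @param path BED file (chrom, start, end; no header).
#' @return a `bin_grid`
#' @export
read_bins_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"))
  attr(df, "chrom_order") <- unique(df$chrom)
  attr(df, "bin_size") <- if (nrow(df)) max(df$end - df$start) else NA_real_
  class(df) <- c("bin_grid", "data.frame")
  df
}

#' Write a bin grid as BED
#' @param grid a `bin_grid`
#' @param path output path
#' @export
write_bins_bed <- function(grid, path) {
  utils::write.table(as.data.frame(grid)[, c("chrom", "start", "end")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
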