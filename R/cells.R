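#' Flag whether a cell carries somatic copy-number alterations
#'
#' TRUE iff the profile contains at least one contiguous autosomal run of
#' bins with copy-number state different from 2 spanning at least
#' `min_event_span` bp. The span rule suppresses isolated HMM errors: real
#' clonal SCNAs in these tumors are multi-megabase.
#'
#' @param profile a `cn_profile` with `cn_state` filled.
#' @param min_event_span minimum genomic span in bp (default 5 Mb).
#' @return logical
#' @export
ploidy_flag <- function(profile, min_event_span = 5e6) {
  if (is.null(profile$cn_state) || length(profile$cn_state) == 0L)
    stop("empty profile or cn_state not inferred")
  grid <- profile$grid
  auto <- !(grid$chrom %in% c("chrX", "chrY", "X", "Y"))
  for (chr in unique(grid$chrom[auto])) {
    idx <- which(grid$chrom == chr)
    ab <- profile$cn_state[idx] != 2L
    r <- rle(ab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span <- grid$end[idx[ends[k]]] - grid$start[idx[starts[k]]]
      if (span >= min_event_span) return(TRUE)
    }
  }
  FALSE
}

#' Validation panel for cell-identity calls
#'
#' Two targeted Sanger panels per patient: 5-6 ubiquitous nonsynonymous
#' mutations used to screen out somatic diploid cells, and 14 nonsynonymous
#' mutations used to confirm tumor cells.
#'
#' @param patient patient id.
#' @param candidate_mutations character vector (length 5 or 6) of variant
#'   keys for the diploid screen.
#' @param tumor_panel character vector (length 14) for tumor confirmation.
#' @return list of class `validation_panel`
#' @export
validation_panel <- function(patient, candidate_mutations, tumor_panel) {
  if (!length(candidate_mutations) %in% c(5L, 6L))
    stop("candidate panel must contain 5 or 6 mutations")
  if (length(tumor_panel) != 14L)
    stop("tumor panel must contain 14 mutations")
  structure(list(patient = patient,
                 candidate_mutations = candidate_mutations,
                 tumor_panel = tumor_panel),
            class = "validation_panel")
}

count_present <- function(assays, cell_id, panel_variants) {
  rows <- assays$cell_id == cell_id & assays$variant %in% panel_variants
  if (!any(rows)) return(NA_integer_)
  # 'failed' outcomes count as absent (conservative toward exclusion)
  sum(assays$outcome[rows] == "present")
}

#' Classify one sorted cell as normal, tumor, mixture or ambiguous
#'
#' Decision rules, applied in order:
#' * no SCNA and zero candidate-panel mutations present -> `normal`
#'   (somatic diploid cell);
#' * no SCNA but more than 3 candidate mutations present -> `mixture`
#'   (likely one diploid cell plus tumor-cell debris; excluded);
#' * SCNA present and at least 4 of the 14 tumor-panel mutations present ->
#'   `tumor`;
#' * anything else -> `ambiguous` (excluded from downstream analysis).
#'
#' @param cell_id cell name.
#' @param has_scna from [ploidy_flag()].
#' @param assays long data.frame (`cell_id`, `variant`, `outcome` in
#'   present/absent/failed).
#' @param panel a [validation_panel()].
#' @param mixture_threshold candidate-mutation count above which a diploid
#'   cell is called a mixture (default 3, i.e. "more than three").
#' @param tumor_min_mutations minimum tumor-panel mutations for
#'   confirmation (default 4).
#' @return list of class `cell_record` with `identity`, `n_present` etc.
#' @export
classify_cell <- function(cell_id, has_scna, assays, panel,
                          mixture_threshold = 3L, tumor_min_mutations = 4L,
                          region = NA_character_) {
  cand_n <- count_present(assays, cell_id, panel$candidate_mutations)
  tum_n <- count_present(assays, cell_id, panel$tumor_panel)
  if (is.na(cand_n) && is.na(tum_n))
    stop(sprintf("no assay outcomes for cell %s", cell_id))
  identity <- if (!has_scna) {
    if (is.na(cand_n)) "ambiguous"
    else if (cand_n == 0L) "normal"
    else if (cand_n > mixture_threshold) "mixture"
    else "ambiguous"
  } else {
    if (!is.na(tum_n) && tum_n >= tumor_min_mutations) "tumor" else "ambiguous"
  }
  structure(list(cell_id = cell_id, patient = panel$patient, region = region,
                 has_scna = has_scna,
                 n_present = if (has_scna) tum_n else cand_n,
                 identity = identity),
            class = "cell_record")
}

#' Classify a whole cohort of cells
#'
#' @param profiles list of `cn_profile` with `cn_state` filled (names or
#'   `sample_id` give the cell ids).
#' @param assays assay-outcome table.
#' @param panel a [validation_panel()].
#' @param regions optional named vector cell_id -> region.
#' @param min_event_span passed to [ploidy_flag()].
#' @inheritParams classify_cell
#' @return data.frame, one row per cell
#' @export
classify_cohort <- function(profiles, assays, panel, regions = NULL,
                            min_event_span = 5e6, mixture_threshold = 3L,
                            tumor_min_mutations = 4L) {
  rows <- lapply(profiles, function(p) {
    rec <- classify_cell(p$sample_id, ploidy_flag(p, min_event_span),
                         assays, panel, mixture_threshold,
                         tumor_min_mutations,
                         region = if (is.null(regions)) NA_character_
                                  else regions[[p$sample_id]])
    data.frame(cell_id = rec$cell_id, patient = rec$patient,
               region = rec$region, has_scna = rec$has_scna,
               n_present = rec$n_present, identity = rec$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identity counts per patient and region
#'
#' @param records data.frame from [classify_cohort()] (columns `patient`,
#'   `region`, `identity`).
#' @return list(by_region = long count table, totals = per patient x
#'   identity counts, n = total cells)
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0L)
    return(list(by_region = records[0, ], totals = records[0, ], n = 0L))
  by_region <- as.data.frame(
    table(patient = records$patient, region = records$region,
          identity = records$identity),
    responseName = "count", stringsAsFactors = FALSE)
  by_region <- by_region[by_region$count > 0, ]
  rownames(by_region) <- NULL
  totals <- as.data.frame(
    table(patient = records$patient, identity = records$identity),
    responseName = "count", stringsAsFactors = FALSE)
  list(by_region = by_region, totals = totals, n = nrow(records))
}
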