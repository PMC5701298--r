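write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build single-cell profiles from a simulated dataset
#'
#' Normalizes every cell against the control, computes MAPD, applies the
#' QC filter and infers integer copy number for passing cells.
#' @param sim a `scith_sim` from [simulate_dataset()].
#' @param params a [pipeline_params()] list.
#' @return list(profiles = named list of `cn_profile` (QC pass, CN
#'   inferred), qc = QC table, failed = failed profiles)
#' @export
profile_cells <- function(sim, params = pipeline_params()) {
  cells <- colnames(sim$depths$counts)
  profs <- lapply(cells, function(cid)
    add_mapd(normalize_depth(sim$depths$counts[, cid], sim$depths$control,
                             sim$grid, sample_id = cid,
                             min_control_count = params$min_control_count)))
  qc <- qc_filter(profs, params)
  pass <- lapply(qc$pass, infer_copy_number, params = params)
  names(pass) <- vapply(pass, `[[`, character(1), "sample_id")
  list(profiles = pass, qc = qc$qc, failed = qc$fail)
}

#' Select validation panels from a categorized mutation catalog
#'
#' Candidate (diploid-screen) panel: the first `n_candidate` ubiquitous
#' nonsynonymous SNVs; tumor panel: the first 14 nonsynonymous SNVs by
#' descending quality. Deterministic given the catalog.
#' @param mm a categorized `mutation_matrix`.
#' @param patient patient id.
#' @param n_candidate candidate panel size (5 or 6).
#' @return a [validation_panel()]
#' @export
select_panels <- function(mm, patient = "P1", n_candidate = 6L) {
  snv <- !mm$variants$is_indel & mm$variants$EFFECT == "nonsynonymous"
  ubiq <- which(snv & mm$category == "ubiquitous")
  if (length(ubiq) < n_candidate)
    stop("not enough ubiquitous nonsynonymous mutations for the panel")
  ord <- order(-mm$variants$QUAL)
  tum <- ord[ord %in% which(snv)][1:14]
  if (length(tum) < 14 || any(is.na(tum)))
    stop("not enough nonsynonymous mutations for the tumor panel")
  validation_panel(patient,
                   mm$variants$key[ubiq[seq_len(n_candidate)]],
                   mm$variants$key[tum])
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages, in dependency order: `simulate` (generate the dataset),
#' `scna` (per-cell normalization, MAPD QC, HMM copy number), `mutations`
#' (dual-caller catalog with rescue and categorization), `cells`
#' (tumor/normal/mixture classification), `subclones` (variance + PCA bin
#' mining, large-event selection, PAM subpopulations). Writes TSV/BED/JSON
#' artifacts and a manifest with per-file checksums; identical config and
#' seed reproduce identical checksums.
#'
#' @param config list with elements `seed`, `outdir`, optional `sim`
#'   (a [sim_config()] or argument list), `params` ([pipeline_params()]),
#'   `subclone` ([subclone_params()]), `stages` (character subset).
#' @return list with stage results and `manifest`
#' @export
run_pipeline <- function(config) {
  stages <- config$stages %||% c("simulate", "scna", "mutations", "cells",
                                 "subclones")
  outdir <- config$outdir %||% tempfile("scith_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params %||% pipeline_params()
  sparams <- config$subclone %||% subclone_params()
  res <- list(outdir = outdir)
  written <- character(0)

  sim_cfg <- config$sim %||% sim_config(seed = config$seed %||% 1L)
  if (!inherits(sim_cfg, "sim_config"))
    sim_cfg <- do.call(sim_config, sim_cfg)
  if (!is.null(config$seed)) sim_cfg$seed <- as.integer(config$seed)

  if ("simulate" %in% stages) {
    sim <- simulate_dataset(sim_cfg)
    res$sim <- sim
    written <- c(written,
      write_bins_bed(sim$grid, file.path(outdir, "bins.bed")),
      write_tsv(cbind(as.data.frame(sim$grid),
                      as.data.frame(sim$depths$counts)),
                file.path(outdir, "cell_depths.tsv")),
      write_tsv(data.frame(control = sim$depths$control),
                file.path(outdir, "control.tsv")),
      write_tsv(sim$mutations$caller_a, file.path(outdir, "caller_a.tsv")),
      write_tsv(sim$mutations$caller_b, file.path(outdir, "caller_b.tsv")),
      write_tsv(sim$truth$cell_assignments,
                file.path(outdir, "truth_cells.tsv")))
  } else stop("pipeline currently runs from the simulate stage")

  if ("scna" %in% stages) {
    res$scna <- profile_cells(sim, params)
    written <- c(written,
      write_tsv(res$scna$qc, file.path(outdir, "qc.tsv")))
    prof_tab <- do.call(cbind, lapply(res$scna$profiles,
                                      function(p) p$cn_state))
    written <- c(written,
      write_tsv(cbind(as.data.frame(sim$grid), as.data.frame(prof_tab)),
                file.path(outdir, "cn_states.tsv")))
  }

  if ("mutations" %in% stages) {
    res$catalog <- build_mutation_catalog(
      sim$mutations$caller_a, sim$mutations$caller_b,
      blood = sim$mutations$blood, indels = sim$mutations$indels)
    cat_tab <- cbind(res$catalog$variants,
                     category = res$catalog$category,
                     as.data.frame(res$catalog$presence))
    written <- c(written,
      write_tsv(cat_tab, file.path(outdir, "mutation_catalog.tsv")),
      write_tsv(as.data.frame(mutation_spectrum(res$catalog)),
                file.path(outdir, "spectrum.tsv")))
  }

  if ("cells" %in% stages) {
    panel <- select_panels(res$catalog, patient = "SIM")
    regions <- stats::setNames(sim$truth$cell_assignments$region,
                               sim$truth$cell_assignments$cell_id)
    res$panel <- panel
    res$cells <- classify_cohort(res$scna$profiles, sim$mutations$assays,
                                 panel, regions = regions)
    res$summary <- cohort_summary(res$cells)
    written <- c(written,
      write_tsv(res$cells, file.path(outdir, "cell_identity.tsv")))
  }

  if ("subclones" %in% stages) {
    tumor_ids <- res$cells$cell_id[res$cells$identity == "tumor"]
    mat <- t(vapply(res$scna$profiles[tumor_ids], `[[`,
                    integer(nrow(sim$grid)), "cn_state"))
    cand <- pca_candidate_bins(mat, sparams)
    sel <- select_large_events(cand$candidate_bins, sim$grid, sparams)
    res$subclones <- assign_subclones(mat, sel$selected_bins, sparams)
    res$subclone_events <- sel$events
    labs <- data.frame(cell_id = names(res$subclones$labels),
                       cluster = as.integer(res$subclones$labels))
    written <- c(written,
      write_tsv(labs, file.path(outdir, "subclone_labels.tsv")),
      write_tsv(sel$events, file.path(outdir, "subclone_events.bed")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("scith")),
    seed = sim_cfg$seed, stages = stages,
    checksums = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' `scith <simulate|all> --config cfg.yaml --out dir --seed n`. The config
#' file (YAML if the yaml package is available, else JSON) supplies
#' [sim_config()] arguments under `sim`, [pipeline_params()] under
#' `params` and [subclone_params()] under `subclone`.
#'
#' @param args character vector (default: command line).
#' @return exit status, invisibly (0 ok, 1 input error, 2 internal error)
#' @export
scith_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: scith <simulate|all> [--config f] [--out d] [--seed n]",
           call. = FALSE)
    cmd <- args[1]
    opt <- list(config = NULL, out = "scith_out", seed = 1L)
    i <- 2L
    while (i <= length(args)) {
      key <- sub("^--", "", args[i])
      if (!key %in% names(opt)) stop("unknown option: ", args[i], call. = FALSE)
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
    cfg <- list()
    if (!is.null(opt$config)) {
      cfg <- if (grepl("[.]ya?ml$", opt$config) &&
                 requireNamespace("yaml", quietly = TRUE))
        yaml::read_yaml(opt$config)
      else jsonlite::read_json(opt$config, simplifyVector = TRUE)
    }
    cfg$seed <- as.integer(opt$seed)
    cfg$outdir <- opt$out
    if (cmd == "simulate") cfg$stages <- "simulate"
    else if (cmd != "all") stop("unknown command: ", cmd, call. = FALSE)
    run <- run_pipeline(cfg)
    message("wrote ", length(run$manifest$checksums), " artifacts to ",
            run$outdir)
    0L
  }, error = function(e) {
    message("scith: ", conditionMessage(e))
    if (inherits(e, "simpleError") && grepl("usage:|unknown", conditionMessage(e)))
      1L else 2L
  })
  invisible(status)
}
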