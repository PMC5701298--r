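variant_key <- function(tab) paste(tab$CHROM, tab$POS, tab$REF, tab$ALT,
                                   sep = ":")

vaf_columns <- function(tab) grep("^vaf_", names(tab), value = TRUE)

#' Intersect two callers' variant tables
#'
#' A SNV is a consensus call in a region iff both callers reported it
#' there. Per-caller detections and observed VAFs are preserved so the
#' low-VAF rescue step can revisit single-caller evidence.
#'
#' @param caller_a,caller_b call tables (columns `CHROM`, `POS`, `REF`,
#'   `ALT`, `GENE`, `EFFECT`, `QUAL` and one `vaf_<region>` column per
#'   region; `NA` VAF means not called there).
#' @return object of class `mutation_calls`: `variants` data.frame plus
#'   logical matrices `present_a`, `present_b`, `consensus` and numeric
#'   `vaf` (variant x region).
#' @export
consensus_calls <- function(caller_a, caller_b) {
  va <- vaf_columns(caller_a); vb <- vaf_columns(caller_b)
  if (!setequal(va, vb))
    stop("caller tables use different sample naming")
  if (any(caller_a$POS == 0) || any(caller_b$POS == 0))
    stop("position 0 found: coordinate systems likely differ (expect 1-based)")
  regions <- sub("^vaf_", "", va)
  ka <- variant_key(caller_a); kb <- variant_key(caller_b)
  keys <- union(ka, kb)

  presence_of <- function(tab, k) {
    m <- matrix(FALSE, length(keys), length(regions),
                dimnames = list(keys, regions))
    v <- matrix(NA_real_, length(keys), length(regions),
                dimnames = list(keys, regions))
    i <- match(k, keys)
    for (j in seq_along(regions)) {
      obs <- tab[[paste0("vaf_", regions[j])]]
      m[i, j] <- !is.na(obs)
      v[i, j] <- obs
    }
    list(p = m, v = v)
  }
  a <- presence_of(caller_a, ka); b <- presence_of(caller_b, kb)
  consensus <- a$p & b$p
  keep <- rowSums(consensus) > 0
  meta <- rbind(
    caller_a[, c("CHROM", "POS", "REF", "ALT", "GENE", "EFFECT", "QUAL")],
    caller_b[, c("CHROM", "POS", "REF", "ALT", "GENE", "EFFECT", "QUAL")])
  meta$key <- c(ka, kb)
  meta <- meta[order(-meta$QUAL), ]
  meta <- meta[!duplicated(meta$key), ]
  meta <- meta[match(keys[keep], meta$key), ]
  vaf <- a$v
  vaf[is.na(vaf)] <- b$v[is.na(vaf)]
  both <- !is.na(a$v) & !is.na(b$v)
  vaf[both] <- (a$v[both] + b$v[both]) / 2
  structure(list(variants = meta[, c("key", "CHROM", "POS", "REF", "ALT",
                                     "GENE", "EFFECT", "QUAL")],
                 present_a = a$p[keep, , drop = FALSE],
                 present_b = b$p[keep, , drop = FALSE],
                 consensus = consensus[keep, , drop = FALSE],
                 vaf = vaf[keep, , drop = FALSE],
                 regions = regions),
            class = "mutation_calls")
}

subset_calls <- function(mc, keep) {
  mc$variants <- mc$variants[keep, , drop = FALSE]
  for (f in c("present_a", "present_b", "consensus", "vaf"))
    mc[[f]] <- mc[[f]][keep, , drop = FALSE]
  mc
}

#' Quality, spacing and germline filters
#'
#' Drops variants with base quality below 30, drops *both* members of any
#' same-chromosome pair closer than 15 bp, and removes germline variants by
#' exact (chrom, pos, ref, alt) match against the matched-blood call set.
#' Germline subtraction is mandatory: tumor-only tables cannot distinguish
#' somatic from inherited variants.
#'
#' @param mc a `mutation_calls` object.
#' @param blood data.frame of blood (germline) calls with `CHROM`, `POS`,
#'   `REF`, `ALT`.
#' @param min_quality base-quality cut (strictly below is dropped).
#' @param min_spacing minimum distance in bp between two retained variants
#'   on one chromosome (strictly below is dropped).
#' @return filtered `mutation_calls`
#' @export
apply_quality_filters <- function(mc, blood, min_quality = 30,
                                  min_spacing = 15) {
  if (missing(blood) || is.null(blood))
    stop("matched blood sample is required for germline subtraction")
  keep <- mc$variants$QUAL >= min_quality
  bkey <- paste(blood$CHROM, blood$POS, blood$REF, blood$ALT, sep = ":")
  keep <- keep & !(mc$variants$key %in% bkey)
  # spacing on the surviving set: any same-chromosome pair < min_spacing
  # removes both members (equivalent to adjacent check after sorting)
  surv <- which(keep)
  df <- mc$variants[surv, ]
  bad <- rep(FALSE, length(surv))
  for (chr in unique(df$CHROM)) {
    i <- which(df$CHROM == chr)
    o <- i[order(df$POS[i])]
    if (length(o) < 2) next
    d <- diff(df$POS[o])
    close <- d < min_spacing
    bad[o[c(close, FALSE)]] <- bad[o[c(close, FALSE)]] | TRUE
    bad[o[c(FALSE, close)]] <- bad[o[c(FALSE, close)]] | TRUE
  }
  keep[surv[bad]] <- FALSE
  subset_calls(mc, keep)
}

#' Rescue low-frequency variants missed by one caller
#'
#' A variant that is a dual-caller consensus call in at least one region of
#' the patient gains presence in any additional region where exactly one
#' caller detected it, provided the observed VAF there exceeds the
#' threshold (strict >). This recovers false negatives of variants whose
#' reality is already established elsewhere in the tumor.
#'
#' @param mc a filtered `mutation_calls`.
#' @param vaf_threshold rescue cut (default 0.2).
#' @return `mutation_calls` with a `presence` matrix (consensus + rescued)
#'   and a logical `rescued` matrix.
#' @export
rescue_low_vaf <- function(mc, vaf_threshold = 0.2) {
  single <- xor(mc$present_a, mc$present_b)
  if (any(single & is.na(mc$vaf)))
    stop("caller flags claim a detection but VAF is missing")
  eligible <- rowSums(mc$consensus) > 0
  rescued <- single & !mc$consensus & eligible &
    !is.na(mc$vaf) & mc$vaf > vaf_threshold
  mc$presence <- mc$consensus | rescued
  mc$rescued <- rescued
  mc
}

#' Merge single-caller indels into the final mutation set
#'
#' Indels bypass the dual-caller requirement: the indel table (assumed
#' germline-subtracted) is unioned with the rescued SNV set. Duplicate
#' (chrom, pos, ref, alt) keys keep the max-quality record.
#'
#' @param mc a `mutation_calls` after [rescue_low_vaf()].
#' @param indels indel table in the same column layout, or `NULL`.
#' @return object of class `mutation_matrix`: `variants` data.frame (with
#'   `is_indel`), `presence` and `vaf` matrices.
#' @export
merge_indels <- function(mc, indels = NULL) {
  variants <- mc$variants
  variants$is_indel <- nchar(variants$REF) != 1 | nchar(variants$ALT) != 1
  presence <- mc$presence
  vaf <- mc$vaf
  if (!is.null(indels) && nrow(indels)) {
    ik <- variant_key(indels)
    dup <- ik %in% variants$key
    if (any(dup)) {
      # keep max-quality record for duplicated keys
      for (i in which(dup)) {
        j <- match(ik[i], variants$key)
        if (indels$QUAL[i] > variants$QUAL[j])
          variants$QUAL[j] <- indels$QUAL[i]
      }
      indels <- indels[!dup, , drop = FALSE]
      ik <- ik[!dup]
    }
    if (nrow(indels)) {
      iv <- as.matrix(indels[, paste0("vaf_", mc$regions), drop = FALSE])
      rownames(iv) <- ik
      add <- data.frame(key = ik, CHROM = indels$CHROM, POS = indels$POS,
                        REF = indels$REF, ALT = indels$ALT,
                        GENE = indels$GENE, EFFECT = indels$EFFECT,
                        QUAL = indels$QUAL, is_indel = TRUE,
                        stringsAsFactors = FALSE)
      variants <- rbind(variants, add)
      presence <- rbind(presence, !is.na(iv))
      vaf <- rbind(vaf, iv)
    }
  }
  keep <- rowSums(presence) > 0
  structure(list(variants = variants[keep, , drop = FALSE],
                 presence = presence[keep, , drop = FALSE],
                 vaf = vaf[keep, , drop = FALSE],
                 regions = mc$regions),
            class = "mutation_matrix")
}

#' Categorize mutations by regional distribution
#'
#' `ubiquitous`: present in all regions; `shared`: in more than one but not
#' all; `private`: in exactly one. With a single region every retained
#' variant is (degenerately) ubiquitous.
#'
#' @param mm a `mutation_matrix`.
#' @return the matrix with a `category` vector added.
#' @export
categorize_mutations <- function(mm) {
  n <- rowSums(mm$presence)
  if (any(n == 0)) stop("all-false presence row; should be dropped upstream")
  total <- ncol(mm$presence)
  mm$category <- ifelse(n == total, "ubiquitous",
                        ifelse(n > 1, "shared", "private"))
  names(mm$category) <- mm$variants$key
  mm
}

#' Full mutation-catalog construction
#'
#' Chains consensus intersection, quality/spacing/germline filters, low-VAF
#' rescue, indel merging and categorization.
#'
#' @inheritParams consensus_calls
#' @inheritParams apply_quality_filters
#' @param indels optional single-caller indel table.
#' @param vaf_threshold rescue threshold.
#' @return a categorized `mutation_matrix`
#' @export
build_mutation_catalog <- function(caller_a, caller_b, blood, indels = NULL,
                                   min_quality = 30, min_spacing = 15,
                                   vaf_threshold = 0.2) {
  mc <- consensus_calls(caller_a, caller_b)
  mc <- apply_quality_filters(mc, blood, min_quality, min_spacing)
  mc <- rescue_low_vaf(mc, vaf_threshold)
  categorize_mutations(merge_indels(mc, indels))
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d variants x %d regions", nrow(x$presence),
              ncol(x$presence)))
  if (!is.null(x$category))
    cat(" (", paste(sprintf("%s %d", names(table(x$category)),
                            table(x$category)), collapse = ", "), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

collapse_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("G", "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  paste0(ref, ">", alt)
}

#' Six-class mutation spectrum per region
#'
#' Counts SNVs present in each region over the pyrimidine-collapsed
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G (purine-context
#' substitutions are reverse-complemented, e.g. G>A counts as C>T). Indels
#' and non-ACGT records are excluded (the latter with a warning).
#'
#' @param mm a `mutation_matrix` (or data.frame with `REF`, `ALT`).
#' @param presence optional variant x region logical matrix when `mm` is a
#'   bare data.frame; default: count each variant once in a single group.
#' @return integer matrix regions x 6 classes
#' @export
mutation_spectrum <- function(mm, presence = NULL) {
  if (inherits(mm, "mutation_matrix")) {
    variants <- mm$variants[!mm$variants$is_indel, , drop = FALSE]
    presence <- mm$presence[!mm$variants$is_indel, , drop = FALSE]
  } else {
    variants <- mm
    if (is.null(presence))
      presence <- matrix(TRUE, nrow(variants), 1,
                         dimnames = list(NULL, "all"))
  }
  ok <- variants$REF %in% c("A", "C", "G", "T") &
    variants$ALT %in% c("A", "C", "G", "T")
  if (any(!ok)) {
    warning(sprintf("%d records with non-ACGT alleles excluded", sum(!ok)))
    variants <- variants[ok, , drop = FALSE]
    presence <- presence[ok, , drop = FALSE]
  }
  cls <- collapse_substitution(variants$REF, variants$ALT)
  out <- matrix(0L, ncol(presence), length(SPECTRUM_CLASSES),
                dimnames = list(colnames(presence), SPECTRUM_CLASSES))
  for (j in seq_len(ncol(presence))) {
    t <- table(factor(cls[presence[, j]], levels = SPECTRUM_CLASSES))
    out[j, ] <- as.integer(t)
  }
  out
}

#' Contingency test on a mutation-spectrum table
#'
#' Chi-squared test over the full group x class table, or a two-sided
#' Fisher exact test after collapsing to 2x2 (focal class vs rest, focal
#' group vs rest). Zero-margin rows are dropped with a warning. No
#' multiple-testing adjustment is applied.
#'
#' @param counts nonnegative integer matrix, groups x classes.
#' @param mode `"chi2"` or `"fisher"`.
#' @param focal_class,focal_group for `"fisher"`, name or index defining
#'   the 2x2 collapse (defaults: last class / first group if the table is
#'   larger than 2x2).
#' @return list(statistic, p.value, method, table)
#' @export
spectrum_test <- function(counts, mode = c("chi2", "fisher"),
                          focal_class = NULL, focal_group = NULL) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("dropping zero-margin row(s): ",
            paste(rownames(counts)[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  if (mode == "chi2") {
    ht <- suppressWarnings(stats::chisq.test(counts))
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                method = "chi-squared", table = counts))
  }
  if (!all(dim(counts) == c(2, 2))) {
    if (is.null(focal_class)) focal_class <- ncol(counts)
    if (is.null(focal_group)) focal_group <- 1L
    if (is.character(focal_class))
      focal_class <- match(focal_class, colnames(counts))
    if (is.character(focal_group))
      focal_group <- match(focal_group, rownames(counts))
    counts <- rbind(
      c(counts[focal_group, focal_class],
        sum(counts[focal_group, -focal_class])),
      c(sum(counts[-focal_group, focal_class]),
        sum(counts[-focal_group, -focal_class])))
  }
  ht <- stats::fisher.test(counts, alternative = "two.sided")
  list(statistic = unname(ht$estimate), p.value = ht$p.value,
       method = "fisher", table = counts)
}
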