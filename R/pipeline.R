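# Sample QC, call filtering, PennCNV-style merging of neighbouring calls,
# gene-centric genotype construction and CNV-map support annotation.

#' Quality-control thresholds
#'
#' Defaults follow common array-CNV practice for PennCNV output: samples are
#' excluded on LRR standard deviation > 0.28 (with an additional hard cutoff
#' at >= 0.4), BAF drift > 0.01, |waviness factor| > 0.05, LRR outlier rate
#' > 0.1, BAF standard deviation >= 0.2, or more than 100 CNV calls; calls
#' supported by fewer than 5 probes are removed; neighbouring same-type
#' calls separated by a gap below 20% of their combined span are merged.
#' Strict vs non-strict comparisons are deliberate and match the criteria as
#' usually stated (">" vs ">=").
#'
#' @param lrr_sd_max,baf_drift_max,waviness_abs_max,lrr_outlier_max numeric
#'   exclusion cutoffs (sample excluded when strictly exceeded).
#' @param baf_sd_max,lrr_sd_hard_max cutoffs applied with `>=`.
#' @param max_cnvs_per_sample samples with more calls are excluded.
#' @param min_probes_per_call calls with fewer probes are removed.
#' @param merge_gap_fraction gap/span ratio below which neighbouring calls
#'   merge, in (0, 1).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(lrr_sd_max = 0.28, baf_drift_max = 0.01,
                          waviness_abs_max = 0.05, lrr_outlier_max = 0.1,
                          baf_sd_max = 0.2, lrr_sd_hard_max = 0.4,
                          max_cnvs_per_sample = 100L,
                          min_probes_per_call = 5L,
                          merge_gap_fraction = 0.2) {
  thr <- list(lrr_sd_max = lrr_sd_max, baf_drift_max = baf_drift_max,
              waviness_abs_max = waviness_abs_max,
              lrr_outlier_max = lrr_outlier_max, baf_sd_max = baf_sd_max,
              lrr_sd_hard_max = lrr_sd_hard_max,
              max_cnvs_per_sample = as.integer(max_cnvs_per_sample),
              min_probes_per_call = as.integer(min_probes_per_call),
              merge_gap_fraction = merge_gap_fraction)
  stopifnot(all(vapply(thr, function(x) x > 0, logical(1))),
            merge_gap_fraction < 1)
  class(thr) <- "qc_thresholds"
  thr
}

#' Sample-level quality control
#'
#' A sample is excluded if it breaches any criterion; the report lists every
#' breached criterion per excluded sample.
#'
#' @param metrics data.frame with columns `sample_id`, `lrr_sd`, `baf_drift`,
#'   `waviness_factor`, `lrr_outlier_rate`, `baf_sd`, `n_cnvs`.
#' @param thr a [qc_thresholds()].
#' @return A list with `kept` (character sample IDs) and `report`
#'   (data.frame of `sample_id`, `criterion` rows for exclusions).
#' @export
filter_samples <- function(metrics, thr = qc_thresholds()) {
  required <- c("sample_id", "lrr_sd", "baf_drift", "waviness_factor",
                "lrr_outlier_rate", "baf_sd", "n_cnvs")
  missing_col <- setdiff(required, names(metrics))
  if (length(missing_col))
    stop("QC metrics missing column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  for (f in required[-1]) {
    if (anyNA(metrics[[f]]))
      stop("missing QC metric '", f, "' for sample ",
           metrics$sample_id[which(is.na(metrics[[f]]))[1]], call. = FALSE)
  }
  checks <- list(
    lrr_sd = metrics$lrr_sd > thr$lrr_sd_max,
    baf_drift = metrics$baf_drift > thr$baf_drift_max,
    waviness = abs(metrics$waviness_factor) > thr$waviness_abs_max,
    lrr_outliers = metrics$lrr_outlier_rate > thr$lrr_outlier_max,
    baf_sd = metrics$baf_sd >= thr$baf_sd_max,
    lrr_sd_hard = metrics$lrr_sd >= thr$lrr_sd_hard_max,
    max_cnvs = metrics$n_cnvs > thr$max_cnvs_per_sample
  )
  report <- do.call(rbind, lapply(names(checks), function(nm) {
    i <- which(checks[[nm]])
    if (!length(i)) return(NULL)
    data.frame(sample_id = metrics$sample_id[i], criterion = nm,
               stringsAsFactors = FALSE)
  }))
  if (is.null(report))
    report <- data.frame(sample_id = character(), criterion = character(),
                         stringsAsFactors = FALSE)
  excluded <- Reduce(`|`, checks)
  list(kept = metrics$sample_id[!excluded],
       report = report[order(report$sample_id), , drop = FALSE])
}

#' Probe-count call filtering
#'
#' Removes calls supported by fewer than `min_probes_per_call` probes
#' (default: five or more probes retained). Order is preserved.
#'
#' @param calls a [cnv_calls()] table.
#' @param thr a [qc_thresholds()].
#' @return The filtered [cnv_calls()] table.
#' @export
filter_calls <- function(calls, thr = qc_thresholds()) {
  out <- calls[calls$n_probes >= thr$min_probes_per_call, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge neighbouring CNV calls
#'
#' Within each (sample, chromosome, CNV type) group, neighbouring calls are
#' merged left-to-right, repeatedly until a fixed point, whenever the gap
#' between them is less than `fraction` of the total length of the combined
#' call. "Total length" is the merged span `next_end - prev_start + 1` and
#' the gap excludes both endpoints (`next_start - prev_end - 1`), matching
#' PennCNV `clean_cnv` semantics. Merged calls sum their probe counts;
#' the copy number is kept when the parts agree and dropped otherwise.
#'
#' @param calls a [cnv_calls()] table.
#' @param fraction gap/span ratio below which calls merge (default 0.2).
#' @return A [cnv_calls()] table, sorted by sample, chromosome, start.
#' @export
merge_adjacent <- function(calls, fraction = 0.2) {
  if (!nrow(calls)) return(calls)
  calls <- as.data.frame(calls)
  key <- paste(calls$sample_id, calls$chrom, calls$cnv_type, sep = "\r")
  pieces <- lapply(split(calls, key), .merge_group, fraction = fraction)
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample_id, match(out$chrom, .valid_chroms), out$start,
                   out$cnv_type), , drop = FALSE]
  rownames(out) <- NULL
  validate_cnv_calls(out)
}

.merge_group <- function(g, fraction) {
  g <- g[order(g$start, g$end), , drop = FALSE]
  repeat {
    n <- nrow(g)
    if (n < 2) return(g)
    merged_any <- FALSE
    keep <- rep(TRUE, n)
    i <- 1L
    while (i < n) {
      j <- i + 1L
      while (j <= n && !keep[j]) j <- j + 1L
      if (j > n) break
      gap <- g$start[j] - g$end[i] - 1
      span <- max(g$end[i], g$end[j]) - g$start[i] + 1
      if (gap / span < fraction) {
        g$end[i] <- max(g$end[i], g$end[j])
        g$n_probes[i] <- g$n_probes[i] + g$n_probes[j]
        if (!identical(g$copy_number[i], g$copy_number[j]))
          g$copy_number[i] <- NA_integer_
        keep[j] <- FALSE
        merged_any <- TRUE
      } else {
        i <- j
      }
    }
    g <- g[keep, , drop = FALSE]
    if (!merged_any) return(g)
  }
}

.calls_granges <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start, end = calls$end)
  )
}

# findOverlaps, silencing the seqlevels-union warning that fires whenever
# query and subject cover different chromosome subsets (expected here)
.overlaps <- function(query, subject) {
  suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, minoverlap = 1L)
  )
}

.regions_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
}

#' Build the gene-centric genotype matrix
#'
#' A subject carries a deletion (duplication) genotype at a gene region iff
#' any of its deletion (duplication) calls overlaps the region by one or
#' more base pairs. Overlap uses an interval index (GenomicRanges), not an
#' all-pairs scan. Regions flagged hypervariable, or named in
#' `exclude_symbols`, are dropped from the output.
#'
#' @param calls a filtered/merged [cnv_calls()] table.
#' @param regions a [gene_regions()] table.
#' @param sample_ids subject universe (rows of the matrix); defaults to the
#'   samples present in `calls`.
#' @param exclude_symbols additional hypervariable gene symbols to drop.
#' @return An object of class `genotype_matrix`: list with logical matrices
#'   `deletion` and `duplication` (subject x region), a logical `conflict`
#'   matrix (filled by [flag_conflicts()]), and the retained `regions`.
#' @export
overlap_genes <- function(calls, regions,
                          sample_ids = unique(calls$sample_id),
                          exclude_symbols = NULL) {
  keep <- !(regions$excluded_hypervariable |
              regions$gene_symbol %in% exclude_symbols)
  regions <- regions[keep, , drop = FALSE]
  n_s <- length(sample_ids)
  n_r <- nrow(regions)
  dn <- list(sample_ids, regions$gene_symbol)
  mats <- list(deletion = matrix(FALSE, n_s, n_r, dimnames = dn),
               duplication = matrix(FALSE, n_s, n_r, dimnames = dn))
  if (nrow(calls) && n_r) {
    gr_r <- .regions_granges(regions)
    for (type in names(mats)) {
      sub <- calls[calls$cnv_type == type, , drop = FALSE]
      if (!nrow(sub)) next
      hits <- .overlaps(.calls_granges(sub), gr_r)
      si <- match(sub$sample_id[S4Vectors::queryHits(hits)], sample_ids)
      ok <- !is.na(si)
      mats[[type]][cbind(si[ok], S4Vectors::subjectHits(hits)[ok])] <- TRUE
    }
  }
  structure(list(deletion = mats$deletion, duplication = mats$duplication,
                 conflict = matrix(FALSE, n_s, n_r, dimnames = dn),
                 regions = regions, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Gene-centric genotype matrix:", length(x$sample_ids), "subjects x",
      nrow(x$regions), "regions\n")
  cat("  deletion indicators:   ", sum(x$deletion), "\n")
  cat("  duplication indicators:", sum(x$duplication), "\n")
  cat("  conflict-excluded (subject, region) pairs:", sum(x$conflict), "\n")
  invisible(x)
}

#' Flag deletion/duplication conflicts
#'
#' A (subject, region) pair is excluded from association testing when the
#' subject has at least one deletion and one duplication call overlapping
#' the region and some deletion-duplication pair among them does not overlap
#' mutually: a non-overlapping opposite-type pair in one gene region is an
#' inconsistent genotype. Mutually overlapping opposite-type calls are left
#' alone ("non-overlapping" qualifies the pair).
#'
#' @param gm a [overlap_genes()] result.
#' @param calls the same call set the matrix was built from.
#' @return `gm` with its `conflict` matrix filled; conflicted pairs have
#'   their genotype indicators cleared so they contribute to no test.
#' @export
flag_conflicts <- function(gm, calls) {
  both <- which(gm$deletion & gm$duplication, arr.ind = TRUE)
  if (nrow(both)) {
    gr_r <- .regions_granges(gm$regions)
    for (k in seq_len(nrow(both))) {
      s <- gm$sample_ids[both[k, 1]]
      r <- both[k, 2]
      sub <- calls[calls$sample_id == s, , drop = FALSE]
      hits <- .overlaps(.calls_granges(sub), gr_r[r])
      sub <- sub[S4Vectors::queryHits(hits), , drop = FALSE]
      del <- sub[sub$cnv_type == "deletion", , drop = FALSE]
      dup <- sub[sub$cnv_type == "duplication", , drop = FALSE]
      conflict <- FALSE
      for (i in seq_len(nrow(del))) {
        disjoint <- dup$start > del$end[i] | dup$end < del$start[i]
        if (any(disjoint)) { conflict <- TRUE; break }
      }
      if (conflict) gm$conflict[both[k, 1], r] <- TRUE
    }
    gm$deletion[gm$conflict] <- FALSE
    gm$duplication[gm$conflict] <- FALSE
  }
  gm
}

#' CNV-map support per gene region
#'
#' Collapses calls to unique CNVs (distinct chrom/start/end/type across
#' samples) and labels each as represented in a population CNV map iff it
#' overlaps a same-type map interval by one or more base pairs. Returns the
#' supported proportion per gene region (the screen used to down-weight
#' regions whose CNVs look like calling artefacts: regions with < 95%
#' map support pass the prioritisation filter).
#'
#' @param calls a [cnv_calls()] table.
#' @param cnv_map a [cnv_calls()]-like table of map intervals with
#'   `chrom`, `start`, `end`, `cnv_type` (sample_id ignored).
#' @param regions a [gene_regions()] table.
#' @return data.frame with `gene_symbol`, `n_unique`, `n_supported`,
#'   `prop_supported` (NA for regions with no overlapping CNVs).
#' @export
map_support <- function(calls, cnv_map, regions) {
  uniq <- unique(as.data.frame(calls)[, c("chrom", "start", "end", "cnv_type")])
  supported <- rep(FALSE, nrow(uniq))
  for (type in c("deletion", "duplication")) {
    qi <- which(uniq$cnv_type == type)
    mi <- which(cnv_map$cnv_type == type)
    if (!length(qi) || !length(mi)) next
    hits <- .overlaps(.calls_granges(uniq[qi, , drop = FALSE]),
                      .calls_granges(cnv_map[mi, , drop = FALSE]))
    supported[qi[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  gr_r <- .regions_granges(regions)
  hits <- .overlaps(.calls_granges(uniq), gr_r)
  n_unique <- n_supported <- integer(nrow(regions))
  tab <- table(factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(regions))))
  n_unique[] <- as.integer(tab)
  sup_hits <- hits[supported[S4Vectors::queryHits(hits)]]
  tab_s <- table(factor(S4Vectors::subjectHits(sup_hits),
                        levels = seq_len(nrow(regions))))
  n_supported[] <- as.integer(tab_s)
  data.frame(gene_symbol = regions$gene_symbol,
             n_unique = n_unique, n_supported = n_supported,
             prop_supported = ifelse(n_unique > 0, n_supported / n_unique, NA),
             stringsAsFactors = FALSE)
}
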