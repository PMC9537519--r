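# Readers and writers. Internal coordinates are 1-based closed; BED files
# are 0-based half-open and converted at the boundary.

#' Read CNV calls
#'
#' Supports two dialects: `penncnv_rawcnv`, the whitespace-separated text
#' emitted by PennCNV (e.g. `chr2:100-500 numsnp=7 length=401 state2,cn=1
#' S1 startsnp=rs1 endsnp=rs7`), and `tsv`, a plain table with columns
#' sample_id, chrom, start, end, cnv_type, n_probes and optionally
#' copy_number (header optional). Copy-number states below 2 map to
#' deletions, above 2 to duplications; copy-neutral records (cn = 2) are
#' rejected rather than dropped, to surface upstream errors.
#'
#' @param path file path.
#' @param dialect "penncnv_rawcnv" or "tsv".
#' @return A [cnv_calls()] table.
#' @export
read_cnv_calls <- function(path, dialect = c("penncnv_rawcnv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "penncnv_rawcnv") .read_rawcnv(path) else .read_cnv_tsv(path)
}

.read_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(cnv_calls())
  parse_one <- function(line, lineno) {
    f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    loc <- regmatches(f[1], regexec("^(chr)?([0-9XY]+):([0-9]+)-([0-9]+)$", f[1]))[[1]]
    if (length(loc) == 0 || length(f) < 5)
      stop("malformed rawcnv record at line ", lineno, ": ", line, call. = FALSE)
    numsnp <- sub("^numsnp=", "", f[2])
    st <- regmatches(f[4], regexec("^state([0-9]+),cn=([0-9]+)$", f[4]))[[1]]
    if (!grepl("^numsnp=", f[2]) || length(st) == 0)
      stop("malformed rawcnv record at line ", lineno, ": ", line, call. = FALSE)
    cn <- as.integer(st[3])
    if (cn == 2L)
      stop("neutral copy number (cn=2) at line ", lineno, call. = FALSE)
    list(sample_id = f[5], chrom = loc[3],
         start = as.numeric(loc[4]), end = as.numeric(loc[5]),
         cnv_type = if (cn < 2L) "deletion" else "duplication",
         n_probes = as.integer(numsnp), copy_number = cn)
  }
  recs <- mapply(parse_one, lines, seq_along(lines), SIMPLIFY = FALSE)
  cnv_calls(
    sample_id = vapply(recs, `[[`, "", "sample_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0, "start"),
    end = vapply(recs, `[[`, 0, "end"),
    cnv_type = vapply(recs, `[[`, "", "cnv_type"),
    n_probes = vapply(recs, `[[`, 0L, "n_probes"),
    copy_number = vapply(recs, `[[`, 0L, "copy_number")
  )
}

.read_cnv_tsv <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("^sample_id\\b", first)
  df <- read.delim(path, header = header, sep = "", stringsAsFactors = FALSE)
  if (!header) {
    if (ncol(df) < 6) stop("TSV CNV table needs >= 6 columns", call. = FALSE)
    names(df)[1:6] <- c("sample_id", "chrom", "start", "end", "cnv_type",
                        "n_probes")
    if (ncol(df) >= 7) names(df)[7] <- "copy_number"
  }
  if (!nrow(df)) return(cnv_calls())
  cnv_calls(sample_id = df$sample_id, chrom = df$chrom, start = df$start,
            end = df$end, cnv_type = df$cnv_type, n_probes = df$n_probes,
            copy_number = if ("copy_number" %in% names(df)) df$copy_number
                          else NA_integer_)
}

#' Write CNV calls
#'
#' @param calls a [cnv_calls()] table.
#' @param path output path.
#' @param dialect "tsv" (headered table) or "penncnv_rawcnv". Writing rawcnv
#'   requires known copy numbers (for the `state,cn` field).
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path, dialect = c("tsv", "penncnv_rawcnv")) {
  dialect <- match.arg(dialect)
  calls <- validate_cnv_calls(calls)
  if (dialect == "tsv") {
    write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    if (anyNA(calls$copy_number))
      stop("rawcnv output requires known copy_number", call. = FALSE)
    state <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)[as.character(calls$copy_number)]
    lines <- sprintf("chr%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s startsnp=. endsnp=.",
                     calls$chrom, as.integer(calls$start), as.integer(calls$end),
                     calls$n_probes,
                     as.integer(calls$end - calls$start + 1),
                     state, calls$copy_number, calls$sample_id)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a gene track (or CNV map) from BED
#'
#' BED4+ input; half-open 0-based BED coordinates become 1-based closed
#' internally. Rows sharing a gene symbol on the same chromosome are
#' collapsed to one region spanning their union (the non-redundant
#' gene-centric convention); the same symbol on different chromosomes stays
#' distinct.
#'
#' @param path BED file with at least chrom, start, end, name columns.
#' @param exclude_symbols optional character vector of symbols to flag as
#'   hypervariable (`excluded_hypervariable = TRUE`).
#' @return A [gene_regions()] table.
#' @export
read_gene_track <- function(path, exclude_symbols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("missing name column: gene-track BED needs >= 4 columns", call. = FALSE)
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED record with start >= end", call. = FALSE)
  df <- data.frame(
    gene_symbol = gr$name,
    chrom = .norm_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr),  # rtracklayer already 1-based closed
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  key <- paste(df$gene_symbol, df$chrom, sep = "\r")
  agg_start <- tapply(df$start, key, min)
  agg_end <- tapply(df$end, key, max)
  keys <- names(agg_start)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- gene_regions(
    gene_symbol = parts[, 1], chrom = parts[, 2],
    start = as.numeric(agg_start), end = as.numeric(agg_end),
    excluded_hypervariable = parts[, 1] %in% exclude_symbols
  )
  out[order(match(out$chrom, .valid_chroms), out$start), , drop = FALSE]
}

#' Write a gene track as BED4
#'
#' Converts the internal 1-based closed intervals back to BED's 0-based
#' half-open convention; a read/write round trip is coordinate-exact.
#'
#' @param regions a [gene_regions()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_track <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    name = regions$gene_symbol
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read/write a carrier phenotype table (TSV with mandatory header)
#'
#' @param path file path.
#' @return [read_phenotypes()] returns a [subject_records()] table.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  subject_records(read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(sample_id = "character",
                                            family_id = "character")))
}

#' @param subjects a [subject_records()] table.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(subjects, path) {
  write.table(as.data.frame(subjects), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read/write an incidence table (YAML config)
#'
#' The YAML carries two keys, `age_breaks` and `hazard`, holding the
#' piecewise-constant age-specific incidence. The package ships
#' BRCA1-carrier-like and BRCA2-carrier-like default curves under
#' `system.file("extdata", ..., package = "cnvmod")`; their values are
#' configuration, not claims.
#'
#' @param path YAML file path.
#' @return [read_incidence()] returns an [incidence_table()].
#' @export
read_incidence <- function(path) {
  cfg <- yaml::read_yaml(path)
  incidence_table(cfg$age_breaks, cfg$hazard)
}

#' @param tbl an [incidence_table()].
#' @rdname read_incidence
#' @export
write_incidence <- function(tbl, path) {
  yaml::write_yaml(list(age_breaks = tbl$age_breaks, hazard = tbl$hazard), path)
  invisible(path)
}

#' Export association results
#'
#' Writes the standard results table: one row per (region, CNV type, gene
#' group) with carrier count, score, variance, p, HR, CI and the
#' effective-test threshold flag.
#'
#' @param results data.frame as returned by [retro_scan()] or
#'   [weighted_cohort_fit()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assoc_results <- function(results, path) {
  cols <- c(region = "region", type = "cnv_type", group = "gene_group",
            n_cnv = "n_carriers_with_cnv", U = "score_U", V = "variance_V",
            p = "p_value", HR = "hr", CI_low = "ci_low", CI_high = "ci_high",
            pass = "threshold_passed")
  out <- results[, intersect(unname(cols), names(results)), drop = FALSE]
  names(out) <- names(cols)[match(names(out), cols)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
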