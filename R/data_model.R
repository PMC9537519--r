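# Domain types. All genomic coordinates are internally 1-based, closed
# intervals (the PennCNV convention); BED I/O converts at the boundary.
# Chromosomes are restricted to 1-22 and X; Y records are rejected.

.valid_chroms <- c(as.character(1:22), "X")

.norm_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- !(chrom %in% .valid_chroms)
  if (any(bad)) {
    stop("unsupported chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "),
         " (allowed: 1-22, X)", call. = FALSE)
  }
  chrom
}

#' Construct a table of CNV calls
#'
#' One row per called deletion or duplication in one sample. `cnv_type` must
#' be consistent with `copy_number` where the latter is known: copy number
#' below 2 is a deletion, above 2 a duplication; copy-neutral (cn = 2)
#' records are invalid input.
#'
#' @param sample_id character, sample identifiers.
#' @param chrom chromosome labels (1-22, X; a leading "chr" is stripped).
#' @param start,end 1-based closed interval bounds in bp, `start <= end`.
#' @param cnv_type "deletion" or "duplication".
#' @param n_probes positive integer, probes supporting the call.
#' @param copy_number integer 0-4 or `NA` when unknown.
#' @return A `data.frame` of class `cnv_calls`.
#' @examples
#' cnv_calls("S1", "17", 41196312L, 41277500L, "deletion", 12L, 1L)
#' @export
cnv_calls <- function(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      cnv_type = character(), n_probes = integer(),
                      copy_number = NA_integer_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    chrom = if (length(chrom)) .norm_chrom(chrom) else character(),
    start = as.numeric(start),
    end = as.numeric(end),
    cnv_type = as.character(cnv_type),
    n_probes = as.integer(n_probes),
    copy_number = as.integer(rep_len(copy_number, length(sample_id))),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(df)
}

#' Validate (and class) a CNV call table
#'
#' Checks the `cnv_calls` invariants on an arbitrary data.frame — interval
#' orientation, probe support, copy-number/type consistency, rejection of
#' copy-neutral records — and returns it classed as `cnv_calls`.
#'
#' @param df data.frame with the [cnv_calls()] columns.
#' @return `df`, classed as `cnv_calls`.
#' @export
validate_cnv_calls <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df)) {
    if (!all(df$cnv_type %in% c("deletion", "duplication")))
      stop("cnv_type must be 'deletion' or 'duplication'", call. = FALSE)
    if (any(df$start > df$end))
      stop("CNV call with start > end", call. = FALSE)
    if (any(df$n_probes < 1L))
      stop("n_probes must be >= 1", call. = FALSE)
    cn <- df$copy_number
    known <- !is.na(cn)
    if (any(known & cn == 2L))
      stop("neutral copy number (cn = 2) is not a CNV call", call. = FALSE)
    bad <- known &
      ((cn <= 1L & df$cnv_type != "deletion") |
       (cn >= 3L & df$cnv_type != "duplication"))
    if (any(bad))
      stop("cnv_type inconsistent with copy_number", call. = FALSE)
  }
  class(df) <- unique(c("cnv_calls", class(df)))
  df
}

#' Construct a gene-region track
#'
#' Gene regions are (symbol, chromosome) pairs with a single spanning
#' interval; the same symbol on different chromosomes stays distinct.
#'
#' @param gene_symbol character gene symbols.
#' @param chrom chromosome labels (1-22, X).
#' @param start,end 1-based closed bounds in bp.
#' @param excluded_hypervariable logical; regions flagged as hypervariable
#'   (HLA, immunoglobulin superfamily, olfactory receptors) are dropped from
#'   genotype matrices.
#' @return A `data.frame` of class `gene_regions`.
#' @export
gene_regions <- function(gene_symbol, chrom, start, end,
                         excluded_hypervariable = FALSE) {
  df <- data.frame(
    gene_symbol = as.character(gene_symbol),
    chrom = .norm_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    excluded_hypervariable = rep_len(as.logical(excluded_hypervariable),
                                     length(gene_symbol)),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) stop("gene region with start > end", call. = FALSE)
  if (anyDuplicated(paste(df$gene_symbol, df$chrom)))
    stop("duplicate (gene_symbol, chrom) pairs; collapse before construction",
         call. = FALSE)
  class(df) <- unique(c("gene_regions", class(df)))
  df
}

#' Construct a carrier phenotype table
#'
#' One row per carrier. `age_end` is the age at first breast cancer
#' diagnosis for affected subjects, or the censoring age (ovarian cancer,
#' bilateral prophylactic mastectomy or last observation, whichever comes
#' first) for unaffected subjects; follow-up starts at birth. Only breast
#' cancer counts as affected.
#'
#' @param df data.frame with columns `sample_id`, `family_id`, `gene_group`
#'   ("BRCA1"/"BRCA2"), `affected` (logical), `age_end` (years), `country`,
#'   `aj` (logical Ashkenazi-Jewish flag), `birth_cohort` (one of "<1920",
#'   "1920-29", "1930-39", "1940-49", ">=1950"), `array` ("iCOGS"/"OncoArray"),
#'   `mutation_type` ("other"/"deletion"/"duplication").
#' @return The validated data.frame with class `subject_records`.
#' @export
subject_records <- function(df) {
  required <- c("sample_id", "family_id", "gene_group", "affected", "age_end",
                "country", "aj", "birth_cohort", "array", "mutation_type")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$affected <- as.logical(df$affected)
  df$aj <- as.logical(df$aj)
  df$age_end <- as.numeric(df$age_end)
  if (!all(df$gene_group %in% c("BRCA1", "BRCA2")))
    stop("gene_group must be BRCA1 or BRCA2", call. = FALSE)
  if (!all(df$mutation_type %in% c("other", "deletion", "duplication")))
    stop("mutation_type must be other/deletion/duplication", call. = FALSE)
  if (any(df$age_end < 0)) stop("negative age_end", call. = FALSE)
  class(df) <- unique(c("subject_records", class(df)))
  df
}

#' Piecewise-constant age-specific incidence table
#'
#' Holds the baseline breast cancer incidence \eqn{\lambda_0(t)} of carriers
#' as a step function over age bands, e.g. the published age-specific
#' BRCA1/BRCA2 carrier incidences used for ascertainment correction. The
#' cumulative hazard \eqn{\Lambda_0(t)} is its exact piecewise-linear
#' integral.
#'
#' @param age_breaks increasing numeric vector of ages (years) starting at 0;
#'   `length(hazard) + 1` entries.
#' @param hazard non-negative per-interval incidence (events/person-year).
#' @return An object of class `incidence_table`.
#' @examples
#' inc <- incidence_table(c(0, 40, 80), c(0.001, 0.02))
#' cumulative_hazard(inc, 50)  # 0.001*40 + 0.02*10 = 0.24
#' @export
incidence_table <- function(age_breaks, hazard) {
  age_breaks <- as.numeric(age_breaks)
  hazard <- as.numeric(hazard)
  if (length(age_breaks) != length(hazard) + 1L)
    stop("need length(age_breaks) == length(hazard) + 1", call. = FALSE)
  if (age_breaks[1] != 0) stop("age_breaks must start at 0", call. = FALSE)
  if (any(diff(age_breaks) <= 0)) stop("age_breaks must be increasing", call. = FALSE)
  if (any(hazard < 0)) stop("hazard must be non-negative", call. = FALSE)
  structure(list(age_breaks = age_breaks, hazard = hazard),
            class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("Piecewise-constant incidence over", length(x$hazard), "age bands,",
      "0 to", max(x$age_breaks), "years\n")
  cat(sprintf("Cumulative hazard at %g: %.4f\n", max(x$age_breaks),
              cumulative_hazard(x, max(x$age_breaks))))
  invisible(x)
}

#' Cumulative baseline hazard
#'
#' Exact integral of the piecewise-constant incidence from age 0 to `t`.
#' No extrapolation: `t` beyond the table is an error.
#'
#' @param tbl an [incidence_table()].
#' @param t ages in years (vectorised), `0 <= t <= max(age_breaks)`.
#' @return Numeric vector \eqn{\Lambda_0(t)}.
#' @export
cumulative_hazard <- function(tbl, t) {
  stopifnot(inherits(tbl, "incidence_table"))
  t <- as.numeric(t)
  if (any(t < 0) || any(t > max(tbl$age_breaks)))
    stop("age outside incidence table range [0, ", max(tbl$age_breaks), "]",
         call. = FALSE)
  lo <- tbl$age_breaks[-length(tbl$age_breaks)]
  hi <- tbl$age_breaks[-1]
  # overlap of [0, t] with each band, times the band hazard
  vapply(t, function(ti) {
    sum(tbl$hazard * pmax(0, pmin(ti, hi) - lo))
  }, numeric(1))
}

# Inverse of the cumulative hazard: smallest t with Lambda0(t) >= target,
# Inf when the target exceeds the total lifetime hazard.
.inverse_cumulative_hazard <- function(tbl, target) {
  lo <- tbl$age_breaks[-length(tbl$age_breaks)]
  hi <- tbl$age_breaks[-1]
  cum <- c(0, cumsum(tbl$hazard * (hi - lo)))
  total <- cum[length(cum)]
  vapply(target, function(x) {
    if (x > total) return(Inf)
    if (x <= 0) return(0)
    k <- findInterval(x, cum, rightmost.closed = TRUE)
    # flat (zero-hazard) band cannot be entered by x > cum[k] unless hazard>0
    while (tbl$hazard[k] == 0 && x > cum[k]) k <- k + 1L
    if (tbl$hazard[k] == 0) return(lo[k])
    lo[k] + (x - cum[k]) / tbl$hazard[k]
  }, numeric(1))
}
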