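# Synthetic carrier-family cohorts with known truth. Families are sibships
# (the clusters the robust variance needs); CNV genotypes are transmitted
# Mendelianly from unobserved parents so siblings are positively correlated;
# age at onset follows a proportional-hazards modifier of a piecewise-
# constant baseline incidence; clinic-style ascertainment keeps families
# whose proband (first-listed member) is affected.

# hg19-scale autosome lengths (Mb, rounded) for random false-call placement
.chrom_lengths_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                       135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Simulation configuration
#'
#' Defines the synthetic study conditions: family structure, per-region CNV
#' frequency and true log hazard ratio, baseline incidence, censoring,
#' ascertainment, and the error behaviour of the simulated CNV caller.
#'
#' @param n_families number of families to generate (before ascertainment).
#' @param family_size_probs probabilities of sibship sizes 1-4.
#' @param n_regions number of gene regions.
#' @param cnv_frequency per-region carrier frequency in (0, 0.5); recycled.
#' @param true_log_hr per-region true log hazard ratio; recycled.
#' @param region_type per-region CNV type ("deletion"/"duplication"); recycled.
#' @param incidence an [incidence_table()] for the baseline \eqn{\lambda_0(t)}.
#' @param censor_min,censor_max bounds of the uniform age-at-last-observation
#'   distribution (years).
#' @param competing_rate per-year hazard of the independent competing
#'   censoring event (ovarian cancer / prophylactic mastectomy).
#' @param ascertainment "proband_affected" (clinic-style: keep families whose
#'   first member is affected) or "random".
#' @param detection_sensitivity named per-type probability that a true CNV is
#'   called.
#' @param false_call_rate named per-type expected false calls per genome.
#' @param probe_density array probes per kb (used for call probe counts).
#' @param qc_fail_fraction fraction of samples given failing QC metrics.
#' @param mutation_type_probs probabilities of the clinically diagnosed
#'   pathogenic-variant class (other/deletion/duplication); the class is
#'   drawn per family, since relatives share the family variant.
#' @param mutation_log_hr named log hazard ratios attached to the deletion
#'   and duplication variant classes (default no effect).
#' @param gene_group "BRCA1" or "BRCA2" label for the cohort.
#' @param seed integer seed; identical configs give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 1000,
                       family_size_probs = c(0.45, 0.35, 0.15, 0.05),
                       n_regions = 10,
                       cnv_frequency = 0.05,
                       true_log_hr = 0,
                       region_type = "deletion",
                       incidence = default_incidence("BRCA1"),
                       censor_min = 25, censor_max = 80,
                       competing_rate = 0.005,
                       ascertainment = c("proband_affected", "random"),
                       detection_sensitivity = c(deletion = 0.85,
                                                 duplication = 0.65),
                       false_call_rate = c(deletion = 0.5, duplication = 1.0),
                       probe_density = 0.2,
                       qc_fail_fraction = 0.02,
                       mutation_type_probs = c(other = 0.90, deletion = 0.08,
                                               duplication = 0.02),
                       mutation_log_hr = c(deletion = 0, duplication = 0),
                       gene_group = "BRCA1",
                       seed = 1L) {
  ascertainment <- match.arg(ascertainment)
  cfg <- list(
    n_families = as.integer(n_families),
    family_size_probs = family_size_probs / sum(family_size_probs),
    n_regions = as.integer(n_regions),
    cnv_frequency = rep_len(cnv_frequency, n_regions),
    true_log_hr = rep_len(true_log_hr, n_regions),
    region_type = rep_len(region_type, n_regions),
    incidence = incidence,
    censor_min = censor_min, censor_max = censor_max,
    competing_rate = competing_rate,
    ascertainment = ascertainment,
    detection_sensitivity = detection_sensitivity,
    false_call_rate = false_call_rate,
    probe_density = probe_density,
    qc_fail_fraction = qc_fail_fraction,
    mutation_type_probs = mutation_type_probs / sum(mutation_type_probs),
    mutation_log_hr = mutation_log_hr,
    gene_group = gene_group,
    seed = as.integer(seed)
  )
  stopifnot(length(cfg$family_size_probs) == 4,
            all(cfg$cnv_frequency > 0), all(cfg$cnv_frequency < 0.5),
            all(is.finite(cfg$true_log_hr)),
            all(cfg$region_type %in% c("deletion", "duplication")),
            inherits(cfg$incidence, "incidence_table"))
  class(cfg) <- "sim_config"
  cfg
}

#' Default carrier incidence curves
#'
#' Piecewise-constant (5-year band) age-specific breast cancer incidence
#' curves shaped like published BRCA1- and BRCA2-carrier estimates
#' (cumulative risk by age 80 of about 72% and 69% respectively). Shipped as
#' YAML configs under `inst/extdata/`; incidence values are configuration,
#' not claims.
#'
#' @param gene "BRCA1" or "BRCA2".
#' @return An [incidence_table()].
#' @export
default_incidence <- function(gene = c("BRCA1", "BRCA2")) {
  gene <- match.arg(gene)
  path <- system.file("extdata",
                      paste0(tolower(gene), "_incidence.yaml"),
                      package = "cnvmod")
  read_incidence(path)
}

#' Sample an age at onset under a proportional-hazards modifier
#'
#' Inverse-transform draw from the model \eqn{\lambda(t) =
#' \lambda_0(t) e^{\beta g}}: returns the `t` solving
#' \eqn{\Lambda_0(t) e^{\beta g} = -\log u} by exact piecewise-linear
#' inversion, or `Inf` (never affected within the table's age span) when the
#' required hazard exceeds the total lifetime hazard.
#'
#' @param incidence an [incidence_table()].
#' @param beta log hazard ratio.
#' @param g 0/1 genotype (vectorised).
#' @param u uniform(0,1) draws, same length as `g`.
#' @return Ages in years, possibly `Inf`.
#' @export
sample_onset_age <- function(incidence, beta, g, u) {
  stopifnot(all(u > 0), all(u < 1), length(u) == length(g))
  target <- -log(u) * exp(-beta * g)
  .inverse_cumulative_hazard(incidence, target)
}

# Draw family-correlated 0/1 carrier genotypes. The CNV is treated as an
# allele with frequency q = 1 - sqrt(1 - p) so the marginal carrier
# frequency is p; each subject inherits one allele from each (unobserved)
# parent of its family.
.draw_family_genotypes <- function(fam_index, n_fam, p) {
  q <- 1 - sqrt(1 - p)
  par_alleles <- matrix(rbinom(4 * n_fam, 1, q), nrow = n_fam)  # fa1 fa2 ma1 ma2
  n <- length(fam_index)
  pick_f <- rbinom(n, 1, 0.5)
  pick_m <- rbinom(n, 1, 0.5)
  a_f <- ifelse(pick_f == 1, par_alleles[fam_index, 1], par_alleles[fam_index, 2])
  a_m <- ifelse(pick_m == 1, par_alleles[fam_index, 3], par_alleles[fam_index, 4])
  as.integer(a_f | a_m)
}

#' Simulate an ascertained carrier-family cohort
#'
#' Generates sibship families with Mendelian-correlated Bernoulli CNV
#' genotypes, draws each subject's onset age under the proportional-hazards
#' model, censors at an independent uniform last-observation age and an
#' independent exponential competing event (ovarian cancer / mastectomy),
#' drops subjects whose follow-up ends before the recruitment-eligibility
#' age of 18, and (for clinic-style ascertainment) retains only families
#' whose first-listed member is affected.
#'
#' @param cfg a [sim_config()].
#' @return A list with `subjects` (a [subject_records()] table) and `truth`,
#'   itself a list with `genotypes` (subject x region 0/1 matrix), `regions`
#'   (a [gene_regions()] table with simulated coordinates), `calls` (the true
#'   CNV intervals as a [cnv_calls()] table) and `region_type`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sizes <- sample.int(4L, cfg$n_families, replace = TRUE,
                      prob = cfg$family_size_probs)
  fam_index <- rep.int(seq_len(cfg$n_families), sizes)
  n <- length(fam_index)
  first_in_family <- !duplicated(fam_index)

  geno <- matrix(0L, n, cfg$n_regions)
  for (r in seq_len(cfg$n_regions)) {
    geno[, r] <- .draw_family_genotypes(fam_index, cfg$n_families,
                                        cfg$cnv_frequency[r])
  }
  # the clinically diagnosed variant class is shared within a family
  mut_fam <- sample(names(cfg$mutation_type_probs), cfg$n_families,
                    replace = TRUE, prob = cfg$mutation_type_probs)
  mut <- mut_fam[fam_index]
  mut_lp <- ifelse(mut == "other", 0, cfg$mutation_log_hr[mut])

  # proportional-hazards onset with multiplicative per-region effects
  lp <- drop(geno %*% cfg$true_log_hr) + mut_lp
  u <- runif(n)
  onset <- .inverse_cumulative_hazard(cfg$incidence, -log(u) * exp(-lp))
  censor <- runif(n, cfg$censor_min, cfg$censor_max)
  competing <- if (cfg$competing_rate > 0) rexp(n, cfg$competing_rate) else Inf
  age_end <- pmin(onset, censor, competing)
  affected <- onset <= pmin(censor, competing) & is.finite(onset)

  keep <- age_end >= 18
  if (cfg$ascertainment == "proband_affected") {
    proband_ok <- affected & first_in_family & keep
    fam_keep <- unique(fam_index[proband_ok])
    keep <- keep & fam_index %in% fam_keep
  }
  if (!any(keep))
    stop("no families retained after ascertainment; increase n_families",
         call. = FALSE)

  idx <- which(keep)
  subjects <- subject_records(data.frame(
    sample_id = sprintf("S%06d", idx),
    family_id = sprintf("F%05d", fam_index[idx]),
    gene_group = cfg$gene_group,
    affected = affected[idx],
    age_end = age_end[idx],
    country = "SIM",
    aj = FALSE,
    birth_cohort = sample(c("<1920", "1920-29", "1930-39", "1940-49", ">=1950"),
                          length(idx), replace = TRUE,
                          prob = c(0.05, 0.1, 0.2, 0.3, 0.35)),
    array = sample(c("iCOGS", "OncoArray"), length(idx), replace = TRUE,
                   prob = c(0.3, 0.7)),
    mutation_type = mut[idx],
    stringsAsFactors = FALSE
  ))

  regions <- .sim_regions(cfg$n_regions)
  truth_calls <- .truth_calls(geno[idx, , drop = FALSE], subjects$sample_id,
                              regions, cfg)
  list(subjects = subjects,
       truth = list(genotypes = `dimnames<-`(geno[idx, , drop = FALSE],
                                             list(subjects$sample_id,
                                                  regions$gene_symbol)),
                    regions = regions,
                    calls = truth_calls,
                    region_type = cfg$region_type))
}

# Well-separated synthetic gene regions: round-robin over autosomes, 2 Mb
# apart, 30-200 kb long, so calls at one region can never touch another.
.sim_regions <- function(n_regions) {
  chrom <- as.character(rep_len(1:22, n_regions))
  slot <- (seq_len(n_regions) - 1) %/% 22
  start <- 10e6 + slot * 2e6 + 1
  len <- round(seq(30e3, 200e3, length.out = max(n_regions, 2)))[seq_len(n_regions)]
  gene_regions(gene_symbol = sprintf("GENE%03d", seq_len(n_regions)),
               chrom = chrom, start = start, end = start + len - 1)
}

.truth_calls <- function(geno, sample_ids, regions, cfg) {
  hit <- which(geno == 1L, arr.ind = TRUE)
  if (!nrow(hit)) return(cnv_calls())
  r <- hit[, 2]
  # true CNV spans its region with a small (<10 kb) symmetric margin
  margin_l <- round(runif(nrow(hit), 0, 1e4))
  margin_r <- round(runif(nrow(hit), 0, 1e4))
  start <- regions$start[r] - margin_l
  end <- regions$end[r] + margin_r
  len_kb <- (end - start + 1) / 1000
  cnv_calls(
    sample_id = sample_ids[hit[, 1]],
    chrom = regions$chrom[r],
    start = start, end = end,
    cnv_type = cfg$region_type[r],
    n_probes = pmax(1L, as.integer(round(len_kb * cfg$probe_density))),
    copy_number = ifelse(cfg$region_type[r] == "deletion", 1L, 3L)
  )
}

#' Simulate noisy CNV calls and QC metrics from a truth set
#'
#' Emulates array-based CNV calling: each true CNV is emitted with a
#' type-specific detection probability; false calls are added per genome at
#' a type-specific Poisson rate with random placement; per-sample QC metrics
#' are drawn from clean distributions except for a configured fraction of
#' QC-failing samples (which receive an LRR standard deviation above the
#' 0.28 exclusion threshold).
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param cfg the same [sim_config()].
#' @param call_seed seed for the call-level noise (kept separate from the
#'   cohort seed so the same cohort can be re-called).
#' @return A list with `calls` (a [cnv_calls()] table) and `metrics` (a
#'   data.frame of per-sample QC metrics).
#' @export
simulate_calls <- function(truth, cfg, call_seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(call_seed)
  tc <- truth$calls
  sample_ids <- rownames(truth$genotypes)

  sens <- cfg$detection_sensitivity[tc$cnv_type]
  detected <- runif(nrow(tc)) < sens
  calls <- tc[detected, , drop = FALSE]

  # false calls: per genome, per type
  fc <- list()
  for (type in c("deletion", "duplication")) {
    rate <- cfg$false_call_rate[[type]]
    if (is.null(rate) || rate <= 0) next
    n_false <- rpois(length(sample_ids), rate)
    tot <- sum(n_false)
    if (tot == 0) next
    chrom_i <- sample.int(22L, tot, replace = TRUE,
                          prob = .chrom_lengths_mb)
    len <- pmax(1e3, round(rlnorm_len(tot)))
    start <- floor(runif(tot, 1, .chrom_lengths_mb[chrom_i] * 1e6 - len))
    fc[[type]] <- cnv_calls(
      sample_id = rep(sample_ids, n_false),
      chrom = as.character(chrom_i),
      start = start, end = start + len - 1,
      cnv_type = type,
      n_probes = pmax(1L, as.integer(round(len / 1000 * cfg$probe_density))),
      copy_number = if (type == "deletion") 1L else 3L
    )
  }
  calls <- do.call(rbind, c(list(as.data.frame(calls)),
                            lapply(fc, as.data.frame)))
  calls <- validate_cnv_calls(calls[order(calls$sample_id,
                                          match(calls$chrom, .valid_chroms),
                                          calls$start), , drop = FALSE])
  rownames(calls) <- NULL

  n_cnvs <- table(factor(calls$sample_id, levels = sample_ids))
  ns <- length(sample_ids)
  qc_fail <- runif(ns) < cfg$qc_fail_fraction
  metrics <- data.frame(
    sample_id = sample_ids,
    lrr_sd = ifelse(qc_fail, runif(ns, 0.29, 0.5),
                    pmax(0.01, rnorm(ns, 0.12, 0.03))),
    baf_drift = abs(rnorm(ns, 0, 0.002)),
    waviness_factor = rnorm(ns, 0, 0.01),
    lrr_outlier_rate = abs(rnorm(ns, 0.01, 0.01)),
    baf_sd = pmax(0.01, rnorm(ns, 0.08, 0.02)),
    n_cnvs = as.integer(n_cnvs),
    stringsAsFactors = FALSE
  )
  list(calls = calls, metrics = metrics)
}

# log-normal false-call lengths, median ~30 kb
rlnorm_len <- function(n) exp(rnorm(n, log(3e4), 0.8))
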