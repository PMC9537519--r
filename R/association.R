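# The two association engines: an ascertainment-corrected retrospective-
# likelihood score test with family-cluster-robust variance, and a
# weighted-cohort Cox model with incidence-derived weights. Plus the
# effective-test Bonferroni thresholds.

#' Specification for the retrospective-likelihood score test
#'
#' @param incidence an [incidence_table()] supplying the baseline cumulative
#'   hazard \eqn{\Lambda_0(t)}.
#' @param strata character vector of stratifying columns in the subject
#'   table (default country and Ashkenazi-Jewish ancestry).
#' @param cluster clustering column (default family ID).
#' @param min_carriers minimum CNV carriers for a region to be testable.
#' @param min_carriers_per_stratum strata with fewer carriers are pooled
#'   into one residual stratum to avoid degenerate centering.
#' @return An object of class `retro_test_spec`.
#' @export
retro_test_spec <- function(incidence, strata = c("country", "aj"),
                            cluster = "family_id", min_carriers = 2L,
                            min_carriers_per_stratum = 2L) {
  stopifnot(inherits(incidence, "incidence_table"))
  structure(list(incidence = incidence, strata = strata, cluster = cluster,
                 min_carriers = as.integer(min_carriers),
                 min_carriers_per_stratum = as.integer(min_carriers_per_stratum)),
            class = "retro_test_spec")
}

# Fast numeric core. g: 0/1, delta: 0/1 affected, Lambda: baseline
# cumulative hazard at age_end, stratum/family: integer codes (stratum must
# be 1..S dense). Uses the efficient (profile) score: both the genotype and
# the phenotype residual are centred within stratum, so the cluster-robust
# variance accounts for the estimated stratum genotype frequency. U is
# unchanged by the second centring (Sum(g - p_hat) = 0 within stratum).
.retro_score_core <- function(g, delta, Lambda, stratum, family) {
  n_s <- tabulate(stratum)
  p_hat <- rowsum(g, stratum, reorder = TRUE) / n_s
  resid <- delta - Lambda
  resid <- resid - (rowsum(resid, stratum, reorder = TRUE) / n_s)[stratum]
  u <- (g - p_hat[stratum]) * resid
  U <- sum(u)
  fam_sums <- rowsum(u, family)
  V <- sum(fam_sums^2)
  I <- sum(p_hat[stratum] * (1 - p_hat[stratum]) * resid^2)
  list(U = U, V = V, I = I)
}

.stratum_codes <- function(subjects, spec, g) {
  s <- interaction(subjects[spec$strata], drop = TRUE, lex.order = TRUE)
  carriers <- tapply(g, s, sum)
  pooled <- names(carriers)[carriers < spec$min_carriers_per_stratum]
  lev <- levels(s)
  s <- as.character(s)
  if (length(pooled) && length(pooled) < length(lev)) s[s %in% pooled] <- ".pooled"
  as.integer(factor(s))
}

#' Retrospective-likelihood score test for one gene region
#'
#' Tests whether a 0/1 CNV genotype modifies breast cancer risk under the
#' proportional-hazards model \eqn{\lambda_i(t) = \lambda_0(t) e^{\beta
#' g_i}}, using the retrospective likelihood of the genotype conditional on
#' the observed phenotype so that clinic-based (disease-dependent)
#' ascertainment does not bias the test. The stratum-specific genotype
#' frequency is a nuisance parameter profiled at the stratum mean
#' \eqn{\hat p_s}; the corresponding efficient per-subject score at
#' \eqn{\beta = 0} is \eqn{u_i = (g_i - \hat p_{s(i)})\,\tilde c_i} with the
#' stratum-centred phenotype residual \eqn{\tilde c_i = (\delta_i -
#' \Lambda_0(t_i)) - \bar c_{s(i)}}. (Centring \eqn{c_i} leaves the total
#' score \eqn{U = \sum u_i} unchanged but is what makes the cluster-robust
#' variance consistent when \eqn{\hat p_s} is estimated.) The test statistic
#' is \eqn{U^2/V} with the family-cluster-robust \eqn{V = \sum_f (\sum_{i
#' \in f} u_i)^2}, referred to \eqn{\chi^2_1}. A one-step approximation from
#' the profile information \eqn{I = \sum \hat p_s (1 - \hat p_s)\tilde
#' c_i^2} yields \eqn{\hat\beta = U/I}, \eqn{se = \sqrt V / I}, and hence an
#' HR with 95% CI.
#'
#' @param g 0/1 genotype vector aligned with `subjects`; `NA` entries
#'   (e.g. conflict-excluded subjects) are dropped.
#' @param subjects a [subject_records()] table.
#' @param spec a [retro_test_spec()].
#' @param region,cnv_type optional labels copied into the result.
#' @return A one-row data.frame (class `assoc_result`) with columns
#'   `region`, `cnv_type`, `gene_group`, `n`, `n_carriers_with_cnv`,
#'   `score_U`, `variance_V`, `p_value`, `hr`, `ci_low`, `ci_high`,
#'   `threshold_passed`. For monomorphic genotypes `U = 0`, `p = 1` and the
#'   HR is reported missing; regions below `min_carriers` give an all-`NA`
#'   statistics row.
#' @export
retro_score_test <- function(g, subjects, spec, region = NA_character_,
                             cnv_type = NA_character_) {
  stopifnot(length(g) == nrow(subjects))
  keep <- !is.na(g)
  g <- as.numeric(g[keep])
  subjects <- subjects[keep, , drop = FALSE]
  res <- data.frame(region = region, cnv_type = cnv_type,
                    gene_group = if (nrow(subjects)) subjects$gene_group[1] else NA,
                    n = nrow(subjects), n_carriers_with_cnv = sum(g),
                    score_U = NA_real_, variance_V = NA_real_,
                    p_value = NA_real_, hr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, threshold_passed = NA,
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  if (length(g) && (sum(g) == 0 || sum(g) == length(g))) {
    # monomorphic: centred score is identically zero
    res$score_U <- 0; res$variance_V <- 0; res$p_value <- 1
    return(res)
  }
  if (sum(g) < spec$min_carriers) return(res)

  Lambda <- cumulative_hazard(spec$incidence, subjects$age_end)
  stratum <- .stratum_codes(subjects, spec, g)
  family <- as.integer(factor(subjects[[spec$cluster]]))
  core <- .retro_score_core(g, as.numeric(subjects$affected), Lambda,
                            stratum, family)
  res$score_U <- core$U
  res$variance_V <- core$V
  if (core$V <= 0) {               # monomorphic within every stratum
    res$p_value <- 1
    return(res)
  }
  res$p_value <- pchisq(core$U^2 / core$V, df = 1, lower.tail = FALSE)
  if (core$I > 0) {
    beta <- core$U / core$I
    se <- sqrt(core$V) / core$I
    res$hr <- exp(beta)
    res$ci_low <- exp(beta - 1.96 * se)
    res$ci_high <- exp(beta + 1.96 * se)
  }
  res
}

#' Genome-wide retrospective-likelihood scan
#'
#' Runs [retro_score_test()] for every gene region and CNV type in a
#' genotype matrix, applying the effective-test threshold for each type
#' (the Bonferroni denominator counts only regions with at least one
#' overlapping CNV of that type). Conflict-excluded (subject, region) pairs
#' contribute to no test for that region.
#'
#' @param gm a [overlap_genes()] (optionally [flag_conflicts()]-ed) result.
#' @param subjects a [subject_records()] table covering `gm$sample_ids`.
#' @param spec a [retro_test_spec()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame of per-(region, type) results with `threshold_passed`
#'   set against the type-specific effective-test threshold.
#' @export
retro_scan <- function(gm, subjects, spec, alpha = 0.05) {
  ord <- match(gm$sample_ids, subjects$sample_id)
  if (anyNA(ord)) stop("genotype matrix contains samples missing from the phenotype table",
                       call. = FALSE)
  subjects <- subjects[ord, , drop = FALSE]
  out <- list()
  for (type in c("deletion", "duplication")) {
    mat <- gm[[type]]
    testable <- colSums(mat) >= 1L
    n_eff <- sum(testable)
    thr <- if (n_eff) effective_test_threshold(n_eff, alpha)$exact else NA
    for (j in which(testable)) {
      gj <- as.numeric(mat[, j])
      gj[gm$conflict[, j]] <- NA
      r <- retro_score_test(gj, subjects, spec,
                            region = gm$regions$gene_symbol[j],
                            cnv_type = type)
      r$threshold_passed <- !is.na(r$p_value) & r$p_value <= thr
      out[[length(out) + 1L]] <- r
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specification for the weighted-cohort hazard model
#'
#' @param incidence an [incidence_table()] for the expected affected
#'   proportions.
#' @param age_bands break points of the weighting age bands; the default is
#'   5-year bands from 20 to 80 with a single opening band covering ages
#'   below 20, so the bands cover the full follow-up from birth.
#' @param covariates fixed-effect adjustment columns (default birth cohort
#'   and genotyping array).
#' @param strata stratification columns for the baseline hazard.
#' @param cluster clustering column for the robust variance.
#' @return An object of class `weighted_cohort_spec`.
#' @export
weighted_cohort_spec <- function(incidence,
                                 age_bands = c(0, seq(20, 80, by = 5)),
                                 covariates = c("birth_cohort", "array"),
                                 strata = c("country", "aj"),
                                 cluster = "family_id") {
  stopifnot(inherits(incidence, "incidence_table"),
            age_bands[1] == 0,
            max(age_bands) >= max(incidence$age_breaks))
  structure(list(incidence = incidence, age_bands = age_bands,
                 covariates = covariates, strata = strata, cluster = cluster),
            class = "weighted_cohort_spec")
}

#' Incidence-derived cohort weights
#'
#' Reweights affected and unaffected carriers within age-at-end bands so
#' the weighted sample mimics a true cohort followed under the population
#' incidence. For band `a` spanning \eqn{[l_a, u_a)}, the expected affected
#' proportion is the probability of onset within the band conditional on
#' being disease-free at its start, \eqn{e_a = (F(u_a) - F(l_a))/S(l_a) = 1
#' - \exp\{-(\Lambda_0(u_a) - \Lambda_0(l_a))\}}; the observed proportion
#' among subjects whose follow-up ends in the band is \eqn{f_a}; weights are
#' \eqn{e_a/f_a} for affected and \eqn{(1-e_a)/(1-f_a)} for unaffected
#' subjects, so the weighted affected fraction equals the expected fraction
#' in every band. Bands with observed proportion 0 or 1 get weight 1 with a
#' warning; empty bands are skipped.
#'
#' @param subjects a [subject_records()] table.
#' @param spec a [weighted_cohort_spec()].
#' @return Numeric weight per subject, aligned with `subjects`.
#' @export
compute_weights <- function(subjects, spec) {
  max_age <- max(spec$incidence$age_breaks)
  band <- cut(pmin(subjects$age_end, max_age), breaks = spec$age_bands,
              include.lowest = TRUE, right = FALSE)
  lo <- spec$age_bands[-length(spec$age_bands)]
  hi <- spec$age_bands[-1]
  e_band <- 1 - exp(-(cumulative_hazard(spec$incidence, pmin(hi, max_age)) -
                        cumulative_hazard(spec$incidence, pmin(lo, max_age))))
  w <- rep(1, nrow(subjects))
  degenerate <- character()
  for (b in seq_along(levels(band))) {
    i <- which(as.integer(band) == b)
    if (!length(i)) next
    f <- mean(subjects$affected[i])
    e <- e_band[b]
    if (f == 0 || f == 1) { degenerate <- c(degenerate, levels(band)[b]); next }
    w[i] <- ifelse(subjects$affected[i], e / f, (1 - e) / (1 - f))
  }
  if (length(degenerate))
    warning("age band(s) with all-affected or all-unaffected subjects kept at weight 1: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  w
}

#' Weighted-cohort Cox model
#'
#' Fits a weighted Cox proportional-hazards model on the age scale
#' (follow-up from birth to `age_end`), with a baseline hazard stratified by
#' country and Ashkenazi-Jewish ancestry, fixed-effect adjustment for birth
#' cohort and genotyping array, incidence-derived cohort weights, Breslow
#' tie handling, and a cluster-robust (sandwich) variance with families as
#' clusters. Hazard ratios are reported per non-reference exposure level.
#'
#' Exposure codings over the clinically diagnosed mutation type: with
#' `"del_vs_other"` / `"three_level"` the model contrasts deletions (and
#' duplications, retained as a third level) against other pathogenic
#' variants; with `"dup_vs_other_excl_del"` deletion carriers are excluded
#' and duplications contrast against other variants. Alternatively pass a
#' numeric or factor exposure vector (e.g. a per-region CNV genotype).
#'
#' @param subjects a [subject_records()] table.
#' @param exposure one of `"del_vs_other"`, `"dup_vs_other_excl_del"`,
#'   `"three_level"`, or a vector aligned with `subjects`.
#' @param spec a [weighted_cohort_spec()].
#' @param weights optional precomputed weights; by default
#'   [compute_weights()] is applied (after any exposure-based subsetting).
#' @return data.frame (class `assoc_result`) with one row per non-reference
#'   exposure level: `term`, `n`, `n_events`, `beta`, `hr`, `ci_low`,
#'   `ci_high`, `p_value` (robust Wald).
#' @export
weighted_cohort_fit <- function(subjects, exposure = "del_vs_other",
                                spec, weights = NULL) {
  if (is.character(exposure) && length(exposure) == 1) {
    coding <- match.arg(exposure,
                        c("del_vs_other", "dup_vs_other_excl_del", "three_level"))
    if (coding == "dup_vs_other_excl_del") {
      keep <- subjects$mutation_type != "deletion"
      subjects <- subjects[keep, , drop = FALSE]
      if (!is.null(weights)) weights <- weights[keep]
      expo <- factor(subjects$mutation_type, levels = c("other", "duplication"))
    } else {
      expo <- factor(subjects$mutation_type,
                     levels = c("other", "deletion", "duplication"))
    }
  } else {
    stopifnot(length(exposure) == nrow(subjects))
    expo <- if (is.factor(exposure)) exposure else as.numeric(exposure)
  }
  if (is.null(weights)) weights <- compute_weights(subjects, spec)

  dat <- data.frame(
    age_end = subjects$age_end,
    affected = as.integer(subjects$affected),
    .expo = expo,
    .stratum = interaction(subjects[spec$strata], drop = TRUE),
    .cluster = subjects[[spec$cluster]],
    .w = weights,
    stringsAsFactors = FALSE
  )
  for (cv in spec$covariates) dat[[cv]] <- factor(subjects[[cv]])
  # drop strata with no events (they contribute nothing to the partial
  # likelihood; flagged so the user knows)
  ev_by_str <- tapply(dat$affected, dat$.stratum, sum)
  dead <- names(ev_by_str)[ev_by_str == 0]
  if (length(dead)) {
    warning("dropping stratum/strata with no events: ",
            paste(dead, collapse = ", "), call. = FALSE)
    dat <- dat[!(dat$.stratum %in% dead), , drop = FALSE]
    dat$.stratum <- droplevels(dat$.stratum)
  }
  covs <- character()
  for (cv in spec$covariates) {
    dat[[cv]] <- droplevels(dat[[cv]])
    if (nlevels(dat[[cv]]) >= 2) covs <- c(covs, cv)
  }
  rhs <- paste(c(".expo", covs,
                 if (nlevels(factor(dat$.stratum)) > 1) "strata(.stratum)"),
               collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(age_end, affected) ~", rhs)),
    data = dat, weights = dat$.w, cluster = .cluster,
    ties = "breslow", robust = TRUE
  )
  if (any(!is.finite(stats::coef(fit))))
    stop("weighted Cox fit failed to converge (", fit$iter[1],
         " iterations; non-finite coefficients)", call. = FALSE)
  sm <- summary(fit)
  rows <- grep("^\\.expo", rownames(sm$coefficients))
  beta <- sm$coefficients[rows, "coef"]
  se <- sm$coefficients[rows, "robust se"]
  term <- sub("^\\.expo", "", rownames(sm$coefficients)[rows])
  term[term == ""] <- "exposure"
  res <- data.frame(
    term = term, n = nrow(dat), n_events = sum(dat$affected),
    beta = beta, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("assoc_result", "data.frame")
  attr(res, "fit") <- fit
  res
}

#' Effective-test significance threshold
#'
#' Bonferroni threshold over the number of effective tests: the count of
#' gene regions with at least one overlapping CNV of the type and carrier
#' group under study. Returns the exact `alpha/n` and a display value
#' rounded to one significant figure (the convention used when such
#' thresholds are printed, e.g. 0.05/6551 shown as 8e-06).
#'
#' @param n_regions_tested number of testable gene regions (>= 1).
#' @param alpha family-wise level (default 0.05).
#' @return list with `exact` and `display`.
#' @export
effective_test_threshold <- function(n_regions_tested, alpha = 0.05) {
  if (n_regions_tested < 1) stop("no testable regions", call. = FALSE)
  exact <- alpha / n_regions_tested
  list(exact = exact, display = signif(exact, 1))
}
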