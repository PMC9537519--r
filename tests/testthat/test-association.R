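test_that("monomorphic genotypes give a zero score and p = 1", {
  fx <- tiny_fixture()
  spec <- retro_test_spec(test_incidence())
  for (g in list(rep(0, 20), rep(1, 20))) {
    res <- retro_score_test(g, fx$subjects, spec)
    expect_equal(res$score_U, 0)
    expect_equal(res$p_value, 1)
    expect_true(is.na(res$hr))
  }
  # below the minimum carrier count: statistics withheld
  res <- retro_score_test(c(1, rep(0, 19)), fx$subjects, spec)
  expect_true(is.na(res$p_value))
})

test_that("score test is invariant to stratum relabelling and family order", {
  fx <- tiny_fixture()
  spec <- retro_test_spec(test_incidence())
  base <- retro_score_test(fx$g, fx$subjects, spec)

  relabelled <- fx$subjects
  relabelled$country <- paste0("X_", relabelled$country)
  expect_equal(retro_score_test(fx$g, relabelled, spec)[-(1:3)], base[-(1:3)])

  perm <- sample(seq_len(20))
  shuffled <- fx$subjects[perm, ]
  expect_equal(retro_score_test(fx$g[perm], shuffled, spec)[-(1:3)],
               base[-(1:3)])
})

test_that("with singleton families the robust variance is the unclustered score sum", {
  fx <- tiny_fixture()
  solo <- fx$subjects
  solo$family_id <- solo$sample_id
  spec <- retro_test_spec(test_incidence())
  res <- retro_score_test(fx$g, solo, spec)
  Lam <- cumulative_hazard(spec$incidence, solo$age_end)
  cc <- as.numeric(solo$affected) - Lam
  cc <- cc - mean(cc)
  u <- (fx$g - mean(fx$g)) * cc
  expect_equal(res$variance_V, sum(u^2))
  expect_equal(res$score_U, sum(u))
})

test_that("clustering two correlated members inflates the variance but not the score", {
  fx <- tiny_fixture()
  spec <- retro_test_spec(test_incidence())
  clustered <- retro_score_test(fx$g, fx$subjects, spec)
  solo <- fx$subjects
  solo$family_id <- solo$sample_id
  unclustered <- retro_score_test(fx$g, solo, spec)
  expect_equal(clustered$score_U, unclustered$score_U)
  expect_false(identical(clustered$variance_V, unclustered$variance_V))
})

test_that("one-step HR approximates the retrospective-likelihood grid MLE on the printed fixture", {
  fx <- tiny_fixture()
  inc <- test_incidence()
  one <- retro_score_test(fx$g, fx$subjects, retro_test_spec(inc))
  mle <- retro_grid_mle(fx$g, fx$subjects, inc)
  expect_lt(abs(log(one$hr) - mle), 0.15)
  expect_true(one$ci_low <= one$hr && one$hr <= one$ci_high)
})

test_that("sparse strata are pooled instead of degenerating the centring", {
  fx <- tiny_fixture()
  spread <- fx$subjects
  spread$country <- c(rep("A", 16), "B", "B", "C", "C")  # carriers thin out
  spec <- retro_test_spec(test_incidence())
  res <- retro_score_test(fx$g, spread, spec)
  expect_true(is.finite(res$p_value))
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("incidence-derived weights restore the expected affected fraction per band", {
  # one active band [40,45) with e = 1 - exp(-5*lambda) chosen to be 0.2
  lam <- -log(0.8) / 5
  inc <- incidence_table(c(0, 40, 45, 80), c(0, lam, 0))
  spec <- weighted_cohort_spec(inc, age_bands = c(0, 40, 45, 80))
  sub <- tiny_fixture()$subjects[1:10, ]
  sub$age_end <- seq(40, 44.5, by = 0.5)
  sub$affected <- rep(c(TRUE, FALSE), 5)    # observed f = 0.5
  w <- suppressWarnings(compute_weights(sub, spec))
  expect_equal(unique(w[sub$affected]), 0.2 / 0.5)        # 0.4
  expect_equal(unique(w[!sub$affected]), 0.8 / 0.5)       # 1.6
  # weighted affected fraction equals the expected fraction
  expect_equal(sum(w[sub$affected]) / sum(w), 0.2)

  # observed equals expected -> all weights 1
  sub2 <- sub
  sub2$affected <- c(TRUE, TRUE, rep(FALSE, 8))
  w2 <- suppressWarnings(compute_weights(sub2, spec))
  expect_equal(w2, rep(1, 10))

  # degenerate band: all unaffected -> weight 1 with a warning
  sub3 <- sub
  sub3$affected <- rep(FALSE, 10)
  expect_warning(w3 <- compute_weights(sub3, spec), "weight 1")
  expect_equal(w3, rep(1, 10))
})

test_that("unit weights reproduce the reference Cox partial-likelihood fit", {
  set.seed(101)
  n <- 400
  sub <- data.frame(
    sample_id = sprintf("S%03d", 1:n),
    family_id = sprintf("S%03d", 1:n),
    gene_group = "BRCA1",
    affected = runif(n) < 0.4,
    age_end = runif(n, 25, 79),
    country = "SIM", aj = FALSE, birth_cohort = "1940-49",
    array = "OncoArray", mutation_type = "other",
    stringsAsFactors = FALSE
  )
  g <- rbinom(n, 1, 0.3)
  spec <- weighted_cohort_spec(test_incidence())
  fit <- weighted_cohort_fit(subject_records(sub), exposure = g, spec = spec,
                             weights = rep(1, n))
  ref <- survival::coxph(survival::Surv(age_end, affected) ~ g,
                         data = cbind(sub, g = g), ties = "breslow")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-4)
})

test_that("robust CI covers the null HR at nominal rate with independent exposure", {
  set.seed(202)
  reps <- 200
  covered <- logical(reps)
  spec <- weighted_cohort_spec(test_incidence())
  for (r in seq_len(reps)) {
    n <- 5000
    sub <- data.frame(
      sample_id = sprintf("S%05d", 1:n),
      family_id = sprintf("S%05d", 1:n),
      gene_group = "BRCA1",
      affected = runif(n) < 0.3,
      age_end = runif(n, 25, 79),
      country = "SIM", aj = FALSE, birth_cohort = "1940-49",
      array = "OncoArray", mutation_type = "other",
      stringsAsFactors = FALSE
    )
    g <- rbinom(n, 1, 0.2)
    fit <- weighted_cohort_fit(subject_records(sub), exposure = g, spec = spec,
                               weights = rep(1, n))
    covered[r] <- fit$ci_low <= 1 && 1 <= fit$ci_high
  }
  expect_gte(mean(covered), 0.93)
})

test_that("mutation-type codings contrast against 'other' with the documented exclusions", {
  cfg <- sim_config(n_families = 4000, n_regions = 1,
                    mutation_type_probs = c(other = 0.7, deletion = 0.2,
                                            duplication = 0.1),
                    seed = 33)
  sim <- simulate_cohort(cfg)
  spec <- weighted_cohort_spec(test_incidence())
  fit3 <- suppressWarnings(weighted_cohort_fit(sim$subjects, "del_vs_other", spec))
  expect_setequal(fit3$term, c("deletion", "duplication"))
  fit2 <- suppressWarnings(weighted_cohort_fit(sim$subjects,
                                               "dup_vs_other_excl_del", spec))
  expect_equal(fit2$term, "duplication")
  n_del <- sum(sim$subjects$mutation_type == "deletion")
  expect_equal(fit2$n, nrow(sim$subjects) - n_del)
  expect_true(all(fit3$ci_low <= fit3$hr & fit3$hr <= fit3$ci_high))
})

test_that("duplicating subjects as one two-member family inflates only the robust variance", {
  cfg <- sim_config(n_families = 800, family_size_probs = c(1, 0, 0, 0),
                    n_regions = 1, cnv_frequency = 0.2, seed = 44)
  sim <- simulate_cohort(cfg)
  n <- nrow(sim$subjects)
  # the same subject table duplicated: each subject appears twice
  dup <- rbind(as.data.frame(sim$subjects), as.data.frame(sim$subjects))
  dup$sample_id <- sprintf("D%05d", seq_len(2 * n))
  g <- rep(sim$truth$genotypes[, 1], 2)
  spec <- weighted_cohort_spec(test_incidence())
  w <- suppressWarnings(compute_weights(subject_records(dup), spec))

  paired <- dup
  paired$family_id <- rep(sprintf("P%05d", seq_len(n)), 2)  # copies share a family
  solo <- dup
  solo$family_id <- solo$sample_id                           # all singletons
  fit_paired <- suppressWarnings(
    weighted_cohort_fit(subject_records(paired), g, spec, weights = w))
  fit_solo <- suppressWarnings(
    weighted_cohort_fit(subject_records(solo), g, spec, weights = w))
  expect_equal(fit_paired$beta, fit_solo$beta, tolerance = 1e-8)
  se_paired <- (log(fit_paired$ci_high) - log(fit_paired$ci_low)) / (2 * 1.96)
  se_solo <- (log(fit_solo$ci_high) - log(fit_solo$ci_low)) / (2 * 1.96)
  expect_gt(se_paired, se_solo)  # perfectly correlated cluster members
})

test_that("effective-test thresholds reproduce the one-significant-figure convention", {
  expect_equal(effective_test_threshold(6551)$display, 8e-6)
  expect_equal(effective_test_threshold(10240)$display, 5e-6)
  expect_equal(effective_test_threshold(5094)$display, 1e-5)
  expect_equal(effective_test_threshold(8469)$display, 6e-6)
  expect_equal(effective_test_threshold(10)$exact, 5e-3)
  expect_error(effective_test_threshold(0), "testable")
})

test_that("the genome-wide scan counts effective tests per CNV type", {
  cfg <- sim_config(n_families = 800, n_regions = 6, cnv_frequency = 0.1,
                    region_type = rep(c("deletion", "duplication"), 3),
                    seed = 55)
  sim <- simulate_cohort(cfg)
  out <- simulate_calls(sim$truth, cfg)
  calls <- merge_adjacent(filter_calls(out$calls))
  gm <- flag_conflicts(overlap_genes(calls, sim$truth$regions,
                                     sample_ids = sim$subjects$sample_id), calls)
  res <- retro_scan(gm, sim$subjects, retro_test_spec(test_incidence()))
  expect_true(all(res$cnv_type %in% c("deletion", "duplication")))
  expect_true(all(res$n_carriers_with_cnv >= 1))
  ok <- !is.na(res$p_value)
  expect_true(all(res$p_value[ok] > 0 & res$p_value[ok] <= 1))
  # p and U^2/V are monotonically related
  ok2 <- ok & res$variance_V > 0
  stat <- res$score_U[ok2]^2 / res$variance_V[ok2]
  expect_equal(order(res$p_value[ok2]), order(-stat))
})
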