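# Independent oracles and fixture builders shared across tests.

# Quadratic all-pairs overlap oracle: logical matrix calls x regions.
brute_force_overlap <- function(calls, regions) {
  out <- matrix(FALSE, nrow(calls), nrow(regions))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(regions))) {
      out[i, j] <- calls$chrom[i] == regions$chrom[j] &&
        calls$start[i] <= regions$end[j] &&
        calls$end[i] >= regions$start[j]
    }
  }
  out
}

# Quadratic type-aware call-vs-truth support oracle.
brute_force_support <- function(calls, truth) {
  vapply(seq_len(nrow(calls)), function(i) {
    any(truth$cnv_type == calls$cnv_type[i] &
          truth$chrom == calls$chrom[i] &
          truth$start <= calls$end[i] &
          truth$end >= calls$start[i])
  }, logical(1))
}

# Grid-search maximiser of the full retrospective log-likelihood
# P(g | delta, t) with the stratum genotype frequency profiled numerically
# per beta; independent of the package's score-test code path.
retro_grid_mle <- function(g, subjects, incidence, grid = seq(-2, 2, 0.005)) {
  Lam <- cumulative_hazard(incidence, subjects$age_end)
  d <- as.numeric(subjects$affected)
  ll <- vapply(grid, function(b) {
    prof <- function(p) {
      num <- d * b * g - Lam * exp(b * g) + g * log(p) + (1 - g) * log(1 - p)
      den <- log(p * exp(d * b - Lam * exp(b)) + (1 - p) * exp(-Lam))
      sum(num - den)
    }
    optimize(prof, c(1e-4, 1 - 1e-4), maximum = TRUE)$objective
  }, numeric(1))
  grid[which.max(ll)]
}

# Random CNV-call/region instances for oracle-equivalence properties.
random_instance <- function(n_calls, n_regions, n_samples = 5,
                            chroms = c("1", "2", "X")) {
  calls <- cnv_calls(
    sample_id = sample(sprintf("S%d", seq_len(n_samples)), n_calls, TRUE),
    chrom = sample(chroms, n_calls, TRUE),
    start = st <- sample.int(5000, n_calls, TRUE),
    end = st + sample.int(500, n_calls, TRUE) - 1L,
    cnv_type = sample(c("deletion", "duplication"), n_calls, TRUE),
    n_probes = sample(5:50, n_calls, TRUE)
  )
  rst <- sample.int(5000, n_regions, TRUE)
  regions <- gene_regions(
    gene_symbol = sprintf("G%03d", seq_len(n_regions)),
    chrom = sample(chroms, n_regions, TRUE),
    start = rst, end = rst + sample.int(400, n_regions, TRUE) - 1L
  )
  list(calls = calls, regions = regions)
}

# Printed 20-subject sibship fixture: ten families of two, clinic-style
# (all probands affected), seven CNV carriers spread across statuses so the
# realised effect is mild.
tiny_fixture <- function() {
  subjects <- subject_records(data.frame(
    sample_id = sprintf("P%02d", 1:20),
    family_id = rep(sprintf("F%02d", 1:10), each = 2),
    gene_group = "BRCA1",
    affected = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                 TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    age_end = c(40, 50, 35, 60, 45, 42, 50, 55, 38, 45,
                55, 65, 42, 48, 60, 70, 36, 40, 52, 58),
    country = "SIM", aj = FALSE, birth_cohort = "1940-49",
    array = "OncoArray", mutation_type = "other",
    stringsAsFactors = FALSE
  ))
  list(subjects = subjects,
       g = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1, 0, 0, 0))
}

# Cached BRCA1-like incidence for tests.
test_incidence <- function() default_incidence("BRCA1")
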