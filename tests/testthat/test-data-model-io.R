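test_that("rawcnv dialect parses, maps copy-number states, and rejects bad records", {
  path <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines(c(
    "chr2:100-500 numsnp=7 length=401 state2,cn=1 S1 startsnp=rs1 endsnp=rs7",
    "chr17:41196312-41277500 numsnp=12 length=81189 state5,cn=3 S2 startsnp=rs8 endsnp=rs19"
  ), path)
  calls <- read_cnv_calls(path, "penncnv_rawcnv")
  expect_s3_class(calls, "cnv_calls")
  expect_equal(calls$sample_id, c("S1", "S2"))
  expect_equal(calls$chrom, c("2", "17"))   # leading "chr" stripped
  expect_equal(calls$start, c(100, 41196312))
  expect_equal(calls$end, c(500, 41277500))
  expect_equal(calls$cnv_type, c("deletion", "duplication"))
  expect_equal(calls$n_probes, c(7L, 12L))
  expect_equal(calls$copy_number, c(1L, 3L))

  writeLines("chr2:100-500 numsnp=7 length=401 state3,cn=2 S1 startsnp=rs1 endsnp=rs7", path)
  expect_error(read_cnv_calls(path, "penncnv_rawcnv"), "neutral copy number")

  writeLines(c(
    "chr1:1-10 numsnp=5 length=10 state2,cn=1 S1 startsnp=rs1 endsnp=rs5",
    "not a rawcnv record"
  ), path)
  expect_error(read_cnv_calls(path, "penncnv_rawcnv"), "line 2")

  writeLines("chrY:100-500 numsnp=7 length=401 state2,cn=1 S1 startsnp=rs1 endsnp=rs7", path)
  expect_error(read_cnv_calls(path, "penncnv_rawcnv"), "chromosome")
})

test_that("tsv dialect parses with and without header and round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("S2 17 41196312 41277500 duplication 12", path)
  calls <- read_cnv_calls(path, "tsv")
  expect_equal(calls$sample_id, "S2")
  expect_equal(calls$chrom, "17")
  expect_equal(calls$cnv_type, "duplication")
  expect_true(is.na(calls$copy_number))

  orig <- cnv_calls(
    sample_id = c("A", "A", "B"), chrom = c("1", "2", "X"),
    start = c(100, 5000, 7), end = c(200, 6000, 9),
    cnv_type = c("deletion", "duplication", "deletion"),
    n_probes = c(5L, 12L, 6L), copy_number = c(1L, 4L, 0L)
  )
  write_cnv_calls(orig, path, "tsv")
  back <- read_cnv_calls(path, "tsv")
  expect_equal(as.data.frame(back), as.data.frame(orig))

  # rawcnv round trip (requires known copy numbers)
  raw <- withr::local_tempfile(fileext = ".rawcnv")
  write_cnv_calls(orig, raw, "penncnv_rawcnv")
  expect_equal(as.data.frame(read_cnv_calls(raw, "penncnv_rawcnv")),
               as.data.frame(orig))
})

test_that("cnv_calls enforces its invariants", {
  expect_error(cnv_calls("S", "1", 10, 5, "deletion", 5L), "start > end")
  expect_error(cnv_calls("S", "1", 1, 5, "deletion", 0L), "n_probes")
  expect_error(cnv_calls("S", "1", 1, 5, "deletion", 5L, 2L), "neutral")
  expect_error(cnv_calls("S", "1", 1, 5, "duplication", 5L, 1L), "inconsistent")
  expect_error(cnv_calls("S", "Y", 1, 5, "deletion", 5L), "chromosome")
})

test_that("BED gene tracks convert coordinates, collapse symbols, round-trip", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr16\t28616908\t28634909\tSULT1A1", bed)
  reg <- read_gene_track(bed)
  expect_equal(reg$gene_symbol, "SULT1A1")
  expect_equal(reg$chrom, "16")
  expect_equal(reg$start, 28616909)  # BED 0-based half-open -> 1-based closed
  expect_equal(reg$end, 28634909)

  # duplicate symbols collapse to the union span
  writeLines(c("chr1\t100\t200\tGENEA", "chr1\t150\t300\tGENEA"), bed)
  reg <- read_gene_track(bed)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(101, 300))

  # same symbol on different chromosomes stays distinct
  writeLines(c("chr1\t100\t200\tGENEA", "chr2\t100\t200\tGENEA"), bed)
  expect_equal(nrow(read_gene_track(bed)), 2L)

  # 3-column BED has no name column
  writeLines("chr1\t100\t200", bed)
  expect_error(read_gene_track(bed), "name column")

  # round trip is coordinate-exact
  writeLines(c("chr16\t28616908\t28634909\tSULT1A1",
               "chrX\t1000\t2000\tGENEX"), bed)
  reg <- read_gene_track(bed)
  out <- withr::local_tempfile(fileext = ".bed")
  write_gene_track(reg, out)
  expect_equal(as.data.frame(read_gene_track(out)), as.data.frame(reg))
})

test_that("phenotype and incidence tables round-trip and validate", {
  fx <- tiny_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(fx$subjects, path)
  back <- read_phenotypes(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$subjects))

  bad <- as.data.frame(fx$subjects)
  bad$family_id <- NULL
  expect_error(subject_records(bad), "family_id")

  inc <- incidence_table(c(0, 40, 80), c(0.001, 0.02))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_incidence(inc, ypath)
  expect_equal(read_incidence(ypath), inc)
  expect_error(incidence_table(c(0, 40), c(0.1, 0.2)), "length")
  expect_error(incidence_table(c(0, 40, 30), c(0.1, 0.2)), "increasing")
  expect_error(incidence_table(c(0, 40, 80), c(0.1, -0.2)), "non-negative")
})

test_that("cumulative hazard integrates the step function exactly", {
  const <- incidence_table(c(0, 80), 0.01)
  expect_equal(cumulative_hazard(const, 50), 0.5)
  expect_equal(cumulative_hazard(const, 0), 0)
  two <- incidence_table(c(0, 40, 80), c(0.001, 0.02))
  expect_equal(cumulative_hazard(two, 50), 0.001 * 40 + 0.02 * 10)
  expect_error(cumulative_hazard(two, 81), "outside")

  # non-decreasing, and band-boundary values match the banded cumsum
  inc <- test_incidence()
  ts <- seq(0, 80, by = 0.5)
  L <- cumulative_hazard(inc, ts)
  expect_true(all(diff(L) >= 0))
  expect_equal(cumulative_hazard(inc, inc$age_breaks),
               c(0, cumsum(inc$hazard * diff(inc$age_breaks))))
})

test_that("association results export with the standard column set", {
  fx <- tiny_fixture()
  res <- retro_score_test(fx$g, fx$subjects, retro_test_spec(test_incidence()),
                          region = "GENE1", cnv_type = "deletion")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assoc_results(res, path)
  out <- read.delim(path)
  expect_true(all(c("region", "type", "n_cnv", "U", "V", "p", "HR",
                    "CI_low", "CI_high", "pass") %in% names(out)))
  expect_equal(out$n_cnv, sum(fx$g))
})
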