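test_that("population counts are read with multi-allelic decomposition", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  rec <- suppressMessages(read_population_counts(vcf))
  expect_equal(nrow(rec), 6L)  # 4 biallelic lines + 2 alts of one line

  ma <- rec[rec$pos == 200, ]
  expect_equal(ma$alt, c("C", "T"))
  expect_equal(ma$ac_NFE, c(2, 7))  # allele-indexed values follow the alt
  expect_equal(ma$ac_AFR, c(1, 5))
  expect_equal(ma$an_NFE, c(10000, 10000))

  # AN present but AC absent: population still absent from counts
  no_ac <- rec[rec$pos == 300, ]
  expect_true(is.na(no_ac$ac_NFE) && is.na(no_ac$an_NFE))

  # line with none of the mapped keys is kept but flagged
  empty <- rec[rec$pos == 400, ]
  expect_false(empty$has_counts)
})

test_that("records with AC > AN are skipped with a warning", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        include_bad = TRUE)
  expect_warning(rec <- suppressMessages(read_population_counts(vcf)),
                 "AC > AN")
  expect_false(any(rec$pos == 500))
  expect_equal(nrow(rec), 6L)
})

test_that("annotation adds per-population and popmax filtering AFs", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  rec <- suppressMessages(read_population_counts(vcf))
  ann <- suppressMessages(annotate_filtering_af(rec))

  first <- ann[ann$pos == 100, ]
  expect_equal(first$faf_popmax, 3.5e-5)
  expect_identical(first$faf_popmax_pop, "NFE")
  # all counts <= 1 in every population: never filtered
  low <- ann[ann$pos == 350, ]
  expect_equal(low$faf_popmax, 0)
  # no eligible population: popmax 0, no attaining population
  expect_equal(ann$faf_popmax[ann$pos == 400], 0)
  expect_true(is.na(ann$faf_popmax_pop[ann$pos == 400]))
})

test_that("annotated VCF round-trips identity, counts and FAF values", {
  src <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  out <- withr::local_tempfile(fileext = ".vcf")
  ann <- suppressMessages(annotate_vcf(src, out))

  txt <- readLines(out)
  expect_true(any(grepl("^##INFO=<ID=FAF95_popmax,", txt)))
  expect_true(any(grepl("FAF95_popmax=3.5e-05", txt, fixed = TRUE)))

  back <- suppressMessages(read_population_counts(out))
  orig <- suppressMessages(read_population_counts(src))
  expect_equal(back[c("variant_id", "chrom", "pos", "ref", "alt")],
               orig[c("variant_id", "chrom", "pos", "ref", "alt")])
  expect_equal(back$ac_NFE, orig$ac_NFE)
  expect_equal(back$an_AFR, orig$an_AFR)

  # written FAF values re-parse to the annotation, at the written precision
  reread <- VariantAnnotation::readVcf(out, genome = "unknown")
  faf <- unlist(VariantAnnotation::info(reread)$FAF95_popmax)
  expect_equal(as.numeric(faf), round(ann$faf_popmax, 6), tolerance = 1e-9)
})

test_that("disease filtering applies the >= rule to popmax filtering AF", {
  # ExAC-scale pathogenic variant observed 3 times must survive filtering
  rec <- data.frame(variant_id = "MYBPC3:c.1504C>T",
                    ac_NFE = 3, an_NFE = 121412)
  ann <- annotate_filtering_af(rec)
  expect_lt(ann$faf_popmax, 4e-5)
  dec <- suppressMessages(apply_disease_filter(ann, 4e-5))
  expect_identical(as.character(dec$decision), "retained")

  # boundary: popmax exactly at threshold is filtered
  edge <- data.frame(variant_id = c("at", "below", "absent"),
                     faf_popmax = c(4e-5, 3.9e-5, 0))
  dec <- suppressMessages(apply_disease_filter(edge, 4e-5))
  expect_identical(as.character(dec$decision),
                   c("filtered", "retained", "retained"))

  thr <- max_credible_af(
    disease_architecture("1/500", "dominant", 0.02, penetrance = 0.5))
  dec2 <- suppressMessages(apply_disease_filter(edge, thr))
  expect_identical(dec$decision, dec2$decision)

  expect_error(suppressMessages(apply_disease_filter(
    data.frame(variant_id = "x", faf_popmax = NA_real_), 4e-5)),
    "unannotated")
  expect_error(apply_disease_filter(data.frame(variant_id = "x"), 4e-5),
               "not annotated")
})

test_that("decisions recompute from raw counts and tighten monotonically", {
  set.seed(3)
  cfg <- simulation_config(n_sites = 150, an = 10000, seed = 3)
  panel <- simulate_reference_panel(cfg)
  ann <- suppressMessages(annotate_filtering_af(panel$counts))

  # consistency: re-deriving each popmax from raw counts gives the decision
  t <- 1e-4
  dec <- suppressMessages(apply_disease_filter(ann, t))
  recompute <- vapply(seq_len(nrow(ann)), function(i) {
    counts <- data.frame(
      population = exac_populations(),
      ac = as.numeric(ann[i, paste0("ac_", exac_populations())]),
      an = as.numeric(ann[i, paste0("an_", exac_populations())]))
    popmax_filtering_af(counts)$popmax_af
  }, numeric(1))
  expect_equal(recompute, ann$faf_popmax)
  expect_identical(dec$decision == "filtered", recompute >= t)

  # a lower (stricter) threshold filters a superset of variants
  strict <- suppressMessages(apply_disease_filter(ann, 1e-5))
  filtered_loose <- dec$variant_id[dec$decision == "filtered"]
  filtered_strict <- strict$variant_id[strict$decision == "filtered"]
  expect_true(all(filtered_loose %in% filtered_strict))
})

test_that("filter_vcf writes only retained records", {
  src <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  out <- withr::local_tempfile(fileext = ".vcf")
  dec <- suppressMessages(filter_vcf(src, out, 4e-5))
  kept <- suppressMessages(read_population_counts(out))
  expect_equal(sort(kept$variant_id),
               sort(dec$variant_id[dec$decision == "retained"]))
  # by disease preset name
  out2 <- withr::local_tempfile(fileext = ".vcf")
  dec2 <- suppressMessages(filter_vcf(src, out2, "HCM"))
  expect_equal(dec2$threshold_used[1], 4e-5)
})
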