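# Retention-time class assignment, m/z annotation, abundance assembly.

test_that("class windows assign by retention time and reject overlaps", {
  w <- class_rt_map()
  pk <- tibble::tibble(mz = c(700, 700, 700), rt = c(450, 300, 550))
  got <- assign_class(pk, w)
  expect_identical(got$class, c("PC", NA, "SM"))
  bad <- tibble::tibble(class = c("A", "B"), rt_min = c(0, 50),
                        rt_max = c(100, 150))
  expect_error(validate_rt_windows(bad), "overlapping")
  expect_error(validate_rt_windows(
    tibble::tibble(class = "A", rt_min = 10, rt_max = 10)), "rt_max")
})

test_that("noise-free simulation annotates as a bijection onto ground truth", {
  lip <- noise_free_lipidome()
  des <- study_design()
  ft <- simulate_features(lip, des, seed = 4)
  db <- build_lipid_database(include_odd_carbons = TRUE)
  de <- deisotope(ft)
  ann <- annotate_species(de$peaks, db)
  expect_identical(nrow(ann), 306L)
  expect_false(any(ann$ambiguous))
  truth <- de$peaks$truth_species[match(ann$mz, de$peaks$mz)]
  expect_identical(ann$species, truth)
  expect_setequal(ann$species, lip$species$species)
})

test_that("simulated class jitter stays within the class windows", {
  lip <- noise_free_lipidome(seed = 31, rt_sd = 5)
  ft <- simulate_features(lip, study_design(), seed = 32)
  mono <- ft[ft$provenance == "monoisotopic", ]
  got <- assign_class(mono, class_rt_map())
  truth_class <- lip$species$class[match(mono$truth_species,
                                         lip$species$species)]
  expect_identical(got$class, truth_class)
})

test_that("tolerance gates annotation: a 0.3 Da-off peak stays unannotated", {
  db <- build_lipid_database()
  pc <- db[db$class == "PC", ][1, ]
  pk <- structure(tibble::tibble(mz = pc$mz + 0.3, rt = 450, A = 1e6),
                  sample_ids = "A")
  ann <- annotate_species(pk, db, tolerance = 5)
  expect_identical(nrow(ann), 0L)
})

test_that("a peak within tolerance of two entries is flagged ambiguous and excluded", {
  db <- build_lipid_database("PC", carbons = 34, double_bonds = c(0, 1),
                             mode = "negative", mz_range = NULL)
  # midway between two entries 2.0157 Th apart, at an ion-trap tolerance
  pk <- structure(tibble::tibble(mz = mean(db$mz), rt = 450, A = 1e6),
                  sample_ids = "A")
  ann <- annotate_species(pk, db, tolerance = 1.1, unit = "Da")
  expect_true(ann$ambiguous)
  expect_identical(ann$n_candidates, 2L)
  des1 <- tibble::tibble(sample_id = "A", time_h = 12, dose_uM = 0,
                         replicate = 1)
  ab <- build_abundance_table(ann, des1)
  expect_identical(nrow(ab), 0L)
})

test_that("class gating controls matching of unassigned-rt peaks", {
  db <- build_lipid_database()
  pk <- structure(tibble::tibble(mz = db$mz[50], rt = 999, A = 1),
                  sample_ids = "A")
  expect_identical(nrow(annotate_species(pk, db, class_gate = TRUE)), 0L)
  ann <- annotate_species(pk, db, class_gate = FALSE)
  expect_identical(ann$species, db$species[50])
})

test_that("abundance table sums adducts/peaks per species and keeps design", {
  des <- study_design(times = 12, doses = c(0, 25), replicates = 1)
  ann <- structure(tibble::tibble(
    mz = c(700, 701, 750), rt = c(100, 100, 100),
    class = "PE", species = c("PE 34:1", "PE 34:1", "PE 36:1"),
    adduct = "[M-H]-", carbons = c(34L, 34L, 36L),
    double_bonds = 1L, error_ppm = 0, error_da = 0,
    n_candidates = 1L, ambiguous = FALSE,
    "T12_D0_R1" = c(10, 5, 1), "T12_D25_R1" = c(20, 2, 3)),
    sample_ids = des$sample_id, ambiguity = "exclude",
    class = c("annotation_table", class(tibble::tibble())))
  ab <- build_abundance_table(ann, des)
  expect_identical(nrow(ab), 2L)
  expect_equal(ab$T12_D0_R1[ab$species == "PE 34:1"], 15)
  expect_equal(ab$T12_D25_R1[ab$species == "PE 34:1"], 22)
  expect_identical(attr(ab, "design"), des)

  empty <- ann[0, ]
  attr(empty, "sample_ids") <- des$sample_id
  ab0 <- build_abundance_table(empty, des)
  expect_identical(nrow(ab0), 0L)
  expect_identical(attr(ab0, "design"), des)
})

test_that("full synthetic run recovers at least 95% of ground-truth species", {
  res <- default_pipeline_run()
  truth <- res$lipidome$species$species
  recovered <- intersect(res$abundance$species, truth)
  expect_gte(length(recovered) / length(truth), 0.95)
})

test_that("abundance CSV round-trips through the annotate dialect", {
  res <- default_pipeline_run()
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_table(res$abundance, path)
  back <- read_abundance_table(path, attr(res$abundance, "design"))
  expect_equal(back$species, res$abundance$species)
  expect_equal(as.matrix(back[, -(1:4)]),
               as.matrix(res$abundance[, -(1:4)]), tolerance = 1e-12)
})
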