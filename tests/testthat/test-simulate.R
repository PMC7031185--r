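# Synthetic study design, lipidome and LC-MS feature simulation.

test_that("study design is balanced and matches the treatment layout", {
  d <- study_design()
  expect_identical(nrow(d), 24L)
  expect_true(all(table(d$time_h, d$dose_uM) == 4))
  expect_setequal(unique(d$dose_uM), c(0, 12.5, 25))
  expect_setequal(unique(d$time_h), c(12, 24))
})

test_that("default inventory has the reported per-class species counts", {
  inv <- default_lipidome_inventory()
  counts <- table(inv$class)
  expect_identical(nrow(inv), 306L)
  expect_identical(as.integer(counts[c("PC", "PE", "PG", "PI", "PS", "SM")]),
                   c(72L, 129L, 15L, 27L, 34L, 29L))
  expect_false(anyDuplicated(inv$species) > 0)
})

test_that("simulate_lipidome is deterministic and honours the template", {
  a <- simulate_lipidome(17)
  b <- simulate_lipidome(17)
  expect_identical(a$species, b$species)
  expect_identical(a$effects, b$effects)
  expect_error(simulate_lipidome(1, inventory = lipid_species("PC", 34, 1)[0, ]),
               "empty")

  z <- simulate_lipidome(17, template = null_effect_template())
  expect_true(all(z$effects$log2fc == 0))

  ef <- a$effects[a$effects$dose_uM == 25 & a$effects$time_h == 24, ]
  d_of <- a$species$double_bonds[match(ef$species, a$species$species)]
  expect_lt(mean(ef$log2fc[d_of == 0]), 0)
  expect_gt(mean(ef$log2fc[d_of == 4]), 0)
})

test_that("isotopologue satellites follow the binomial intensity model", {
  # closed-form oracle: B(n, p, k) / B(n, p, 0)
  p13 <- 0.0107
  expect_equal(dbinom(1, 42, p13) / dbinom(0, 42, p13),
               42 * p13 / (1 - p13), tolerance = 1e-12)
  expect_equal(dbinom(1, 42, p13) / dbinom(0, 42, p13), 0.454,
               tolerance = 2e-3)

  lip <- noise_free_lipidome()
  des <- study_design()
  ft <- simulate_features(lip, des, seed = 4)
  mono <- ft[ft$provenance == "monoisotopic", ]
  for (k in 1:2) {
    sat <- ft[ft$provenance == paste0("isotope+", k), ]
    i <- match(sat$truth_species, mono$truth_species)
    nC <- vapply(sat$truth_species, function(s)
      parse_formula(lip$species$formula[lip$species$species == s])[["C"]],
      numeric(1))
    expected <- dbinom(k, nC, p13) / dbinom(0, nC, p13)
    obs <- rowMeans(as.matrix(sat[, des$sample_id])) /
      rowMeans(as.matrix(mono[i, des$sample_id]))
    expect_equal(unname(obs), unname(expected), tolerance = 1e-9)
    expect_equal(sat$mz, mono$mz[i] + k * 1.003355, tolerance = 1e-9)
  }
})

test_that("zero-noise features map exactly onto database entries", {
  lip <- noise_free_lipidome()
  ft <- simulate_features(lip, study_design(), seed = 4)
  db <- build_lipid_database(include_odd_carbons = TRUE)
  mono <- ft[ft$provenance == "monoisotopic", ]
  j <- match(paste(mono$truth_species, mono$truth_adduct),
             paste(db$species, db$adduct))
  expect_false(anyNA(j))
  expect_equal(mono$mz, db$mz[j], tolerance = 1e-12)
})

test_that("replicate intensity CV matches the configured CV", {
  des <- study_design(times = 12, doses = c(0, 25), replicates = 100)
  inv <- default_lipidome_inventory()
  lip <- simulate_lipidome(5, inventory = inv[inv$class == "PG", ],
                           template = null_effect_template(), design = des,
                           cv = 0.2, noise_density = 0, ppm_sd = 0, rt_sd = 0)
  ft <- simulate_features(lip, des, seed = 6)
  mono <- as.matrix(ft[ft$provenance == "monoisotopic", des$sample_id])
  cvs <- apply(mono, 1, function(v) sd(v) / mean(v))
  # 200 samples per species; configured CV recovered within 20%
  expect_true(all(abs(cvs - 0.2) / 0.2 < 0.2))
})

test_that("same seed gives byte-identical feature CSV output", {
  lip <- simulate_lipidome(9)
  des <- study_design()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(simulate_features(lip, des, seed = 2), p1)
  write_feature_table(simulate_features(lip, des, seed = 2), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("feature table CSV round-trips at the stated precision", {
  lip <- simulate_lipidome(9)
  des <- study_design()
  ft <- simulate_features(lip, des, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$mz, ft$mz, tolerance = 1e-6)
  expect_equal(back$rt, ft$rt, tolerance = 1e-2)
  for (s in des$sample_id)
    expect_equal(back[[s]], ft[[s]], tolerance = 1e-6)
  expect_identical(back$provenance, ft$provenance)

  # empty table: header-only file reads back empty
  empty <- ft[0, ]
  attr(empty, "sample_ids") <- des$sample_id
  write_feature_table(empty, path)
  expect_identical(nrow(read_feature_table(path)), 0L)
})

test_that("malformed and negative-intensity rows are rejected with line numbers", {
  des <- study_design(times = 12, doses = c(0, 25), replicates = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,A,B", "700.1,100.0,1e5,2e5", "701.1,100.0,-3,2e5"),
             path)
  expect_error(read_feature_table(path, sample_ids = c("A", "B")),
               "negative intensity.*line 3")
  writeLines(c("mz,rt,A", "700.1,abc,1e5"), path)
  expect_error(read_feature_table(path, sample_ids = "A"),
               "malformed.*line 2")
})

test_that("design/lipidome condition mismatch is rejected", {
  lip <- simulate_lipidome(1, design = study_design(times = 12))
  expect_error(simulate_features(lip, study_design(), seed = 1),
               "mismatch")
})
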