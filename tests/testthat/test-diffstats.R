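# Percent normalization, variance filter, PCA, acyl aggregation, ANOVA.

small_design <- function() study_design(replicates = 2)

test_that("percent normalization sums to 100 over its basis group", {
  des <- small_design()
  meta <- tibble::tibble(species = c("PC 32:0", "PC 34:1", "PE 34:1"),
                         class = c("PC", "PC", "PE"),
                         carbons = c(32L, 34L, 34L),
                         double_bonds = c(0L, 1L, 1L))
  m <- matrix(rep(c(1, 1, 2), nrow(des)), 3, nrow(des))
  ab <- make_abundance(m, meta, des)
  tot <- normalize_percent(ab, "total")
  expect_true(all(abs(colSums(as.matrix(tot[, des$sample_id])) - 100) < 1e-9))
  expect_equal(unname(unlist(tot[1, des$sample_id])), rep(25, nrow(des)))
  cls <- normalize_percent(ab, "class")
  for (cl in c("PC", "PE")) {
    s <- colSums(as.matrix(cls[cls$class == cl, des$sample_id]))
    expect_true(all(abs(s - 100) < 1e-9))
  }
  # single species: 100% everywhere
  one <- make_abundance(m[1, , drop = FALSE], meta[1, ], des)
  expect_true(all(as.matrix(normalize_percent(one)[, des$sample_id]) == 100))
  # zero basis total names the sample
  m0 <- m; m0[, 1] <- 0
  expect_error(normalize_percent(make_abundance(m0, meta, des)),
               des$sample_id[1])
})

test_that("variance filter removes constants and respects the threshold", {
  des <- small_design()
  set.seed(8)
  meta <- make_species_meta(3)
  m <- rbind(rep(5, nrow(des)),               # constant
             5 + rnorm(nrow(des), sd = 2),    # variable
             5 + rnorm(nrow(des), sd = 2))
  ab <- make_abundance(m, meta, des)
  f <- variance_filter(ab, metric = "variance", threshold = 0.01)
  expect_false("PC_01" %in% f$table$species)
  expect_identical(nrow(f$table), 2L)
  expect_identical(nrow(f$report), 3L)
  all_kept <- variance_filter(ab, threshold = 0)
  expect_identical(nrow(all_kept$table), 3L)
})

test_that("shipped CV threshold keeps 216 of 306 reference species", {
  ref <- synthetic_reference_abundance()
  expect_identical(nrow(ref), 306L)
  f <- variance_filter(ref)   # defaults: cv, 0.10
  expect_identical(nrow(f$table), 216L)
  # the retained species are exactly the constructed variable ones
  expect_identical(sum(f$report$kept), 216L)
  expect_true(all(f$report$kept == !attr(ref, "stable")))
})

test_that("PCA scores agree with a brute-force eigendecomposition", {
  des <- study_design(times = 12, doses = c(0, 1, 2), replicates = 2)
  set.seed(19)
  meta <- make_species_meta(10)
  m <- matrix(rnorm(10 * 6), 10, 6)
  ab <- make_abundance(m, meta, des)
  pc <- pca_samples(ab, n_components = 3, scale. = FALSE)
  # oracle: eigendecomposition of the sample covariance of centred data
  x <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  sc <- x %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    i <- which.max(abs(ev$vectors[, j]))
    if (ev$vectors[i, j] < 0) sc[, j] <- -sc[, j]
  }
  expect_lt(max(abs(as.matrix(pc$scores[, 2:4]) - sc)), 1e-8)
  expect_equal(pc$explained, ev$values[1:3] / sum(ev$values),
               tolerance = 1e-10)
})

test_that("PCA invariants: duplicates, rank deficiency, permutation", {
  des <- study_design(times = 12, doses = c(0, 1, 2), replicates = 2)
  set.seed(20)
  meta <- make_species_meta(8)
  base <- matrix(rnorm(8 * 3), 8, 3)
  m <- base[, c(1, 1, 2, 2, 3, 3)]  # duplicated samples
  ab <- make_abundance(m + 0, meta, des)
  pc <- suppressWarnings(pca_samples(ab, scale. = FALSE))
  sc <- as.matrix(pc$scores[, -1])
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-10)
  expect_equal(sc[3, ], sc[4, ], tolerance = 1e-10)
  # data confined to a plane: third component explains ~0
  plane <- outer(rnorm(8), rnorm(6)) + outer(rnorm(8), rnorm(6))
  pcp <- suppressWarnings(pca_samples(make_abundance(plane, meta, des),
                                      scale. = FALSE))
  if (length(pcp$explained) >= 3) expect_lt(pcp$explained[3], 1e-10)
  # explained fractions invariant to sample permutation
  perm <- sample(ncol(m))
  des2 <- des; des2$sample_id <- des$sample_id[perm]
  ab2 <- make_abundance(m[, perm], make_species_meta(8), des)
  pc2 <- suppressWarnings(pca_samples(ab2, scale. = FALSE))
  expect_equal(pc2$explained, pc$explained, tolerance = 1e-10)
  expect_error(pca_samples(make_abundance(m[, 1:3], meta, des[1:3, ])),
               "n_components")
})

test_that("fatty-acyl aggregation sums percent into bins that total 100", {
  des <- small_design()
  meta <- tibble::tibble(species = c("A", "B", "C"), class = "PC",
                         carbons = c(32L, 32L, 36L),
                         double_bonds = c(0L, 4L, 4L))
  m <- matrix(rep(c(1, 1, 2), nrow(des)), 3, nrow(des))
  pct <- normalize_percent(make_abundance(m, meta, des))
  for (by in c("double_bonds", "carbons")) {
    agg <- aggregate_fatty_acyl(pct, by, des)
    tot <- tapply(agg$per_sample$percent, agg$per_sample$sample_id, sum)
    expect_true(all(abs(tot - 100) < 1e-9))
  }
  agg <- aggregate_fatty_acyl(pct, "double_bonds", des)
  expect_equal(agg$summary$mean_percent[agg$summary$key == 0],
               rep(25, 6), tolerance = 1e-12)
  # two equal-abundance species, d = 0 and d = 4 -> 50/50 bins
  pct2 <- normalize_percent(make_abundance(m[1:2, ], meta[1:2, ], des))
  agg2 <- aggregate_fatty_acyl(pct2, "double_bonds", des)
  expect_true(all(abs(agg2$per_sample$percent - 50) < 1e-9))
})

test_that("two-way ANOVA handles degenerate and extreme inputs", {
  des <- study_design()
  meta <- make_species_meta(2)
  m <- rbind(rep(7, 24), rep(7, 24))
  # constant species: no significance, p = 1
  st <- anova_dunnett(make_abundance(m, meta, des), des, seed = 3)
  expect_true(all(st$p_adj == 1))
  expect_true(all(st$stars == ""))
  # one dose shifted by 10 SDs: adjusted p < 0.001
  set.seed(33)
  v <- rnorm(24, 100, 1)
  v[des$dose_uM == 25 & des$time_h == 24] <- v[des$dose_uM == 25 &
                                                 des$time_h == 24] + 10
  st2 <- anova_dunnett(make_abundance(rbind(v), make_species_meta(1), des),
                       des, seed = 3)
  hit <- st2[st2$dose_uM == 25 & st2$time_h == 24, ]
  expect_lt(hit$p_adj, 0.001)
  expect_identical(hit$stars, "***")
  expect_equal(st2$df[1], 18)
})

test_that("adjusted p >= raw p and both lie in [0, 1]", {
  des <- study_design()
  set.seed(41)
  n <- 40
  m <- matrix(rnorm(n * 24, 50, 5), n, 24)
  st <- anova_dunnett(make_abundance(m, make_species_meta(n), des), des,
                      seed = 5)
  expect_true(all(st$p >= 0 & st$p <= 1))
  expect_true(all(st$p_adj >= 0 & st$p_adj <= 1))
  expect_true(all(st$p_adj >= st$p))
})

test_that("power for |log2FC| >= 1 species exceeds 80% at n=4, CV 0.2", {
  res <- default_pipeline_run()
  st <- res$stats
  eff <- res$lipidome$effects
  fc <- eff$log2fc[match(paste(st$species, st$time_h, st$dose_uM),
                         paste(eff$species, eff$time_h, eff$dose_uM))]
  sel <- !is.na(fc) & abs(fc) >= 1
  expect_gt(mean(st$p_adj[sel] < 0.05), 0.8)
})
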