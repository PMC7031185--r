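#' Balanced study design: time x dose x replicate
#'
#' Default mirrors the cell-treatment design: 12 and 24 h exposures to 0,
#' 12.5 or 25 uM 6-OHDA, four biological replicates per cell (24 samples).
#'
#' @param times Exposure times in hours.
#' @param doses Doses in uM; the first is the control.
#' @param replicates Replicates per (time, dose) cell.
#' @return Tibble with `sample_id`, `time_h`, `dose_uM`, `replicate`.
#' @export
study_design <- function(times = c(12, 24), doses = c(0, 12.5, 25),
                         replicates = 4) {
  stopifnot(length(times) >= 1, length(doses) >= 2, replicates >= 1)
  g <- expand.grid(replicate = seq_len(replicates), dose_uM = doses,
                   time_h = times)
  tibble::tibble(
    sample_id = sprintf("T%g_D%g_R%d", g$time_h, g$dose_uM, g$replicate),
    time_h = g$time_h, dose_uM = g$dose_uM, replicate = g$replicate
  )
}

#' Write / read a study design CSV
#' @param design,path Design tibble and file path.
#' @return The design tibble (read) or `path` invisibly (write).
#' @export
write_study_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_study_design
#' @export
read_study_design <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "time_h", "dose_uM", "replicate")
  if (!all(need %in% names(raw)))
    stop("design CSV missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  tibble::as_tibble(raw[need])
}

#' Default species inventory (306 species across six classes)
#'
#' A deterministic species list matching the inventory arithmetic of the
#' profiled SH-SY5Y lipidome: 72 PC, 129 PE, 15 PG, 27 PI, 34 PS and 29 SM
#' species (306 total). All classes use even total carbons except PE, whose
#' count requires 30 odd-carbon species beyond the even 24--44 x 0--8 grid.
#'
#' @return Tibble in the [lipid_species()] layout.
#' @export
default_lipidome_inventory <- function() {
  grids <- list(
    PC = expand.grid(c = seq(28, 44, 2), d = 0:7),                 # 72
    PE = rbind(expand.grid(c = seq(24, 44, 2), d = 0:8),           # 99
               expand.grid(c = seq(33, 41, 2), d = 0:5)),          # +30
    PG = expand.grid(c = seq(32, 40, 2), d = 0:2),                 # 15
    PI = expand.grid(c = c(34, 36, 38), d = 0:8),                  # 27
    PS = expand.grid(c = seq(34, 42, 2), d = 0:6),                 # 35 - 1
    SM = expand.grid(c = seq(30, 42, 2), d = 0:3)                  # 28 + 1
  )
  grids$PS <- grids$PS[!(grids$PS$c == 34 & grids$PS$d == 6), ]
  grids$SM <- rbind(grids$SM, data.frame(c = 44, d = 2))
  dplyr::bind_rows(lapply(names(grids), function(cl) {
    g <- grids[[cl]]
    dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i)
      lipid_species(cl, g$c[i], g$d[i])))
  }))
}

#' Default treatment effect template
#'
#' Encodes the reported direction of change: species with zero double bonds
#' or 32 total carbons decrease under treatment; species with 1 or 4 double
#' bonds or 36/38 carbons increase. Effects are log2 fold-changes versus the
#' dose-0 control at the same time, scaled linearly by dose relative to
#' `dose_ref` and attenuated at the earlier time point.
#'
#' @param max_log2fc Absolute log2 fold-change at the reference dose and
#'   24 h (default 1, i.e. a two-fold change for the strongest condition).
#' @param dose_ref Dose (uM) at which `max_log2fc` applies, default 25.
#' @param time_scale Named multipliers per time point, default
#'   `c("12" = 0.6, "24" = 1)`.
#' @return A list of class `effect_template`.
#' @export
default_effect_template <- function(max_log2fc = 1, dose_ref = 25,
                                    time_scale = c("12" = 0.6, "24" = 1)) {
  structure(list(
    down = list(double_bonds = 0, carbons = 32),
    up = list(double_bonds = c(1, 4), carbons = c(36, 38)),
    max_log2fc = max_log2fc, dose_ref = dose_ref, time_scale = time_scale
  ), class = "effect_template")
}

#' All-zero effect template (null lipidome)
#' @return An `effect_template` assigning log2FC 0 to every species.
#' @export
null_effect_template <- function() {
  structure(list(down = list(double_bonds = numeric(0), carbons = numeric(0)),
                 up = list(double_bonds = numeric(0), carbons = numeric(0)),
                 max_log2fc = 0, dose_ref = 25,
                 time_scale = c("12" = 0.6, "24" = 1)),
            class = "effect_template")
}

## Base effect direction per species: -1 (down), +1 (up) or 0. The "down"
## rule takes precedence so a species cannot be both.
effect_direction <- function(inventory, template) {
  down <- inventory$double_bonds %in% template$down$double_bonds |
    inventory$carbons %in% template$down$carbons
  up <- inventory$double_bonds %in% template$up$double_bonds |
    inventory$carbons %in% template$up$carbons
  ifelse(down, -1, ifelse(up, 1, 0))
}

#' Default class retention-time map for the simulated HILIC gradient
#'
#' Classes elute as disjoint windows over a 0--600 s gradient in the order
#' PG, PE, PI, PS, PC, SM; the HILIC method separates by headgroup class but
#' exact times are instrument-specific, so these centres are the package's
#' simulation convention.
#'
#' @return Tibble with `class`, `rt_center`, `rt_min`, `rt_max` (seconds).
#' @export
class_rt_map <- function() {
  tibble::tibble(
    class = c("PG", "PE", "PI", "PS", "PC", "SM"),
    rt_center = c(50, 150, 250, 350, 450, 550),
    rt_min = c(50, 150, 250, 350, 450, 550) - 45,
    rt_max = c(50, 150, 250, 350, 450, 550) + 45
  )
}

#' Simulate a ground-truth lipidome
#'
#' Draws per-species baseline abundances (log-normal) and assigns each
#' species a per-condition log2 fold-change from the effect template, plus
#' the noise parameters used by [simulate_features()].
#'
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param inventory Species tibble, default [default_lipidome_inventory()].
#' @param template [default_effect_template()] or [null_effect_template()].
#' @param design Study design whose (time, dose) cells define conditions.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (arbitrary intensity units).
#' @param ppm_sd Mass-error scale: sd of the Gaussian per-species
#'   calibration error in ppm (default 5/3, i.e. a 5 ppm accuracy
#'   specification treated as a 3-sigma bound); shared by a species'
#'   isotopologues as for peaks read off one calibrated spectrum.
#' @param ppm_sd_indep Additional independent per-peak centroiding error in
#'   ppm (default 0), applied to every row separately; nonzero values
#'   perturb the isotopologue spacing.
#' @param rt_sd Retention-time jitter sd in seconds (default 5).
#' @param cv Intensity coefficient of variation across replicates (default
#'   0.2, typical LC-MS biological + technical noise).
#' @param noise_density Noise-peak rows as a fraction of signal rows
#'   (default 0.2).
#' @param dropout Probability that a low-intensity measurement is missing
#'   (default 0).
#' @param isotope_p Per-carbon 13C probability (default 0.0107).
#' @return A list of class `lipidome`: `$species` (inventory + `baseline` +
#'   `direction`), `$effects` (species x condition log2FC, long), `$rt`
#'   (class map), `$params`.
#' @export
simulate_lipidome <- function(seed,
                              inventory = default_lipidome_inventory(),
                              template = default_effect_template(),
                              design = study_design(),
                              baseline_meanlog = log(1e6),
                              baseline_sdlog = 1,
                              ppm_sd = 5 / 3, ppm_sd_indep = 0,
                              rt_sd = 5, cv = 0.2,
                              noise_density = 0.2, dropout = 0,
                              isotope_p = C13_ABUNDANCE) {
  if (nrow(inventory) == 0) stop("empty species inventory", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::local_seed(as.integer(seed))
  species <- inventory
  species$baseline <- stats::rlnorm(nrow(species), baseline_meanlog,
                                    baseline_sdlog)
  species$direction <- effect_direction(species, template)

  conds <- unique(design[, c("time_h", "dose_uM")])
  effects <- tidyr::expand_grid(species = species$species,
                                conds)
  idx <- match(effects$species, species$species)
  dose0 <- min(design$dose_uM)
  scale <- (effects$dose_uM - dose0) / (template$dose_ref - dose0)
  tfac <- template$time_scale[as.character(effects$time_h)]
  tfac[is.na(tfac)] <- 1
  effects$log2fc <- species$direction[idx] * template$max_log2fc *
    scale * as.numeric(tfac)

  structure(list(
    species = species, effects = effects, rt = class_rt_map(),
    params = list(ppm_sd = ppm_sd, ppm_sd_indep = ppm_sd_indep,
                  rt_sd = rt_sd, cv = cv,
                  noise_density = noise_density, dropout = dropout,
                  isotope_p = isotope_p, mz_range = c(450, 950),
                  rt_range = c(0, 600), seed = as.integer(seed))
  ), class = "lipidome")
}

#' Expected noise-free percent abundances of a lipidome
#'
#' The expected intensity of a species under a condition is
#' `baseline * 2^log2fc`; this converts those to percent-of-total per
#' condition — the ground truth against which percent-scale effect
#' estimates are compared (it includes the compositional shift that raw
#' fold-changes induce in all other species).
#'
#' @param lipidome A `lipidome` object.
#' @return Tibble `species`, `time_h`, `dose_uM`, `expected_percent`.
#' @export
lipidome_expected_percent <- function(lipidome) {
  ef <- lipidome$effects
  ef$intensity <- lipidome$species$baseline[
    match(ef$species, lipidome$species$species)] * 2^ef$log2fc
  ef <- dplyr::group_by(ef, .data$time_h, .data$dose_uM)
  ef <- dplyr::mutate(ef,
                      expected_percent = 100 * .data$intensity / sum(.data$intensity))
  dplyr::ungroup(ef)[, c("species", "time_h", "dose_uM", "expected_percent")]
}

#' Simulate an LC-MS feature table from a lipidome
#'
#' Produces one monoisotopic row per (species, adduct) in the active
#' ionization mode, M+1 and M+2 isotopologue satellites with binomial
#' intensity ratios, and uniform noise rows. The mass-calibration error
#' (ppm) is drawn once per species and shared by its isotopologues, as for
#' peaks read off a single calibrated spectrum; satellites co-elute with
#' their parent. Intensities are baseline x 2^log2FC x log-normal noise per
#' sample. Deterministic given `seed`.
#'
#' @param lipidome A `lipidome` from [simulate_lipidome()].
#' @param design Study design; its `sample_id`s become intensity columns.
#' @param seed Integer seed.
#' @param mode Ionization mode for adduct selection (default negative).
#' @return Tibble of class `feature_table`: `mz`, `rt`, one intensity
#'   column per sample, `provenance` (monoisotopic / isotope+1 / isotope+2 /
#'   noise) and ground-truth columns `truth_species`, `truth_adduct`
#'   (present because the table is synthetic).
#' @export
simulate_features <- function(lipidome, design, seed,
                              mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lipidome, "lipidome"))
  if (!all(c("sample_id", "time_h", "dose_uM") %in% names(design)))
    stop("design/lipidome mismatch: design lacks sample_id/time_h/dose_uM",
         call. = FALSE)
  miss <- setdiff(unique(paste(design$time_h, design$dose_uM)),
                  unique(paste(lipidome$effects$time_h,
                               lipidome$effects$dose_uM)))
  if (length(miss) > 0)
    stop("design/lipidome mismatch: conditions absent from lipidome: ",
         paste(miss, collapse = "; "), call. = FALSE)
  p <- lipidome$params
  withr::local_seed(as.integer(seed))

  sp <- lipidome$species
  rtmap <- lipidome$rt
  ns <- nrow(design)
  ## per-species observed rt and shared ppm calibration error
  rt_obs <- rtmap$rt_center[match(sp$class, rtmap$class)] +
    stats::rnorm(nrow(sp), 0, p$rt_sd)
  ppm_err <- stats::rnorm(nrow(sp), 0, p$ppm_sd)

  ## per-sample expected intensity: baseline x 2^log2fc(condition) x noise
  key <- paste(lipidome$effects$species, lipidome$effects$time_h,
               lipidome$effects$dose_uM)
  fc <- lipidome$effects$log2fc[
    match(paste(rep(sp$species, each = ns),
                rep(design$time_h, nrow(sp)),
                rep(design$dose_uM, nrow(sp))), key)]
  fc[is.na(fc)] <- 0
  sdlog <- sqrt(log(1 + p$cv^2))
  noise <- stats::rlnorm(nrow(sp) * ns, -sdlog^2 / 2, sdlog)
  inten <- matrix(rep(sp$baseline, each = ns) * 2^fc * noise,
                  nrow = nrow(sp), ncol = ns, byrow = TRUE)
  if (p$dropout > 0) {
    thr <- stats::quantile(inten, 0.25)
    drop <- matrix(stats::runif(length(inten)) < p$dropout, nrow(sp)) &
      inten < thr
    inten[drop] <- 0
  }

  rows <- list()
  for (i in seq_len(nrow(sp))) {
    ads <- allowed_adducts(sp$class[i], mode)
    nC <- parse_formula(sp$formula[i])[["C"]]
    r1 <- stats::dbinom(1, nC, p$isotope_p) / stats::dbinom(0, nC, p$isotope_p)
    r2 <- stats::dbinom(2, nC, p$isotope_p) / stats::dbinom(0, nC, p$isotope_p)
    for (ad in ads) {
      mz0 <- adduct_mz(sp$mass[i], ad) * (1 + ppm_err[i] * 1e-6)
      if (p$ppm_sd_indep > 0)
        mz0 <- mz0 * (1 + stats::rnorm(1, 0, p$ppm_sd_indep) * 1e-6)
      if (mz0 < p$mz_range[1] || mz0 > p$mz_range[2]) next
      base <- inten[i, ]
      rows[[length(rows) + 1]] <- c(list(mz = mz0, rt = rt_obs[i]),
        as.list(base), list(provenance = "monoisotopic",
                            truth_species = sp$species[i], truth_adduct = ad))
      for (k in 1:2) {
        mzk <- mz0 + k * C13_SPACING
        if (p$ppm_sd_indep > 0)
          mzk <- mzk * (1 + stats::rnorm(1, 0, p$ppm_sd_indep) * 1e-6)
        if (mzk > p$mz_range[2]) next
        rows[[length(rows) + 1]] <- c(list(mz = mzk, rt = rt_obs[i]),
          as.list(base * if (k == 1) r1 else r2),
          list(provenance = paste0("isotope+", k),
               truth_species = sp$species[i], truth_adduct = ad))
      }
    }
  }
  ft <- dplyr::bind_rows(lapply(rows, function(r) {
    names(r) <- c("mz", "rt", design$sample_id, "provenance",
                  "truth_species", "truth_adduct")
    tibble::as_tibble(r)
  }))

  n_noise <- floor(p$noise_density * sum(ft$provenance == "monoisotopic"))
  if (n_noise > 0) {
    sig <- as.matrix(ft[ft$provenance == "monoisotopic", design$sample_id])
    lo <- min(sig[sig > 0])
    hi <- stats::quantile(sig[sig > 0], 0.1)
    nz <- tibble::tibble(
      mz = stats::runif(n_noise, p$mz_range[1], p$mz_range[2]),
      rt = stats::runif(n_noise, p$rt_range[1], p$rt_range[2])
    )
    nint <- matrix(stats::runif(n_noise * ns, lo, hi), n_noise, ns)
    colnames(nint) <- design$sample_id
    nz <- dplyr::bind_cols(nz, tibble::as_tibble(nint))
    nz$provenance <- "noise"
    nz$truth_species <- NA_character_
    nz$truth_adduct <- NA_character_
    ft <- dplyr::bind_rows(ft, nz)
  }
  ft <- ft[order(ft$mz), , drop = FALSE]
  structure(ft, sample_ids = design$sample_id,
            class = c("feature_table", class(tibble::tibble())))
}

#' Write / read a feature table CSV
#'
#' m/z is written with 6 decimals, retention time with 2, intensities in
#' scientific notation with 6 significant decimals; optional `provenance`
#' and truth columns round-trip unchanged. Reading validates the table and
#' rejects malformed or negative-intensity rows, naming the offending line.
#'
#' @param table Feature table tibble.
#' @param path CSV path.
#' @param sample_ids Optional explicit sample columns (read); by default all
#'   columns except `mz`, `rt`, `provenance`, `truth_species`,
#'   `truth_adduct` are intensities.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_feature_table <- function(table, path) {
  out <- as.data.frame(table)
  meta <- intersect(c("provenance", "truth_species", "truth_adduct"),
                    names(out))
  samples <- setdiff(names(out), c("mz", "rt", meta))
  out$mz <- sprintf("%.6f", out$mz)
  out$rt <- sprintf("%.2f", out$rt)
  for (s in samples) out[[s]] <- sprintf("%.6e", as.numeric(out[[s]]))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, sample_ids = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  if (!all(c("mz", "rt") %in% names(raw)))
    stop("feature CSV must have mz and rt columns", call. = FALSE)
  meta <- intersect(c("provenance", "truth_species", "truth_adduct"),
                    names(raw))
  samples <- if (is.null(sample_ids))
    setdiff(names(raw), c("mz", "rt", meta)) else sample_ids
  out <- tibble::as_tibble(raw)
  for (col in c("mz", "rt", samples)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !(out[[col]] %in% c("NA", "")))
    if (length(bad) > 0)
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, bad[1] + 1L, path), call. = FALSE)
    out[[col]] <- v
  }
  for (s in samples) {
    bad <- which(out[[s]] < 0)
    if (length(bad) > 0)
      stop(sprintf("negative intensity in column '%s' at line %d of %s",
                   s, bad[1] + 1L, path), call. = FALSE)
  }
  structure(out, sample_ids = samples,
            class = c("feature_table", class(tibble::tibble())))
}
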