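#' Percent normalization of an abundance table
#'
#' Converts intensities to percentages of a per-sample basis: the total
#' identified lipid signal (`basis = "total"`, the default, used for
#' whole-lipidome summaries) or the per-class signal (`basis = "class"`,
#' used for per-class species panels).
#'
#' @param table An `abundance_table` (or percent table to re-normalize).
#' @param basis `"total"` or `"class"`.
#' @return A tibble of class `percent_table` with the same layout; per
#'   sample, values over each basis group sum to 100.
#' @export
normalize_percent <- function(table, basis = c("total", "class")) {
  basis <- match.arg(basis)
  samples <- attr(table, "sample_ids")
  if (is.null(samples))
    samples <- setdiff(names(table),
                       c("species", "class", "carbons", "double_bonds"))
  out <- table
  groups <- if (basis == "total") rep("all", nrow(table)) else table$class
  for (g in unique(groups)) {
    rows <- which(groups == g)
    for (s in samples) {
      tot <- sum(out[[s]][rows])
      if (!is.finite(tot) || tot <= 0)
        stop(sprintf("zero %s basis total in sample '%s'%s", basis, s,
                     if (basis == "class") paste0(" (class ", g, ")") else ""),
             call. = FALSE)
      out[[s]][rows] <- 100 * out[[s]][rows] / tot
    }
  }
  structure(out, design = attr(table, "design"), sample_ids = samples,
            basis = basis,
            class = unique(c("percent_table", class(tibble::tibble()))))
}

#' Variability filter on a species table
#'
#' Retains species whose variability metric across all samples exceeds the
#' threshold; near-constant species carry no treatment information and are
#' removed before multivariate analysis. The shipped default (CV on
#' percent abundance, threshold 0.10) is calibrated on the packaged
#' synthetic reference lipidome, where it retains 216 of 306 species.
#'
#' @param table An `abundance_table` or `percent_table`.
#' @param metric `"cv"` (sd/mean, default) or `"variance"`.
#' @param threshold Non-negative; species with metric strictly greater are
#'   kept (so threshold 0 keeps everything with any variability, and a
#'   constant species is removed at any threshold >= 0... it has metric 0,
#'   kept only if threshold < 0 is impossible — i.e. removed whenever
#'   threshold > 0, kept at threshold 0 via `>=` on exact zero). See
#'   Details.
#' @details At `threshold = 0` every species is kept (the filter is
#'   inactive); for any `threshold > 0` a constant species (metric 0) is
#'   removed.
#' @return List with `table` (filtered, same class/attributes) and
#'   `report` (tibble `species`, `metric`, `value`, `kept`).
#' @export
variance_filter <- function(table, metric = c("cv", "variance"),
                            threshold = 0.10) {
  metric <- match.arg(metric)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  samples <- attr(table, "sample_ids")
  if (is.null(samples))
    samples <- setdiff(names(table),
                       c("species", "class", "carbons", "double_bonds"))
  m <- as.matrix(table[, samples, drop = FALSE])
  v <- apply(m, 1, stats::var)
  value <- if (metric == "cv") sqrt(v) / rowMeans(m) else v
  kept <- if (threshold == 0) rep(TRUE, length(value)) else value > threshold
  out <- table[kept, , drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(table)[c("design", "sample_ids", "basis")])
  list(
    table = structure(out, class = class(table)),
    report = tibble::tibble(species = table$species, metric = metric,
                            value = value, kept = kept)
  )
}

#' Principal component analysis of a species x sample table
#'
#' Samples are the observations; species are the variables (centred and,
#' by default, unit-variance scaled). Components are sign-fixed so that
#' each component's largest-magnitude loading is positive, making score
#' orientation deterministic.
#'
#' @param table A `percent_table` (or abundance table).
#' @param n_components Number of components to return, default 3.
#' @param center,scale. Passed to [stats::prcomp()].
#' @return List of class `pca_result`: `scores` (samples x components,
#'   with `sample_id`), `loadings` (species x components), `explained`
#'   (fraction of variance per component).
#' @export
pca_samples <- function(table, n_components = 3, center = TRUE,
                        scale. = TRUE) {
  samples <- attr(table, "sample_ids")
  if (is.null(samples))
    samples <- setdiff(names(table),
                       c("species", "class", "carbons", "double_bonds"))
  if (length(samples) < n_components + 1)
    stop("need at least n_components + 1 samples", call. = FALSE)
  x <- t(as.matrix(table[, samples, drop = FALSE]))
  colnames(x) <- table$species
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0),
              " zero-variance species before scaling")
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = center, scale. = scale.)
  total_var <- sum(pc$sdev^2)
  rank <- sum(pc$sdev^2 > pc$sdev[1]^2 * 1e-12)
  nc <- min(n_components, rank)
  if (nc < n_components)
    warning("rank-deficient input: returning ", nc, " components")
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  loadings <- pc$rotation[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = tibble::as_tibble(scores) |>
      dplyr::mutate(sample_id = samples, .before = 1),
    loadings = tibble::as_tibble(loadings) |>
      dplyr::mutate(species = colnames(x), .before = 1),
    explained = pc$sdev[seq_len(nc)]^2 / total_var
  ), class = "pca_result")
}

#' Fatty-acyl aggregation of percent abundances
#'
#' Sums per-sample percentages over species sharing a double-bond count or
#' a total carbon number, then summarises each (time, dose) cell as
#' mean +/- SD across replicates — the per-panel layout of double-bond /
#' chain-length distribution figures.
#'
#' @param table A `percent_table` with `carbons` and `double_bonds`
#'   metadata.
#' @param by `"double_bonds"` or `"carbons"`.
#' @param design Study design; defaults to the design attached to `table`.
#' @return List of class `acyl_aggregate`: `per_sample` (key x sample
#'   percent sums, long) and `summary` (key, time_h, dose_uM,
#'   mean_percent, sd_percent).
#' @export
aggregate_fatty_acyl <- function(table, by = c("double_bonds", "carbons"),
                                 design = attr(table, "design")) {
  by <- match.arg(by)
  if (is.null(design)) stop("no study design available", call. = FALSE)
  samples <- attr(table, "sample_ids")
  if (is.null(samples)) samples <- design$sample_id
  long <- tidyr::pivot_longer(table[, c(by, samples)],
                              dplyr::all_of(samples),
                              names_to = "sample_id", values_to = "percent")
  names(long)[1] <- "key"
  per_sample <- dplyr::summarise(
    dplyr::group_by(long, .data$key, .data$sample_id),
    percent = sum(.data$percent), .groups = "drop")
  per_sample <- dplyr::left_join(per_sample, design, by = "sample_id")
  summary <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$key, .data$time_h, .data$dose_uM),
    mean_percent = mean(.data$percent),
    sd_percent = stats::sd(.data$percent), .groups = "drop")
  structure(list(per_sample = per_sample, summary = summary, by = by),
            class = "acyl_aggregate")
}

#' Per-species two-way ANOVA with Dunnett many-to-one comparisons
#'
#' For each species, fits a fixed-effects two-way ANOVA (dose, time and
#' their interaction, both categorical) on the per-sample values, then
#' compares each non-control dose against the control within each time
#' point using the pooled error. Within a time point the comparisons form
#' one Dunnett family (adjusted by the equicorrelated multivariate t,
#' matching per-panel significance marks); families are defined per time
#' point. Degenerate species (zero residual variance) are reported with
#' p = 1 when the contrast is also zero and p = 0 under perfect
#' separation; species with empty design cells are skipped and listed in
#' the report.
#'
#' @param table An `abundance_table` or `percent_table` (species rows,
#'   sample columns).
#' @param design Study design; defaults to the attached design.
#' @param seed Seed for the Monte-Carlo Dunnett adjustment.
#' @param nsim Monte-Carlo draws for the adjustment.
#' @return Tibble of class `stat_result`: per (species, time_h, dose_uM)
#'   contrast `estimate` (difference of means vs control), `t`, `df`,
#'   `p` (raw two-sided), `p_adj` (Dunnett), `stars`, and per-species
#'   ANOVA columns `F_dose`, `p_dose`, `F_time`, `p_time`,
#'   `F_interaction`, `p_interaction`. Skipped species are recorded in
#'   `attr(, "skipped")`.
#' @export
anova_dunnett <- function(table, design = attr(table, "design"),
                          seed = 1, nsim = 200000) {
  if (is.null(design)) stop("no study design available", call. = FALSE)
  samples <- design$sample_id
  if (!all(samples %in% names(table)))
    stop("table lacks sample columns named in the design", call. = FALSE)
  dose <- factor(design$dose_uM)
  time <- factor(design$time_h)
  dose0 <- levels(dose)[which.min(as.numeric(levels(dose)))]
  two_way <- nlevels(time) > 1
  cells <- table(dose, time)
  if (any(cells < 2))
    stop("need >= 2 replicates per (dose, time) cell", call. = FALSE)

  m <- as.matrix(table[, samples, drop = FALSE])
  k <- nlevels(dose) - 1
  ## shared projection machinery: the design is identical across species
  X <- if (two_way) stats::model.matrix(~ dose * time)
       else stats::model.matrix(~ dose)
  qrX <- qr(X)
  df_err <- nrow(X) - qrX$rank
  maxt <- dunnett_maxt_sample(k, df_err, rho = 0.5, nsim = nsim, seed = seed)

  res <- vector("list", nrow(table))
  skipped <- character(0)
  for (i in seq_len(nrow(table))) {
    v <- m[i, ]
    if (any(!is.finite(v))) { skipped <- c(skipped, table$species[i]); next }
    fit <- if (two_way) stats::aov(v ~ dose * time) else stats::aov(v ~ dose)
    ## constant species trigger "essentially perfect fit" noise; that path
    ## is handled explicitly below via the zero-MSE branch
    an <- suppressWarnings(stats::anova(fit))
    mse <- an["Residuals", "Mean Sq"]
    eps <- max(mean(v)^2, 1) * 1e-20
    rows <- list()
    for (tl in levels(time)) {
      sel0 <- dose == dose0 & time == tl
      for (dl in setdiff(levels(dose), dose0)) {
        seld <- dose == dl & time == tl
        est <- mean(v[seld]) - mean(v[sel0])
        se <- sqrt(mse * (1 / sum(seld) + 1 / sum(sel0)))
        if (mse <= eps) {
          tstat <- if (abs(est) < sqrt(eps)) 0 else Inf * sign(est)
          p <- if (abs(est) < sqrt(eps)) 1 else 0
          padj <- p
        } else {
          tstat <- est / se
          p <- 2 * stats::pt(-abs(tstat), df_err)
          padj <- dunnett_adjust(tstat, k, df_err, maxt_sample = maxt)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = table$species[i], time_h = as.numeric(tl),
          dose_uM = as.numeric(dl), estimate = est, t = tstat,
          df = df_err, p = p, p_adj = padj,
          stars = significance_stars(padj))
      }
    }
    out <- dplyr::bind_rows(rows)
    get_f <- function(term) {
      if (term %in% rownames(an)) an[term, "F value"] else NA_real_
    }
    get_p <- function(term) {
      if (term %in% rownames(an)) an[term, "Pr(>F)"] else NA_real_
    }
    out$F_dose <- get_f("dose"); out$p_dose <- get_p("dose")
    out$F_time <- get_f("time"); out$p_time <- get_p("time")
    out$F_interaction <- get_f("dose:time")
    out$p_interaction <- get_p("dose:time")
    res[[i]] <- out
  }
  structure(dplyr::bind_rows(res), skipped = skipped,
            class = c("stat_result", class(tibble::tibble())))
}
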