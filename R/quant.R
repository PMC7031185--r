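#' Fit an external calibration curve
#'
#' Ordinary least-squares line `response = slope * concentration +
#' intercept`; the slope is the response factor converting SRM signal to
#' analyte concentration. The intercept is estimated by default; set
#' `through_origin = TRUE` to force the line through zero.
#'
#' @param concentration,response Numeric vectors of standard
#'   concentrations and instrument responses (>= 2 distinct
#'   concentrations).
#' @param through_origin Force a zero intercept (default FALSE).
#' @return List of class `calibration_curve`: `slope` (response factor),
#'   `intercept`, `r_squared`, `model` (the `lm` fit).
#' @examples
#' fit_calibration(c(0, 1, 2), c(0, 2, 4))
#' @export
fit_calibration <- function(concentration, response,
                            through_origin = FALSE) {
  stopifnot(length(concentration) == length(response),
            length(concentration) >= 2)
  if (length(unique(concentration)) < 2)
    stop("need at least 2 distinct standard concentrations", call. = FALSE)
  fit <- if (through_origin) stats::lm(response ~ 0 + concentration)
         else stats::lm(response ~ concentration)
  co <- stats::coef(fit)
  slope <- unname(co[["concentration"]])
  intercept <- if (through_origin) 0 else unname(co[["(Intercept)"]])
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 model = fit),
            class = "calibration_curve")
}

#' Concentration from a calibrated response
#'
#' Inverts the calibration line: `(response - intercept) / slope`.
#' Negative results (responses below the intercept) are floored at zero
#' and flagged.
#'
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param response Numeric vector of measured responses.
#' @return Tibble with `response`, `concentration`, `below_range`
#'   (TRUE where the raw estimate was negative and floored).
#' @export
quantify_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("calibration slope must be > 0 for a valid assay", call. = FALSE)
  conc <- (response - curve$intercept) / curve$slope
  tibble::tibble(response = response,
                 concentration = pmax(conc, 0),
                 below_range = conc < 0)
}

#' Relative expression from takeoff and amplification values
#'
#' Rotor-Gene comparative quantitation: for each gene,
#' `expression = amplification ^ (mean calibrator takeoff - takeoff)`,
#' so a one-cycle earlier takeoff at amplification 2 doubles expression,
#' and calibrator samples average to expression 1.
#'
#' @param records Tibble with columns `sample_id`, `gene`, `takeoff`
#'   (cycles, > 0) and `amplification` (fold per cycle, in (1, 2]).
#' @param calibrator Character vector of `sample_id`s forming the
#'   calibrator group (e.g. the untreated controls).
#' @return `records` with an added `expression` column.
#' @export
relative_expression <- function(records, calibrator) {
  need <- c("sample_id", "gene", "takeoff", "amplification")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(records$takeoff <= 0))
    stop("takeoff values must be > 0", call. = FALSE)
  if (any(records$amplification <= 1 | records$amplification > 2))
    stop("amplification values must lie in (1, 2]", call. = FALSE)
  miss_cal <- setdiff(calibrator, records$sample_id)
  if (length(miss_cal) > 0)
    stop("calibrator samples missing from records: ",
         paste(miss_cal, collapse = ", "), call. = FALSE)
  out <- records
  out$expression <- NA_real_
  for (g in unique(records$gene)) {
    sel <- records$gene == g
    cal <- sel & records$sample_id %in% calibrator
    if (!any(cal))
      stop("no calibrator records for gene ", g, call. = FALSE)
    cal_takeoff <- mean(records$takeoff[cal])
    out$expression[sel] <-
      records$amplification[sel]^(cal_takeoff - records$takeoff[sel])
  }
  out
}

#' geNorm reference-gene stability and normalization factors
#'
#' For each gene j, the stability measure `M_j` is the mean, over the
#' other genes k, of the standard deviation across samples of
#' `log2(expression_j / expression_k)` — perfectly co-regulated reference
#' genes give M = 0. The per-sample normalization factor is the geometric
#' mean of the housekeeping expressions; target genes are divided by it.
#' With only two housekeeping genes the stepwise exclusion ranking is
#' skipped (two genes admit no ranking).
#'
#' @param expression Numeric matrix of housekeeping expressions, genes in
#'   rows (rownames = gene ids), samples in columns; all values > 0.
#' @return List of class `genorm_result`: `M` (named per-gene stability),
#'   `normalization_factor` (named per-sample geometric mean).
#' @export
genorm <- function(expression) {
  expression <- as.matrix(expression)
  if (nrow(expression) < 2 || ncol(expression) < 2)
    stop("need >= 2 housekeeping genes and >= 2 samples", call. = FALSE)
  if (any(!is.finite(expression)) || any(expression <= 0))
    stop("all expression values must be positive", call. = FALSE)
  lg <- log2(expression)
  ngene <- nrow(lg)
  M <- vapply(seq_len(ngene), function(j) {
    mean(vapply(setdiff(seq_len(ngene), j), function(k)
      stats::sd(lg[j, ] - lg[k, ]), numeric(1)))
  }, numeric(1))
  names(M) <- rownames(expression)
  nf <- exp(colMeans(log(expression)))
  structure(list(M = M, normalization_factor = nf),
            class = "genorm_result")
}

#' Normalize target expressions by geNorm factors
#' @param expression Named numeric vector or genes x samples matrix of
#'   target expressions (sample order matching the factors).
#' @param genorm_result A `genorm_result` from [genorm()].
#' @return Normalized expressions (same shape).
#' @export
normalize_by_genorm <- function(expression, genorm_result) {
  stopifnot(inherits(genorm_result, "genorm_result"))
  nf <- genorm_result$normalization_factor
  if (is.matrix(expression)) sweep(expression, 2, nf, "/")
  else expression / nf
}
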