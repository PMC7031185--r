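#' Carbon-13 de-isotoping of a centroided feature table
#'
#' Scans peaks in ascending m/z and flags a peak as a 13C isotopologue
#' satellite of a lighter parent when (i) a retained parent exists at
#' `mz - k * 1.003355` within `mz_tol` for k in 1, 2, (ii) the retention
#' times agree within `rt_tol`, and (iii) the mean satellite/parent
#' intensity ratio lies within `ratio_band` times the binomial expectation
#' for the parent's carbon count. The carbon count is estimated as
#' `round(carbon_slope * parent mz)` unless a database hint is supplied.
#' Chains (a satellite of a satellite) resolve to the lowest-m/z retained
#' parent. Satellite intensities are added to the parent (`merge = "add"`,
#' conserving total signal) or discarded (`merge = "drop"`).
#'
#' @param table A `feature_table` tibble (columns `mz`, `rt`, sample
#'   intensities; any `provenance`/truth columns are carried through).
#' @param mz_tol m/z tolerance in Th for the satellite spacing (default
#'   0.005, high-resolution data).
#' @param rt_tol Retention-time tolerance in seconds (default 10).
#' @param ratio_band Multiplicative bounds around the expected isotope
#'   ratio, default `c(0.5, 2)` (wide, because measured intensities are
#'   noisy).
#' @param carbon_slope Carbons per Th for the carbon-count estimate,
#'   default 0.055.
#' @param merge `"add"` (default) or `"drop"`.
#' @param isotope_p Per-carbon 13C probability, default 0.0107.
#' @param db Optional `lipid_db`; when supplied, the carbon count of the
#'   nearest database entry (within 0.01 Th) overrides the slope estimate.
#' @return A list of class `deisotope_result`: `$peaks` (retained rows,
#'   satellite intensity merged per `merge`), `$satellites` (removed rows
#'   with `parent_mz`, `parent_row`, `k`), `$carbon_estimate` (per retained
#'   peak).
#' @export
deisotope <- function(table, mz_tol = 0.005, rt_tol = 10,
                      ratio_band = c(0.5, 2), carbon_slope = 0.055,
                      merge = c("add", "drop"), isotope_p = C13_ABUNDANCE,
                      db = NULL) {
  merge <- match.arg(merge)
  stopifnot(mz_tol > 0, rt_tol > 0, length(ratio_band) == 2,
            ratio_band[1] > 0, ratio_band[2] >= ratio_band[1])
  meta <- intersect(c("provenance", "truth_species", "truth_adduct"),
                    names(table))
  samples <- attr(table, "sample_ids")
  if (is.null(samples)) samples <- setdiff(names(table), c("mz", "rt", meta))

  ord <- order(table$mz)
  tb <- table[ord, , drop = FALSE]
  n <- nrow(tb)
  inten <- as.matrix(tb[, samples, drop = FALSE])
  mean_int <- rowMeans(inten)

  carbons <- round(carbon_slope * tb$mz)
  if (!is.null(db)) {
    for (i in seq_len(n)) {
      j <- which.min(abs(db$mz - tb$mz[i]))
      if (length(j) == 1 && abs(db$mz[j] - tb$mz[i]) <= 0.01)
        carbons[i] <- parse_formula(db$formula[j])[["C"]]
    }
  }

  is_sat <- logical(n)
  parent_of <- rep(NA_integer_, n)
  sat_k <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NULL
    for (k in 1:2) {
      target <- tb$mz[i] - k * C13_SPACING
      cand <- which(!is_sat[seq_len(i - 1)] &
                      abs(tb$mz[seq_len(i - 1)] - target) <= mz_tol &
                      abs(tb$rt[seq_len(i - 1)] - tb$rt[i]) <= rt_tol)
      if (length(cand) == 0) next
      for (p in cand) {
        nC <- max(carbons[p], 1)
        expected <- stats::dbinom(k, nC, isotope_p) /
          stats::dbinom(0, nC, isotope_p)
        if (mean_int[p] <= 0) next
        ratio <- mean_int[i] / mean_int[p]
        if (ratio >= ratio_band[1] * expected &&
            ratio <= ratio_band[2] * expected) {
          derr <- abs(tb$mz[p] - target)
          if (is.null(best) || derr < best$err ||
              (derr == best$err && tb$mz[p] < tb$mz[best$p]))
            best <- list(p = p, k = k, err = derr)
        }
      }
    }
    if (!is.null(best)) {
      is_sat[i] <- TRUE
      parent_of[i] <- best$p   # candidates are retained peaks, so this is
      sat_k[i] <- best$k       # already the lowest-mz (chain-root) parent
      if (merge == "add") inten[best$p, ] <- inten[best$p, ] + inten[i, ]
    }
  }

  peaks <- tb[!is_sat, , drop = FALSE]
  peaks[, samples] <- tibble::as_tibble(inten[!is_sat, , drop = FALSE])
  sats <- tb[is_sat, , drop = FALSE]
  sats$parent_mz <- tb$mz[parent_of[is_sat]]
  sats$parent_row <- match(parent_of[is_sat], which(!is_sat))
  sats$k <- sat_k[is_sat]
  structure(list(peaks = structure(peaks, sample_ids = samples,
                                   class = class(tb)),
                 satellites = sats,
                 carbon_estimate = carbons[!is_sat]),
            class = "deisotope_result")
}
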