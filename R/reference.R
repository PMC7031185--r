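#' Synthetic reference lipidome (stand-in for the study's species table)
#'
#' The study's own species/abundance supplement is a spreadsheet that is
#' not programmatically deposited, so the package ships a synthetic
#' stand-in generated in code: a percent-abundance table over the full
#' 306-species inventory (72 PC, 129 PE, 15 PG, 27 PI, 34 PS, 29 SM; see
#' [default_lipidome_inventory()]) and the 24-sample design. It is
#' constructed so that 90 species are near-constant across samples
#' (coefficient of variation ~0.02) and 216 are variable (CV ~0.3): the
#' shipped variance-filter default (CV > 0.10) therefore retains exactly
#' the 216 variable species, reproducing the study's 306 -> 216 filtering
#' outcome by construction. The dataset is deterministic (internally
#' seeded) — it plays the role of a fixed packaged fixture, not of a
#' simulation.
#'
#' @param n_stable Number of near-constant species (default 90).
#' @param cv_stable,cv_variable Log-normal noise CVs of the two groups.
#' @return A `percent_table` tibble (species metadata + 24 sample columns,
#'   percentages summing to 100 per sample) with the study design attached
#'   and a logical `attr(, "stable")` marking the low-variability species.
#' @export
synthetic_reference_abundance <- function(n_stable = 90, cv_stable = 0.02,
                                          cv_variable = 0.3) {
  inv <- default_lipidome_inventory()
  design <- study_design()
  n <- nrow(inv)
  withr::local_seed(306216L)
  base <- stats::rlnorm(n, log(1), 1.2)
  base <- 100 * base / sum(base)
  stable <- seq_len(n) %in% sample.int(n, n_stable)
  cv <- ifelse(stable, cv_stable, cv_variable)
  sdlog <- sqrt(log(1 + cv^2))
  m <- matrix(0, n, nrow(design))
  for (j in seq_len(nrow(design)))
    m[, j] <- base * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  m <- sweep(m, 2, colSums(m), "/") * 100
  colnames(m) <- design$sample_id
  out <- dplyr::bind_cols(inv[, c("species", "class", "carbons",
                                  "double_bonds")],
                          tibble::as_tibble(m))
  structure(out, design = design, sample_ids = design$sample_id,
            basis = "total", stable = stable,
            class = c("percent_table", class(tibble::tibble())))
}
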