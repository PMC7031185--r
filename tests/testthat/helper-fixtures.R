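# Small in-code fixtures shared across test files.

# Minimal abundance table: species metadata + per-sample intensities.
make_abundance <- function(intensities, species_meta, design) {
  m <- as.matrix(intensities)
  colnames(m) <- design$sample_id
  tb <- dplyr::bind_cols(species_meta, tibble::as_tibble(m))
  structure(tb, design = design, sample_ids = design$sample_id,
            class = c("abundance_table", class(tibble::tibble())))
}

# One-class, few-species metadata block.
make_species_meta <- function(n, class = "PC", carbons = 34L,
                              double_bonds = NULL) {
  tibble::tibble(
    species = sprintf("%s_%02d", class, seq_len(n)),
    class = class,
    carbons = rep_len(carbons, n),
    double_bonds = if (is.null(double_bonds)) rep(1L, n)
                   else rep_len(double_bonds, n)
  )
}

# A noise-free lipidome (deterministic intensities, no noise peaks).
noise_free_lipidome <- function(seed = 3, ...) {
  args <- utils::modifyList(list(seed = seed, ppm_sd = 0, rt_sd = 0, cv = 0,
                                 noise_density = 0), list(...))
  do.call(simulate_lipidome, args)
}

# Default-settings pipeline run at a fixed seed, computed once per session.
.pipeline_cache <- new.env(parent = emptyenv())
default_pipeline_run <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.pipeline_cache[[key]]))
    .pipeline_cache[[key]] <- run_pipeline(seed = seed)
  .pipeline_cache[[key]]
}
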