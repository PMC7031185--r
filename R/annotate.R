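#' Validate and apply class retention-time windows
#'
#' Class assignment follows the HILIC logic: the headgroup class determines
#' elution, so a peak's retention time places it in at most one class
#' window. Windows must be non-overlapping; this is validated when the
#' window table is used.
#'
#' @param windows Tibble with `class`, `rt_min`, `rt_max` (seconds), e.g.
#'   [class_rt_map()].
#' @return The validated window tibble (invisibly re-ordered by `rt_min`).
#' @export
validate_rt_windows <- function(windows) {
  stopifnot(all(c("class", "rt_min", "rt_max") %in% names(windows)))
  w <- windows[order(windows$rt_min), , drop = FALSE]
  if (any(w$rt_max <= w$rt_min))
    stop("retention-time window with rt_max <= rt_min", call. = FALSE)
  if (nrow(w) > 1 && any(w$rt_min[-1] < w$rt_max[-nrow(w)]))
    stop("overlapping class retention-time windows", call. = FALSE)
  w
}

#' Assign lipid class by retention time
#'
#' @param peaks Feature/peak tibble with an `rt` column.
#' @param windows Class window tibble (validated; must be non-overlapping).
#' @return `peaks` with an added `class` column (`NA` outside all windows).
#' @export
assign_class <- function(peaks, windows = class_rt_map()) {
  w <- validate_rt_windows(windows)
  idx <- vapply(peaks$rt, function(rt) {
    j <- which(rt >= w$rt_min & rt <= w$rt_max)
    if (length(j) == 1) j else NA_integer_
  }, integer(1))
  peaks$class <- w$class[idx]
  peaks
}

#' Annotate de-isotoped peaks against the lipid database
#'
#' Two-step identification: each monoisotopic peak is first gated to the
#' lipid class of its retention-time window, then matched by m/z against
#' the database entries of that class (within the active ionization mode of
#' the database). The candidate with the smallest absolute ppm error wins;
#' when two or more candidates fall within the tolerance the annotation is
#' flagged ambiguous (and excluded from the abundance table under the
#' default policy). Peaks outside every class window are matched against
#' the full database only when `class_gate = FALSE`.
#'
#' @param peaks Retained peaks from [deisotope()] (`$peaks`), or any peak
#'   tibble with `mz`, `rt` and sample intensity columns.
#' @param db A `lipid_db` from [build_lipid_database()].
#' @param windows Class retention-time windows, default [class_rt_map()].
#' @param tolerance,unit Match tolerance (default 5 ppm).
#' @param ambiguity `"exclude"` (default) or `"keep-nearest"`.
#' @param class_gate Gate candidates by RT-assigned class (default TRUE).
#' @return Tibble of class `annotation_table`: peak `mz`, `rt`, `class`,
#'   `species`, `adduct`, `carbons`, `double_bonds`, `error_ppm`,
#'   `error_da`, `n_candidates`, `ambiguous`, plus the sample intensity
#'   columns. Unmatched peaks are omitted.
#' @export
annotate_species <- function(peaks, db, windows = class_rt_map(),
                             tolerance = 5, unit = c("ppm", "Da"),
                             ambiguity = c("exclude", "keep-nearest"),
                             class_gate = TRUE) {
  unit <- match.arg(unit)
  ambiguity <- match.arg(ambiguity)
  if (nrow(db) == 0) stop("empty lipid database", call. = FALSE)
  samples <- attr(peaks, "sample_ids")
  if (is.null(samples))
    samples <- setdiff(names(peaks),
                       c("mz", "rt", "class", "provenance", "truth_species",
                         "truth_adduct"))
  peaks <- assign_class(peaks, windows)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    cl <- peaks$class[i]
    if (is.na(cl)) {
      if (class_gate) next
      sub <- db
    } else {
      sub <- db[db$class == cl, , drop = FALSE]
    }
    hits <- query_mz(sub, peaks$mz[i], tolerance, unit)
    if (nrow(hits) == 0) next
    amb <- nrow(hits) >= 2
    ann <- tibble::tibble(
      mz = peaks$mz[i], rt = peaks$rt[i], class = hits$class[1],
      species = hits$species[1], adduct = hits$adduct[1],
      carbons = hits$carbons[1], double_bonds = hits$double_bonds[1],
      error_ppm = hits$error_ppm[1], error_da = hits$error_da[1],
      n_candidates = nrow(hits), ambiguous = amb
    )
    out[[length(out) + 1]] <- dplyr::bind_cols(
      ann, peaks[i, samples, drop = FALSE])
  }
  ann <- if (length(out) == 0) {
    tibble::tibble(mz = numeric(0), rt = numeric(0), class = character(0),
                   species = character(0), adduct = character(0),
                   carbons = integer(0), double_bonds = integer(0),
                   error_ppm = numeric(0), error_da = numeric(0),
                   n_candidates = integer(0), ambiguous = logical(0))
  } else dplyr::bind_rows(out)
  structure(ann, sample_ids = samples, ambiguity = ambiguity,
            class = c("annotation_table", class(tibble::tibble())))
}

#' Build a species x sample abundance table from annotations
#'
#' Ambiguous annotations are dropped under the `"exclude"` policy (kept if
#' the annotation table was built with `"keep-nearest"`). Multiple peaks or
#' adducts of one species are summed per sample; species are ordered by
#' (class, carbons, double_bonds).
#'
#' @param annotations An `annotation_table` from [annotate_species()].
#' @param design Study design tibble; its `sample_id`s must match the
#'   intensity columns.
#' @return Tibble of class `abundance_table` (`species`, `class`,
#'   `carbons`, `double_bonds`, one column per sample) with the design in
#'   `attr(, "design")`.
#' @export
build_abundance_table <- function(annotations, design) {
  samples <- attr(annotations, "sample_ids")
  if (is.null(samples)) samples <- design$sample_id
  if (!all(samples %in% design$sample_id) ||
      !all(design$sample_id %in% samples))
    stop("annotation sample columns do not match the design", call. = FALSE)
  keep <- annotations
  if (!identical(attr(annotations, "ambiguity"), "keep-nearest"))
    keep <- keep[!keep$ambiguous, , drop = FALSE]
  if (nrow(keep) == 0) {
    empty <- tibble::tibble(species = character(0), class = character(0),
                            carbons = integer(0), double_bonds = integer(0))
    for (s in design$sample_id) empty[[s]] <- numeric(0)
    return(structure(empty, design = design, sample_ids = design$sample_id,
                     class = c("abundance_table", class(tibble::tibble()))))
  }
  ab <- dplyr::summarise(
    dplyr::group_by(keep, .data$species, .data$class, .data$carbons,
                    .data$double_bonds),
    dplyr::across(dplyr::all_of(samples), sum), .groups = "drop")
  ab <- ab[order(ab$class, ab$carbons, ab$double_bonds), , drop = FALSE]
  ab <- ab[, c("species", "class", "carbons", "double_bonds",
               design$sample_id)]
  structure(ab, design = design, sample_ids = design$sample_id,
            class = c("abundance_table", class(tibble::tibble())))
}

#' Write / read an abundance table CSV
#' @param table `abundance_table` tibble.
#' @param path,design CSV path; design to re-attach on read.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_abundance_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path, design) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("species", "class", "carbons", "double_bonds", design$sample_id)
  if (!all(need %in% names(raw)))
    stop("abundance CSV missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  structure(tibble::as_tibble(raw[need]), design = design,
            sample_ids = design$sample_id,
            class = c("abundance_table", class(tibble::tibble())))
}
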