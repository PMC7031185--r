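#' Build the in silico lipid m/z database
#'
#' Enumerates lipid species over a (carbons, double_bonds) grid for each
#' class, attaches the adducts formed in the chosen ionization mode, and
#' keeps entries whose m/z falls inside the instrument scan window. The
#' default grid (even total carbons 24--44, 0--8 double bonds, scan window
#' m/z 450--950) reflects mammalian diacyl/ceramide lipid chemistry and a
#' full-scan HILIC acquisition.
#'
#' @param classes Character vector of lipid classes to enumerate (subset of
#'   PC, PE, PG, PI, PS, SM; `"CHOL"` may be added for positive mode).
#' @param carbons Integer vector of total acyl carbons, default
#'   `seq(24, 44, 2)`. Use `include_odd_carbons = TRUE` to expand a
#'   min--max range to step 1.
#' @param double_bonds Integer vector, default `0:8`.
#' @param mode `"negative"` (default; formate adducts for PC/SM, [M-H]- for
#'   the acidic classes) or `"positive"`.
#' @param mz_range Scan window in Th, default `c(450, 950)`. `NULL` disables
#'   windowing.
#' @param include_odd_carbons Expand `carbons` to every integer between its
#'   min and max.
#' @return A tibble of class `lipid_db`, sorted ascending by `mz`, with
#'   columns `class`, `carbons`, `double_bonds`, `species`, `formula`,
#'   `mass`, `adduct`, `mz`.
#' @examples
#' db <- build_lipid_database()
#' range(db$mz)
#' @export
build_lipid_database <- function(classes = LIPID_CLASSES,
                                 carbons = seq(24L, 44L, 2L),
                                 double_bonds = 0:8,
                                 mode = c("negative", "positive"),
                                 mz_range = c(450, 950),
                                 include_odd_carbons = FALSE) {
  mode <- match.arg(mode)
  if (length(classes) == 0) stop("empty class list", call. = FALSE)
  if (include_odd_carbons) carbons <- seq(min(carbons), max(carbons))
  rows <- list()
  for (cl in classes) {
    if (cl == "CHOL") {
      sp <- cholesterol_species()
    } else {
      grid <- expand.grid(carbons = carbons, double_bonds = double_bonds)
      sp <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
        lipid_species(cl, grid$carbons[i], grid$double_bonds[i])))
    }
    for (ad in allowed_adducts(cl, mode)) {
      e <- sp
      e$adduct <- ad
      e$mz <- adduct_mz(e$mass, ad)
      rows[[length(rows) + 1]] <- e
    }
  }
  db <- dplyr::bind_rows(rows)
  if (!is.null(mz_range))
    db <- db[db$mz >= mz_range[1] & db$mz <= mz_range[2], , drop = FALSE]
  db <- db[order(db$mz, db$class, db$carbons, db$double_bonds), , drop = FALSE]
  db <- dplyr::distinct(db, .data$species, .data$adduct, .keep_all = TRUE)
  if (nrow(db) == 0) warning("database is empty for this configuration")
  structure(tibble::as_tibble(db),
            mode = mode, class = c("lipid_db", class(tibble::tibble())))
}

#' Query the lipid database around an m/z value
#'
#' Returns every database entry whose m/z lies within the tolerance of the
#' query, sorted by absolute mass error; ties are broken by (class, carbons,
#' double_bonds) lexicographic order so results are deterministic.
#'
#' @param db A `lipid_db` tibble from [build_lipid_database()].
#' @param mz Query m/z (Th), scalar.
#' @param tolerance Positive match tolerance. Defaults to 5 ppm, appropriate
#'   for high-resolution (Orbitrap-class) data; use `tolerance = 0.3,
#'   unit = "Da"` for ion-trap data.
#' @param unit `"ppm"` or `"Da"`.
#' @return Tibble of candidate entries with added `error_da` and `error_ppm`
#'   columns (signed, entry minus query); zero rows if nothing matches.
#' @export
query_mz <- function(db, mz, tolerance = 5, unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  stopifnot(length(mz) == 1, is.finite(mz))
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  tol_da <- if (unit == "ppm") tolerance * mz * 1e-6 else tolerance
  err <- db$mz - mz
  hit <- abs(err) <= tol_da
  out <- db[hit, , drop = FALSE]
  out$error_da <- err[hit]
  out$error_ppm <- out$error_da / mz * 1e6
  out[order(abs(out$error_da), out$class, out$carbons, out$double_bonds), ,
      drop = FALSE]
}

#' Write / read a lipid database as CSV
#'
#' Plain-UTF-8 CSV with a header row and '.' decimal separator; round-trips
#' entries and their order exactly.
#'
#' @param db `lipid_db` tibble.
#' @param path File path.
#' @return `read_lipid_database()` returns the `lipid_db` tibble;
#'   `write_lipid_database()` returns `path` invisibly.
#' @export
write_lipid_database <- function(db, path) {
  out <- db[, c("class", "carbons", "double_bonds", "formula",
                "monoisotopic_mass" = "mass", "adduct", "mz")]
  names(out) <- c("class", "carbons", "double_bonds", "formula",
                  "monoisotopic_mass", "adduct", "mz")
  out$monoisotopic_mass <- sprintf("%.10f", out$monoisotopic_mass)
  out$mz <- sprintf("%.10f", out$mz)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lipid_database
#' @export
read_lipid_database <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("class", "carbons", "double_bonds", "formula",
            "monoisotopic_mass", "adduct", "mz")
  if (!all(need %in% names(raw)))
    stop("database CSV missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  db <- tibble::tibble(
    class = raw$class,
    carbons = as.integer(raw$carbons),
    double_bonds = as.integer(raw$double_bonds),
    species = ifelse(raw$class == "CHOL", "CHOL",
                     sprintf("%s %d:%d", raw$class, as.integer(raw$carbons),
                             as.integer(raw$double_bonds))),
    formula = raw$formula,
    mass = as.numeric(raw$monoisotopic_mass),
    adduct = raw$adduct,
    mz = as.numeric(raw$mz)
  )
  structure(db, class = c("lipid_db", class(tibble::tibble())))
}
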