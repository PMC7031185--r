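#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Monoisotopic atomic masses (Da). C is exactly 12 by definition.
ATOMIC_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)

## Mass added to the neutral monoisotopic mass by each supported adduct.
## Values include the electron mass, so they are applied to neutral masses
## directly to give singly charged m/z.
ADDUCT_DELTA <- c(
  "[M+H]+"      =  1.007276,
  "[M+H-H2O]+"  = -17.003289,
  "[M-H]-"      = -1.007276,
  "[M+HCOO]-"   = 44.998201
)

## 13C - 12C mass difference (Th per isotope substitution) and natural 13C
## abundance used for isotopologue intensity models.
C13_SPACING   <- 1.003355
C13_ABUNDANCE <- 0.0107

LIPID_CLASSES <- c("PC", "PE", "PG", "PI", "PS", "SM")

## Headgroup/backbone templates: element counts as affine functions of total
## acyl carbons c and double bonds d. Diacyl glycerophospholipids; SM on a
## ceramide backbone collapsed to total c:d (sphingoid + N-acyl).
CLASS_TEMPLATE <- list(
  PC = list(C = c(1, 8),  H = c(2, 16), Hd = -2, N = 1, O = 8,  P = 1),
  PE = list(C = c(1, 5),  H = c(2, 10), Hd = -2, N = 1, O = 8,  P = 1),
  PG = list(C = c(1, 6),  H = c(2, 11), Hd = -2, N = 0, O = 10, P = 1),
  PI = list(C = c(1, 9),  H = c(2, 15), Hd = -2, N = 0, O = 13, P = 1),
  PS = list(C = c(1, 6),  H = c(2, 10), Hd = -2, N = 1, O = 10, P = 1),
  SM = list(C = c(1, 5),  H = c(2, 13), Hd = -2, N = 2, O = 6,  P = 1)
)

## Cholesterol is a fixed single species, not (c, d)-parameterised.
CHOL_FORMULA <- c(C = 27L, H = 46L, N = 0L, O = 1L, P = 0L)

## Adducts formed by each class under the formate/formic-acid mobile phase.
ADDUCT_POLICY <- list(
  positive = list(PC = "[M+H]+", PE = "[M+H]+", PG = "[M+H]+", PI = "[M+H]+",
                  PS = "[M+H]+", SM = "[M+H]+", CHOL = "[M+H-H2O]+"),
  negative = list(PC = "[M+HCOO]-", PE = "[M-H]-", PG = "[M-H]-",
                  PI = "[M-H]-", PS = "[M-H]-", SM = "[M+HCOO]-")
)

#' Elemental formula of a lipid species
#'
#' Computes the neutral elemental formula (C/H/N/O/P counts) of a diacyl
#' glycerophospholipid or sphingomyelin from its class, total acyl carbons
#' and total double bonds. Sphingomyelin is parameterised by total carbons
#' and double bonds of sphingoid base plus N-acyl chain (so SM d18:1;16:0 is
#' SM 34:1), the resolution at which MS1 m/z can identify it.
#'
#' @param lipid_class One of `"PC"`, `"PE"`, `"PG"`, `"PI"`, `"PS"`, `"SM"`.
#'   Cholesterol has a fixed formula and is rejected here; see
#'   [cholesterol_species()].
#' @param carbons Total acyl-chain carbons (integer).
#' @param double_bonds Total acyl-chain double bonds (integer, 0--8).
#' @param carbon_range Allowed total-carbon range, default `c(20, 50)`.
#' @return Named integer vector with elements `C`, `H`, `N`, `O`, `P`.
#' @examples
#' lipid_formula("PC", 34, 1)   # C42 H82 N1 O8 P1
#' @export
lipid_formula <- function(lipid_class, carbons, double_bonds,
                          carbon_range = c(20, 50)) {
  lipid_class <- match.arg(lipid_class, c(LIPID_CLASSES, "CHOL"))
  if (lipid_class == "CHOL") {
    stop("CHOL is a fixed species with no (carbons, double_bonds) parameters; ",
         "use cholesterol_species()", call. = FALSE)
  }
  if (!is.numeric(carbons) || carbons != round(carbons) ||
      carbons < carbon_range[1] || carbons > carbon_range[2]) {
    stop(sprintf("carbons = %s outside allowed range [%d, %d] for %s",
                 format(carbons), carbon_range[1], carbon_range[2],
                 lipid_class), call. = FALSE)
  }
  if (!is.numeric(double_bonds) || double_bonds != round(double_bonds) ||
      double_bonds < 0 || double_bonds > 8) {
    stop(sprintf("double_bonds = %s outside allowed range [0, 8]",
                 format(double_bonds)), call. = FALSE)
  }
  tp <- CLASS_TEMPLATE[[lipid_class]]
  f <- c(
    C = tp$C[1] * carbons + tp$C[2],
    H = tp$H[1] * carbons + tp$H[2] + tp$Hd * double_bonds,
    N = tp$N, O = tp$O, P = tp$P
  )
  storage.mode(f) <- "integer"
  if (any(f < 0)) stop("formula template yielded a negative element count",
                       call. = FALSE)
  f
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named numeric vector of element counts (subset of C, H, N,
#'   O, P), or a formula string such as `"C42H82NO8P"`.
#' @return Mass in Da; the empty formula has mass 0.
#' @examples
#' monoisotopic_mass(lipid_formula("PC", 34, 1))  # 759.5778
#' monoisotopic_mass("H2O")                       # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0) return(0)
  if (is.null(names(formula)) || !all(names(formula) %in% names(ATOMIC_MASS)))
    stop("formula must be named with elements among C, H, N, O, P",
         call. = FALSE)
  if (any(formula < 0)) stop("negative element count", call. = FALSE)
  sum(formula * ATOMIC_MASS[names(formula)])
}

#' Format an element-count vector as a Hill-order formula string
#' @param formula Named integer vector (C, H, N, O, P counts).
#' @return String such as `"C42H82NO8P"`; counts of 1 are implicit, zeros
#'   omitted.
#' @export
format_formula <- function(formula) {
  ord <- c("C", "H", "N", "O", "P")
  f <- formula[ord[ord %in% names(formula)]]
  f <- f[f > 0]
  paste0(vapply(seq_along(f), function(i) {
    if (f[i] == 1) names(f)[i] else paste0(names(f)[i], f[i])
  }, character(1)), collapse = "")
}

#' Parse a formula string into element counts
#' @param x String such as `"C42H82NO8P"` (elements restricted to C,H,N,O,P).
#' @return Named integer vector of counts.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  m <- gregexpr("([CHNOP])([0-9]*)", x)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(x))
    stop("cannot parse formula: ", x, call. = FALSE)
  parts <- regmatches(x, m)[[1]]
  el <- substr(parts, 1, 1)
  n <- as.integer(ifelse(nchar(parts) > 1, substring(parts, 2), "1"))
  out <- integer(length(ATOMIC_MASS))
  names(out) <- names(ATOMIC_MASS)
  for (i in seq_along(el)) out[el[i]] <- out[el[i]] + n[i]
  out
}

#' Construct a lipid species record
#'
#' @inheritParams lipid_formula
#' @return One-row tibble with `species`, `class`, `carbons`, `double_bonds`,
#'   `formula` (string) and `mass` (monoisotopic, Da).
#' @examples
#' lipid_species("PI", 38, 4)
#' @export
lipid_species <- function(lipid_class, carbons, double_bonds) {
  f <- lipid_formula(lipid_class, carbons, double_bonds)
  tibble::tibble(
    species = sprintf("%s %d:%d", lipid_class, carbons, double_bonds),
    class = lipid_class,
    carbons = as.integer(carbons),
    double_bonds = as.integer(double_bonds),
    formula = format_formula(f),
    mass = monoisotopic_mass(f)
  )
}

#' Cholesterol as a species record
#'
#' Cholesterol (C27H46O) is carried as a fixed species outside the
#' (carbons, double_bonds) parameterisation of the phospholipid classes; it
#' ionises as [M+H-H2O]+ under positive electrospray.
#' @return One-row tibble in the [lipid_species()] layout.
#' @export
cholesterol_species <- function() {
  tibble::tibble(
    species = "CHOL", class = "CHOL",
    carbons = 27L, double_bonds = 1L,
    formula = format_formula(CHOL_FORMULA),
    mass = monoisotopic_mass(CHOL_FORMULA)
  )
}

#' Adducts allowed for a class in an ionization mode
#' @param lipid_class Class name (including `"CHOL"`).
#' @param mode `"positive"` or `"negative"`.
#' @return Character vector of adduct labels (possibly empty).
#' @export
allowed_adducts <- function(lipid_class, mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  a <- ADDUCT_POLICY[[mode]][[lipid_class]]
  if (is.null(a)) character(0) else a
}

#' m/z of a lipid adduct ion
#'
#' @param species One-row species tibble from [lipid_species()] /
#'   [cholesterol_species()], or a bare monoisotopic mass in Da.
#' @param adduct Adduct label: `"[M+H]+"`, `"[M+H-H2O]+"`, `"[M-H]-"` or
#'   `"[M+HCOO]-"`.
#' @param check_policy If `TRUE` (default) and a species record was given,
#'   reject class/adduct pairings outside the ionization policy.
#' @return m/z (Th) of the singly charged ion.
#' @examples
#' adduct_mz(cholesterol_species(), "[M+H-H2O]+")  # 369.3516
#' adduct_mz(lipid_species("PC", 34, 1), "[M+H]+") # 760.5850
#' @export
adduct_mz <- function(species, adduct, check_policy = TRUE) {
  if (!adduct %in% names(ADDUCT_DELTA))
    stop("unknown adduct: ", adduct, call. = FALSE)
  if (is.numeric(species)) {
    mass <- species
  } else {
    mass <- species$mass
    if (check_policy) {
      ok <- adduct %in% c(allowed_adducts(species$class, "positive"),
                          allowed_adducts(species$class, "negative"))
      if (!all(ok))
        stop("adduct ", adduct, " not allowed for class ",
             paste(unique(species$class[!ok]), collapse = ", "),
             call. = FALSE)
    }
  }
  mz <- mass + ADDUCT_DELTA[[adduct]]
  if (any(mz <= 0)) stop("non-positive m/z", call. = FALSE)
  unname(mz)
}
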