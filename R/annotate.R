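# Formula-based monoisotopic mass computation, adduct chemistry and ppm
# matching of cell-profile peaks against a lipid library, optionally
# co-gated by ion mobility.

# Most-abundant-isotope masses (Da), CODATA/IUPAC values, >= 6 decimals.
.MONOISOTOPIC_MASS <- c(
  C = 12.000000, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Si = 27.9769265325, Fe = 55.9349375,
  Se = 79.9165213, Br = 78.9183371, I = 126.904473)

.PROTON_MASS <- 1.007276467
.WATER_MASS <- 18.010565  # H2O monoisotopic

#' Parse an elemental formula
#'
#' Accepts Hill-style formulas such as `"C44H84NO8P"`; element symbols
#' are one capital plus optional lowercase letter, counts default to 1.
#'
#' @param formula character scalar.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(elems, names(.MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  out <- tapply(counts, elems, sum)
  out <- setNames(as.integer(out), names(out))
  if (sum(out) < 1) stop("formula must contain at least one atom")
  out
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses over the formula.
#'
#' @param formula character formula (e.g. `"C44H84NO8P"`) or a named
#'   count vector from [parse_formula()].
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.MONOISOTOPIC_MASS[names(counts)] * as.numeric(counts))
}

.ADDUCTS <- list(
  "[M+H]+"      = function(M) M + .PROTON_MASS,
  "[M-H]-"      = function(M) M - .PROTON_MASS,
  "[M+H-H2O]+"  = function(M) M + .PROTON_MASS - .WATER_MASS)

#' Theoretical m/z of an adduct
#'
#' Supported adducts: `[M+H]+` (protonation), `[M-H]-` (deprotonation),
#' `[M+H-H2O]+` (protonation with water loss). The proton mass
#' (1.007276 Da) is used, not the hydrogen atom mass: the electron mass
#' matters at the fourth decimal for lipid-sized ions.
#'
#' @param mass neutral monoisotopic mass, Da.
#' @param adduct adduct code string; unicode minus signs are normalized.
#' @return m/z in Da.
#' @export
adduct_mz <- function(mass, adduct) {
  key <- gsub("−|–", "-", gsub("\\s", "", adduct))
  f <- .ADDUCTS[[key]]
  if (is.null(f))
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  f(mass)
}

#' Load a lipid library
#'
#' Reads a CSV with columns `name, formula, adduct` and optionally
#' `expected_ook0` and `printed_mz` (a measured/literature m/z kept for
#' reference). Theoretical m/z is always recomputed from the formula and
#' adduct. With `path = NULL` the bundled library of lipid species
#' commonly observed in single-cell MALDI-MSI of cultured human cells
#' (PC/PE/PS/PI/LPC/LPE/FA/Cer classes) is loaded.
#'
#' @param path CSV path or NULL for the bundled library.
#' @return data.frame of class `lipid_library` with `theoretical_mz`.
#' @export
lipid_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lipid_library.csv", package = "scmsi",
                        mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "adduct")
  if (!all(need %in% names(tab)))
    stop("lipid library must have columns ", paste(need, collapse = ", "))
  tab$theoretical_mz <- vapply(seq_len(nrow(tab)), function(i)
    adduct_mz(monoisotopic_mass(tab$formula[i]), tab$adduct[i]), numeric(1))
  if (!"expected_ook0" %in% names(tab)) tab$expected_ook0 <- NA_real_
  class(tab) <- c("lipid_library", "data.frame")
  tab
}

#' Annotate peaks against a lipid library
#'
#' Reports every (peak, record) pair whose m/z agree within `tol_ppm`
#' (ppm error computed relative to the theoretical m/z; closed
#' interval). When both the peak and the record carry mobility values
#' and `mobility_tol` is given, pairs additionally require
#' |ook0 - expected_ook0| <= mobility_tol. Multiple hits per peak are
#' allowed and ranked by |ppm_error| (ties broken by library order).
#'
#' @param peaks a `peak_list`.
#' @param library a `lipid_library` (default: bundled).
#' @param tol_ppm mass tolerance (default 10).
#' @param mobility_tol optional 1/K0 tolerance; NULL disables the gate.
#' @return data.frame of hits: peak_mz, peak_intensity, name, adduct,
#'   theoretical_mz, ppm_error (signed), mobility_match.
#' @export
annotate_peaks <- function(peaks, library = lipid_library(), tol_ppm = 10,
                           mobility_tol = NULL) {
  if (nrow(library) == 0) stop("empty lipid library")
  hits <- list()
  has_k0 <- !is.null(peaks$ook0)
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - library$theoretical_mz) /
      library$theoretical_mz * 1e6
    sel <- which(abs(ppm) <= tol_ppm)
    if (!is.null(mobility_tol) && has_k0 && !is.na(peaks$ook0[i])) {
      mob_ok <- is.na(library$expected_ook0[sel]) |
        abs(peaks$ook0[i] - library$expected_ook0[sel]) <= mobility_tol
      mob_flag <- ifelse(is.na(library$expected_ook0[sel]), NA, mob_ok)
      sel <- sel[mob_ok]
      mob_flag <- mob_flag[mob_ok]
    } else {
      mob_flag <- rep(NA, length(sel))
    }
    if (length(sel) == 0) next
    o <- order(abs(ppm[sel]), sel)
    sel <- sel[o]; mob_flag <- mob_flag[o]
    hits[[length(hits) + 1L]] <- data.frame(
      peak_mz = peaks$mz[i], peak_intensity = peaks$intensity[i],
      name = library$name[sel], adduct = library$adduct[sel],
      theoretical_mz = library$theoretical_mz[sel],
      ppm_error = ppm[sel], mobility_match = mob_flag)
  }
  if (length(hits) == 0)
    return(data.frame(peak_mz = numeric(0), peak_intensity = numeric(0),
                      name = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      mobility_match = logical(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
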