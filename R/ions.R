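#' Electrospray ion species
#'
#' Supported adducts and their charge/polarity:
#' \itemize{
#'   \item \code{"[M-H]-"}: z = 1, negative
#'   \item \code{"[M-2H]2-"}: z = 2, negative
#'   \item \code{"[M-2H+Na]-"}: z = 1, negative (sodium-exchanged)
#'   \item \code{"[M+H]+"}: z = 1, positive
#'   \item \code{"[M+Na]+"}: z = 1, positive
#'   \item \code{"[M]+"}: z = 1, positive (intrinsic cation, e.g. N1-methyl
#'     quaternised adenine printed with its full hydrogen count)
#' }
#'
#' @param adduct One of the adduct strings above.
#' @return Object of class \code{ion_spec} with fields \code{adduct},
#'   \code{z}, \code{polarity}.
#' @examples
#' ion_spec("[M-2H]2-")
#' @export
ion_spec <- function(adduct = "[M-H]-") {
  tab <- .adduct_table()
  if (!adduct %in% names(tab)) {
    stop("unknown adduct '", adduct, "'; supported: ",
         paste(names(tab), collapse = ", "))
  }
  a <- tab[[adduct]]
  structure(list(adduct = adduct, z = a$z, polarity = a$polarity),
            class = "ion_spec")
}

# delta = mass change of the neutral before charging; charge carriers are
# whole H atoms (electron bookkeeping handled in mz_of)
.adduct_table <- function() {
  list(
    "[M-H]-"     = list(z = 1L, polarity = "negative", dH = -1L, dNa = 0L),
    "[M-2H]2-"   = list(z = 2L, polarity = "negative", dH = -2L, dNa = 0L),
    "[M-2H+Na]-" = list(z = 1L, polarity = "negative", dH = -2L, dNa = 1L),
    "[M+H]+"     = list(z = 1L, polarity = "positive", dH = +1L, dNa = 0L),
    "[M+Na]+"    = list(z = 1L, polarity = "positive", dH = 0L,  dNa = 1L),
    "[M]+"       = list(z = 1L, polarity = "positive", dH = 0L,  dNa = 0L)
  )
}

#' @export
print.ion_spec <- function(x, ...) {
  cat("<ion_spec> ", x$adduct, " (z = ", x$z, ", ", x$polarity, ")\n", sep = "")
  invisible(x)
}

#' Theoretical m/z of an ionised neutral formula
#'
#' Electron-inclusive arithmetic: the ion mass is the neutral mass plus/minus
#' the adduct atoms, then minus z electrons (positive mode) or plus z
#' electrons (negative mode); m/z is the ion mass over z. Deprotonation
#' adducts require at least z hydrogens in the neutral.
#'
#' @param f A neutral \code{mol_formula} (its label state, natural or 15N,
#'   is honoured).
#' @param ion An \code{ion_spec} or adduct string.
#' @return m/z in Th.
#' @examples
#' mz_of(cap_formula(cap_structure("A", "A", 3)), "[M-H]-")  # ~ 755.0747
#' @export
mz_of <- function(f, ion = ion_spec("[M-H]-")) {
  stopifnot(inherits(f, "mol_formula"))
  if (is.character(ion)) ion <- ion_spec(ion)
  stopifnot(inherits(ion, "ion_spec"))
  a <- .adduct_table()[[ion$adduct]]
  m <- element_masses()
  nH <- if ("H" %in% names(f)) f[["H"]] else 0L
  if (a$dH < 0 && nH < -a$dH)
    stop("formula has fewer than ", -a$dH, " hydrogens to remove")
  M <- monoisotopic_mass(f)
  ion_mass <- M + a$dH * m[["H"]] + a$dNa * m[["Na"]]
  ion_mass <- if (ion$polarity == "negative") {
    ion_mass + ion$z * m[["electron"]]
  } else {
    ion_mass - ion$z * m[["electron"]]
  }
  unname(ion_mass / ion$z)
}

#' m/z directly from an ion's elemental composition
#'
#' For compositions printed as the ion itself (e.g. HRMS "calc." entries):
#' sums the monoisotopic masses and applies only the electron correction for
#' the stated charge.
#'
#' @param f \code{mol_formula} of the ion (not the neutral).
#' @param z Charge magnitude.
#' @param polarity \code{"negative"} (adds z electrons) or \code{"positive"}
#'   (removes z electrons).
#' @return m/z in Th.
#' @examples
#' # printed anion composition of N6-methyl-AMP
#' ion_mz_from_formula(parse_formula("C11H15O7N5P"), 1, "negative")
#' @export
ion_mz_from_formula <- function(f, z = 1L, polarity = "negative") {
  stopifnot(inherits(f, "mol_formula"), z >= 1)
  polarity <- match.arg(polarity, c("negative", "positive"))
  m <- element_masses()
  M <- monoisotopic_mass(f)
  ion_mass <- M + (if (polarity == "negative") z else -z) * m[["electron"]]
  ion_mass / z
}

#' Invert adduct arithmetic: neutral mass from an observed m/z
#'
#' @param mz Observed m/z (Th).
#' @param ion An \code{ion_spec} or adduct string.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_of <- function(mz, ion = ion_spec("[M-H]-")) {
  if (is.character(ion)) ion <- ion_spec(ion)
  a <- .adduct_table()[[ion$adduct]]
  m <- element_masses()
  ion_mass <- mz * ion$z
  ion_mass <- if (ion$polarity == "negative") {
    ion_mass - ion$z * m[["electron"]]
  } else {
    ion_mass + ion$z * m[["electron"]]
  }
  unname(ion_mass - a$dH * m[["H"]] - a$dNa * m[["Na"]])
}
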