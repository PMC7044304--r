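#' Monoisotopic element masses
#'
#' Returns the element mass table shipped with the package: monoisotopic
#' masses (Da) of the elements used in nucleotide chemistry, plus the proton,
#' electron and heavy-nitrogen (\code{N15}) masses needed for ion and
#' stable-isotope arithmetic.
#'
#' @return Named numeric vector of masses in Da, indexed by element symbol.
#'   Special entries: \code{proton}, \code{electron}, \code{N15}.
#' @examples
#' element_masses()[["O"]]
#' @export
element_masses <- function() {
  tab <- .npn_env$element_masses
  if (is.null(tab)) {
    path <- system.file("extdata", "element_masses.tsv", package = "npncaps",
                        mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab <- stats::setNames(df$mass, df$symbol)
    stopifnot(all(tab > 0))
    # 15N - 14N increment must be the known 0.9970349 Da
    stopifnot(abs((tab[["N15"]] - tab[["N"]]) - 0.9970349) < 1e-6)
    .npn_env$element_masses <- tab
  }
  tab
}

.npn_env <- new.env(parent = emptyenv())

#' Mass difference between 15N and 14N (Da)
#' @return The per-nitrogen mass increment under full 15N substitution.
#' @export
delta_15n <- function() {
  m <- element_masses()
  unname(m[["N15"]] - m[["N"]])
}

#' Construct a molecular formula
#'
#' A molecular formula is a named integer vector of element counts with an
#' isotope-label state: \code{"natural"} (all elements at their most abundant
#' isotope) or \code{"15N"} (every nitrogen fully substituted by 15N, as in
#' metabolic labelling on a sole 15N nitrogen source).
#'
#' @param counts Named integer vector, element symbol -> count (>= 0).
#' @param label \code{"natural"} or \code{"15N"}.
#' @return Object of class \code{mol_formula}.
#' @examples
#' mol_formula(c(H = 2, O = 1))
#' @export
mol_formula <- function(counts = integer(0), label = "natural") {
  label <- match.arg(label, c("natural", "15N"))
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("element counts must be named by symbol")
    if (any(counts < 0)) stop("element counts must be non-negative")
    if (any(counts != round(counts))) stop("element counts must be integers")
    counts <- counts[counts > 0]
    known <- setdiff(names(element_masses()), c("proton", "electron", "N15"))
    bad <- setdiff(names(counts), known)
    if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (!length(counts)) {
    return(structure(stats::setNames(integer(0), character(0)),
                     label = label, class = "mol_formula"))
  }
  ord <- order(names(counts))
  structure(stats::setNames(as.integer(counts)[ord], names(counts)[ord]),
            label = label, class = "mol_formula")
}

#' Parse a Hill-notation formula string
#'
#' @param x String such as \code{"C21H28O16N10P3"}. Two-letter symbols
#'   (e.g. \code{Na}) are supported; an omitted count means 1.
#' @param label Isotope label state, see [mol_formula()].
#' @return A \code{mol_formula}.
#' @examples
#' parse_formula("C10H13N5O4")
#' @export
parse_formula <- function(x, label = "natural") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("\\s", "", x)
  if (!nzchar(x)) return(mol_formula(label = label))
  pieces <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(pieces)) != nchar(x))
    stop("cannot parse formula string: ", x)
  syms <- sub("[0-9]*$", "", pieces)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                            sub("^[A-Za-z]+", "", pieces), "1"))
  counts <- tapply(cnts, syms, sum)
  mol_formula(stats::setNames(as.integer(counts), names(counts)), label = label)
}

#' Format a formula in Hill notation
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (all alphabetical when no carbon is present).
#'
#' @param f A \code{mol_formula}.
#' @return A single string; \code{""} for the empty formula.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  if (!length(f)) return("")
  syms <- names(f)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(f[ord] == 1L, "", f[ord]), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format_formula(x),
      if (formula_label(x) == "15N") "  [fully 15N-labelled]", "\n", sep = "")
  invisible(x)
}

#' Isotope-label state of a formula
#' @param f A \code{mol_formula}.
#' @return \code{"natural"} or \code{"15N"}.
#' @export
formula_label <- function(f) attr(f, "label", exact = TRUE)

#' Element-wise formula arithmetic
#'
#' Addition and subtraction combine counts element-wise; subtraction that
#' would drive any count negative is an error (a fragment cannot contain
#' atoms its parent lacks). Operands must share the same label state.
#'
#' @param e1,e2 \code{mol_formula} objects.
#' @return A \code{mol_formula}.
#' @export
Ops.mol_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    stop("operation '", .Generic, "' not defined for molecular formulas")
  stopifnot(inherits(e1, "mol_formula"), inherits(e2, "mol_formula"))
  if (!identical(formula_label(e1), formula_label(e2)))
    stop("cannot combine formulas with different isotope labels")
  syms <- union(names(e1), names(e2))
  a <- stats::setNames(integer(length(syms)), syms)
  b <- a
  a[names(e1)] <- e1
  b[names(e2)] <- e2
  out <- if (.Generic == "+") a + b else a - b
  if (any(out < 0))
    stop("formula subtraction yields negative count for: ",
         paste(syms[out < 0], collapse = ", "))
  mol_formula(out, label = formula_label(e1))
}

#' Number of nitrogen atoms in a formula
#' @param f A \code{mol_formula}.
#' @return Integer count (0 if no nitrogen).
#' @export
nitrogen_count <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  if ("N" %in% names(f)) unname(f[["N"]]) else 0L
}

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times monoisotopic masses. Under the \code{"15N"}
#' label every nitrogen contributes the 15N mass instead of 14N.
#'
#' @param f A \code{mol_formula}.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))  # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  if (!length(f)) return(0)
  m <- element_masses()
  masses <- m[names(f)]
  if (identical(formula_label(f), "15N") && "N" %in% names(f))
    masses[["N"]] <- m[["N15"]]
  sum(unclass(f) * masses)
}

#' Fully 15N-label a formula
#'
#' Models complete metabolic substitution of 14N by 15N, as in growth on
#' 15NH4Cl as the sole nitrogen source.
#'
#' @param f A \code{mol_formula} (natural label).
#' @return List with \code{formula} (the labelled \code{mol_formula}) and
#'   \code{delta_mass}, the mass increment \code{N_count * 0.9970349} Da.
#' @examples
#' apply_15n(parse_formula("C20H27N10O16P3"))$delta_mass  # ~ 9.9703
#' @export
apply_15n <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  n <- nitrogen_count(f)
  labelled <- mol_formula(stats::setNames(as.integer(f), names(f)), label = "15N")
  list(formula = labelled, delta_mass = n * delta_15n())
}
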