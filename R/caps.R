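#' Nucleoside formulas
#'
#' Neutral ribonucleoside formulas for the four canonical bases.
#'
#' @param base One of \code{"A"}, \code{"G"}, \code{"C"}, \code{"U"}.
#' @return A \code{mol_formula}.
#' @export
nucleoside_formula <- function(base) {
  switch(match.arg(base, c("A", "G", "C", "U")),
         A = parse_formula("C10H13N5O4"),
         G = parse_formula("C10H13N5O5"),
         C = parse_formula("C9H13N3O5"),
         U = parse_formula("C9H12N2O6"))
}

# methyl positions chemically available on each base (ribose 2'-O allowed on all)
.methyl_positions <- list(
  A = c("N1", "N6", "2'-O"),
  G = c("N1", "N2", "N7", "2'-O"),
  C = c("2'-O"),
  U = c("2'-O")
)

#' Describe a candidate dinucleoside polyphosphate cap
#'
#' An NpnN cap is two ribonucleosides joined 5'-to-5' through an internal
#' chain of \code{n} phosphates. Methyl groups may decorate either side; each
#' methyl adds CH2 to the composition regardless of position, so position
#' tags are carried as metadata only (they matter for fragmentation and
#' retention-time interpretation, not mass). The unordered nucleoside pair is
#' canonicalised alphabetically, swapping the per-side methyl tags along.
#' The named cofactor caps NAD and CoA are represented via stored formula
#' overrides (\code{ref}).
#'
#' @param base1,base2 Nucleobases in \code{{A, G, C, U}}.
#' @param n Phosphate-bridge length, 2 to 6.
#' @param methyl1,methyl2 Methyl count on each side (0 to 2).
#' @param pos1,pos2 Optional character vectors of methyl position labels
#'   (subset of \code{N1, N2, N6, N7, 2'-O}), checked against the base.
#' @param ref Optional named reference cap, \code{"NAD"} or \code{"CoA"};
#'   overrides all other fields.
#' @param id Optional label; autogenerated when missing (e.g. \code{"mAp3G"}).
#' @return Object of class \code{cap_structure}.
#' @examples
#' cap_structure("A", "A", n = 3)
#' cap_structure("G", "G", n = 4, methyl1 = 1, methyl2 = 1,
#'               pos1 = "N7", pos2 = "2'-O", id = "m7Gp4Gm")
#' @export
cap_structure <- function(base1 = "A", base2 = "A", n = 3,
                          methyl1 = 0L, methyl2 = 0L,
                          pos1 = NULL, pos2 = NULL,
                          ref = NULL, id = NULL) {
  if (!is.null(ref)) {
    ref <- match.arg(ref, c("NAD", "CoA"))
    out <- structure(list(ref = ref, id = if (is.null(id)) ref else id),
                     class = "cap_structure")
    return(out)
  }
  base1 <- match.arg(base1, c("A", "G", "C", "U"))
  base2 <- match.arg(base2, c("A", "G", "C", "U"))
  stopifnot(length(n) == 1L, n == round(n))
  if (n < 2 || n > 6) stop("phosphate count n must be in 2..6")
  stopifnot(methyl1 >= 0, methyl1 <= 2, methyl2 >= 0, methyl2 <= 2)
  if (methyl1 + methyl2 > 4) stop("total methyl count must be <= 4")
  check_pos <- function(base, pos, k) {
    if (is.null(pos)) return(invisible())
    if (length(pos) > k) stop("more position tags than methyl groups")
    bad <- setdiff(pos, .methyl_positions[[base]])
    if (length(bad))
      stop("methyl position(s) ", paste(bad, collapse = ", "),
           " incompatible with base ", base)
  }
  check_pos(base1, pos1, methyl1)
  check_pos(base2, pos2, methyl2)
  # canonical order: alphabetical bases, side tags travel with their base
  if (base2 < base1) {
    tmp <- base1; base1 <- base2; base2 <- tmp
    tmp <- methyl1; methyl1 <- methyl2; methyl2 <- tmp
    tmp <- pos1; pos1 <- pos2; pos2 <- tmp
  }
  out <- structure(list(base1 = base1, base2 = base2, n = as.integer(n),
                        methyl1 = as.integer(methyl1),
                        methyl2 = as.integer(methyl2),
                        pos1 = pos1, pos2 = pos2, ref = NULL),
                   class = "cap_structure")
  out$id <- if (is.null(id)) cap_label(out) else id
  out
}

#' Canonical label for a cap structure
#'
#' Position-free labels of the form \code{"2mGp4G"}: total methyl count
#' prefix (\code{m}, \code{2m}, ...), then \code{<base1>p<n><base2>}.
#'
#' @param cap A \code{cap_structure}.
#' @return A string.
#' @export
cap_label <- function(cap) {
  stopifnot(inherits(cap, "cap_structure"))
  if (!is.null(cap$ref)) return(cap$ref)
  k <- cap$methyl1 + cap$methyl2
  pre <- if (k == 0) "" else if (k == 1) "m" else paste0(k, "m")
  paste0(pre, cap$base1, "p", cap$n, cap$base2)
}

#' @export
print.cap_structure <- function(x, ...) {
  if (!is.null(x$ref)) {
    cat("<cap_structure> ", x$id, " (reference cofactor cap)\n", sep = "")
  } else {
    cat("<cap_structure> ", x$id, ": ", x$base1, "-(p)", x$n, "-", x$base2,
        ", methyls ", x$methyl1, "+", x$methyl2, "\n", sep = "")
  }
  invisible(x)
}

# reference cofactor cap formulas (neutral)
.ref_formulas <- list(
  NAD = "C21H27N7O14P2",
  CoA = "C21H36N7O16P3S"
)

#' Linear polyphosphate chain formula
#'
#' The free acid H(n+2)PnO(3n+1): phosphoric acid for n = 1, pyrophosphoric
#' acid for n = 2, and so on.
#'
#' @param n Number of phosphorus atoms (>= 1).
#' @return A \code{mol_formula}.
#' @export
polyphosphate_formula <- function(n) {
  stopifnot(n >= 1, n == round(n))
  mol_formula(c(P = as.integer(n), O = as.integer(3 * n + 1),
                H = as.integer(n + 2)))
}

#' Neutral molecular formula of a cap
#'
#' Condensation rule: nucleoside1 + nucleoside2 + polyphosphate(n) minus two
#' waters (one phosphoester bond per side), plus CH2 per methyl group.
#' Reference cofactor caps (NAD, CoA) return their stored formulas.
#'
#' @param cap A \code{cap_structure}.
#' @return A \code{mol_formula}.
#' @examples
#' format_formula(cap_formula(cap_structure("A", "A", 3)))  # C20H27N10O16P3
#' @export
cap_formula <- function(cap) {
  stopifnot(inherits(cap, "cap_structure"))
  if (!is.null(cap$ref)) return(parse_formula(.ref_formulas[[cap$ref]]))
  f <- nucleoside_formula(cap$base1) + nucleoside_formula(cap$base2) +
    polyphosphate_formula(cap$n) - parse_formula("H4O2")
  k <- cap$methyl1 + cap$methyl2
  if (k > 0) f <- f + mol_formula(c(C = k, H = 2L * k))
  f
}
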