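#' In-source stability of a dinucleotide polyphosphate topology
#'
#' Discriminates the two isomeric topologies a detected NpnN mass can hide:
#' an internal-bridge cap (N-5'-ppp...p-5'-N) survives electrospray intact,
#' whereas a 5'-terminal polyphosphate dinucleotide (pnNpN, a free
#' polyphosphate tail on an ordinary 5'-5'... phosphodiester dinucleotide)
#' sheds HPO3 units in the ion source. The terminal isomer of an n-phosphate
#' cap carries n-1 terminal phosphates plus one diester phosphate, so its
#' ladder has n-2 successive -HPO3 losses (down to pNpN).
#'
#' @param cap A \code{cap_structure} giving the composition (total phosphate
#'   count \code{n} and nucleosides).
#' @param topology \code{"internal"} (bridge cap, e.g. Gp4G) or
#'   \code{"terminal"} (e.g. p3GpG, the isomer of Gp4G).
#' @return List with \code{topology}, \code{stability} (\code{"stable"} /
#'   \code{"labile"}) and \code{fragments}: a data frame of predicted
#'   in-source fragment ions (empty for stable caps) with columns
#'   \code{label}, \code{formula}, \code{mz} (\code{[M-H]-}), \code{class}.
#' @examples
#' insource_stability(cap_structure("G", "G", 4), "terminal")$stability
#' @export
insource_stability <- function(cap, topology = c("internal", "terminal")) {
  stopifnot(inherits(cap, "cap_structure"))
  if (!is.null(cap$ref)) stop("unknown topology for reference cofactor caps")
  topology <- match.arg(topology)
  parent <- cap_formula(cap)
  if (topology == "internal") {
    frags <- data.frame(label = character(), formula = character(),
                        mz = numeric(), class = character(),
                        stringsAsFactors = FALSE)
    return(list(topology = topology, stability = "stable", fragments = frags))
  }
  if (cap$n < 2) stop("terminal topology needs at least two phosphates")
  hpo3 <- parse_formula("HPO3")
  steps <- max(cap$n - 2L, 1L)  # p2NpN still shows one -HPO3 step
  frags <- lapply(seq_len(steps), function(k) {
    f <- parent
    for (j in seq_len(k)) f <- f - hpo3
    data.frame(label = paste0("p", cap$n - 1L - k, cap$base1, "p", cap$base2),
               formula = format_formula(f),
               mz = mz_of(f, "[M-H]-"),
               class = "in-source", stringsAsFactors = FALSE)
  })
  list(topology = topology, stability = "labile",
       fragments = do.call(rbind, frags))
}

#' Predict MS2/MS3 fragments of an internal-bridge cap
#'
#' Rule-based library restricted to the cleavages used as structural
#' evidence: phosphoester bond breaks along the bridge yielding, for each
#' side, the mono-, di- and tri-phosphorylated nucleoside (bounded by the
#' bridge length) with and without water loss. Methyl tags stay with their
#' nucleoside, so a methylated side yields methylated fragments.
#'
#' @param cap A \code{cap_structure} (internal-bridge topology).
#' @param polarity Only \code{"negative"} is modelled; fragment m/z are
#'   \code{[M-H]-}.
#' @return Data frame: \code{side} (1 or 2), \code{base}, \code{label}
#'   (e.g. \code{"ATP-H2O"}), \code{formula}, \code{mz}, \code{class}.
#' @examples
#' fr <- predict_msn_fragments(cap_structure("A", "A", 3))
#' fr[fr$label == "ATP-H2O", "mz"]  # ~ 487.98, the printed 487.8 selection
#' @export
predict_msn_fragments <- function(cap, polarity = "negative") {
  stopifnot(inherits(cap, "cap_structure"))
  polarity <- match.arg(polarity, "negative")
  if (!is.null(cap$ref)) stop("fragment rules are defined for NpnN caps only")
  hpo3 <- parse_formula("HPO3")
  water <- parse_formula("H2O")
  sides <- list(list(side = 1L, base = cap$base1, methyls = cap$methyl1),
                list(side = 2L, base = cap$base2, methyls = cap$methyl2))
  pref <- c("1" = "M", "2" = "D", "3" = "T")  # NMP/NDP/NTP naming
  rows <- list()
  for (s in sides) {
    nuc <- nucleoside_formula(s$base)
    if (s$methyls > 0)
      nuc <- nuc + mol_formula(c(C = s$methyls, H = 2L * s$methyls))
    mtag <- if (s$methyls == 0) "" else if (s$methyls == 1) "m" else
      paste0(s$methyls, "m")
    for (k in seq_len(min(cap$n, 3L))) {
      f <- nuc
      for (j in seq_len(k)) f <- f + hpo3
      base_label <- paste0(mtag, s$base, pref[[as.character(k)]], "P")
      rows[[length(rows) + 1L]] <- data.frame(
        side = s$side, base = s$base, label = base_label,
        formula = format_formula(f), mz = mz_of(f, "[M-H]-"),
        class = "MS2/MS3", stringsAsFactors = FALSE)
      fd <- f - water
      rows[[length(rows) + 1L]] <- data.frame(
        side = s$side, base = s$base, label = paste0(base_label, "-H2O"),
        formula = format_formula(fd), mz = mz_of(fd, "[M-H]-"),
        class = "MS2/MS3", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export fragment predictions as TSV
#' @param predictions Data frame from [predict_msn_fragments()] or the
#'   \code{fragments} element of [insource_stability()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
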