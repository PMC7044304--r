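#' Enumerate a candidate cap ion library
#'
#' Builds the theoretical search space of NpnN caps: every unordered
#' nucleobase pair from \code{bases}, every bridge length in \code{n_range},
#' every total methyl count up to \code{max_methyls} (mass-distinct
#' compositions; positions are unresolved at the survey stage), each paired
#' with every requested ion species, in both natural and fully-15N label
#' states. Optionally appends the NAD and CoA cofactor caps.
#'
#' @param bases Character vector of nucleobases; default purines only, which
#'   is the space the detected species occupy (widen to include C/U with
#'   \code{bases = c("A","G","C","U")}).
#' @param n_range Integer vector of phosphate-bridge lengths, subset of 2:6.
#' @param max_methyls Maximum total methyl count (0 to 4).
#' @param ions List of \code{ion_spec}s or adduct strings; defaults to the
#'   negative-mode species caps present as: \code{[M-H]-} and \code{[M-2H]2-}.
#' @param include_refs Append NAD and CoA entries?
#' @return A data frame of class \code{cap_library}, one row per
#'   (cap, label, ion): columns \code{cap_id}, \code{base1}, \code{base2},
#'   \code{n}, \code{methyls}, \code{formula}, \code{n_nitrogen},
#'   \code{label}, \code{adduct}, \code{z}, \code{mz}. Ordered by ascending
#'   neutral mass, then label, then adduct.
#' @examples
#' lib <- enumerate_candidates(bases = c("A", "G"), n_range = 3:6,
#'                             max_methyls = 0)
#' length(unique(lib$cap_id))  # 12 structures
#' @export
enumerate_candidates <- function(bases = c("A", "G"),
                                 n_range = 2:6,
                                 max_methyls = 2,
                                 ions = list("[M-H]-", "[M-2H]2-"),
                                 include_refs = FALSE) {
  if (!length(bases)) stop("base set must not be empty")
  bases <- sort(unique(match.arg(bases, c("A", "G", "C", "U"),
                                 several.ok = TRUE)))
  stopifnot(all(n_range %in% 2:6), max_methyls >= 0, max_methyls <= 4)
  ions <- lapply(ions, function(i) if (is.character(i)) ion_spec(i) else i)

  caps <- list()
  for (i in seq_along(bases)) {
    for (j in i:length(bases)) {
      for (n in sort(unique(as.integer(n_range)))) {
        for (k in 0:max_methyls) {
          m1 <- min(k, 2L)
          caps[[length(caps) + 1L]] <-
            cap_structure(bases[i], bases[j], n,
                          methyl1 = m1, methyl2 = k - m1)
        }
      }
    }
  }
  if (include_refs) {
    caps <- c(caps, list(cap_structure(ref = "NAD"), cap_structure(ref = "CoA")))
  }

  rows <- lapply(caps, function(cap) {
    f <- cap_formula(cap)
    f15 <- apply_15n(f)$formula
    per_label <- lapply(list(`14N` = f, `15N` = f15), function(ff) {
      do.call(rbind, lapply(ions, function(io) {
        data.frame(cap_id = cap$id,
                   base1 = if (is.null(cap$ref)) cap$base1 else NA_character_,
                   base2 = if (is.null(cap$ref)) cap$base2 else NA_character_,
                   n = if (is.null(cap$ref)) cap$n else NA_integer_,
                   methyls = if (is.null(cap$ref)) cap$methyl1 + cap$methyl2 else 0L,
                   formula = format_formula(f),
                   n_nitrogen = nitrogen_count(f),
                   neutral_mass = monoisotopic_mass(ff),
                   adduct = io$adduct, z = io$z,
                   mz = mz_of(ff, io),
                   stringsAsFactors = FALSE)
      }))
    })
    out <- rbind(cbind(per_label[["14N"]], label = "14N"),
                 cbind(per_label[["15N"]], label = "15N"))
    out
  })
  lib <- do.call(rbind, rows)
  stopifnot(all(lib$mz > 0))
  if (anyDuplicated(lib[c("cap_id", "label", "adduct")]))
    stop("duplicate (structure, ion) pairs in library")
  lib <- lib[order(lib$neutral_mass, lib$label, lib$adduct), ]
  rownames(lib) <- NULL
  lib <- lib[c("cap_id", "base1", "base2", "n", "methyls", "formula",
               "n_nitrogen", "label", "adduct", "z", "mz")]
  class(lib) <- c("cap_library", "data.frame")
  lib
}

#' The default cap search library
#'
#' Purine caps with bridge lengths 2..6 and up to two methyl groups, as
#' \code{[M-H]-} and \code{[M-2H]2-} ions, natural and 15N label states,
#' plus NAD and CoA. Covers every cap species reported from digested
#' \emph{E. coli} sRNA.
#'
#' @return A \code{cap_library} data frame.
#' @export
default_cap_library <- function() {
  enumerate_candidates(bases = c("A", "G"), n_range = 2:6, max_methyls = 2,
                       include_refs = TRUE)
}

#' Export / import a cap library as TSV
#'
#' @param lib A \code{cap_library}.
#' @param path File path.
#' @return \code{write_cap_library}: the path, invisibly.
#' @export
write_cap_library <- function(lib, path) {
  stopifnot(inherits(lib, "cap_library"))
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cap_library
#' @return \code{read_cap_library}: a \code{cap_library} data frame.
#' @export
read_cap_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(lib) <- c("cap_library", "data.frame")
  lib
}
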