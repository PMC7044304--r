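#' End-to-end cap discovery from a paired LC-MS experiment
#'
#' Chains the survey stages: annotate the 14N sample run against the
#' candidate library, reject species present in the no-digestion negative
#' control, and confirm survivors by nitrogen counting against the paired
#' 15N run. Evidence is aggregated per cap species: a species is
#' \emph{detected} when at least one of its ions passes the control filter,
#' and \emph{confirmed} when at least one passing ion's inferred nitrogen
#' count matches its formula.
#'
#' @param run14 Sample \code{ms_run}, 14N label.
#' @param run15 Paired \code{ms_run}, 15N label (optional; without it the
#'   confirmation columns are NA).
#' @param control No-digestion control \code{ms_run} (optional).
#' @param lib A \code{cap_library}; defaults to [default_cap_library()].
#' @param tol_ppm,min_intensity,max_control_fraction,tol Stage parameters,
#'   see [match_peaks()], [control_filter()], [infer_nitrogen_count()].
#' @return List with \code{annotations} (ion-level table) and \code{species}
#'   (per-cap summary: \code{cap_id}, \code{n_ions}, \code{detected},
#'   \code{confirmed}, \code{n_nitrogen}, \code{eic_area}).
#' @export
discover_caps <- function(run14, run15 = NULL, control = NULL,
                          lib = default_cap_library(),
                          tol_ppm = 20, min_intensity = 50,
                          max_control_fraction = 0.05, tol = 0.03) {
  if (!is.null(run15)) {
    ann <- pair_runs(run14, run15, lib, tol_ppm, min_intensity, tol)
  } else {
    ann <- match_peaks(run14, lib, tol_ppm, min_intensity)
    if (nrow(ann)) {
      ann$status <- NA_character_
      ann$expected_n <- NA_integer_
      ann$n_nitrogen <- NA_integer_
    }
  }
  if (!is.null(control) && nrow(ann))
    ann <- control_filter(ann, control, run14, max_control_fraction, tol_ppm)
  if (!nrow(ann)) {
    species <- data.frame(cap_id = character(), n_ions = integer(),
                          detected = logical(), confirmed = logical(),
                          n_nitrogen = integer(), eic_area = numeric(),
                          stringsAsFactors = FALSE)
    return(list(annotations = ann, species = species))
  }
  species <- do.call(rbind, lapply(split(ann, ann$cap_id), function(g) {
    ok <- g[g$accepted, , drop = FALSE]
    conf <- ok[!is.na(ok$status) & ok$status == "confirmed" &
                 ok$n_nitrogen == ok$expected_n, , drop = FALSE]
    data.frame(cap_id = g$cap_id[1], n_ions = nrow(g),
               detected = nrow(ok) > 0,
               confirmed = nrow(conf) > 0,
               n_nitrogen = if (nrow(conf)) conf$n_nitrogen[1] else NA_integer_,
               eic_area = if (nrow(ok)) max(ok$eic_area) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(species) <- NULL
  list(annotations = ann, species = species)
}
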