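#' A centroided LC-MS run
#'
#' Container for one centroided peak list with its experimental context:
#' isotope label (14N or 15N growth), growth condition, and whether the run
#' is a digestion negative control (same workup without nuclease, so any
#' signal it shares with the sample is non-covalently bound contamination).
#'
#' @param peaks Data frame with numeric columns \code{mz}, \code{intensity},
#'   \code{rt} (retention time, min). Sorted by m/z on construction.
#' @param label \code{"14N"} or \code{"15N"}.
#' @param condition Free-form condition tag (e.g. \code{"EXP"}, \code{"STA"}).
#' @param control Logical; TRUE for a no-digestion negative control.
#' @param metadata Optional named list (seed, instrument tag, ...).
#' @return Object of class \code{ms_run}.
#' @export
ms_run <- function(peaks, label = "14N", condition = "EXP",
                   control = FALSE, metadata = list()) {
  label <- match.arg(label, c("14N", "15N"))
  stopifnot(is.data.frame(peaks),
            all(c("mz", "intensity", "rt") %in% names(peaks)))
  peaks <- peaks[c("mz", "intensity", "rt")]
  if (nrow(peaks)) {
    stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0))
    peaks <- peaks[order(peaks$mz), ]
    rownames(peaks) <- NULL
  }
  structure(list(peaks = peaks, label = label, condition = condition,
                 control = isTRUE(control), metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat("<ms_run> ", nrow(x$peaks), " peaks, label ", x$label,
      ", condition ", x$condition,
      if (x$control) " [negative control]", "\n", sep = "")
  invisible(x)
}

#' Read / write a peak-list CSV
#'
#' Dialect: UTF-8 CSV with header \code{mz,intensity,rt}, one centroided
#' peak per row.
#'
#' @param path File path.
#' @param ... Passed to [ms_run()] (label, condition, control, metadata).
#' @return \code{read_peak_csv}: an \code{ms_run}.
#' @export
read_peak_csv <- function(path, ...) {
  ms_run(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @rdname read_peak_csv
#' @param run An \code{ms_run}.
#' @return \code{write_peak_csv}: the path, invisibly.
#' @export
write_peak_csv <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  utils::write.csv(run$peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative mass error in parts per million
#' @param observed,theoretical m/z values (Th).
#' @return Signed ppm error \code{(observed - theoretical)/theoretical * 1e6}.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Match a peak list against a candidate library
#'
#' Each library ion (of the run's label state) is assigned the single peak
#' minimising |ppm error| within \code{tol_ppm}, considering only peaks at
#' or above \code{min_intensity}; ties in |ppm| go to the more intense peak.
#' Unmatched ions are absent from the output. A peak may serve several ions
#' (isobars are resolved downstream by 15N pairing and fragmentation). The
#' EIC area over the full run at the theoretical m/z is attached.
#'
#' @param run An \code{ms_run}.
#' @param lib A \code{cap_library}.
#' @param tol_ppm Match tolerance in ppm (> 0). The default 20 ppm covers
#'   the spread between printed detections and theory across instruments.
#' @param min_intensity Minimum peak intensity in counts; ions below this
#'   are not considered (survey default 50 counts).
#' @return Data frame of annotations: \code{cap_id}, \code{adduct}, \code{z},
#'   \code{theoretical_mz}, \code{observed_mz}, \code{ppm}, \code{intensity},
#'   \code{eic_area}, \code{accepted} (TRUE until a control filter runs).
#' @export
match_peaks <- function(run, lib, tol_ppm = 20, min_intensity = 50) {
  stopifnot(inherits(run, "ms_run"), inherits(lib, "cap_library"),
            tol_ppm > 0)
  if (!nrow(run$peaks)) stop("run contains no peaks")
  lib <- lib[lib$label == run$label, , drop = FALSE]
  pk <- run$peaks[run$peaks$intensity >= min_intensity, , drop = FALSE]
  out <- lapply(seq_len(nrow(lib)), function(i) {
    theo <- lib$mz[i]
    err <- ppm_error(pk$mz, theo)
    cand <- which(abs(err) <= tol_ppm)
    if (!length(cand)) return(NULL)
    best <- cand[order(abs(err[cand]), -pk$intensity[cand])][1]
    data.frame(cap_id = lib$cap_id[i], adduct = lib$adduct[i], z = lib$z[i],
               theoretical_mz = theo, observed_mz = pk$mz[best],
               ppm = err[best], intensity = pk$intensity[best],
               eic_area = eic_area(run, theo, tol_ppm),
               accepted = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cap_id = character(), adduct = character(),
                      z = integer(), theoretical_mz = numeric(),
                      observed_mz = numeric(), ppm = numeric(),
                      intensity = numeric(), eic_area = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Extracted-ion chromatogram area
#'
#' Sum of intensities of all peaks within a ppm window around \code{mz},
#' optionally restricted to a retention-time window. With centroided input
#' and no chromatographic profile model, the summed intensity is the EIC
#' area surrogate.
#'
#' @param run An \code{ms_run}.
#' @param mz Target m/z (Th).
#' @param tol_ppm Window half-width in ppm.
#' @param rt_window Optional \code{c(min, max)} in minutes.
#' @return Numeric area (0 when no peak falls in the window).
#' @export
eic_area <- function(run, mz, tol_ppm = 20, rt_window = NULL) {
  stopifnot(inherits(run, "ms_run"), mz > 0)
  pk <- run$peaks
  sel <- abs(ppm_error(pk$mz, mz)) <= tol_ppm
  if (!is.null(rt_window)) {
    stopifnot(length(rt_window) == 2L, rt_window[1] <= rt_window[2])
    sel <- sel & pk$rt >= rt_window[1] & pk$rt <= rt_window[2]
  }
  sum(pk$intensity[sel])
}

#' Digestion-negative-control filter
#'
#' An annotation is accepted only when the control run's EIC area at the
#' same m/z is at most \code{max_control_fraction} of the sample area: a
#' species present without nuclease digestion is non-covalently bound
#' contamination, not a cap. Rejected annotations are retained with
#' \code{accepted = FALSE}.
#'
#' @param annotations Annotation data frame from [match_peaks()].
#' @param control_run The paired no-digestion \code{ms_run}
#'   (\code{control = TRUE}, same condition as the sample).
#' @param sample_run The sample \code{ms_run} the annotations came from
#'   (used to check condition pairing).
#' @param max_control_fraction Acceptance threshold on control/sample area
#'   ratio; default 0.05 absorbs the noise floor under the reported
#'   "no signal in controls" regime.
#' @param tol_ppm ppm window for the control EIC.
#' @return The annotation data frame with updated \code{accepted} and new
#'   \code{control_area} column.
#' @export
control_filter <- function(annotations, control_run, sample_run = NULL,
                           max_control_fraction = 0.05, tol_ppm = 20) {
  stopifnot(inherits(control_run, "ms_run"))
  if (!control_run$control)
    stop("control_run is not flagged as a negative control")
  if (!is.null(sample_run) &&
      !identical(sample_run$condition, control_run$condition))
    stop("sample and control runs have mismatched conditions")
  if (!nrow(annotations)) {
    annotations$control_area <- numeric(0)
    return(annotations)
  }
  ctrl <- vapply(annotations$theoretical_mz, function(mz)
    eic_area(control_run, mz, tol_ppm), numeric(1))
  annotations$control_area <- ctrl
  annotations$accepted <- annotations$accepted &
    (ctrl <= max_control_fraction * annotations$eic_area)
  annotations
}

#' Export annotations
#'
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(annotations, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
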