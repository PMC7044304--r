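#' Count nitrogens from a 14N/15N m/z pair
#'
#' Under full metabolic 15N substitution every nitrogen adds 0.9970349 Da to
#' the molecule, so the m/z shift between matched 14N- and 15N-grown runs,
#' multiplied by the charge, counts the nitrogens:
#' \code{N = round((mz15 - mz14) * z / 0.9970349)}. The residual between the
#' observed shift and the nearest integer hypothesis flags inconsistent
#' pairs (including charge misassignment: a true z = 2 species evaluated at
#' z = 1 leaves a residual far above tolerance).
#'
#' @param mz14,mz15 Observed m/z in the 14N and 15N runs (Th);
#'   \code{mz15 > mz14} required.
#' @param z Charge magnitude (1 or 2).
#' @param tol Acceptance residual in Da; default 0.03 separates the N and
#'   N±1 hypotheses decisively at these masses.
#' @param species_id Optional identifier carried into the result.
#' @return A one-row data frame (\code{isotope_pair} result): \code{species_id},
#'   \code{mz14}, \code{mz15}, \code{z}, \code{n_nitrogen}, \code{residual},
#'   \code{accepted}.
#' @examples
#' infer_nitrogen_count(771.065, 781.051, z = 1)$n_nitrogen  # 10
#' @export
infer_nitrogen_count <- function(mz14, mz15, z = 1L, tol = 0.03,
                                 species_id = NA_character_) {
  stopifnot(z %in% c(1L, 2L))
  if (mz15 < mz14) stop("negative label shift: mz15 must be >= mz14")
  shift <- (mz15 - mz14) * z
  n <- as.integer(round(shift / delta_15n()))
  residual <- abs(shift - n * delta_15n())
  data.frame(species_id = species_id, mz14 = mz14, mz15 = mz15,
             z = as.integer(z), n_nitrogen = n, residual = residual,
             accepted = residual <= tol, stringsAsFactors = FALSE)
}

#' Pair 14N and 15N runs and count nitrogens per candidate
#'
#' Annotates the 14N run against the library, then searches the 15N run at
#' each candidate's predicted fully-labelled m/z. For every candidate found
#' in both runs the nitrogen count is inferred from the observed shift at
#' the library's charge state; candidates whose predicted 15N peak is
#' missing are reported with status \code{"not confirmed"}.
#'
#' @param run14,run15 \code{ms_run}s with labels \code{"14N"} and
#'   \code{"15N"}, same condition.
#' @param lib A \code{cap_library} containing both label states.
#' @param tol_ppm Match tolerance (ppm).
#' @param min_intensity Minimum peak intensity (counts).
#' @param tol Residual tolerance (Da) passed to [infer_nitrogen_count()].
#' @return Data frame with one row per 14N-annotated candidate ion:
#'   annotation columns plus \code{predicted_mz15}, \code{observed_mz15},
#'   \code{n_nitrogen}, \code{expected_n}, \code{residual}, \code{status}
#'   (\code{"confirmed"} / \code{"not confirmed"} / \code{"inconsistent"}).
#' @export
pair_runs <- function(run14, run15, lib, tol_ppm = 20, min_intensity = 50,
                      tol = 0.03) {
  stopifnot(inherits(run14, "ms_run"), inherits(run15, "ms_run"))
  if (!identical(run14$label, "14N") || !identical(run15$label, "15N"))
    stop("runs must carry labels 14N and 15N respectively")
  if (!identical(run14$condition, run15$condition))
    stop("paired runs must share their condition")
  ann <- match_peaks(run14, lib, tol_ppm, min_intensity)
  if (!nrow(ann)) {
    ann$predicted_mz15 <- ann$observed_mz15 <- numeric(0)
    ann$n_nitrogen <- integer(0)
    ann$expected_n <- integer(0)
    ann$residual <- numeric(0)
    ann$status <- character(0)
    return(ann)
  }
  lib15 <- lib[lib$label == "15N", , drop = FALSE]
  lib14 <- lib[lib$label == "14N", , drop = FALSE]
  pk15 <- run15$peaks[run15$peaks$intensity >= min_intensity, , drop = FALSE]
  res <- lapply(seq_len(nrow(ann)), function(i) {
    key <- lib15$cap_id == ann$cap_id[i] & lib15$adduct == ann$adduct[i]
    pred <- lib15$mz[key][1]
    expn <- lib14$n_nitrogen[lib14$cap_id == ann$cap_id[i] &
                               lib14$adduct == ann$adduct[i]][1]
    row <- ann[i, ]
    row$predicted_mz15 <- pred
    err <- ppm_error(pk15$mz, pred)
    cand <- which(abs(err) <= tol_ppm)
    if (!length(cand)) {
      row$observed_mz15 <- NA_real_
      row$n_nitrogen <- NA_integer_
      row$expected_n <- expn
      row$residual <- NA_real_
      row$status <- "not confirmed"
      return(row)
    }
    best <- cand[order(abs(err[cand]), -pk15$intensity[cand])][1]
    ipr <- infer_nitrogen_count(row$observed_mz, pk15$mz[best],
                                z = row$z, tol = tol,
                                species_id = row$cap_id)
    row$observed_mz15 <- pk15$mz[best]
    row$n_nitrogen <- ipr$n_nitrogen
    row$expected_n <- expn
    row$residual <- ipr$residual
    row$status <- if (ipr$accepted) "confirmed" else "inconsistent"
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
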