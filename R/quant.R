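#' Percent capped RNA from gel densitometry
#'
#' From integrated band areas of the uncapped (5'-ppp / 5'-p) and capped RNA
#' bands: \code{Ar_cap / (Ar_p + Ar_cap) * 100}. Bounded in \[0, 100\] and
#' invariant under common rescaling of both areas.
#'
#' @param ar_p Area of the uncapped band (>= 0).
#' @param ar_cap Area of the capped band (>= 0).
#' @return Percentage of capped RNA.
#' @examples
#' percent_capped(30, 70)  # 70
#' @export
percent_capped <- function(ar_p, ar_cap) {
  stopifnot(ar_p >= 0, ar_cap >= 0)
  if (ar_p + ar_cap == 0) stop("both band areas are zero")
  ar_cap / (ar_p + ar_cap) * 100
}

#' Standard-addition quantification
#'
#' Fits the spiked-response line y = a x + b by ordinary least squares and
#' reports the analyte amount as the magnitude of the x-intercept,
#' c0 = b / a, in the units of the spike axis (e.g. fmol per ug sRNA). The
#' confidence interval comes from first-order propagation of the (a, b)
#' covariance onto b / a.
#'
#' @param spike Spike amounts x (>= 3 distinct levels; include 0 for the
#'   unspiked aliquot).
#' @param area EIC areas y at each spike level.
#' @param conf Confidence level for the interval.
#' @return List: \code{slope}, \code{intercept}, \code{c0}, \code{se}
#'   (standard error of c0), \code{ci} (two-sided interval), \code{fit}
#'   (the underlying \code{lm}).
#' @examples
#' standard_addition(c(0, 1, 2, 4), c(2, 4, 6, 10))$c0  # exactly 1
#' @export
standard_addition <- function(spike, area, conf = 0.95) {
  stopifnot(length(spike) == length(area))
  if (length(unique(spike)) < 3) stop("need at least 3 distinct spike levels")
  fit <- stats::lm(area ~ spike)
  b <- unname(stats::coef(fit)[1])
  a <- unname(stats::coef(fit)[2])
  if (a <= 0) stop("no response: fitted slope is not positive")
  if (b < 0) stop("below blank: fitted intercept is negative")
  c0 <- b / a
  # noiseless series are legitimate input; silence the perfect-fit notice
  V <- suppressWarnings(stats::vcov(fit))
  # delta method on g(a,b) = b/a: grad = (db, da) -> (1/a, -b/a^2)
  g <- c(1 / a, -b / a^2)          # order: (intercept, slope)
  se <- sqrt(drop(t(g) %*% V %*% g))
  tq <- stats::qt(1 - (1 - conf) / 2, df = stats::df.residual(fit))
  list(slope = a, intercept = b, c0 = c0, se = se,
       ci = c(c0 - tq * se, c0 + tq * se), fit = fit)
}

#' Relative abundance between two conditions
#'
#' Fold change of EIC areas between conditions (e.g. stationary vs
#' exponential growth). With replicate vectors both conventions are
#' reported, since a ratio of triplicate means and a mean of per-replicate
#' ratios need not agree.
#'
#' @param area_a Area(s) in the reference condition (denominator).
#' @param area_b Area(s) in the comparison condition (numerator).
#' @return List: \code{fold} (ratio of means), and when both vectors have
#'   equal length > 1, \code{fold_paired} with \code{mean} and \code{sd}
#'   of per-replicate ratios.
#' @examples
#' relative_abundance(c(1, 1, 1), c(2, 2, 2))$fold  # 2
#' @export
relative_abundance <- function(area_a, area_b) {
  stopifnot(all(area_a > 0), all(area_b > 0))
  out <- list(fold = mean(area_b) / mean(area_a))
  if (length(area_a) == length(area_b) && length(area_a) > 1) {
    r <- area_b / area_a
    out$fold_paired <- list(mean = mean(r), sd = stats::sd(r))
  }
  out
}

#' Classify a cap's decapping-enzyme sensitivity
#'
#' Two-enzyme truth table from before/after EIC areas: an enzyme counts as
#' cleaving when the fractional area loss reaches \code{threshold}.
#' RppH-sensitive caps are unmethylated; the methylated-cap signature is
#' RppH resistance with ApaH sensitivity; resistance to both indicates no
#' cap turnover by either enzyme.
#'
#' @param before EIC area before treatment (> 0).
#' @param after_rpph,after_apah Areas after 1 h of each enzyme.
#' @param threshold Cleaved fraction defining sensitivity; the default 0.5
#'   sits far from both the "completely cleaved" and the "remained
#'   unchanged" regimes.
#' @param species_id Optional identifier.
#' @return One-row data frame: \code{species_id}, \code{before},
#'   \code{after_rpph}, \code{after_apah}, \code{cleaved_rpph},
#'   \code{cleaved_apah} (fractions), \code{class} in
#'   \code{{"RppH-sensitive", "RppH-resistant/ApaH-sensitive",
#'   "resistant-to-both"}}.
#' @examples
#' classify_decapping(100, 98, 3)$class  # methylated-cap signature
#' @export
classify_decapping <- function(before, after_rpph, after_apah,
                               threshold = 0.5, species_id = NA_character_) {
  stopifnot(before > 0, after_rpph >= 0, after_apah >= 0,
            threshold > 0, threshold <= 1)
  cr <- (before - after_rpph) / before
  ca <- (before - after_apah) / before
  cls <- if (cr >= threshold) "RppH-sensitive"
         else if (ca >= threshold) "RppH-resistant/ApaH-sensitive"
         else "resistant-to-both"
  data.frame(species_id = species_id, before = before,
             after_rpph = after_rpph, after_apah = after_apah,
             cleaved_rpph = cr, cleaved_apah = ca, class = cls,
             stringsAsFactors = FALSE)
}

#' Normalised cleavage kinetics and first-order rate
#'
#' Normalises band areas to the zero-minute aliquot (100%) and fits a
#' single-exponential decay by least squares on the log of the remaining
#' fraction (positive points only). The normalised curve is the primary
#' output; the rate is a convenience summary.
#'
#' @param time Time points in minutes, strictly increasing, including 0.
#' @param area Band areas at each time point; area at t = 0 must be > 0.
#' @return List: \code{curve} (data frame \code{time}, \code{area},
#'   \code{percent_remaining}), \code{k} (first-order rate, 1/min; 0 for a
#'   flat series), \code{half_life} (ln 2 / k, Inf when k = 0).
#' @examples
#' kinetics_curve(c(0, 1, 2, 4), 100 * exp(-0.3 * c(0, 1, 2, 4)))$k
#' @export
kinetics_curve <- function(time, area) {
  stopifnot(length(time) == length(area), length(time) >= 2)
  if (is.unsorted(time, strictly = TRUE)) stop("times must strictly increase")
  if (time[1] != 0) stop("series must include t = 0")
  if (area[1] <= 0) stop("area at t = 0 must be positive")
  pct <- area / area[1] * 100
  curve <- data.frame(time = time, area = area, percent_remaining = pct)
  pos <- pct > 0
  if (sum(pos) >= 2 && stats::var(log(pct[pos])) > 0) {
    fit <- stats::lm(log(pct[pos] / 100) ~ time[pos])
    k <- max(-unname(stats::coef(fit)[2]), 0)
  } else {
    k <- 0
  }
  list(curve = curve, k = k, half_life = if (k > 0) log(2) / k else Inf)
}
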