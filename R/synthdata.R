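# run code under a local RNG state so generators are pure in (config, seed)
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for the synthetic LC-MS and assay generator
#'
#' Fixes every parameter of the emulated experiment: which caps are present
#' and at what abundance, the instrument mass-error regime, the shared
#' contamination background, and the true values behind each quantitative
#' assay. Defaults mirror the exponential-phase study conditions: the six
#' caps detected in EXP-phase sRNA, 3 ppm mass noise (high-resolution
#' instrument regime), dominant mononucleotide digestion products, and
#' assay truths at the reported concentration scales (75, 1200 and 1900
#' fmol per ug sRNA), the reported kinetics time grid, and the
#' methylation-dependent decapping truth table.
#'
#' @param caps List of \code{cap_structure}s present in the sample.
#' @param abundances Median peak intensities (counts) per cap, recycled.
#' @param abundance_sdlog Log-normal spread of cap peak intensities.
#' @param ppm_sigma Gaussian m/z error, ppm.
#' @param n_background Number of uniform background (contaminant) peaks
#'   shared between sample and no-digestion control.
#' @param background_mz_range m/z range of background peaks (Th).
#' @param background_mean_intensity Mean of their exponential intensities.
#' @param mononucleotide_intensity Median intensity of the dominant
#'   AMP/GMP/CMP/UMP digestion peaks.
#' @param condition Condition tag for generated runs.
#' @param area_cv Multiplicative (log-normal) noise level on assay areas.
#' @param c0 Named true concentrations for standard addition (spike units).
#' @param sa_slope True response slope (area per spike unit).
#' @param kinetics Data frame \code{species}, \code{enzyme}, \code{k}
#'   (1/min) of true first-order cleavage rates.
#' @param kinetics_time Sampling grid in minutes.
#' @param decapping Data frame \code{species}, \code{rpph_cleaves},
#'   \code{apah_cleaves} (logical truth table).
#' @param gel_fractions Named true capped fractions for gel lanes.
#' @param fold_sta_exp True STA/EXP abundance ratio for relative
#'   quantification.
#' @return List of class \code{synth_truth}.
#' @export
synth_truth <- function(
    caps = list(
      cap_structure("A", "A", 3),
      cap_structure("A", "A", 3, methyl1 = 1, pos1 = "N6", id = "mAp3A"),
      cap_structure("A", "G", 3),
      cap_structure("G", "G", 4, methyl1 = 1, methyl2 = 1,
                    pos1 = "N7", pos2 = "2'-O", id = "2mGp4G"),
      cap_structure("A", "A", 5),
      cap_structure("A", "G", 5, methyl1 = 1, id = "mAp5G")),
    abundances = 5e4,
    abundance_sdlog = 0.5,
    ppm_sigma = 3,
    n_background = 150,
    background_mz_range = c(150, 1000),
    background_mean_intensity = 300,
    mononucleotide_intensity = 1e6,
    condition = "EXP",
    area_cv = 0.05,
    c0 = c(Ap3A = 75, Ap3G = 75, Ap5A = 75, `2mGp4G` = 1200, NAD = 1900),
    sa_slope = 50,
    kinetics = data.frame(
      species = c("Ap4A-RNA", "ppp-RNA"),
      enzyme = c("RppH", "RppH"),
      k = c(0.32, log(2) / 40),
      stringsAsFactors = FALSE),
    kinetics_time = c(0, 0.5, 1, 2, 5, 10, 20, 40),
    decapping = data.frame(
      species = c("Gp4G", "2mGp4G", "uncapped-control"),
      rpph_cleaves = c(TRUE, FALSE, FALSE),
      apah_cleaves = c(TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    gel_fractions = c(Ap3A = 0.35, Ap4G = 0.46, Ap6A = 0.27),
    fold_sta_exp = 2.5) {
  stopifnot(all(vapply(caps, inherits, logical(1), "cap_structure")),
            ppm_sigma >= 0, n_background >= 0, area_cv >= 0,
            all(abundances > 0))
  structure(list(
    caps = caps,
    abundances = rep_len(abundances, length(caps)),
    abundance_sdlog = abundance_sdlog,
    ppm_sigma = ppm_sigma,
    n_background = as.integer(n_background),
    background_mz_range = background_mz_range,
    background_mean_intensity = background_mean_intensity,
    mononucleotide_intensity = mononucleotide_intensity,
    condition = condition,
    area_cv = area_cv,
    c0 = c0, sa_slope = sa_slope,
    kinetics = kinetics, kinetics_time = kinetics_time,
    decapping = decapping, gel_fractions = gel_fractions,
    fold_sta_exp = fold_sta_exp,
    cap_ids = vapply(caps, function(cp) cp$id, character(1))),
    class = "synth_truth")
}

.mononucleotide_ions <- function() {
  bases <- c("A", "G", "C", "U")
  do.call(rbind, lapply(bases, function(b) {
    f <- nucleoside_formula(b) + parse_formula("HPO3")
    data.frame(base = b, mz = mz_of(f, "[M-H]-"), z = 1L,
               n_nitrogen = nitrogen_count(f), stringsAsFactors = FALSE)
  }))
}

#' Simulate a digested-sRNA LC-MS experiment
#'
#' Emulates the comparative workflow: a nuclease-digested sample run
#' (cap ions with Gaussian ppm mass error and log-normal intensities,
#' dominant mononucleotide peaks, uniform contaminant background), the
#' matched fully-15N-labelled run (every nitrogenous peak shifted by
#' \code{N * 0.9970349 / z}; the nitrogen-free background does not move),
#' and the no-digestion negative control carrying only the shared
#' background. Deterministic given (truth, seed).
#'
#' @param truth A [synth_truth()].
#' @param seed Integer seed.
#' @return List of \code{ms_run}s: \code{sample} (14N), \code{sample15}
#'   (15N), \code{control}, plus \code{ground_truth} (data frame of emitted
#'   cap ions with true m/z and intensity).
#' @export
simulate_run <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  .with_seed(seed, {
    jitter_mz <- function(mz) mz * (1 + stats::rnorm(length(mz), 0,
                                                     truth$ppm_sigma) / 1e6)
    ions <- c("[M-H]-", "[M-2H]2-")
    emitted <- list()
    for (i in seq_along(truth$caps)) {
      cap <- truth$caps[[i]]
      f <- cap_formula(cap)
      f15 <- apply_15n(f)$formula
      inten <- stats::rlnorm(1, log(truth$abundances[i]),
                             truth$abundance_sdlog)
      rt <- stats::runif(1, 1, 15)
      for (io in ions) {
        emitted[[length(emitted) + 1L]] <- data.frame(
          cap_id = cap$id, adduct = io,
          mz14 = mz_of(f, io), mz15 = mz_of(f15, io),
          intensity = inten * stats::runif(1, 0.5, 1),
          rt = rt, stringsAsFactors = FALSE)
      }
    }
    emitted <- do.call(rbind, emitted)
    if (is.null(emitted)) {
      emitted <- data.frame(cap_id = character(), adduct = character(),
                            mz14 = numeric(), mz15 = numeric(),
                            intensity = numeric(), rt = numeric(),
                            stringsAsFactors = FALSE)
    }

    mono <- .mononucleotide_ions()
    mono$intensity <- stats::rlnorm(nrow(mono),
                                    log(truth$mononucleotide_intensity), 0.2)
    mono$rt <- stats::runif(nrow(mono), 1, 15)
    mono$mz15 <- mono$mz + mono$n_nitrogen * delta_15n() / mono$z

    nbg <- truth$n_background
    bg <- data.frame(
      mz = stats::runif(nbg, truth$background_mz_range[1],
                        truth$background_mz_range[2]),
      intensity = stats::rexp(nbg, 1 / truth$background_mean_intensity),
      rt = stats::runif(nbg, 1, 15))

    sample_peaks <- rbind(
      data.frame(mz = jitter_mz(emitted$mz14), intensity = emitted$intensity,
                 rt = emitted$rt),
      data.frame(mz = jitter_mz(mono$mz), intensity = mono$intensity,
                 rt = mono$rt),
      data.frame(mz = jitter_mz(bg$mz),
                 intensity = bg$intensity * stats::rlnorm(nbg, 0, 0.05),
                 rt = bg$rt))
    sample15_peaks <- rbind(
      data.frame(mz = jitter_mz(emitted$mz15),
                 intensity = emitted$intensity * stats::rlnorm(nrow(emitted), 0, 0.1),
                 rt = emitted$rt),
      data.frame(mz = jitter_mz(mono$mz15),
                 intensity = mono$intensity * stats::rlnorm(nrow(mono), 0, 0.1),
                 rt = mono$rt),
      data.frame(mz = jitter_mz(bg$mz),
                 intensity = bg$intensity * stats::rlnorm(nbg, 0, 0.05),
                 rt = bg$rt))
    control_peaks <- data.frame(
      mz = jitter_mz(bg$mz),
      intensity = bg$intensity * stats::rlnorm(nbg, 0, 0.05),
      rt = bg$rt)

    meta <- list(seed = seed, instrument = "synthetic-qtof")
    list(sample = ms_run(sample_peaks, "14N", truth$condition, FALSE, meta),
         sample15 = ms_run(sample15_peaks, "15N", truth$condition, FALSE, meta),
         control = ms_run(control_peaks, "14N", truth$condition, TRUE, meta),
         ground_truth = emitted)
  })
}

#' Simulate the quantitative assay tables
#'
#' Standard-addition series \code{y = a (x + c0) (1 + eps)}, first-order
#' kinetics \code{A(t) = 100 exp(-k t) (1 + eps)} on the configured time
#' grid, decapping before/after areas following the enzyme truth table,
#' gel lanes from the true capped fractions, and replicate EIC areas for
#' the STA/EXP comparison; \code{eps} is multiplicative log-normal noise at
#' \code{truth$area_cv}. Deterministic given (truth, seed).
#'
#' @param truth A [synth_truth()].
#' @param seed Integer seed.
#' @return List of data frames: \code{standard_addition} (\code{species},
#'   \code{spike}, \code{area}), \code{kinetics} (\code{species},
#'   \code{enzyme}, \code{time}, \code{area}), \code{decapping}
#'   (\code{species}, \code{before}, \code{after_rpph}, \code{after_apah}),
#'   \code{gel} (\code{species}, \code{ar_p}, \code{ar_cap}),
#'   \code{relative} (\code{condition}, \code{replicate}, \code{area}).
#' @export
simulate_assays <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  .with_seed(seed, {
    noise <- function(n) stats::rlnorm(n, 0, truth$area_cv)

    sa <- do.call(rbind, lapply(names(truth$c0), function(sp) {
      c0 <- truth$c0[[sp]]
      spike <- c0 * c(0, 0.5, 1, 2)
      data.frame(species = sp, spike = spike,
                 area = truth$sa_slope * (spike + c0) * noise(length(spike)),
                 stringsAsFactors = FALSE)
    }))

    kin <- do.call(rbind, lapply(seq_len(nrow(truth$kinetics)), function(i) {
      tt <- truth$kinetics_time
      a0 <- 1e5
      data.frame(species = truth$kinetics$species[i],
                 enzyme = truth$kinetics$enzyme[i], time = tt,
                 area = a0 * exp(-truth$kinetics$k[i] * tt) * noise(length(tt)),
                 stringsAsFactors = FALSE)
    }))

    dec <- truth$decapping
    before <- 1e5 * noise(nrow(dec))
    # cleavage is near-complete for a true substrate, near-zero otherwise
    remain <- function(cleaves) ifelse(cleaves, 0.03, 0.97)
    dcp <- data.frame(species = dec$species, before = before,
                      after_rpph = before * remain(dec$rpph_cleaves) *
                        noise(nrow(dec)),
                      after_apah = before * remain(dec$apah_cleaves) *
                        noise(nrow(dec)),
                      stringsAsFactors = FALSE)

    total <- 1000
    gel <- data.frame(species = names(truth$gel_fractions),
                      ar_p = total * (1 - truth$gel_fractions) *
                        noise(length(truth$gel_fractions)),
                      ar_cap = total * truth$gel_fractions *
                        noise(length(truth$gel_fractions)),
                      stringsAsFactors = FALSE)
    rownames(gel) <- NULL

    base_area <- 1e4
    rel <- rbind(
      data.frame(condition = "EXP", replicate = 1:3,
                 area = base_area * noise(3)),
      data.frame(condition = "STA", replicate = 1:3,
                 area = base_area * truth$fold_sta_exp * noise(3)))

    list(standard_addition = sa, kinetics = kin, decapping = dcp,
         gel = gel, relative = rel)
  })
}
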