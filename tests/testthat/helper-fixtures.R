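# Printed survey detections (m/z) the default library must explain.
# Observed values come from the published detection tables; adducts are the
# negative-mode species each cap was reported as.
survey_detections <- function() {
  data.frame(
    cap_id = c("Ap3A", "Ap3G", "Ap5A", "mAp3A", "2mGp4G",
               "mAp5G", "mAp4G", "mAp5A", "2mAp5G"),
    adduct = c("[M-H]-", "[M-H]-", "[M-2H]2-", "[M-H]-", "[M-2H]2-",
               "[M-2H]2-", "[M-2H]2-", "[M-2H]2-", "[M-2H]2-"),
    observed = c(755.077, 771.071, 457.009, 769.077, 447.017,
                 472.019, 432.019, 463.992, 479.014),
    stringsAsFactors = FALSE)
}

# independent brute-force mass oracle: hand-kept atomic masses, plain sum
oracle_mass <- function(formula_string) {
  masses <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
              O = 15.9949146196, P = 30.97376163, S = 31.97207100,
              Na = 22.9897692809, Cl = 34.96885268)
  pieces <- regmatches(formula_string,
                       gregexpr("([A-Z][a-z]?)([0-9]*)", formula_string))[[1]]
  syms <- sub("[0-9]*$", "", pieces)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                            sub("^[A-Za-z]+", "", pieces), "1"))
  sum(cnts * masses[syms])
}

random_formula <- function() {
  syms <- c("C", "H", "N", "O", "P", "S", "Na")
  k <- sample(2:5, 1)
  pick <- sample(syms, k)
  mol_formula(stats::setNames(sample(1:30, k, replace = TRUE), pick))
}
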