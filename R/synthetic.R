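#' Packaged fixture structures
#'
#' The versioned SMILES set used throughout the package's examples and
#' tests: the sensitiser fragment BD B10
#' (N-methyl-(5-pyrid-3-ylthien-2-yl)methylamine), the five Akt-inhibitor
#' references (trigonelline, SC66, honokiol, loureirin A, ISC-4), the five
#' natural-metabolite references (tryptamine, N-methylserotonin,
#' protonated serotonin, metanephrine, indol-3-ylacetaldehyde), plus
#' gemcitabine and desipramine. Structures were reconstructed from the
#' compounds' published names/depictions.
#'
#' @param as_molecules Parse the SMILES into `molecule` objects.
#' @return Named character vector of SMILES (or named list of molecules),
#'   with attribute `version`.
#' @export
fixture_structures <- function(as_molecules = FALSE) {
  path <- system.file("extdata", "fixture_structures.smi",
                      package = "fragsens", mustWork = TRUE)
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  smiles <- stats::setNames(vapply(parts, `[`, "", 1L),
                            vapply(parts, `[`, "", 2L))
  out <- if (as_molecules)
    stats::setNames(lapply(names(smiles), function(nm)
      parse_structure(smiles[[nm]], nm)), names(smiles))
  else smiles
  attr(out, "version") <- "1"
  out
}

#' Calibration pairs with printed Tc values
#'
#' The ten reference pairs (BD B10 against each panel member) with the Tc
#' values printed in the source similarity tables, as input for
#' [calibrate_scheme()].
#'
#' @return Data frame with columns `name_a`, `smiles_a`, `name_b`,
#'   `smiles_b`, `printed_tc`, `panel`.
#' @export
calibration_pairs <- function() {
  utils::read.csv(system.file("extdata", "calibration_pairs.csv",
                              package = "fragsens", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# Template pools for the synthetic fragment library. The compliant pool is
# scaffold x substituent x small-substituent; every combination passes the
# default Rule-of-3 thresholds. The non-compliant pool members each violate
# at least one criterion (size, lipophilicity, donors/acceptors, polarity
# or flexibility).
.frag_scaffolds <- c("c1ccc(%s)cc1%s", "c1ccnc(%s)c1%s", "c1cc(%s)oc1%s",
                     "c1cc(%s)sc1%s", "C1CCC(%s)CC1%s")
.frag_subs1 <- c("C", "O", "N", "F", "OC", "CO", "C#N")
.frag_subs2 <- c("C", "F")
.frag_noncompliant <- c(
  "OCC(O)C(O)C(O)C(O)CO",                      # sorbitol: donors
  "CCCCCCCCCCCCCCCC",                          # hexadecane: logP
  "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1",            # p-terphenyl: logP
  "COCCOCCOCCOCCOC",                           # glyme chain: acceptors
  "NC(=N)NCCCC(N)C(=O)O",                      # arginine: donors/polarity
  "CC(C)CC(NC(=O)C(N)CC(C)C)C(=O)O",           # dipeptide: donors
  "Oc1cc(O)c2c(c1)OC(c3ccc(O)c(O)c3)C(O)C2",   # catechin: donors
  "CCCCCCCCCCCC(=O)OCC",                       # fatty ester: logP
  "OC(=O)CCCCCCCCC(=O)O",                      # sebacic acid: flexibility
  "c1ccc2cc3ccccc3cc2c1",                      # anthracene: logP
  "CCCCCCCCCCCCCCCC(=O)OC",                    # palmitate: logP/size
  "OCC1OC(O)C(O)C(O)C1O"                       # pyranose: donors
)

#' Generate a synthetic fragment library
#'
#' Assembles fragment molecules from packaged scaffold/substituent template
#' lists. A fraction `frac_ro3` of the library (in expectation) is drawn
#' from a pool whose every member passes the default Rule-of-3 filter; the
#' rest from a pool whose every member fails it. Deterministic for a fixed
#' seed.
#'
#' @param n Library size.
#' @param frac_ro3 Expected fraction of Rule-of-3-compliant fragments.
#' @param seed Integer seed.
#' @return List of `molecule` objects with ids `frag0001`, ...
#' @export
generate_fragment_library <- function(n, frac_ro3 = 0.5, seed = 1L) {
  stopifnot(n >= 1L, frac_ro3 >= 0, frac_ro3 <= 1)
  with_seed(seed, {
    compliant <- stats::runif(n) < frac_ro3
    smiles <- vapply(compliant, function(ok) {
      if (ok) {
        sprintf(sample(.frag_scaffolds, 1L),
                sample(.frag_subs1, 1L), sample(.frag_subs2, 1L))
      } else {
        sample(.frag_noncompliant, 1L)
      }
    }, character(1))
    lapply(seq_len(n), function(k)
      parse_structure(smiles[k], sprintf("frag%04d", k)))
  })
}

#' Hill-model parameters for synthetic dose-response matrices
#'
#' Defaults emulate a gemcitabine-like viability curve in a pancreatic
#' cancer line (untreated viability 100 %, full kill attainable, EC50
#' 0.3 uM, slope 1.5) with a pure potency-shift sensitiser: the sensitiser
#' multiplies the EC50 by `s(b) = 1 / (1 + rho * b / (b + kb))` and has no
#' intrinsic toxicity. With `rho = 0.15`, `kb = 3` uM the implied
#' dose-sparing at 10 uM sensitiser is about 0.10. An optional hormetic
#' bump adds `hormesis_amp` percentage points at the top drug A dose.
#'
#' @param e0 Untreated viability (percent).
#' @param emax Maximal kill (percentage points).
#' @param ec50 Drug A EC50 in uM (> 0).
#' @param hill Hill slope (> 0).
#' @param rho Sensitiser potency-shift magnitude (>= 0).
#' @param kb Sensitiser half-shift dose in uM.
#' @param hormesis_amp Viability bump at the top dose (percentage points).
#' @param noise_sd Gaussian replicate noise SD (percentage points).
#' @param n_reps Replicates per dose cell.
#' @param seed Integer seed.
#' @return A `hill_params` list.
#' @export
hill_params <- function(e0 = 100, emax = 100, ec50 = 0.3, hill = 1.5,
                        rho = 0.15, kb = 3, hormesis_amp = 0, noise_sd = 3,
                        n_reps = 4L, seed = 1L) {
  stopifnot(ec50 > 0, hill > 0, emax >= 0, emax <= 100, noise_sd >= 0,
            n_reps >= 1L, rho >= 0, kb > 0)
  structure(list(e0 = e0, emax = emax, ec50 = ec50, hill = hill, rho = rho,
                 kb = kb, hormesis_amp = hormesis_amp, noise_sd = noise_sd,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "hill_params")
}

#' The default co-administration dose grids
#'
#' Seven half-log drug A concentrations (0.003-3 uM) and three sensitiser
#' concentrations (3, 10, 30 uM), each with the 0-dose control arm.
#'
#' @return List with `drug_a` and `sensitiser` dose vectors (uM).
#' @export
default_dose_grids <- function() {
  list(drug_a = c(0, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3),
       sensitiser = c(0, 3, 10, 30))
}

# EC50 shift factor s(b) and the sparing it implies at equal effect
hill_shift_factor <- function(p, b) 1 / (1 + p$rho * b / (b + p$kb))

#' True dose-sparing implied by Hill parameters
#'
#' The sensitiser multiplies the EC50 by `s(b)`; at equal effect the
#' drug A dose scales by the same factor, so the true sparing fraction is
#' `1 - s(b)`.
#'
#' @param p A [hill_params()] object.
#' @param b Sensitiser dose in uM.
#' @return Sparing fraction.
#' @export
hill_true_sparing <- function(p, b) 1 - hill_shift_factor(p, b)

#' Mean viability surface of the Hill model
#'
#' `e0 - emax * g^h / (g^h + (ec50 * s(b))^h) + hormesis_amp * [g = top dose]`
#' evaluated over the grid, without noise.
#'
#' @param doses_a,doses_b Dose grids (uM), including 0.
#' @param p A [hill_params()] object.
#' @return Matrix of mean viabilities (percent).
#' @export
hill_mean_viability <- function(doses_a, doses_b, p) {
  g_top <- max(doses_a)
  outer(doses_a, doses_b, function(g, b) {
    s <- hill_shift_factor(p, b)
    eff <- ifelse(g > 0, p$emax * g^p$hill / (g^p$hill + (p$ec50 * s)^p$hill), 0)
    p$e0 - eff + p$hormesis_amp * as.numeric(g == g_top & g > 0)
  })
}

#' Generate a synthetic co-administration dose-response matrix
#'
#' Simulates replicate plate signals from the Hill model of
#' [hill_mean_viability()] with i.i.d. Gaussian replicate noise.
#' Deterministic for a fixed seed (stored in the result's metadata).
#'
#' @param doses_a,doses_b Dose grids (uM) including 0; default the
#'   [default_dose_grids()].
#' @param p A [hill_params()] object.
#' @param cell_line Label for the simulated plate.
#' @return A [dose_response_matrix()] with attributes `hill_params` and
#'   `seed`.
#' @examples
#' m <- generate_dose_response(p = hill_params(noise_sd = 0))
#' normalize_viability(m)
#' @export
generate_dose_response <- function(doses_a = default_dose_grids()$drug_a,
                                   doses_b = default_dose_grids()$sensitiser,
                                   p = hill_params(),
                                   cell_line = "synthetic") {
  stopifnot(inherits(p, "hill_params"))
  mu <- hill_mean_viability(doses_a, doses_b, p)
  sig <- with_seed(p$seed, {
    arr <- array(NA_real_, c(length(doses_a), length(doses_b), p$n_reps))
    for (r in seq_len(p$n_reps))
      arr[, , r] <- mu + matrix(stats::rnorm(length(mu), 0, p$noise_sd),
                                nrow(mu), ncol(mu))
    arr
  })
  m <- dose_response_matrix(doses_a, doses_b, sig, cell_line)
  attr(m, "hill_params") <- p
  attr(m, "seed") <- p$seed
  m
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
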