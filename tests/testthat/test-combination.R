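mk_matrix <- function(means, reps = 2, sem_noise = NULL,
                      doses_a = NULL, doses_b = NULL) {
  # means: matrix doses_a x doses_b of intended signals
  if (is.null(doses_a)) doses_a <- seq(0, nrow(means) - 1)
  if (is.null(doses_b)) doses_b <- seq(0, ncol(means) - 1)
  arr <- array(rep(means, reps), c(nrow(means), ncol(means), reps))
  dose_response_matrix(doses_a, doses_b, arr, "test")
}

test_that("normalisation maps the control to exactly 100 and scales linearly", {
  m <- mk_matrix(matrix(c(1.0, 0.5, 1.0, 0.5), 2, 2))
  v <- normalize_viability(m)
  expect_identical(v$mean_percent[1, 1], 100)
  expect_identical(v$mean_percent[2, 1], 50)

  flat <- normalize_viability(mk_matrix(matrix(3.7, 3, 2)))
  expect_true(all(flat$mean_percent == 100))

  one <- dose_response_matrix(c(0, 1), c(0, 1),
                              array(c(2, 1.76, 2, 1.76), c(2, 2, 1)))
  expect_identical(normalize_viability(one)$mean_percent[2, 1], 88)
})

test_that("normalisation is scale-invariant and validates its control", {
  m <- generate_dose_response(p = hill_params(noise_sd = 2, seed = 9))
  v1 <- normalize_viability(m)
  m2 <- m
  m2$signals <- m$signals * 7.3
  v2 <- normalize_viability(m2)
  expect_equal(v1$mean_percent, v2$mean_percent)
  expect_equal(v1$sem_percent, v2$sem_percent)

  bad <- mk_matrix(matrix(c(0, 1, 1, 1), 2, 2))
  expect_error(normalize_viability(bad), "control-cell mean")
  expect_error(dose_response_matrix(c(0.1, 1), c(0, 1),
                                    array(1, c(2, 2, 1))), "include 0")
})

test_that("zero-noise matrices reproduce the Hill means exactly", {
  p <- hill_params(noise_sd = 0, rho = 0.3)
  m <- generate_dose_response(p = p)
  v <- normalize_viability(m)
  mu <- hill_mean_viability(m$drug_a_doses, m$sensitiser_doses, p)
  expect_equal(v$mean_percent, mu, tolerance = 1e-12)
})

test_that("enhancement delta mirrors the gem-alone vs combo comparison", {
  means <- matrix(100, 3, 2)
  means[2, ] <- c(70, 58)    # drug A dose 1: alone 70 %, combo 58 %
  means[3, ] <- c(40, 45)    # drug A dose 2: combo higher (antagonism)
  v <- normalize_viability(mk_matrix(means))
  expect_equal(enhancement_delta(v, 1, 1), 12)
  expect_identical(enhancement_delta(v, 1, 0), 0)      # sensitiser dose 0
  expect_equal(enhancement_delta(v, 2, 1), -5)         # negative, not clipped
  expect_error(enhancement_delta(v, 0.5, 1), "no drug A dose")
})

test_that("dose sparing recovers constructed potency shifts exactly", {
  doses_a <- c(0, 0.01, 0.03, 0.1, 0.3, 1)
  viab <- c(100, 95, 80, 50, 25, 10)
  # combo column: identical curve -> sparing 0
  means <- cbind(viab, viab)
  v <- normalize_viability(mk_matrix(means, doses_a = doses_a, doses_b = c(0, 10)))
  expect_equal(dose_sparing(v, 10, 60), 0)
  # log-linear curve shifted x0.9 in dose -> sparing exactly 0.10 at any target
  d2 <- c(0, 10^seq(-2, 0, by = 0.5))
  alone <- 95 - 30 * (seq(-2, 0, by = 0.5) + 2)      # 95 ... 35, linear in log10
  combo <- alone + 30 * log10(0.9)                   # same line, doses x0.9
  v3 <- normalize_viability(mk_matrix(cbind(c(100, alone), c(100, combo)),
                                      doses_a = d2, doses_b = c(0, 10)))
  for (target in c(40, 55, 70))
    expect_equal(dose_sparing(v3, 10, target), 0.10, tolerance = 1e-9)
})

test_that("dose sparing errors name the achievable interval and flag hormesis", {
  doses_a <- c(0, 0.01, 0.1, 1)
  v <- normalize_viability(mk_matrix(cbind(c(100, 90, 50, 20), c(100, 88, 48, 18)),
                                     doses_a = doses_a, doses_b = c(0, 10)))
  err <- tryCatch(dose_sparing(v, 10, 95), error = identity)
  expect_match(conditionMessage(err), "achievable interval")
  expect_match(conditionMessage(err), "90")
  # low-dose hormetic rebound: the only segment bracketing the target rises
  horm <- normalize_viability(mk_matrix(cbind(c(100, 40, 60, 20), c(100, 40, 60, 20)),
                                        doses_a = doses_a, doses_b = c(0, 10)))
  expect_error(dose_sparing(horm, 10, 50), "hormesis")
})

test_that("sparing grows monotonically with the potency-shift parameter", {
  rhos <- c(0, 0.05, 0.1, 0.2, 0.4, 0.8)
  est <- vapply(rhos, function(r) {
    v <- normalize_viability(generate_dose_response(
      p = hill_params(noise_sd = 0, rho = r)))
    dose_sparing_profile(v, 10)$sparing
  }, numeric(1))
  expect_equal(est[1], 0, tolerance = 1e-12)
  expect_false(is.unsorted(est))
  truth <- vapply(rhos, function(r) hill_true_sparing(hill_params(rho = r), 10),
                  numeric(1))
  expect_equal(est, truth, tolerance = 0.08)  # interpolation bias only
})

test_that("hormesis detection flags rebounds and stays quiet on clean curves", {
  doses_a <- c(0, 1, 2, 3)
  clean <- normalize_viability(mk_matrix(
    cbind(c(100, 80, 60, 40)), doses_a = doses_a, doses_b = 0))
  expect_false(detect_hormesis(clean, 0)$flag)

  m <- mk_matrix(cbind(c(100, 80, 60, 75)), doses_a = doses_a, doses_b = 0)
  v <- normalize_viability(m)
  v$sem_percent[] <- 1
  res <- detect_hormesis(v, 0)
  expect_true(res$flag)
  expect_identical(nrow(res$locations), 1L)
  expect_identical(res$locations$dose_low, 2)
  expect_identical(res$locations$dose_high, 3)
  # larger k suppresses the call
  expect_false(detect_hormesis(v, 0, k = 20)$flag)
  shallow <- normalize_viability(mk_matrix(
    cbind(c(100, 90)), doses_a = c(0, 1), doses_b = 0))
  expect_error(detect_hormesis(shallow, 0), "at least 3")
})

test_that("the generator's terminal hormetic bump is detected", {
  p <- hill_params(ec50 = 1e-3, emax = 60, hormesis_amp = 15, noise_sd = 3,
                   seed = 4)
  v <- normalize_viability(generate_dose_response(p = p))
  expect_true(detect_hormesis(v, 0)$flag)
  top <- max(v$drug_a_doses)
  expect_true(top %in% detect_hormesis(v, 0)$locations$dose_high)
})

test_that("group comparison matches a sums-of-squares oracle and handles edge cases", {
  const <- compare_groups(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_identical(const$p, 1)
  expect_true(all(const$pairwise$p_adj == 1))

  set.seed(12)
  sep <- compare_groups(list(a = rnorm(10, 0, 0.1), b = rnorm(10, 10, 0.1)))
  expect_lt(sep$p, 1e-6)
  expect_identical(sep$pairwise$stars, "****")

  pg <- split(datasets::PlantGrowth$weight, datasets::PlantGrowth$group)
  res <- compare_groups(pg)
  expect_equal(res$F, oracle_anova_f(pg), tolerance = 1e-6)
  expect_identical(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))

  expect_error(compare_groups(list(a = 1:3)), "at least 2 groups")
  expect_error(compare_groups(list(a = 1:3, b = 2)), "at least 2 replicates")
})

test_that("vehicle dilution arithmetic is exact", {
  expect_identical(dilution_percent(5000), 0.02)
  expect_identical(dilution_percent(c(2, 100)), c(50, 1))
  expect_error(dilution_percent(0))
})
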