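#' Dose-response matrix of replicate viability signals
#'
#' Raw plate readings over a (drug A x sensitiser) concentration grid.
#' Both dose grids must be strictly ascending, non-negative and include 0;
#' the (0, 0) cell is the untreated control. Replicates sit along the
#' third dimension of `signals`; ragged replicate counts are represented
#' by `NA` padding (every cell needs at least one reading).
#'
#' @param drug_a_doses,sensitiser_doses Ascending concentrations in uM,
#'   including 0.
#' @param signals Numeric array `length(drug_a_doses)` x
#'   `length(sensitiser_doses)` x replicates.
#' @param cell_line Label.
#' @return A `dose_response_matrix`.
#' @export
dose_response_matrix <- function(drug_a_doses, sensitiser_doses, signals,
                                 cell_line = "unknown") {
  check_doses <- function(d, what) {
    if (any(d < 0) || any(diff(d) <= 0))
      stop(what, " doses must be non-negative and strictly ascending")
    if (!0 %in% d) stop(what, " doses must include 0 (control)")
  }
  check_doses(drug_a_doses, "drug A")
  check_doses(sensitiser_doses, "sensitiser")
  signals <- as.array(signals)
  if (length(dim(signals)) == 2L)
    dim(signals) <- c(dim(signals), 1L)
  stopifnot(length(dim(signals)) == 3L,
            dim(signals)[1L] == length(drug_a_doses),
            dim(signals)[2L] == length(sensitiser_doses))
  n_ok <- apply(!is.na(signals), c(1L, 2L), sum)
  if (any(n_ok < 1L)) stop("every dose cell needs at least one replicate")
  structure(list(drug_a_doses = as.numeric(drug_a_doses),
                 sensitiser_doses = as.numeric(sensitiser_doses),
                 signals = signals, cell_line = cell_line),
            class = "dose_response_matrix")
}

#' @export
print.dose_response_matrix <- function(x, ...) {
  cat(sprintf("<dose-response matrix> %s: %d x %d doses, up to %d replicates\n",
              x$cell_line, length(x$drug_a_doses), length(x$sensitiser_doses),
              dim(x$signals)[3L]))
  invisible(x)
}

#' Normalise a plate to percent of untreated control
#'
#' Replicates are aggregated first (mean and SEM per dose cell), then every
#' cell is expressed as percent of the control-cell mean, so the untreated
#' control maps to exactly 100 %. SEMs are propagated by the same division.
#'
#' @param m A [dose_response_matrix()].
#' @return A `viability_summary`: matrices `mean_percent`, `sem_percent`,
#'   `n`, plus the dose grids and cell line.
#' @export
normalize_viability <- function(m) {
  stopifnot(inherits(m, "dose_response_matrix"))
  mean_raw <- apply(m$signals, c(1L, 2L), mean, na.rm = TRUE)
  n <- apply(!is.na(m$signals), c(1L, 2L), sum)
  sd_raw <- apply(m$signals, c(1L, 2L), stats::sd, na.rm = TRUE)
  sem_raw <- ifelse(n > 1L, sd_raw / sqrt(n), 0)
  i0 <- match(0, m$drug_a_doses)
  j0 <- match(0, m$sensitiser_doses)
  if (is.na(i0) || is.na(j0)) stop("untreated (0, 0) control cell is missing")
  ctrl <- mean_raw[i0, j0]
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control-cell mean must be positive; got ", format(ctrl))
  structure(list(mean_percent = mean_raw / ctrl * 100,
                 sem_percent = sem_raw / ctrl * 100,
                 n = n,
                 drug_a_doses = m$drug_a_doses,
                 sensitiser_doses = m$sensitiser_doses,
                 cell_line = m$cell_line),
            class = "viability_summary")
}

#' @export
print.viability_summary <- function(x, ...) {
  cat(sprintf("<viability summary> %s (%% of control)\n", x$cell_line))
  tab <- round(x$mean_percent, 1)
  dimnames(tab) <- list(paste0("A=", x$drug_a_doses),
                        paste0("B=", x$sensitiser_doses))
  print(tab)
  invisible(x)
}

dose_index <- function(doses, value, what) {
  k <- which(abs(doses - value) < 1e-9)
  if (!length(k))
    stop("no ", what, " dose ", value, " uM on the grid (",
         paste(doses, collapse = ", "), ")")
  k[1L]
}

#' Sensitiser enhancement at a dose pair
#'
#' The drop in viability attributable to the sensitiser at a given drug-A
#' dose: `viability(dose_a, 0) - viability(dose_a, dose_b)` in percentage
#' points. Positive values mean sensitisation; negative values (antagonism)
#' are reported as-is, not clipped.
#'
#' @param v A `viability_summary`.
#' @param dose_a Drug A dose (uM) present on the grid.
#' @param dose_b Sensitiser dose (uM) present on the grid.
#' @return Percentage points.
#' @export
enhancement_delta <- function(v, dose_a, dose_b) {
  stopifnot(inherits(v, "viability_summary"))
  i <- dose_index(v$drug_a_doses, dose_a, "drug A")
  j <- dose_index(v$sensitiser_doses, dose_b, "sensitiser")
  j0 <- dose_index(v$sensitiser_doses, 0, "sensitiser")
  v$mean_percent[i, j0] - v$mean_percent[i, j]
}

# Dose achieving `target` viability in one sensitiser column, by piecewise
# linear interpolation on log10(dose); the 0-dose anchor is excluded.
interpolate_dose <- function(v, j, target) {
  keep <- v$drug_a_doses > 0
  d <- v$drug_a_doses[keep]
  y <- v$mean_percent[keep, j]
  if (length(d) < 2L) stop("need at least two non-zero drug A doses")
  lo <- min(y); hi <- max(y)
  hit <- NULL
  for (i in seq_len(length(d) - 1L)) {
    if ((y[i] - target) * (y[i + 1L] - target) <= 0) { hit <- i; break }
  }
  if (is.null(hit))
    stop(sprintf(paste0("target viability %.4g%% is outside the achievable ",
                        "interval [%.4g%%, %.4g%%] of this column"),
                 target, lo, hi))
  if (y[hit] < y[hit + 1L])
    stop(sprintf(paste0("viability rises with dose across the segment ",
                        "containing the %.4g%% target (%.4g%% -> %.4g%%); ",
                        "inspect for hormesis (detect_hormesis) before ",
                        "interpolating"), target, y[hit], y[hit + 1L]))
  ld <- log10(d)
  frac <- if (y[hit + 1L] == y[hit]) 0 else
    (target - y[hit]) / (y[hit + 1L] - y[hit])
  10^(ld[hit] + frac * (ld[hit + 1L] - ld[hit]))
}

#' Dose-sparing fraction afforded by a sensitiser
#'
#' Interpolates the drug-A-alone column and the chosen sensitiser column on
#' log10(dose) to find the doses achieving a common target viability, and
#' returns `1 - D_combo / D_alone`: the fraction by which the sensitiser
#' reduces the drug A dose requirement at equal effect.
#'
#' @param v A `viability_summary`.
#' @param sensitiser_dose Sensitiser dose (uM) on the grid.
#' @param target_viability Target viability in percent of control; must be
#'   bracketed by both columns over the non-zero dose range.
#' @return Sparing fraction (0 = no sparing; 0.10 = 10 % dose reduction).
#' @export
dose_sparing <- function(v, sensitiser_dose, target_viability) {
  stopifnot(inherits(v, "viability_summary"))
  j0 <- dose_index(v$sensitiser_doses, 0, "sensitiser")
  j1 <- dose_index(v$sensitiser_doses, sensitiser_dose, "sensitiser")
  d_alone <- interpolate_dose(v, j0, target_viability)
  d_combo <- interpolate_dose(v, j1, target_viability)
  1 - d_combo / d_alone
}

#' Dose-sparing summarised over a target-viability grid
#'
#' [dose_sparing()] at a single target inherits the noise of the two dose
#' cells bracketing that target. Summarising over a grid of targets along
#' the overlapping monotone range of the two columns gives a steadier
#' estimate of the potency shift. Targets that either column cannot reach
#' (or reaches on a rising, hormetic segment) are skipped.
#'
#' @param v A `viability_summary`.
#' @param sensitiser_dose Sensitiser dose (uM) on the grid.
#' @param targets Viability targets in percent.
#' @return List with `sparing` (mean over usable targets), `per_target`
#'   (named vector, NA where a target was unusable) and `n_targets`.
#' @export
dose_sparing_profile <- function(v, sensitiser_dose,
                                 targets = seq(20, 80, by = 5)) {
  per <- vapply(targets, function(tg)
    tryCatch(dose_sparing(v, sensitiser_dose, tg), error = function(e) NA_real_),
    numeric(1))
  names(per) <- targets
  if (all(is.na(per)))
    stop("no target viability is reachable by both columns")
  list(sparing = mean(per, na.rm = TRUE), per_target = per,
       n_targets = sum(!is.na(per)))
}

#' Detect hormesis (biphasic dose response) in one sensitiser column
#'
#' Flags a column when the mean viability at some higher drug A dose
#' exceeds that at a lower dose by more than `k` pooled SEMs
#' (`sqrt(sem_lo^2 + sem_hi^2)`), the signature of an adaptive/hormetic
#' rebound. All ordered dose pairs are examined and every offending pair
#' is reported.
#'
#' @param v A `viability_summary`.
#' @param sensitiser_dose Sensitiser column to examine (uM, on grid).
#' @param k SEM multiplier (default 2).
#' @return List with `flag` and `locations` (data frame of offending
#'   `dose_low`, `dose_high` pairs with their means and the pooled SEM).
#' @export
detect_hormesis <- function(v, sensitiser_dose, k = 2) {
  stopifnot(inherits(v, "viability_summary"))
  j <- dose_index(v$sensitiser_doses, sensitiser_dose, "sensitiser")
  d <- v$drug_a_doses
  if (length(d) < 3L) stop("hormesis detection needs at least 3 dose points")
  y <- v$mean_percent[, j]
  s <- v$sem_percent[, j]
  loc <- list()
  for (i in seq_len(length(d) - 1L)) {
    for (h in (i + 1L):length(d)) {
      pooled <- sqrt(s[i]^2 + s[h]^2)
      if (y[h] > y[i] + k * pooled) {
        loc[[length(loc) + 1L]] <- data.frame(
          dose_low = d[i], dose_high = d[h],
          mean_low = y[i], mean_high = y[h], pooled_sem = pooled)
      }
    }
  }
  locations <- if (length(loc)) do.call(rbind, loc) else
    data.frame(dose_low = numeric(0), dose_high = numeric(0),
               mean_low = numeric(0), mean_high = numeric(0),
               pooled_sem = numeric(0))
  list(flag = length(loc) > 0L, locations = locations)
}

#' One-way ANOVA with Tukey correction across treatment groups
#'
#' Compares replicate sets across two or more treatment groups with
#' `stats::aov` followed by Tukey's HSD, the standard workflow for plate
#' viability comparisons, and attaches the usual significance stars at the
#' 0.05 / 0.01 / 0.001 / 0.0001 levels.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups,
#'   each with >= 2 replicates).
#' @return List with `F`, `p`, and `pairwise` (data frame: comparison,
#'   difference, adjusted p, stars).
#' @export
compare_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 replicates")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  if (stats::var(y) == 0) {
    cmb <- utils::combn(names(groups), 2L)
    pw <- data.frame(comparison = paste(cmb[2L, ], cmb[1L, ], sep = "-"),
                     diff = 0, p_adj = 1, stars = "ns",
                     stringsAsFactors = FALSE)
    return(list(F = 0, p = 1, pairwise = pw))
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1L]]
  tuk <- stats::TukeyHSD(fit)$g
  pw <- data.frame(comparison = rownames(tuk),
                   diff = unname(tuk[, "diff"]),
                   p_adj = unname(tuk[, "p adj"]),
                   stringsAsFactors = FALSE)
  pw$stars <- significance_stars(pw$p_adj)
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L], pairwise = pw)
}

significance_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                   labels = c("****", "***", "**", "*", "ns")))
}

#' Vehicle dilution arithmetic
#'
#' Percent (v/v) of the original stock remaining after an n-fold dilution,
#' e.g. the DMSO load of a compound dosed at a 5000-fold dilution:
#' `dilution_percent(5000)` is 0.02 %.
#'
#' @param fold Dilution factor (> 0).
#' @return Percent v/v.
#' @export
dilution_percent <- function(fold) {
  stopifnot(is.numeric(fold), all(fold > 0))
  100 / fold
}
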