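# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (explicit loops, exhaustive enumeration) so they share
# no code path with the package implementation they check.

# Tanimoto by an explicit per-bit loop.
oracle_tanimoto <- function(bits_a, bits_b) {
  a <- 0L; b <- 0L; c_ <- 0L
  for (k in seq_along(bits_a)) {
    if (bits_a[k] == 1L) a <- a + 1L
    if (bits_b[k] == 1L) b <- b + 1L
    if (bits_a[k] == 1L && bits_b[k] == 1L) c_ <- c_ + 1L
  }
  if (a + b == 0L) return(0)
  c_ / (a + b - c_)
}

# Exhaustive maximum-common-connected-induced-subgraph size: enumerate all
# atom subsets of A from largest down, keep connected ones, and search for
# an induced, label-preserving embedding into B by plain backtracking.
oracle_mcs_size <- function(molA, molB, rules = match_rules()) {
  nA <- n_atoms(molA); nB <- n_atoms(molB)
  ordA <- fragsens:::bond_order_matrix(molA)
  ordB <- fragsens:::bond_order_matrix(molB)
  atom_ok <- outer(seq_len(nA), seq_len(nB), function(i, j) {
    ok <- molA$atoms$element[i] == molB$atoms$element[j]
    if (rules$match_aromatic)
      ok <- ok & (molA$atoms$aromatic[i] == molB$atoms$aromatic[j])
    if (rules$match_charge)
      ok <- ok & (molA$atoms$charge[i] == molB$atoms$charge[j])
    ok
  })
  bond_ok <- function(oa, ob) {
    if (rules$any_bond_order) (oa > 0) == (ob > 0) else oa == ob
  }
  connected <- function(sub) {
    if (length(sub) <= 1L) return(TRUE)
    seen <- sub[1L]
    repeat {
      grow <- unique(c(seen, sub[vapply(sub, function(s)
        any(ordA[s, seen] > 0), logical(1))]))
      if (length(grow) == length(seen)) break
      seen <- grow
    }
    length(seen) == length(sub)
  }
  embeds <- function(sub) {
    assign_next <- function(pos, used, map) {
      if (pos > length(sub)) return(TRUE)
      i <- sub[pos]
      for (j in seq_len(nB)) {
        if (used[j] || !atom_ok[i, j]) next
        ok <- TRUE
        for (q in seq_len(pos - 1L)) {
          if (!bond_ok(ordA[i, sub[q]], ordB[j, map[q]])) { ok <- FALSE; break }
        }
        if (ok) {
          used[j] <- TRUE; map[pos] <- j
          if (assign_next(pos + 1L, used, map)) return(TRUE)
          used[j] <- FALSE
        }
      }
      FALSE
    }
    assign_next(1L, rep(FALSE, nB), integer(length(sub)))
  }
  for (size in seq(min(nA, nB), 1L)) {
    subs <- utils::combn(nA, size)
    for (col in seq_len(ncol(subs))) {
      sub <- subs[, col]
      if (connected(sub) && embeds(sub)) return(size)
    }
  }
  0L
}

# One-way ANOVA F statistic from explicit sums of squares.
oracle_anova_f <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(y) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Small molecules (all <= 12 heavy atoms) used for MCS oracle comparisons.
mcs_fixture_smiles <- c(
  ethanol = "CCO",
  dimethyl_ether = "COC",
  propanal = "CCC=O",
  acetic_acid = "CC(=O)O",
  acetamide = "CC(N)=O",
  isobutane = "CC(C)C",
  benzene = "c1ccccc1",
  pyridine = "c1ccncc1",
  pyrrole = "c1cc[nH]c1",
  furan = "c1ccoc1",
  phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1",
  toluene = "Cc1ccccc1",
  cyclohexane = "C1CCCCC1",
  pyrimidine = "c1cncnc1",
  thiophene = "c1ccsc1"
)

mcs_fixture_molecules <- function() {
  ms <- lapply(names(mcs_fixture_smiles), function(nm)
    parse_structure(mcs_fixture_smiles[[nm]], nm))
  names(ms) <- names(mcs_fixture_smiles)
  ms
}

# Panels mirroring the screening study design, built from the packaged set.
fixture_panels <- function() {
  fx <- fixture_structures(as_molecules = TRUE)
  list(
    b10 = fx$bd_b10,
    inhibitors = reference_panel("akt_inhibitors",
      fx[c("trigonelline", "sc66", "honokiol", "loureirin_a", "isc4")]),
    metabolites = reference_panel("natural_metabolites",
      fx[c("tryptamine", "n_methylserotonin", "serotonin_1plus",
           "metanephrine", "indol3ylacetaldehyde")])
  )
}

random_fingerprint_pair <- function(len, density = NULL) {
  if (is.null(density)) density <- stats::runif(1, 0.05, 0.6)
  list(a = as.integer(stats::runif(len) < density),
       b = as.integer(stats::runif(len) < density))
}
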