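# Thin bridge to OpenBabel (via ChemmineOB) for the standard cheminformatics
# steps that are deliberately not re-implemented here: physico-chemical
# descriptors, fingerprint bit generation, canonical SMILES and SMARTS
# substructure matching. Everything specific to this package (the molecular
# graph, Tc, Ro3 logic, the modular product and MCS) is native code.

ob_for_each <- function(smiles, f) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  txt <- paste0(smiles, " m", seq_along(smiles), "\n", collapse = "")
  out <- ChemmineOB::forEachMol("SMI", txt, f)
  if (length(out) != length(smiles))
    stop("OpenBabel failed to process ", length(smiles) - length(out),
         " of ", length(smiles), " structures")
  out
}

# data frame of OpenBabel descriptors, one row per SMILES
ob_descriptors <- function(smiles) {
  rows <- ob_for_each(smiles, function(m) ChemmineOB::prop_OB(m))
  do.call(rbind, rows)
}

# list of 0/1 integer vectors under an OpenBabel fingerprint name
ob_fingerprints <- function(smiles, ob_name) {
  ob_for_each(smiles, function(m)
    as.integer(ChemmineOB::fingerprint_OB(list(m), ob_name)))
}

# number of unique matches of a SMARTS pattern in each SMILES
ob_smarts_count <- function(smiles, pattern) {
  vapply(
    ob_for_each(smiles, function(m)
      ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE)),
    as.numeric, numeric(1)
  )
}

ob_canonical_smiles <- function(smiles) {
  vapply(ob_for_each(smiles, function(m) ChemmineOB::prop_OB(m)$cansmiNS),
         as.character, character(1))
}
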