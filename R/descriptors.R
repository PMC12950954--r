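#' Physico-chemical descriptors for a molecule
#'
#' Computes the descriptor record used by the Rule-of-3 fragment filter:
#' molecular weight, H-bond donor and acceptor counts, calculated logP,
#' rotatable-bond count and topological polar surface area. Standard
#' descriptor definitions are delegated to OpenBabel; the rotatable-bond
#' count is derived from the package's own molecular graph (acyclic single
#' bonds between two non-terminal heavy atoms).
#'
#' @param mol A `molecule` from [parse_structure()].
#' @return A `descriptor_record`: list with `molecular_weight` (g/mol),
#'   `hbd`, `hba` (counts), `clogp` (unitless), `rotatable_bonds` (count)
#'   and `tpsa` (squared Angstroms).
#' @examples
#' compute_descriptors(parse_structure("O", "water"))
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  descriptor_table(list(mol))[[1L]]
}

# Vectorised descriptor computation over a list of molecules (one OpenBabel
# pass). Returns a list of descriptor_record objects.
descriptor_table <- function(mols) {
  smiles <- vapply(mols, function(m) m$source, character(1))
  d <- ob_descriptors(smiles)
  rotb <- vapply(mols, count_rotatable_bonds, integer(1))
  lapply(seq_along(mols), function(k) {
    structure(list(
      molecular_weight = as.numeric(d$MW[k]),
      hbd = as.integer(d$HBD[k]),
      hba = as.integer(d$HBA1[k]),
      clogp = as.numeric(d$logP[k]),
      rotatable_bonds = rotb[k],
      tpsa = as.numeric(d$TPSA[k])
    ), class = "descriptor_record")
  })
}

# Acyclic, non-aromatic single bonds whose two atoms each carry at least one
# further heavy neighbour. Terminal methyls and ring bonds never rotate.
count_rotatable_bonds <- function(mol) {
  if (!n_bonds(mol)) return(0L)
  deg <- atom_degrees(mol)
  in_ring <- ring_bond_flags(mol)
  sum(mol$bonds$order == 1L & !in_ring &
        deg[mol$bonds$i] >= 2L & deg[mol$bonds$j] >= 2L)
}

#' @export
print.descriptor_record <- function(x, ...) {
  cat(sprintf(paste0("<descriptors> MW %.2f g/mol | cLogP %.2f | HBD %d | ",
                     "HBA %d | RotB %d | TPSA %.1f A^2\n"),
              x$molecular_weight, x$clogp, x$hbd, x$hba,
              x$rotatable_bonds, x$tpsa))
  invisible(x)
}

#' Rule-of-3 thresholds
#'
#' The fragment-library convention: molecular weight at most 300 g/mol,
#' cLogP at most 3, at most 3 H-bond donors, 3 acceptors, 3 rotatable bonds
#' and TPSA at most 60 squared Angstroms. All boundaries are inclusive.
#'
#' @param molecular_weight,clogp,hbd,hba,rotatable_bonds,tpsa Upper limits.
#' @return A named list of thresholds.
#' @export
ro3_thresholds <- function(molecular_weight = 300, clogp = 3, hbd = 3,
                           hba = 3, rotatable_bonds = 3, tpsa = 60) {
  list(molecular_weight = molecular_weight, clogp = clogp, hbd = hbd,
       hba = hba, rotatable_bonds = rotatable_bonds, tpsa = tpsa)
}

#' Rule-of-3 fragment filter
#'
#' Tests a descriptor record against Rule-of-3 thresholds. Every violated
#' criterion is reported, not only the first; a record exactly at a
#' threshold passes (boundaries inclusive).
#'
#' @param rec A `descriptor_record` from [compute_descriptors()].
#' @param thresholds Thresholds from [ro3_thresholds()].
#' @return List with `pass` (logical) and `failed_criteria` (character
#'   vector of violated descriptor names, empty when compliant).
#' @examples
#' rec <- compute_descriptors(parse_structure("c1ccccc1", "benzene"))
#' ro3_filter(rec)
#' @export
ro3_filter <- function(rec, thresholds = ro3_thresholds()) {
  stopifnot(inherits(rec, "descriptor_record"))
  failed <- names(thresholds)[vapply(names(thresholds), function(k)
    isTRUE(rec[[k]] > thresholds[[k]]), logical(1))]
  list(pass = length(failed) == 0L, failed_criteria = failed)
}
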