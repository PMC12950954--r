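#' Supported fingerprint schemes
#'
#' Three standard bit-vector fingerprints are supported, mapped onto
#' OpenBabel generators:
#' \describe{
#'   \item{`structural-keys-166`}{166 MACCS structural keys (default).}
#'   \item{`path-based`}{hashed linear-fragment (path) fingerprint, 1024
#'     bits (OpenBabel FP2, paths up to 7 atoms).}
#'   \item{`circular-r2`}{extended-connectivity circular fingerprint of
#'     radius 2, 4096 bits (ECFP4).}
#' }
#' The screening module can pick among them by calibration against a table
#' of reference similarity values ([calibrate_scheme()]).
#'
#' @return Character vector of scheme identifiers.
#' @export
fingerprint_schemes <- function() {
  c("structural-keys-166", "path-based", "circular-r2")
}

.scheme_ob_name <- c("structural-keys-166" = "MACCS",
                     "path-based" = "FP2",
                     "circular-r2" = "ECFP4")
.scheme_length <- c("structural-keys-166" = 166L,
                    "path-based" = 1024L,
                    "circular-r2" = 4096L)

#' Low-level fingerprint constructor
#'
#' Wraps a 0/1 bit vector as a `fingerprint`. Normally fingerprints come
#' from [compute_fingerprint()]; the constructor exists for tests and for
#' synthetic bit vectors. With `scheme = "custom"` any length is allowed.
#'
#' @param bits Integer/logical vector of 0s and 1s.
#' @param scheme Scheme identifier, or `"custom"`.
#' @return A `fingerprint` object with fields `scheme`, `bits`, `popcount`.
#' @export
fingerprint <- function(bits, scheme = "custom") {
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("fingerprint bits must be 0/1")
  if (scheme != "custom") {
    if (!scheme %in% fingerprint_schemes())
      stop_config("unknown fingerprint scheme '", scheme, "'")
    if (length(bits) != .scheme_length[[scheme]])
      stop("scheme '", scheme, "' requires ", .scheme_length[[scheme]], " bits")
  }
  structure(list(scheme = scheme, bits = bits, popcount = sum(bits)),
            class = "fingerprint")
}

#' Compute a molecular fingerprint
#'
#' Generates the bit-vector fingerprint of a molecule under one of the
#' supported schemes (see [fingerprint_schemes()]). Deterministic: the same
#' molecule (any SMILES spelling of it) always yields the same bits, since
#' bits are derived from the perceived molecular graph.
#'
#' @param mol A `molecule`.
#' @param scheme Scheme identifier.
#' @return A `fingerprint`.
#' @examples
#' fp <- compute_fingerprint(parse_structure("c1ccccc1", "benzene"))
#' fp$popcount
#' @export
compute_fingerprint <- function(mol, scheme = "structural-keys-166") {
  stopifnot(inherits(mol, "molecule"))
  fingerprint_batch(list(mol), scheme)[[1L]]
}

# One OpenBabel pass for a list of molecules.
fingerprint_batch <- function(mols, scheme) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% fingerprint_schemes())
    stop_config("unknown fingerprint scheme '", paste(scheme, collapse = ","), "'")
  smiles <- vapply(mols, function(m) m$source, character(1))
  raw <- ob_fingerprints(smiles, .scheme_ob_name[[scheme]])
  lapply(raw, function(bits) {
    # OpenBabel emits MACCS as a 256-bit block; keys occupy positions 1..166
    bits <- bits[seq_len(.scheme_length[[scheme]])]
    fingerprint(bits, scheme)
  })
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s> %d bits, popcount %d\n",
              x$scheme, length(x$bits), x$popcount))
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' For bit vectors A and B with `a` and `b` set bits and `c` bits in
#' common, Tc = c / (a + b - c). Symmetric, bounded in \[0, 1\], and 1
#' exactly for identical non-empty fingerprints. Two empty fingerprints
#' compare as 0 (with a warning) rather than 0/0.
#'
#' @param fpA,fpB `fingerprint` objects under the same scheme.
#' @return Similarity in \[0, 1\].
#' @examples
#' a <- fingerprint(c(1, 1, 1, 1, 0, 0), scheme = "custom")
#' b <- fingerprint(c(1, 1, 1, 0, 1, 1), scheme = "custom")
#' tanimoto(a, b)  # 3 / (4 + 4 - 3)
#' @export
tanimoto <- function(fpA, fpB) {
  stopifnot(inherits(fpA, "fingerprint"), inherits(fpB, "fingerprint"))
  if (fpA$scheme != fpB$scheme || length(fpA$bits) != length(fpB$bits))
    stop("fingerprints use different schemes ('", fpA$scheme, "' vs '",
         fpB$scheme, "'); Tc is only defined within one scheme")
  a <- fpA$popcount
  b <- fpB$popcount
  if (a + b == 0L) {
    warning("both fingerprints are empty; returning Tc = 0")
    return(0)
  }
  c_ <- sum(bitwAnd(fpA$bits, fpB$bits))
  c_ / (a + b - c_)
}

#' Round a Tanimoto coefficient for reporting
#'
#' Round-half-up to two decimals, the convention used for similarity-panel
#' tables (plain `round()` rounds half to even).
#'
#' @param x Numeric vector in \[0, 1\].
#' @return Rounded values.
#' @export
round_tc <- function(x) floor(x * 100 + 0.5) / 100

stop_config <- function(...) {
  stop(structure(
    class = c("fragsens_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
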