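#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph of a molecule from a SMILES string. Aromaticity
#' is taken as written (lowercase atoms), formal charges are preserved (so a
#' zwitterion such as trigonelline stays a zwitterion), and hydrogens are kept
#' implicit. The graph may be disconnected (salts, mixtures written with `.`).
#'
#' The reader covers the SMILES subset used for small drug-like organic
#' molecules: the organic subset (`B C N O P S F Cl Br I` and aromatic
#' `b c n o p s`), bracket atoms with isotope, two-letter elements, explicit
#' hydrogen counts and formal charges, branches, ring closures (including
#' `%nn`), explicit bond symbols (`- = # :`), directional bonds (`/` and `\`,
#' read as single bonds) and dot-separated components. Tetrahedral `@` marks
#' are accepted and ignored; the graph model is 2D.
#'
#' @param text A single SMILES string.
#' @param id Identifier label stored on the molecule.
#' @return A `molecule` object: list with `id`, `atoms` (data frame with
#'   columns `element`, `charge`, `aromatic`), `bonds` (data frame with
#'   columns `i`, `j`, `order`, where order 4 codes an aromatic bond) and
#'   `source` (the input string).
#' @examples
#' m <- parse_structure("CNCc1ccc(-c2cccnc2)s1", "bd_b10")
#' n_atoms(m)
#' @export
parse_structure <- function(text, id = "mol") {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop_parse("SMILES input must be a single non-empty string", 0L, text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  element <- character(); charge <- integer(); aromatic <- logical()
  bi <- integer(); bj <- integer(); border <- integer()

  prev <- NA_integer_       # atom awaiting the next bond
  pending <- NA_integer_    # explicit bond symbol waiting to be used
  pending_pos <- 0L
  stack <- integer()        # branch return points
  ring_atom <- list()       # open ring closures: label -> atom index
  ring_bond <- list()       # label -> explicit bond order (or NA)

  bond_code <- c("-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L, "/" = 1L, "\\" = 1L)
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  arom1 <- c("b", "c", "n", "o", "p", "s")

  add_atom <- function(el, chg, arom, pos) {
    element[length(element) + 1L] <<- el
    charge[length(charge) + 1L] <<- chg
    aromatic[length(aromatic) + 1L] <<- arom
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (aromatic[prev] && arom) 4L else 1L
      add_bond(prev, idx, ord, pos)
    }
    pending <<- NA_integer_
    prev <<- idx
    invisible(idx)
  }
  add_bond <- function(a, b, ord, pos) {
    if (a == b) stop_parse("bond joins an atom to itself", pos, text)
    lo <- min(a, b); hi <- max(a, b)
    if (any(bi == lo & bj == hi))
      stop_parse("duplicate bond between atoms", pos, text)
    bi[length(bi) + 1L] <<- lo
    bj[length(bj) + 1L] <<- hi
    border[length(border) + 1L] <<- ord
  }
  close_ring <- function(label, pos) {
    if (is.na(prev)) stop_parse("ring closure before any atom", pos, text)
    if (is.null(ring_atom[[label]])) {
      ring_atom[[label]] <<- prev
      ring_bond[[label]] <<- pending
    } else {
      other <- ring_atom[[label]]
      stored <- ring_bond[[label]]
      ord <- pending
      if (!is.na(stored) && !is.na(ord) && stored != ord)
        stop_parse("conflicting bond orders at ring closure", pos, text)
      if (is.na(ord)) ord <- stored
      if (is.na(ord)) ord <- if (aromatic[other] && aromatic[prev]) 4L else 1L
      add_bond(other, prev, ord, pos)
      ring_atom[[label]] <<- NULL
      ring_bond[[label]] <<- NULL
    }
    pending <<- NA_integer_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop_parse("branch opened before any atom", i, text)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop_parse("unmatched closing parenthesis", i, text)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% names(bond_code)) {
      if (!is.na(pending)) stop_parse("two consecutive bond symbols", i, text)
      pending <- bond_code[[ch]]
      pending_pos <- i
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.na(pending)) stop_parse("bond symbol before dot separator", i, text)
      prev <- NA_integer_
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        stop_parse("'%' ring closure needs two digits", i, text)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == "[") {
      close_pos <- i
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > n) stop_parse("unterminated bracket atom", i, text)
      body <- paste0(chars[(i + 1L):(close_pos - 1L)], collapse = "")
      at <- parse_bracket_atom(body, i, text)
      add_atom(at$element, at$charge, at$aromatic, i)
      i <- close_pos + 1L
    } else if (ch %in% c("C", "N", "O", "S", "B", "P", "F", "I")) {
      # two-letter organic-subset halogens first
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, FALSE, i)
        i <- i + 2L
      } else {
        add_atom(ch, 0L, FALSE, i)
        i <- i + 1L
      }
    } else if (ch %in% arom1) {
      add_atom(toupper(ch), 0L, TRUE, i)
      i <- i + 1L
    } else {
      stop_parse(sprintf("unexpected character '%s'", ch), i, text)
    }
  }

  if (!is.na(pending))
    stop_parse("dangling bond symbol at end of string", pending_pos, text)
  if (length(stack)) stop_parse("unclosed branch", n, text)
  if (length(ring_atom))
    stop_parse(sprintf("unclosed ring closure '%s'", names(ring_atom)[1L]), n, text)
  if (!length(element)) stop_parse("no atoms found", 1L, text)

  new_molecule(
    id = id,
    atoms = data.frame(element = element, charge = charge, aromatic = aromatic,
                       stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = border),
    source = text
  )
}

# Bracket-atom body, e.g. "nH+", "13CH2", "O-", "Se", "NH3+"
parse_bracket_atom <- function(body, pos, text) {
  rest <- sub("^[0-9]+", "", body)  # isotope label dropped
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", rest))
  if (!length(m) || !nzchar(m))
    stop_parse("cannot read element in bracket atom", pos, text)
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  arom <- sym == tolower(sym)
  el <- paste0(toupper(substring(sym, 1L, 1L)), substring(sym, 2L))
  rest <- sub("^@{1,2}", "", rest)          # chirality ignored
  rest <- sub("^H[0-9]*", "", rest)         # explicit H count: implicit model
  chg <- 0L
  cm <- regmatches(rest, regexpr("^(\\+[0-9]+|-[0-9]+|\\++|-+)", rest))
  if (length(cm) && nzchar(cm)) {
    chg <- if (grepl("[0-9]", cm)) {
      as.integer(cm)
    } else {
      if (substring(cm, 1L, 1L) == "+") nchar(cm) else -nchar(cm)
    }
    rest <- substring(rest, nchar(cm) + 1L)
  }
  rest <- sub("^:[0-9]+", "", rest)         # atom-map label ignored
  if (nzchar(rest))
    stop_parse(sprintf("unexpected text '%s' in bracket atom", rest), pos, text)
  list(element = el, charge = chg, aromatic = arom)
}

stop_parse <- function(msg, pos, text) {
  stop(structure(
    class = c("fragsens_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error at position %d: %s (input: '%s')",
                           pos, msg, text),
         call = NULL, position = pos)
  ))
}

new_molecule <- function(id, atoms, bonds, source) {
  structure(list(id = id, atoms = atoms, bonds = bonds, source = source),
            class = "molecule")
}

#' Number of heavy atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Number of bonds in a molecule
#' @param mol A `molecule`.
#' @return Integer count.
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s'> %d heavy atoms, %d bonds\n  %s\n",
              x$id, n_atoms(x), n_bonds(x), x$source))
  invisible(x)
}

# Square matrix of bond orders (0 = not bonded, 4 = aromatic).
bond_order_matrix <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  if (n_bonds(mol)) {
    idx <- cbind(mol$bonds$i, mol$bonds$j)
    m[idx] <- mol$bonds$order
    m[idx[, 2:1, drop = FALSE]] <- mol$bonds$order
  }
  m
}

# TRUE for each bond that lies on a ring (its removal keeps endpoints connected)
ring_bond_flags <- function(mol) {
  nb <- n_bonds(mol)
  if (!nb) return(logical(0))
  adj <- lapply(seq_len(n_atoms(mol)), function(a)
    c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a]))
  vapply(seq_len(nb), function(b) {
    from <- mol$bonds$i[b]; to <- mol$bonds$j[b]
    seen <- rep(FALSE, n_atoms(mol)); seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      for (nb2 in adj[[a]]) {
        if ((a == from && nb2 == to) || (a == to && nb2 == from)) next
        if (!seen[nb2]) { seen[nb2] <- TRUE; queue <- c(queue, nb2) }
      }
      if (seen[to]) return(TRUE)
    }
    seen[to]
  }, logical(1))
}

# Heavy-atom degree vector
atom_degrees <- function(mol) {
  tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n_atoms(mol))
}
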