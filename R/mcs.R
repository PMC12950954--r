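#' Atom and bond matching rules for the MCS search
#'
#' Atoms match on element identity, plus aromaticity by default; formal
#' charge is ignored by default so that, e.g., a zwitterionic aromatic
#' nitrogen can match a neutral one. Bonds match on exact order (aromatic
#' with aromatic) unless `any_bond_order` relaxes this to bonded-vs-bonded.
#'
#' @param match_aromatic Require equal aromatic flags on matched atoms.
#' @param match_charge Require equal formal charges.
#' @param any_bond_order Treat any two bonds as compatible regardless of order.
#' @return A `match_rules` list.
#' @export
match_rules <- function(match_aromatic = TRUE, match_charge = FALSE,
                        any_bond_order = FALSE) {
  structure(list(match_aromatic = match_aromatic,
                 match_charge = match_charge,
                 any_bond_order = any_bond_order),
            class = "match_rules")
}

#' Modular (compatibility) product graph of two molecules
#'
#' Vertices are atom pairs (i in A, j in B) whose atoms match under the
#' rules. Two vertices (i,j) and (k,l) are adjacent iff i != k, j != l and
#' the bond relation is consistent: either both pairs are bonded with
#' compatible bond types (a "strong" edge) or both are non-bonded. Cliques
#' of this graph are exactly the common induced subgraph mappings of A and
#' B; cliques connected through strong edges correspond to connected common
#' substructures. Vertices sharing an A-atom or a B-atom are never
#' adjacent, so no clique can map one atom twice.
#'
#' @param molA,molB `molecule` objects.
#' @param rules [match_rules()].
#' @return A `compatibility_graph`: vertex table (`a`, `b` atom indices),
#'   full adjacency matrix, strong-edge matrix, and the input molecules.
#' @export
build_modular_product <- function(molA, molB, rules = match_rules()) {
  stopifnot(inherits(molA, "molecule"), inherits(molB, "molecule"),
            n_atoms(molA) > 0L, n_atoms(molB) > 0L)
  atom_ok <- outer(seq_len(n_atoms(molA)), seq_len(n_atoms(molB)),
                   function(i, j) {
    ok <- molA$atoms$element[i] == molB$atoms$element[j]
    if (rules$match_aromatic)
      ok <- ok & (molA$atoms$aromatic[i] == molB$atoms$aromatic[j])
    if (rules$match_charge)
      ok <- ok & (molA$atoms$charge[i] == molB$atoms$charge[j])
    ok
  })
  hits <- which(atom_ok, arr.ind = TRUE)
  # lexicographic vertex order by (a, b)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  vertices <- data.frame(a = hits[, 1L], b = hits[, 2L])
  m <- nrow(vertices)
  if (m == 0L) {
    adjacency <- strong <- matrix(FALSE, 0L, 0L)
  } else {
    ordA <- bond_order_matrix(molA)
    ordB <- bond_order_matrix(molB)
    oa <- ordA[vertices$a, vertices$a, drop = FALSE]
    ob <- ordB[vertices$b, vertices$b, drop = FALSE]
    same_a <- outer(vertices$a, vertices$a, "==")
    same_b <- outer(vertices$b, vertices$b, "==")
    bond_ok <- if (rules$any_bond_order) (oa > 0L) & (ob > 0L)
               else (oa > 0L) & (oa == ob)
    strong <- !same_a & !same_b & bond_ok
    adjacency <- strong | (!same_a & !same_b & oa == 0L & ob == 0L)
    diag(adjacency) <- FALSE
    diag(strong) <- FALSE
  }
  structure(list(vertices = vertices, adjacency = adjacency, strong = strong,
                 n_vertices = m, mol_a = molA, mol_b = molB, rules = rules),
            class = "compatibility_graph")
}

#' @export
print.compatibility_graph <- function(x, ...) {
  cat(sprintf("<compatibility graph> %d vertices, %d edges (%d strong)\n",
              x$n_vertices, sum(x$adjacency) / 2L, sum(x$strong) / 2L))
  invisible(x)
}

#' Maximum cliques of a compatibility graph
#'
#' Exact branch-and-bound clique search. With the connected constraint
#' (default) only cliques whose induced common subgraph is connected
#' through bonded-bonded (strong) edges are considered, enumerated by a
#' c-clique variant of Bron-Kerbosch; without it, classic Bron-Kerbosch
#' with pivoting. Deterministic: cliques are returned in lexicographic
#' order of their sorted vertex lists.
#'
#' @param g A `compatibility_graph`.
#' @param connected_constraint Restrict to connected common subgraphs.
#' @param cap Maximum number of co-optimal cliques to return.
#' @param vertex_limit Refuse graphs larger than this (pre-filter fragments
#'   instead).
#' @param node_limit Abort if the search tree exceeds this many nodes.
#' @return List of integer vertex vectors (possibly empty), with attribute
#'   `size` (the clique number) and `complete` (FALSE if `cap` truncated
#'   the list of co-optimal cliques).
#' @export
find_max_clique <- function(g, connected_constraint = TRUE, cap = 256L,
                            vertex_limit = 4000L, node_limit = 5e7) {
  stopifnot(inherits(g, "compatibility_graph"))
  if (g$n_vertices > vertex_limit)
    stop("compatibility graph has ", g$n_vertices, " vertices (limit ",
         vertex_limit, "); pre-filter fragments or raise vertex_limit")
  if (g$n_vertices == 0L)
    return(structure(list(), size = 0L, complete = TRUE))
  res <- clique_search_cpp(g$adjacency, g$strong, connected_constraint,
                           as.integer(cap), as.numeric(node_limit))
  if (res$limit_hit)
    stop("clique search exceeded the node limit (", format(node_limit),
         "); the molecules are too large for exact MCS")
  structure(res$cliques, size = res$size, complete = !res$truncated)
}

#' Exact maximum common substructure of two molecules
#'
#' Finds the largest common induced substructure (most atoms; ties broken
#' by most bonds, then by the lexicographically smallest atom mapping) via
#' the modular product graph and an exact clique search. By default the
#' common substructure must be connected, matching how MCS panels are
#' usually depicted; set `connected = FALSE` to allow multi-fragment
#' solutions.
#'
#' @param molA,molB `molecule` objects.
#' @param rules [match_rules()].
#' @param connected Require a connected common substructure.
#' @param all_mappings Also return every co-optimal mapping.
#' @param ... Passed to [find_max_clique()] (`cap`, limits).
#' @return An `mcs_result`: `mapping` (two-column matrix of atom indices in
#'   A and B), `n_atoms`, `n_bonds`, `pattern` (SMARTS of the common
#'   substructure), `connected`. With `all_mappings = TRUE`, attribute
#'   `mappings` holds all co-optimal mappings.
#' @examples
#' benzene <- parse_structure("c1ccccc1", "benzene")
#' pyridine <- parse_structure("c1ccncc1", "pyridine")
#' compute_mcs(benzene, pyridine)
#' @export
compute_mcs <- function(molA, molB, rules = match_rules(), connected = TRUE,
                        all_mappings = FALSE, ...) {
  g <- build_modular_product(molA, molB, rules)
  cliques <- find_max_clique(g, connected_constraint = connected, ...)
  if (!length(cliques)) {
    res <- structure(list(mapping = matrix(integer(0), 0L, 2L,
                                           dimnames = list(NULL, c("a", "b"))),
                          n_atoms = 0L, n_bonds = 0L,
                          pattern = NA_character_, connected = connected),
                     class = "mcs_result")
    return(res)
  }
  n_bonds_of <- vapply(cliques, function(cl)
    sum(g$strong[cl, cl, drop = FALSE]) / 2L, numeric(1))
  keys <- vapply(cliques, function(cl)
    paste(sprintf("%05d%05d", g$vertices$a[cl], g$vertices$b[cl]),
          collapse = ""), character(1))
  ord <- order(-n_bonds_of, keys)
  best <- cliques[[ord[1L]]]
  mapping <- cbind(a = g$vertices$a[best], b = g$vertices$b[best])
  mapping <- mapping[order(mapping[, "a"]), , drop = FALSE]
  res <- structure(list(
    mapping = mapping,
    n_atoms = nrow(mapping),
    n_bonds = as.integer(n_bonds_of[ord[1L]]),
    pattern = subgraph_smarts(molA, mapping[, "a"],
                              include_charge = rules$match_charge),
    connected = connected || is_connected_clique(g, best)
  ), class = "mcs_result")
  if (all_mappings) {
    attr(res, "mappings") <- lapply(ord, function(k) {
      m <- cbind(a = g$vertices$a[cliques[[k]]], b = g$vertices$b[cliques[[k]]])
      m[order(m[, "a"]), , drop = FALSE]
    })
  }
  res
}

is_connected_clique <- function(g, clique) {
  if (length(clique) <= 1L) return(TRUE)
  s <- g$strong[clique, clique, drop = FALSE]
  seen <- c(TRUE, rep(FALSE, length(clique) - 1L))
  repeat {
    grown <- seen | (colSums(s[seen, , drop = FALSE]) > 0L)
    if (all(grown == seen)) break
    seen <- grown
  }
  all(seen)
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<MCS> %d atoms, %d bonds%s\n  pattern: %s\n",
              x$n_atoms, x$n_bonds,
              if (x$connected) " (connected)" else "",
              if (is.na(x$pattern)) "<none>" else x$pattern))
  invisible(x)
}

# SMARTS for the subgraph of `mol` induced by `atom_ids`. Atoms are written
# by element + aromaticity (optionally + charge); bonds explicitly as
# - = # : so the pattern carries the exact matching semantics of the MCS.
# Two passes: a DFS first classifies tree vs ring-closure bonds (closure
# digits must be known before any atom text is emitted), then the spanning
# tree is written with closure digits attached to both end atoms.
subgraph_smarts <- function(mol, atom_ids, include_charge = FALSE) {
  atom_ids <- sort(unique(as.integer(atom_ids)))
  if (!length(atom_ids)) return(NA_character_)
  sub <- mol$bonds[mol$bonds$i %in% atom_ids & mol$bonds$j %in% atom_ids, ,
                   drop = FALSE]
  key_of <- function(a, o) paste(min(a, o), max(a, o))
  nbrs <- stats::setNames(lapply(atom_ids, function(a) {
    rows <- sub$i == a | sub$j == a
    nb <- data.frame(other = ifelse(sub$i[rows] == a, sub$j[rows], sub$i[rows]),
                     order = sub$order[rows])
    nb[order(nb$other), , drop = FALSE]
  }), atom_ids)
  bond_char <- c("-", "=", "#", ":")
  atom_expr <- function(a) {
    el <- mol$atoms$element[a]
    arom <- mol$atoms$aromatic[a]
    chg <- mol$atoms$charge[a]
    core <- if (arom) {
      if (el %in% c("B", "C", "N", "O", "P", "S")) tolower(el)
      else paste0("[", tolower(el), "]")
    } else {
      if (el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) el
      else paste0("[", el, "]")
    }
    if (include_charge && chg != 0L) {
      sym <- if (chg > 0L) strrep("+", chg) else strrep("-", -chg)
      core <- paste0("[", sub("^\\[|\\]$", "", core), sym, "]")
    }
    core
  }
  ring_digit <- function(num) if (num <= 9L) as.character(num)
                              else sprintf("%%%02d", num)

  visited <- stats::setNames(rep(FALSE, length(atom_ids)), atom_ids)
  tree_edge <- character(0)
  closure_at <- stats::setNames(vector("list", length(atom_ids)), atom_ids)
  closure_n <- 0L
  roots <- integer(0)
  classify <- function(a, from) {
    visited[as.character(a)] <<- TRUE
    nb <- nbrs[[as.character(a)]]
    for (r in seq_len(nrow(nb))) {
      o <- nb$other[r]
      if (!is.null(from) && o == from) next
      k <- key_of(a, o)
      if (k %in% tree_edge || !is.null(closure_at[[as.character(a)]][[k]]))
        next
      if (visited[as.character(o)]) {
        closure_n <<- closure_n + 1L
        tag <- paste0(bond_char[nb$order[r]], ring_digit(closure_n))
        for (end in c(a, o)) {
          lst <- closure_at[[as.character(end)]]
          if (is.null(lst)) lst <- list()
          lst[[k]] <- tag
          closure_at[[as.character(end)]] <<- lst
        }
      } else {
        tree_edge <<- c(tree_edge, k)
        classify(o, a)
      }
    }
  }
  for (a in atom_ids) if (!visited[as.character(a)]) {
    roots <- c(roots, a)
    classify(a, NULL)
  }

  emit <- function(a, from) {
    out <- atom_expr(a)
    cl <- closure_at[[as.character(a)]]
    if (!is.null(cl) && length(cl))
      out <- paste0(out, paste0(unlist(cl[order(names(cl))]), collapse = ""))
    nb <- nbrs[[as.character(a)]]
    # descend only into tree edges, from the parent side
    children <- nb[vapply(nb$other, function(o)
      identical(parent_of[[as.character(o)]], a), logical(1)), , drop = FALSE]
    if (nrow(children)) {
      branches <- vapply(seq_len(nrow(children)), function(r)
        paste0(bond_char[children$order[r]], emit(children$other[r], a)),
        character(1))
      if (length(branches) > 1L)
        out <- paste0(out, paste0("(", branches[-length(branches)], ")",
                                  collapse = ""))
      out <- paste0(out, branches[length(branches)])
    }
    out
  }
  # parent map from a fresh DFS over tree edges
  parent_of <- stats::setNames(vector("list", length(atom_ids)), atom_ids)
  assign_parents <- function(a, from) {
    parent_of[[as.character(a)]] <<- if (is.null(from)) -1L else from
    nb <- nbrs[[as.character(a)]]
    for (o in nb$other) {
      if (key_of(a, o) %in% tree_edge && is.null(parent_of[[as.character(o)]]))
        assign_parents(o, a)
    }
  }
  for (a in roots) assign_parents(a, NULL)
  paste(vapply(roots, function(a) emit(a, NULL), character(1)), collapse = ".")
}
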