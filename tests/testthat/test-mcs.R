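test_that("modular product vertices and edges follow the matching rules", {
  co <- parse_structure("CO", "methanol")
  g <- build_modular_product(co, co)
  expect_identical(g$n_vertices, 2L)           # (C,C) and (O,O)
  expect_identical(sum(g$adjacency) / 2L, 1)   # one strong edge
  expect_identical(sum(g$strong), sum(g$adjacency))

  none <- build_modular_product(parse_structure("C", "methane"),
                                parse_structure("O", "water"))
  expect_identical(none$n_vertices, 0L)

  bz <- parse_structure("c1ccccc1", "benzene")
  py <- parse_structure("c1ccncc1", "pyridine")
  expect_identical(build_modular_product(bz, py)$n_vertices, 30L)  # 6 x 5 C

  # aromatic flag matters unless relaxed
  chx <- parse_structure("C1CCCCC1", "cyclohexane")
  expect_identical(build_modular_product(bz, chx)$n_vertices, 0L)
  relaxed <- build_modular_product(bz, chx,
                                   match_rules(match_aromatic = FALSE))
  expect_identical(relaxed$n_vertices, 36L)
})

test_that("clique search is exact on hand-checkable graphs", {
  mk <- function(adj) structure(
    list(vertices = data.frame(a = seq_len(nrow(adj)), b = seq_len(nrow(adj))),
         adjacency = adj, strong = adj, n_vertices = nrow(adj)),
    class = "compatibility_graph")
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  cl <- find_max_clique(mk(tri))
  expect_identical(attr(cl, "size"), 3L)
  expect_identical(cl[[1]], 1:3)

  c5 <- matrix(FALSE, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; c5[i, j] <- TRUE; c5[j, i] <- TRUE }
  cl5 <- find_max_clique(mk(c5), connected_constraint = FALSE)
  expect_identical(attr(cl5, "size"), 2L)      # 5-cycle has no triangle
  expect_identical(length(cl5), 5L)            # its 5 edges, all co-optimal
  # deterministic lexicographic order
  expect_identical(cl5, find_max_clique(mk(c5), connected_constraint = FALSE))

  empty <- mk(matrix(FALSE, 0, 0))
  expect_identical(length(find_max_clique(empty)), 0L)
  expect_identical(attr(find_max_clique(empty), "size"), 0L)

  big <- mk(matrix(FALSE, 2, 2))
  expect_error(find_max_clique(big, vertex_limit = 1L), "pre-filter")
})

test_that("clique number agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:14, 1)
    adj <- matrix(stats::runif(n * n) < 0.45, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    g <- structure(list(vertices = data.frame(a = 1:n, b = 1:n),
                        adjacency = adj, strong = adj, n_vertices = n),
                   class = "compatibility_graph")
    got <- attr(find_max_clique(g, connected_constraint = FALSE), "size")
    ref <- igraph::clique_num(igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected"))
    expect_identical(got, as.integer(ref))
  }
})

test_that("MCS identities and frozen small-molecule cases", {
  b10 <- parse_structure("CNCc1ccc(-c2cccnc2)s1", "b10")
  self <- compute_mcs(b10, b10)
  expect_identical(self$n_atoms, 14L)
  expect_identical(self$n_bonds, 15L)

  bz <- parse_structure("c1ccccc1", "benzene")
  py <- parse_structure("c1ccncc1", "pyridine")
  bp <- compute_mcs(bz, py)
  expect_identical(bp$n_atoms, 5L)   # the 5 aromatic carbons
  expect_identical(bp$n_bonds, 4L)   # as a path: pyridine's Cs are not a cycle

  eth <- compute_mcs(parse_structure("CCO", "ethanol"),
                     parse_structure("COC", "dme"))
  expect_identical(eth$n_atoms, 2L)  # C-O; the C-C-O path has no ether image
  expect_identical(eth$n_bonds, 1L)
  expect_identical(eth$pattern, "C-O")
})

test_that("MCS size is symmetric and its pattern matches both parents", {
  mols <- mcs_fixture_molecules()
  set.seed(7)
  picks <- replicate(12, sample(names(mols), 2), simplify = FALSE)
  for (pk in picks) {
    a <- mols[[pk[1]]]; b <- mols[[pk[2]]]
    ab <- compute_mcs(a, b)
    ba <- compute_mcs(b, a)
    expect_identical(ab$n_atoms, ba$n_atoms, info = paste(pk, collapse = "/"))
    expect_identical(ab$n_bonds, ba$n_bonds)
    if (ab$n_atoms > 0) {
      counts <- fragsens:::ob_smarts_count(c(a$source, b$source), ab$pattern)
      expect_true(all(counts >= 1), info = paste(pk, collapse = "/"))
    }
  }
})

test_that("MCS equals the exhaustive enumeration oracle on small pairs", {
  mols <- mcs_fixture_molecules()
  pairs <- list(c("ethanol", "propanal"), c("acetic_acid", "acetamide"),
                c("benzene", "furan"), c("pyridine", "pyrimidine"),
                c("phenol", "aniline"), c("toluene", "thiophene"),
                c("pyrrole", "furan"), c("isobutane", "cyclohexane"))
  for (pk in pairs) {
    a <- mols[[pk[1]]]; b <- mols[[pk[2]]]
    expect_identical(compute_mcs(a, b)$n_atoms,
                     oracle_mcs_size(a, b),
                     info = paste(pk, collapse = "/"))
  }
})

test_that("deleting an atom never grows the MCS", {
  mols <- mcs_fixture_molecules()
  a <- mols$phenol; b <- mols$pyridine
  full <- compute_mcs(a, b)$n_atoms
  for (drop in seq_len(n_atoms(a))) {
    keep <- setdiff(seq_len(n_atoms(a)), drop)
    bonds <- a$bonds[a$bonds$i %in% keep & a$bonds$j %in% keep, , drop = FALSE]
    remap <- match(seq_len(n_atoms(a)), keep)
    sub <- fragsens:::new_molecule(
      id = "sub",
      atoms = a$atoms[keep, , drop = FALSE],
      bonds = data.frame(i = remap[bonds$i], j = remap[bonds$j],
                         order = bonds$order),
      source = a$source)
    expect_lte(compute_mcs(sub, b)$n_atoms, full)
  }
})

test_that("disconnected MCS can exceed connected MCS and ties break deterministically", {
  # two lone oxygens vs the two ether oxygens: connected MCS 1, disconnected 2
  a <- parse_structure("O.O", "two_waters")
  b <- parse_structure("OCO", "methanediol")
  expect_identical(compute_mcs(a, b, connected = TRUE)$n_atoms, 1L)
  dis <- compute_mcs(a, b, connected = FALSE)
  expect_identical(dis$n_atoms, 2L)
  expect_identical(dis$pattern, "O.O")  # multi-fragment SMARTS
  # co-optimal mappings are reported in deterministic order
  bz <- parse_structure("c1ccccc1", "benzene")
  py <- parse_structure("c1ccncc1", "pyridine")
  m1 <- compute_mcs(bz, py, all_mappings = TRUE)
  m2 <- compute_mcs(bz, py, all_mappings = TRUE)
  expect_identical(attr(m1, "mappings"), attr(m2, "mappings"))
  expect_identical(m1$mapping, attr(m1, "mappings")[[1]])
})
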