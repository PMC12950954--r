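test_that("ranking puts an exact panel duplicate first and breaks ties by id", {
  px <- fixture_panels()
  lib <- list(
    parse_structure("NCCc1c[nH]c2ccccc12", "dup_tryptamine"),
    parse_structure("CCO", "zz_ethanol"),
    parse_structure("OCC", "aa_ethanol")  # same molecule, different id
  )
  hits <- rank_library(lib, px$metabolites, apply_ro3 = FALSE, mcs = FALSE)
  expect_identical(hits[[1]]$fragment_id, "dup_tryptamine")
  expect_identical(hits[[1]]$best_tc, 1)
  expect_identical(hits[[1]]$best_reference, "tryptamine")
  expect_identical(vapply(hits, `[[`, integer(1), "rank"), 1:3)
  # equal best Tc -> ordered by id ascending
  expect_identical(hits[[2]]$fragment_id, "aa_ethanol")
  expect_identical(hits[[2]]$best_tc, hits[[3]]$best_tc)
})

test_that("rank order is invariant under permutation of the library", {
  px <- fixture_panels()
  fx <- fixture_structures(as_molecules = TRUE)
  lib <- unname(fx[c("bd_b10", "gemcitabine", "desipramine", "tryptamine")])
  h1 <- rank_library(lib, px$inhibitors, apply_ro3 = FALSE, mcs = FALSE)
  set.seed(2)
  h2 <- rank_library(sample(lib), px$inhibitors, apply_ro3 = FALSE, mcs = FALSE)
  expect_identical(lapply(h1, `[[`, "fragment_id"),
                   lapply(h2, `[[`, "fragment_id"))
  expect_identical(lapply(h1, `[[`, "per_reference_tc"),
                   lapply(h2, `[[`, "per_reference_tc"))
})

test_that("every hit carries the full per-reference Tc map and MCS evidence", {
  px <- fixture_panels()
  hits <- rank_library(list(px$b10), px$inhibitors, apply_ro3 = FALSE)
  h <- hits[[1]]
  expect_setequal(names(h$per_reference_tc),
                  names(px$inhibitors$members))
  expect_identical(h$best_tc, max(h$per_reference_tc))
  expect_s3_class(h$mcs_vs_best, "mcs_result")
  expect_gt(h$mcs_vs_best$n_atoms, 0L)
})

test_that("dual-panel selection enforces both thresholds and min-Tc ordering", {
  px <- fixture_panels()
  fx <- fixture_structures(as_molecules = TRUE)
  lib <- list(px$b10, fx$gemcitabine, fx$tryptamine)
  # impossible threshold on a library without duplicates of the panel
  none <- dual_panel_select(list(px$b10), px$inhibitors, px$metabolites,
                            t_inhibitor = 1.0, t_metabolite = 0,
                            apply_ro3 = FALSE, mcs = FALSE)
  expect_length(none, 0L)
  # permissive thresholds keep hits, each a subset of the per-panel rankings
  sel <- dual_panel_select(lib, px$inhibitors, px$metabolites,
                           t_inhibitor = 0.2, t_metabolite = 0.2,
                           apply_ro3 = FALSE, mcs = FALSE)
  expect_gt(length(sel), 0L)
  ri <- rank_library(lib, px$inhibitors, apply_ro3 = FALSE, mcs = FALSE)
  ids_ri <- vapply(ri, `[[`, character(1), "fragment_id")
  for (h in sel) {
    expect_true(h$fragment_id %in% ids_ri)
    expect_gte(h$tc_inhibitor, 0.2)
    expect_gte(h$tc_metabolite, 0.2)
    expect_identical(h$min_tc, min(h$tc_inhibitor, h$tc_metabolite))
  }
  mins <- vapply(sel, `[[`, numeric(1), "min_tc")
  expect_false(is.unsorted(rev(mins)))
  # a fragment passing one panel but not the other is excluded
  strict <- dual_panel_select(lib, px$inhibitors, px$metabolites,
                              t_inhibitor = 0.9, t_metabolite = 0,
                              apply_ro3 = FALSE, mcs = FALSE)
  expect_length(strict, 0L)
})

test_that("scheme calibration round-trips values synthesised from one scheme", {
  fx <- fixture_structures(as_molecules = TRUE)
  pick <- fx[c("bd_b10", "trigonelline", "tryptamine", "metanephrine",
               "gemcitabine", "desipramine")]
  combos <- utils::combn(names(pick), 2)
  for (truth in fingerprint_schemes()) {
    pairs <- lapply(seq_len(ncol(combos)), function(k) {
      a <- pick[[combos[1, k]]]; b <- pick[[combos[2, k]]]
      list(a, b, round_tc(tanimoto(compute_fingerprint(a, truth),
                                   compute_fingerprint(b, truth))))
    })
    res <- calibrate_scheme(pairs)
    expect_identical(res$scheme, truth)
    expect_identical(res$max_abs_dev, 0)
  }
  expect_error(calibrate_scheme(list(list(fx$bd_b10, fx$tryptamine, 0.5))),
               "at least 2")
})

test_that("reports render identically as CSV and JSON", {
  px <- fixture_panels()
  hits <- rank_library(list(px$b10,
                            parse_structure("NCCc1c[nH]c2ccccc12", "frag_t")),
                       px$inhibitors, apply_ro3 = FALSE)
  df <- make_report(hits)
  expect_identical(nrow(df), 2L)
  expect_true(all(c("fragment_id", "rank", "best_reference", "best_tc") %in%
                    names(df)))
  csv_path <- tempfile(fileext = ".csv")
  json_path <- tempfile(fileext = ".json")
  make_report(hits, "csv", csv_path)
  make_report(hits, "json", json_path)
  csv_df <- utils::read.csv(csv_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  js <- jsonlite::fromJSON(json_path)
  expect_identical(csv_df$fragment_id, df$fragment_id)
  expect_equal(js$hits$best_tc, df$best_tc)
  expect_equal(csv_df$best_tc, df$best_tc)
  expect_match(readLines(csv_path, n = 1L), "config=")
  expect_identical(js$meta$package, "fragsens")
  # reruns are byte-identical (no timestamps embedded)
  csv2 <- tempfile(fileext = ".csv")
  make_report(hits, "csv", csv2)
  expect_identical(readLines(csv_path), readLines(csv2))
  expect_error(make_report(hits, "xml"), class = "fragsens_config_error")
  expect_error(make_report(list()), "no hits")
})
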