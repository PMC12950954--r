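#' Reference panel of named molecules
#'
#' A screening panel, e.g. a set of Akt inhibitors or of natural
#' metabolites, against which fragment libraries are ranked.
#'
#' @param name Panel label.
#' @param molecules Named list of `molecule` objects (names are the
#'   reference names; unique, non-empty).
#' @return A `reference_panel`.
#' @export
reference_panel <- function(name, molecules) {
  stopifnot(is.character(name), length(name) == 1L, length(molecules) >= 1L)
  if (is.null(names(molecules)) || anyDuplicated(names(molecules)) ||
      any(!nzchar(names(molecules))))
    stop("panel members must have unique non-empty names")
  lapply(molecules, function(m) stopifnot(inherits(m, "molecule")))
  structure(list(name = name, members = molecules), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference panel '%s'> %d members: %s\n", x$name,
              length(x$members), paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Rank a fragment library against a reference panel
#'
#' Computes the Tanimoto coefficient of every library fragment against
#' every panel member under one fingerprint scheme, and ranks fragments by
#' their best Tc (descending; ties broken by fragment id so the order is a
#' stable total order, invariant under permutation of the input library).
#' By default the library is first restricted to Rule-of-3-compliant
#' fragments, the convention for fragment screening decks.
#'
#' @param library List of `molecule` objects with unique ids.
#' @param panel A [reference_panel()].
#' @param scheme Fingerprint scheme (see [fingerprint_schemes()]).
#' @param apply_ro3 Drop fragments failing [ro3_filter()] before ranking.
#' @param thresholds Rule-of-3 thresholds used when `apply_ro3` is TRUE.
#' @param mcs Attach MCS evidence against the best reference to each hit.
#' @param rules Match rules for the MCS evidence.
#' @return A `screening_hits` object: list of hits, each with
#'   `fragment_id`, `per_reference_tc` (named, 2 dp), `best_reference`,
#'   `best_tc`, `rank`, `ro3_pass` and `mcs_vs_best`.
#' @export
rank_library <- function(library, panel, scheme = "structural-keys-166",
                         apply_ro3 = TRUE, thresholds = ro3_thresholds(),
                         mcs = TRUE, rules = match_rules()) {
  if (!length(library)) stop("empty fragment library")
  stopifnot(inherits(panel, "reference_panel"))
  ids <- vapply(library, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("fragment ids must be unique")

  ro3_pass <- rep(TRUE, length(library))
  if (apply_ro3) {
    recs <- descriptor_table(library)
    ro3_pass <- vapply(recs, function(r) ro3_filter(r, thresholds)$pass,
                       logical(1))
    library <- library[ro3_pass]
    ids <- ids[ro3_pass]
    if (!length(library)) stop("no fragment passes the Rule-of-3 filter")
    ro3_pass <- ro3_pass[ro3_pass]
  }

  lib_fp <- fingerprint_batch(library, scheme)
  ref_fp <- fingerprint_batch(panel$members, scheme)
  tc <- vapply(ref_fp, function(rf)
    vapply(lib_fp, function(lf) tanimoto(lf, rf), numeric(1)),
    numeric(length(lib_fp)))
  tc <- matrix(round_tc(tc), nrow = length(lib_fp),
               dimnames = list(ids, names(panel$members)))

  best_idx <- apply(tc, 1L, which.max)
  best_tc <- tc[cbind(seq_len(nrow(tc)), best_idx)]
  ord <- order(-best_tc, ids)

  hits <- lapply(seq_along(ord), function(r) {
    k <- ord[r]
    structure(list(
      fragment_id = ids[k],
      per_reference_tc = tc[k, ],
      best_reference = colnames(tc)[best_idx[k]],
      best_tc = unname(best_tc[k]),
      rank = r,
      ro3_pass = ro3_pass[k],
      mcs_vs_best = if (mcs)
        compute_mcs(library[[k]], panel$members[[best_idx[k]]], rules = rules)
      else NULL
    ), class = "screening_hit")
  })
  structure(hits, class = "screening_hits", panel = panel$name,
            scheme = scheme)
}

#' @export
print.screening_hits <- function(x, ...) {
  cat(sprintf("<screening hits> %d fragments vs panel '%s' (%s)\n",
              length(x), attr(x, "panel"), attr(x, "scheme")))
  for (h in x[seq_len(min(10L, length(x)))])
    cat(sprintf("  #%d %s: best Tc %.2f vs %s\n", h$rank, h$fragment_id,
                h$best_tc, h$best_reference))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Select sensitiser candidates similar to both reference panels
#'
#' A candidate sensitiser should resemble known pathway inhibitors (so it
#' can act on the target pathway) and known natural metabolites (so it can
#' ride an existing uptake route). This returns the fragments whose best
#' Tc against each panel reaches that panel's threshold, ranked by the
#' smaller of the two best-Tc values (descending), each with MCS evidence
#' against both best references.
#'
#' @param library List of `molecule` objects.
#' @param inhibitor_panel,metabolite_panel [reference_panel()] objects.
#' @param scheme Fingerprint scheme.
#' @param t_inhibitor,t_metabolite Tc thresholds in \[0, 1\].
#' @param ... Passed to [rank_library()].
#' @return A `screening_hits` object; each hit additionally carries
#'   `tc_inhibitor`, `tc_metabolite`, `min_tc` and `mcs_vs_best` as a list
#'   of two MCS results (one per panel).
#' @export
dual_panel_select <- function(library, inhibitor_panel, metabolite_panel,
                              scheme = "structural-keys-166",
                              t_inhibitor = 0.5, t_metabolite = 0.5, ...) {
  stopifnot(t_inhibitor >= 0, t_inhibitor <= 1,
            t_metabolite >= 0, t_metabolite <= 1)
  hi <- rank_library(library, inhibitor_panel, scheme, ...)
  hm <- rank_library(library, metabolite_panel, scheme, ...)
  bi <- stats::setNames(vapply(hi, `[[`, numeric(1), "best_tc"),
                        vapply(hi, `[[`, character(1), "fragment_id"))
  bm <- stats::setNames(vapply(hm, `[[`, numeric(1), "best_tc"),
                        vapply(hm, `[[`, character(1), "fragment_id"))
  keep <- names(bi)[bi[names(bi)] >= t_inhibitor &
                    bm[names(bi)] >= t_metabolite]
  min_tc <- pmin(bi[keep], bm[keep])
  ord <- order(-min_tc, keep)
  hit_by_id <- function(hits, id)
    hits[[which(vapply(hits, `[[`, character(1), "fragment_id") == id)]]
  sel <- lapply(seq_along(ord), function(r) {
    id <- keep[ord[r]]
    a <- hit_by_id(hi, id); b <- hit_by_id(hm, id)
    structure(list(
      fragment_id = id,
      per_reference_tc = c(a$per_reference_tc, b$per_reference_tc),
      best_reference = a$best_reference,
      best_tc = a$best_tc,
      tc_inhibitor = a$best_tc,
      tc_metabolite = b$best_tc,
      min_tc = unname(min_tc[ord[r]]),
      rank = r,
      ro3_pass = a$ro3_pass,
      mcs_vs_best = list(inhibitor = a$mcs_vs_best, metabolite = b$mcs_vs_best)
    ), class = "screening_hit")
  })
  structure(sel, class = "screening_hits",
            panel = paste(inhibitor_panel$name, "&", metabolite_panel$name),
            scheme = scheme)
}

#' Calibrate the fingerprint scheme against printed reference Tc values
#'
#' Similarity tables printed in the literature rarely state which
#' fingerprint generated them. Given reference molecule pairs with their
#' printed Tc values, this evaluates every supported scheme, rounds each
#' computed Tc to 2 decimals, and returns the scheme minimising the
#' maximum absolute deviation from the printed values (ties broken
#' alphabetically by scheme name).
#'
#' @param reference_pairs Either a data frame with columns `smiles_a`,
#'   `smiles_b`, `printed_tc` (plus optional names), or a list of
#'   `list(mol_a, mol_b, printed_tc)` triples. At least 2 pairs.
#' @return List with `scheme`, `max_abs_dev`, and `deviations` (matrix of
#'   per-pair absolute deviations, schemes in columns).
#' @export
calibrate_scheme <- function(reference_pairs) {
  pairs <- normalise_pairs(reference_pairs)
  if (length(pairs) < 2L) stop("calibration needs at least 2 reference pairs")
  printed <- vapply(pairs, `[[`, numeric(1), "printed_tc")
  dev <- sapply(fingerprint_schemes(), function(sc) {
    fa <- fingerprint_batch(lapply(pairs, `[[`, "mol_a"), sc)
    fb <- fingerprint_batch(lapply(pairs, `[[`, "mol_b"), sc)
    got <- round_tc(mapply(tanimoto, fa, fb))
    abs(got - printed)
  })
  max_dev <- apply(dev, 2L, max)
  chosen <- names(sort(max_dev))[1L]  # sort() breaks ties by name
  list(scheme = chosen, max_abs_dev = unname(max_dev[chosen]),
       deviations = dev)
}

normalise_pairs <- function(reference_pairs) {
  if (is.data.frame(reference_pairs)) {
    stopifnot(all(c("smiles_a", "smiles_b", "printed_tc") %in%
                    names(reference_pairs)))
    lapply(seq_len(nrow(reference_pairs)), function(r) list(
      mol_a = parse_structure(reference_pairs$smiles_a[r],
                              if ("name_a" %in% names(reference_pairs))
                                reference_pairs$name_a[r] else "a"),
      mol_b = parse_structure(reference_pairs$smiles_b[r],
                              if ("name_b" %in% names(reference_pairs))
                                reference_pairs$name_b[r] else "b"),
      printed_tc = reference_pairs$printed_tc[r]
    ))
  } else {
    lapply(reference_pairs, function(p) {
      p <- stats::setNames(p, c("mol_a", "mol_b", "printed_tc"))
      stopifnot(inherits(p$mol_a, "molecule"), inherits(p$mol_b, "molecule"))
      p
    })
  }
}

#' Render screening hits as a report
#'
#' Flattens screening hits into a table and optionally writes it as CSV
#' (Tc at 2 decimals, MCS highlights as `;`-separated atom index lists) or
#' JSON (full precision, plus provenance metadata: package version and a
#' hash of the report configuration). CSV and JSON carry identical values.
#'
#' @param hits A `screening_hits` object.
#' @param format `"csv"`, `"json"` or `"data.frame"`.
#' @param path Optional output file.
#' @return The report data frame (invisibly when written to `path`).
#' @export
make_report <- function(hits, format = c("data.frame", "csv", "json"),
                        path = NULL) {
  if (!length(hits)) stop("no hits to report")
  if (!is.character(format) || length(format) < 1L ||
      !format[1L] %in% c("data.frame", "csv", "json"))
    stop_config("unknown report format '", paste(format[1L]), "'")
  format <- format[1L]
  rows <- lapply(hits, function(h) {
    base <- data.frame(
      fragment_id = h$fragment_id, rank = h$rank,
      best_reference = h$best_reference, best_tc = h$best_tc,
      ro3_pass = h$ro3_pass, stringsAsFactors = FALSE)
    for (ref in names(h$per_reference_tc))
      base[[paste0("tc_", ref)]] <- unname(h$per_reference_tc[[ref]])
    m <- h$mcs_vs_best
    if (inherits(m, "mcs_result")) m <- list(best = m)
    if (is.list(m)) {
      for (lbl in names(m)) {
        r <- m[[lbl]]
        if (is.null(r)) next
        base[[paste0("mcs_", lbl, "_n_atoms")]] <- r$n_atoms
        base[[paste0("mcs_", lbl, "_pattern")]] <- r$pattern
        base[[paste0("mcs_", lbl, "_atoms_a")]] <-
          paste(r$mapping[, "a"], collapse = ";")
        base[[paste0("mcs_", lbl, "_atoms_b")]] <-
          paste(r$mapping[, "b"], collapse = ";")
      }
    }
    base
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  df <- do.call(rbind, rows)
  meta <- list(package = "fragsens",
               version = as.character(utils::packageVersion("fragsens")),
               panel = attr(hits, "panel"), scheme = attr(hits, "scheme"))
  meta$config_hash <- config_hash(meta)
  if (format == "data.frame" && is.null(path)) return(df)
  if (format == "csv") {
    out <- c(sprintf("# fragsens %s report; panel=%s; scheme=%s; config=%s",
                     meta$version, meta$panel, meta$scheme, meta$config_hash),
             utils::capture.output(utils::write.csv(df, row.names = FALSE)))
    if (is.null(path)) return(out)
    writeLines(out, path)
  } else if (format == "json") {
    txt <- jsonlite::toJSON(list(meta = meta, hits = df), digits = NA,
                            auto_unbox = TRUE, pretty = TRUE, na = "null")
    if (is.null(path)) return(txt)
    writeLines(txt, path)
  }
  invisible(df)
}

# md5 of the canonical JSON form of a config list (file-based: base R has no
# in-memory md5)
config_hash <- function(config) {
  config <- config[order(names(config))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE), tf)
  unname(tools::md5sum(tf))
}
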