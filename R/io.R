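#' Read molecular structures from a SMILES or SDF file
#'
#' SMILES files hold one record per line, `SMILES<TAB>name` (a space is
#' also accepted). SDF files (V2000) are converted to SMILES through
#' OpenBabel and then parsed. Records that fail to parse are collected and
#' reported with their record numbers rather than silently dropped; the
#' read aborts when more than `max_failure_fraction` of records fail.
#'
#' @param path Input file.
#' @param format `"smi"` or `"sdf"` (default: guessed from the extension).
#' @param max_failure_fraction Abort threshold for the failed fraction.
#' @return List of `molecule` objects (order-preserving), with attribute
#'   `failures`: data frame of record numbers and messages.
#' @export
read_structures <- function(path, format = NULL, max_failure_fraction = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  format <- match.arg(format, c("smi", "sdf"))
  if (format == "sdf") {
    smi_text <- ChemmineOB::convertFormat(
      "SDF", "SMI", paste0(paste(readLines(path), collapse = "\n"), "\n"))
    lines <- strsplit(smi_text, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- readLines(path)
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("no structure records in ", path)
  mols <- list()
  fail_rec <- integer(0)
  fail_msg <- character(0)
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
    smi <- parts[1L]
    nm <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ")
          else sprintf("record%d", k)
    m <- tryCatch(parse_structure(smi, nm), error = function(e) e)
    if (inherits(m, "error")) {
      fail_rec <- c(fail_rec, k)
      fail_msg <- c(fail_msg, conditionMessage(m))
    } else {
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (length(fail_rec) / length(lines) > max_failure_fraction)
    stop(sprintf("%d of %d records failed to parse (first: %s)",
                 length(fail_rec), length(lines), fail_msg[1L]))
  attr(mols, "failures") <- data.frame(record = fail_rec, message = fail_msg,
                                       stringsAsFactors = FALSE)
  mols
}

#' Write molecular structures to a SMILES or SDF file
#'
#' @param mols List of `molecule` objects.
#' @param path Output file.
#' @param format `"smi"` or `"sdf"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_structures <- function(mols, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  format <- match.arg(format, c("smi", "sdf"))
  smi <- vapply(mols, function(m) m$source, character(1))
  nms <- vapply(mols, function(m) m$id, character(1))
  if (format == "smi") {
    writeLines(paste(smi, nms, sep = "\t"), path)
  } else {
    sdf <- ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(paste(smi, nms), "\n", collapse = ""))
    writeLines(sdf, path)
  }
  invisible(path)
}

#' Read a long-form co-administration plate CSV
#'
#' Expected columns: `cell_line`, `drug_a_uM`, `sensitiser_uM`,
#' `replicate`, `signal` (doses in uM). Lines starting with `#` are
#' provenance comments. The grid is assembled into a
#' [dose_response_matrix()]; a missing untreated control or duplicated
#' replicate ids are structured errors.
#'
#' @param path CSV file.
#' @return A `dose_response_matrix`.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_line", "drug_a_uM", "sensitiser_uM", "replicate", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plate CSV is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("drug_a_uM", "sensitiser_uM", "signal")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("non-numeric values in column ", col)
    df[[col]] <- v
  }
  if (length(unique(df$cell_line)) != 1L)
    stop("plate CSV must describe a single cell line")
  if (anyDuplicated(df[c("drug_a_uM", "sensitiser_uM", "replicate")]))
    stop("duplicated replicate ids within a dose cell")
  da <- sort(unique(df$drug_a_uM))
  db <- sort(unique(df$sensitiser_uM))
  if (!0 %in% da || !0 %in% db ||
      !any(df$drug_a_uM == 0 & df$sensitiser_uM == 0))
    stop("plate lacks the untreated (0, 0) control cell")
  reps <- sort(unique(df$replicate))
  arr <- array(NA_real_, c(length(da), length(db), length(reps)))
  arr[cbind(match(df$drug_a_uM, da), match(df$sensitiser_uM, db),
            match(df$replicate, reps))] <- df$signal
  dose_response_matrix(da, db, arr, cell_line = df$cell_line[1L])
}

#' Write a dose-response matrix as a long-form plate CSV
#'
#' The inverse of [read_plate()]; a provenance comment line carries the
#' package version and configuration hash.
#'
#' @param m A `dose_response_matrix`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_plate <- function(m, path) {
  stopifnot(inherits(m, "dose_response_matrix"))
  idx <- which(!is.na(m$signals), arr.ind = TRUE)
  df <- data.frame(cell_line = m$cell_line,
                   drug_a_uM = m$drug_a_doses[idx[, 1L]],
                   sensitiser_uM = m$sensitiser_doses[idx[, 2L]],
                   replicate = idx[, 3L],
                   signal = m$signals[idx])
  df <- df[order(df$drug_a_uM, df$sensitiser_uM, df$replicate), ]
  meta <- list(version = as.character(utils::packageVersion("fragsens")),
               cell_line = m$cell_line)
  hdr <- sprintf("# fragsens %s plate; config=%s", meta$version,
                 config_hash(meta))
  writeLines(c(hdr, utils::capture.output(
    utils::write.csv(df, row.names = FALSE))), path)
  invisible(path)
}
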