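#' Parse a SMILES string into a molecular heavy-atom graph
#'
#' The string is first syntax-checked by the package's own reader, which
#' reports malformed input (unclosed rings or branches, invalid elements)
#' with the offending token position.  Valid input is then canonicalized
#' through OpenBabel, which applies aromatic perception, and the graph is
#' built from the canonical aromatic rendering: hydrogens are collapsed
#' onto heavy atoms, formal charges are preserved and stereochemistry is
#' read but ignored.
#'
#' @param smiles a single SMILES string.
#' @param canonical_input set to `TRUE` when `smiles` is already an
#'   OpenBabel-canonical rendering, to skip the round trip.
#' @return a [molecular_graph] whose `smiles` field holds the canonical
#'   rendering.
#' @examples
#' \dontrun{
#' g <- parse_smiles("c1ccccc1")
#' n_atoms(g)  # 6
#' }
#' @export
parse_smiles <- function(smiles, canonical_input = FALSE) {
  toks <- .parse_smiles_tokens(smiles)  # positional syntax errors
  if (!canonical_input) {
    can <- ob_canonical(smiles)
    if (is.na(can)) {
      parse_error("rejected by canonicalizer (valence or aromaticity)", 1L)
    }
    toks <- .parse_smiles_tokens(can)
    smiles <- can
  }
  toks <- .demote_nonring_aromatic(toks)
  toks$atoms$hcount <- .infer_hydrogens(toks$atoms, toks$bonds)
  g <- .new_molecular_graph(toks$atoms, toks$bonds, smiles = smiles)
  mw <- molecular_weight(g)
  if (!is.na(mw) && mw > 2000) {
    warning(sprintf(
      "molecule of %.0f Da exceeds the 2 kDa applicability domain", mw))
  }
  g
}

## Parse a fragment pattern string (SMILES-like; aromatic atoms may appear
## outside complete rings, hydrogen counts are not interpreted).
parse_pattern <- function(pattern) {
  toks <- .parse_smiles_tokens(pattern)
  .new_molecular_graph(toks$atoms, toks$bonds, smiles = pattern, pattern = TRUE)
}

#' Canonicalize SMILES strings
#'
#' Maps every rendering of a molecule to the same canonical string
#' (OpenBabel canonical SMILES); idempotent.  Vectorised.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @export
canonicalize <- function(smiles) {
  for (s in smiles) .parse_smiles_tokens(s)   # propagate positional errors
  out <- ob_canonical(smiles)
  if (anyNA(out)) {
    parse_error(sprintf("canonicalizer rejected '%s'",
                        smiles[which(is.na(out))[1]]), 1L)
  }
  out
}

## Batch canonicalization via OpenBabel; returns NA for rejected entries.
## Titles carry the input index so that partial failures keep alignment.
ob_canonical <- function(smiles) {
  src <- paste0(paste(smiles, seq_along(smiles)), collapse = "\n")
  res <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"))
  )
  out <- rep(NA_character_, length(smiles))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 2L) {
      idx <- suppressWarnings(as.integer(fields[[2]]))
      if (!is.na(idx)) out[[idx]] <- fields[[1]]
    }
  }
  out
}

#' Read a whitespace-delimited SMILES file
#'
#' One molecule per line: a SMILES string followed by optional identifier
#' and label/value columns.  Blank lines and lines starting with `#` are
#' skipped; unparseable lines are skipped with a warning and counted in
#' the `skipped` attribute.
#'
#' @param path file path.
#' @param id_col,label_col,value_col 1-based column positions of the
#'   identifier, binary label and continuous value columns (`NA` = column
#'   absent).  Column 1 is always the SMILES.
#' @param endpoint_name optional endpoint name attached to each record.
#' @return a data frame of molecule records (`id`, `smiles`, `label`,
#'   `value`, `endpoint_name`) with attribute `skipped`; `label` is coded
#'   1 = active, 0 = inactive.
#' @export
read_smiles_file <- function(path, id_col = 2L, label_col = NA_integer_,
                             value_col = NA_integer_, endpoint_name = NULL) {
  if (!file.exists(path)) data_error(sprintf("cannot read '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  recs <- list()
  skipped <- 0L
  for (ln in lines) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    smi <- fields[[1]]
    ok <- tryCatch({ .parse_smiles_tokens(smi); TRUE },
                   herbsig_parse_error = function(e) FALSE)
    if (ok) ok <- !is.na(ob_canonical(smi))
    if (!ok) {
      skipped <- skipped + 1L
      hs_log("skipping unparseable line: %s", smi, level = "warning")
      next
    }
    get_col <- function(i) {
      if (is.na(i) || length(fields) < i) NA_character_ else fields[[i]]
    }
    recs[[length(recs) + 1L]] <- data.frame(
      id = get_col(id_col) %||% NA_character_,
      smiles = smi,
      label = .parse_label(get_col(label_col)),
      value = suppressWarnings(as.numeric(get_col(value_col))),
      endpoint_name = endpoint_name %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0L) {
    data_error(sprintf("no parseable molecules in '%s'", path))
  }
  out <- do.call(rbind, recs)
  missing_id <- is.na(out$id)
  out$id[missing_id] <- sprintf("mol%d", which(missing_id))
  if (anyDuplicated(out$id)) {
    data_error("duplicate molecule identifiers in input file")
  }
  attr(out, "skipped") <- skipped
  out
}

.parse_label <- function(x) {
  if (is.na(x)) return(NA_integer_)
  lx <- tolower(x)
  if (lx %in% c("1", "active", "true", "pos", "positive")) return(1L)
  if (lx %in% c("0", "inactive", "false", "neg", "negative")) return(0L)
  suppressWarnings(as.integer(as.numeric(x) > 0.5))
}

#' Construct molecule records in memory
#'
#' @param smiles character vector of SMILES.
#' @param id identifiers (defaults to `mol1..moln`).
#' @param label optional binary labels (1 = active).
#' @param value optional continuous endpoint values.
#' @param endpoint_name optional endpoint name.
#' @return a molecule record data frame as from [read_smiles_file()].
#' @export
molecule_records <- function(smiles, id = NULL, label = NULL, value = NULL,
                             endpoint_name = NULL) {
  n <- length(smiles)
  out <- data.frame(
    id = id %||% sprintf("mol%d", seq_len(n)),
    smiles = smiles,
    label = if (is.null(label)) rep(NA_integer_, n) else as.integer(label),
    value = if (is.null(value)) rep(NA_real_, n) else as.numeric(value),
    endpoint_name = if (is.null(endpoint_name)) rep(NA_character_, n)
                    else endpoint_name,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$id)) contract_error("molecule ids must be unique")
  out
}

#' Write a prediction table as CSV
#'
#' One row per molecule: identifier, SMILES, then one column per endpoint.
#' Missing endpoint values are written as empty fields; the file
#' round-trips through [read.csv()].
#'
#' @param records molecule record data frame.
#' @param predictions data frame of prediction columns, one row per record.
#' @param path output file path.
#' @return the written data frame, invisibly.
#' @export
write_prediction_table <- function(records, predictions, path) {
  if (!is.null(predictions) && nrow(predictions) != nrow(records)) {
    contract_error(sprintf(
      "records (%d) and predictions (%d) differ in length",
      nrow(records), nrow(predictions)))
  }
  out <- data.frame(id = records$id, smiles = records$smiles,
                    stringsAsFactors = FALSE)
  if (!is.null(predictions) && ncol(predictions) > 0L) {
    out <- cbind(out, predictions)
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
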