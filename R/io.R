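# Delimited-table ingestion and fingerprint-matrix serialization shared by
# the command-line subcommands. Delimiter auto-detection is limited to comma
# and tab; anything else must be passed explicitly.

.detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab == 0 && n_com == 0) {
    stop("cannot auto-detect delimiter (no comma or tab in header); ",
         "pass `delimiter` explicitly", call. = FALSE)
  }
  if (n_tab >= n_com) "\t" else ","
}

#' Read a delimited dataset table with per-row SMILES validation
#'
#' Reads a delimited text table (header required; comma or tab detected
#' automatically) and validates that each row's SMILES string parses.
#' Malformed rows are never silently dropped: they are routed to a reject
#' data.frame (and optionally a reject file) with the failure reason.
#'
#' @param path Input file path.
#' @param smiles_column Name of the SMILES column.
#' @param label_column Optional name of the label column.
#' @param delimiter Field delimiter; auto-detected when `NULL`.
#' @param reject_path Optional path for a reject CSV (`row`, `smiles`,
#'   `reason`).
#' @return data.frame of valid records; the rejects as attribute
#'   `"rejects"`.
#' @export
read_dataset_table <- function(path, smiles_column, label_column = NULL,
                               delimiter = NULL, reject_path = NULL) {
  if (is.null(delimiter)) delimiter <- .detect_delimiter(path)
  tab <- utils::read.delim(path, sep = delimiter, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (col in c(smiles_column, label_column)) {
    if (!col %in% names(tab)) {
      stop("column '", col, "' not found; available: ",
           paste(names(tab), collapse = ", "), call. = FALSE)
    }
  }
  reasons <- vapply(tab[[smiles_column]], function(s) {
    tryCatch({ parse_smiles(s); NA_character_ },
             error = function(e) conditionMessage(e))
  }, character(1), USE.NAMES = FALSE)
  bad <- !is.na(reasons)
  rejects <- data.frame(row = which(bad), smiles = tab[[smiles_column]][bad],
                        reason = reasons[bad], stringsAsFactors = FALSE)
  if (nrow(rejects) > 0) {
    message(nrow(rejects), " row(s) rejected")
    if (!is.null(reject_path)) {
      utils::write.csv(rejects, reject_path, row.names = FALSE)
    }
  }
  out <- tab[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a fingerprint matrix as delimited text
#'
#' Dense form: one row per complex (`id`, `f1`..`fd`). Sparse form: triplet
#' rows `row,col,value` for the non-zero entries, with the matrix dimensions
#' on a leading `#dims` comment line. Counts are written as integers, never
#' binarized; both forms round-trip exactly through
#' [read_fingerprint_matrix()].
#'
#' @param fps Numeric matrix, list of equal-length vectors, or list of
#'   `electrum_fp` objects (their `combined` vectors are used).
#' @param path Output file path.
#' @param sparse Write the sparse triplet form.
#' @param ids Optional row identifiers (dense form only).
#' @export
write_fingerprint_matrix <- function(fps, path, sparse = FALSE, ids = NULL) {
  if (is.list(fps) && !is.data.frame(fps)) {
    fps <- lapply(fps, function(f) if (inherits(f, "electrum_fp")) f$combined else f)
    if (length(unique(lengths(fps))) > 1) {
      stop("fingerprints have differing lengths", call. = FALSE)
    }
    fps <- if (length(fps) == 0) matrix(numeric(0), 0, 0) else do.call(rbind, fps)
  }
  x <- as.matrix(fps)
  if (sparse) {
    nz <- which(x != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#dims %d %d", nrow(x), ncol(x)), con)
    writeLines("row,col,value", con)
    if (nrow(nz) > 0) {
      o <- order(nz[, 1], nz[, 2])
      writeLines(sprintf("%d,%d,%s", nz[o, 1], nz[o, 2],
                         format(x[nz[o, , drop = FALSE]], trim = TRUE,
                                scientific = FALSE)), con)
    }
  } else {
    df <- as.data.frame(x)
    if (ncol(df) > 0) names(df) <- paste0("f", seq_len(ncol(df)))
    df <- cbind(data.frame(id = if (is.null(ids)) seq_len(nrow(x)) else ids),
                df)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a fingerprint matrix written by [write_fingerprint_matrix()]
#'
#' The sparse and dense forms are distinguished by the leading `#dims`
#' comment line and re-read to identical matrices.
#'
#' @param path Input file path.
#' @return Numeric matrix (row ids as rownames in the dense form).
#' @export
read_fingerprint_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#dims")) {
    dims <- as.integer(strsplit(first, " ")[[1]][2:3])
    trip <- utils::read.csv(path, skip = 1L)
    x <- matrix(0, dims[1], dims[2])
    if (nrow(trip) > 0) x[cbind(trip$row, trip$col)] <- trip$value
    return(x)
  }
  df <- utils::read.csv(path)
  x <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  dimnames(x) <- list(df$id, NULL)
  x
}
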