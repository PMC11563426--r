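#' Construct a labelled peptide dataset
#'
#' The central data container: an ordered set of peptide sequences with
#' optional binary labels (1 = positive class, e.g. IL-10-inducing;
#' 0 = negative). Invariants enforced: unique ids, residues over the
#' canonical alphabet (after the chosen validation policy), labels in
#' \{0, 1\} when present.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of residue strings (same length as `id`).
#' @param label Optional integer/numeric vector of 0/1 labels, or `NULL` for
#'   an unlabelled dataset.
#' @param policy Validation policy passed to [validate_sequence()].
#' @param deduplicate If `TRUE`, drop records whose residue string duplicates
#'   an earlier one (first occurrence kept). Off by default.
#' @return An object of class `peptide_dataset`: a data.frame with columns
#'   `id`, `residues` and (if labelled) `label`.
#' @export
peptide_dataset <- function(id, residues, label = NULL,
                            policy = "strict", deduplicate = FALSE) {
  stopifnot(length(id) == length(residues))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  residues <- vapply(seq_along(residues), function(i) {
    validate_sequence(residues[[i]], policy = policy, id = id[[i]])
  }, character(1))
  keep <- !is.na(residues)
  id <- id[keep]; residues <- residues[keep]
  if (!is.null(label)) {
    label <- label[keep]
    stopifnot(length(label) == length(id))
    if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
    label <- as.integer(label)
  }
  if (deduplicate) {
    keep <- !duplicated(residues)
    id <- id[keep]; residues <- residues[keep]
    if (!is.null(label)) label <- label[keep]
  }
  d <- data.frame(id = id, residues = residues, stringsAsFactors = FALSE)
  if (!is.null(label)) d$label <- label
  class(d) <- c("peptide_dataset", "data.frame")
  d
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat(sprintf("peptide_dataset: %d sequences%s\n", nrow(x),
              if ("label" %in% names(x))
                sprintf(" (%d positive / %d negative)",
                        sum(x$label == 1L), sum(x$label == 0L))
              else " (unlabelled)"))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

#' Read peptides from a FASTA file
#'
#' Parses a plain (optionally line-wrapped) FASTA file into a
#' [peptide_dataset]. Labels are not encoded in FASTA headers; pass `label`
#' to assign one label to every record in the file (the usual pattern is one
#' file of positives, one of negatives), or leave `NULL` for unlabelled data.
#'
#' @param path Path to a FASTA file.
#' @param label Optional single 0/1 label applied to all records.
#' @param policy Validation policy, see [validate_sequence()].
#' @param deduplicate Drop duplicate residue strings (default `FALSE`).
#' @return A [peptide_dataset].
#' @export
read_fasta <- function(path, label = NULL, policy = "strict",
                       deduplicate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header, got %s",
                 first, path, sQuote(substr(trimws(lines[first]), 1, 20))))
  }
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)          # id = first whitespace-delimited token
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- gsub("\\s", "", paste(body, collapse = ""))
    if (!nzchar(body)) {
      stop(sprintf("malformed FASTA at line %d of %s: record '%s' has no sequence",
                   hdr[i], path, ids[i]))
    }
    body
  }, character(1))
  if (!is.null(label)) {
    stopifnot(length(label) == 1L, label %in% c(0, 1))
    label <- rep(as.integer(label), length(ids))
  }
  peptide_dataset(ids, seqs, label, policy = policy, deduplicate = deduplicate)
}

#' Write a peptide dataset to FASTA
#'
#' @param d A [peptide_dataset].
#' @param path Output file path.
#' @param width Line-wrap width for residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(d, path, width = 60L) {
  stopifnot(inherits(d, "peptide_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(">", d$id[i]), con)
    s <- d$residues[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a two-column sequence,label CSV into a peptide dataset
#'
#' Expects a header with at least `sequence` and `label` columns; an optional
#' `id` column supplies identifiers (otherwise `seq1`, `seq2`, ... are used).
#'
#' @inheritParams read_fasta
#' @return A labelled [peptide_dataset].
#' @export
read_peptide_csv <- function(path, policy = "strict", deduplicate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("CSV missing column(s): ", paste(miss, collapse = ", "))
  ids <- if ("id" %in% names(tab)) tab$id else paste0("seq", seq_len(nrow(tab)))
  peptide_dataset(ids, tab$sequence, tab$label,
                  policy = policy, deduplicate = deduplicate)
}

#' Write a feature matrix (plus labels) to CSV
#'
#' Serialises with full precision (17 significant digits) so that
#' re-reading reproduces the matrix bit-for-bit. The label column, when
#' given, is appended last under the name `label`.
#'
#' @param m Numeric matrix with column names (a feature matrix) and row names
#'   (peptide ids).
#' @param path Output path.
#' @param labels Optional 0/1 vector, one per row of `m`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(m, path, labels = NULL) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(m))
  ids <- rownames(m) %||% paste0("row", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m), if (!is.null(labels)) "label"),
                   collapse = ","), con)
  if (nrow(m) > 0) {
    vals <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    body <- paste(ids, vals, sep = ",")
    if (!is.null(labels)) body <- paste(body, as.integer(labels), sep = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A list with `matrix` (numeric, named dims) and `labels`
#'   (integer vector or `NULL`).
#' @export
read_feature_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  has_label <- "label" %in% names(tab)
  feat_cols <- setdiff(names(tab), c("id", "label"))
  m <- as.matrix(tab[, feat_cols, drop = FALSE])
  rownames(m) <- as.character(tab$id)
  list(matrix = m,
       labels = if (has_label) as.integer(tab$label) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
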