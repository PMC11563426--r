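#' The canonical amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes in alphabetical order. This
#' ordering fixes feature-column identity for every encoder in the package:
#' all composition vectors, pair and triple enumerations are laid out in this
#' order (and its Cartesian powers).
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate and normalise a peptide residue string
#'
#' Uppercases the input and applies one of three policies for residues
#' outside the canonical 20-letter alphabet (e.g. B, J, O, U, X, Z, gaps):
#'
#' * `"strict"` (default): any non-canonical character is an error.
#' * `"drop-record"`: returns `NA_character_` so the caller can remove the
#'   offending record.
#' * `"strip-nonstandard"`: non-canonical characters are deleted; an error is
#'   raised if nothing remains.
#'
#' The function is idempotent under every policy: applying it to its own
#' output is a no-op.
#'
#' @param residues Single character string of residues.
#' @param policy One of `"strict"`, `"drop-record"`, `"strip-nonstandard"`.
#' @param id Optional identifier used in error messages.
#' @return The validated (uppercase, canonical-only) residue string, or
#'   `NA_character_` under `"drop-record"` when invalid.
#' @examples
#' validate_sequence("rpferdisnvpfs")            # "RPFERDISNVPFS"
#' validate_sequence("AXG", policy = "strip-nonstandard")  # "AG"
#' @export
validate_sequence <- function(residues,
                              policy = c("strict", "drop-record", "strip-nonstandard"),
                              id = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  if (!nzchar(residues)) {
    stop("empty residue string", if (!is.null(id)) paste0(" for sequence '", id, "'"))
  }
  res <- toupper(residues)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) == 0L) return(res)
  who <- if (is.null(id)) "" else paste0(" in sequence '", id, "'")
  switch(policy,
    "strict" = stop("non-canonical residue(s) ", paste(sQuote(bad), collapse = ", "), who),
    "drop-record" = NA_character_,
    "strip-nonstandard" = {
      kept <- chars[chars %in% AA_ALPHABET]
      if (length(kept) == 0L) {
        stop("sequence", who, " is empty after stripping non-standard residues")
      }
      paste(kept, collapse = "")
    })
}
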