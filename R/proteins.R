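# Protein records: the unit of quantification throughout the package.

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a validated protein table
#'
#' A protein table is a plain `data.frame` with one row per protein and
#' columns `id`, `gene`, `sequence`, `encoding` (`"mitochondrial"` or
#' `"nuclear"`), and optional `complex` / `module` annotations. Sequences are
#' restricted to the 20 canonical amino acids; ambiguity codes (B, J, O, U,
#' X, Z) are rejected with the offending character and position so that
#' downstream digestion never operates on residues whose cleavage behaviour
#' is undefined.
#'
#' @param id character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences (upper case).
#' @param gene optional gene symbols (defaults to `id`).
#' @param encoding `"mitochondrial"` or `"nuclear"`, recycled.
#' @param complex optional complex label (`"CI"`..`"CV"` or `"none"`).
#' @param module optional subcomplex/module label.
#' @return a `data.frame` of class `protein_set`.
#' @examples
#' protein_set(id = "P1", sequence = "MKAAAAAR")
#' @export
protein_set <- function(id, sequence, gene = id, encoding = "nuclear",
                        complex = NA_character_, module = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have equal length")
  if (anyDuplicated(id))
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  encoding <- rep_len(as.character(encoding), length(id))
  bad_enc <- !encoding %in% c("mitochondrial", "nuclear")
  if (any(bad_enc))
    stop("'encoding' must be 'mitochondrial' or 'nuclear'")
  for (i in seq_along(sequence)) validate_sequence(sequence[i], id[i])
  out <- data.frame(
    id = id,
    gene = rep_len(as.character(gene), length(id)),
    sequence = sequence,
    encoding = encoding,
    complex = rep_len(as.character(complex), length(id)),
    module = rep_len(as.character(module), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Validate an amino-acid sequence
#'
#' @param sequence a single string.
#' @param id label used in error messages.
#' @return the sequence, invisibly, if valid.
#' @export
validate_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence for '", id, "' must be a single string")
  if (nchar(sequence) == 0L)
    stop("sequence for '", id, "' is empty")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_CANONICAL)
  if (length(bad))
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1],
         " in sequence '", id, "' (only the 20 canonical amino acids are allowed)")
  invisible(sequence)
}

#' Read protein sequences from a FASTA file
#'
#' Accessions follow the UniProt pipe convention when present
#' (`>db|ACCESSION|NAME` parses to `ACCESSION`), otherwise the first
#' whitespace-delimited header token is used. Duplicate ids and non-canonical
#' residues are rejected.
#'
#' @param path FASTA file.
#' @return a `protein_set`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(aa)
  token <- vapply(strsplit(headers, "[ \t]"), `[[`, "", 1L)
  ids <- vapply(token, function(tk) {
    parts <- strsplit(tk, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && nzchar(parts[2])) parts[2] else tk
  }, "")
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  protein_set(id = unname(ids), sequence = as.character(aa))
}

#' Write a protein table to FASTA
#'
#' @param proteins a `protein_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins))
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", nrow(x), "protein(s);",
      sum(x$encoding == "mitochondrial"), "mitochondrial-encoded\n")
  NextMethod()
}
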