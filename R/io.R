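# Readers/writers for the tab-separated tables the pipeline touches.
# All tables are TSV, UTF-8, one header row; comment lines start with '#';
# missing cells are empty, never 0. Writes go through a temp file and an
# atomic rename.

write_tsv_atomic <- function(x, path, header_lines = character(0)) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  open_con <- TRUE
  on.exit(if (open_con) close(con), add = TRUE)
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  close(con); open_con <- FALSE
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

#' Write SILAC evidence to TSV
#'
#' @param evidence a `silac_evidence` table.
#' @param path output file.
#' @param header_lines optional comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path, header_lines = character(0)) {
  write_tsv_atomic(evidence, path, header_lines)
}

MAXQUANT_COLUMN_MAP <- c(
  peptide_sequence = "Sequence", protein_id = "Proteins",
  replicate_id = "Experiment", condition = "Condition",
  intensity_L = "Intensity L", intensity_M = "Intensity M",
  intensity_H = "Intensity H"
)

#' Read a SILAC evidence table
#'
#' Reads the native schema (`peptide_sequence`, `protein_id`,
#' `replicate_id`, `condition`, `intensity_L/M/H`, optional extras) or an
#' external dialect via `column_map` (native name -> file column name); the
#' built-in `"maxquant"` map covers MaxQuant-style `Intensity L/M/H`
#' evidence columns. Empty cells become `NA`; under a dialect map, zero
#' intensities are additionally treated as missing (that tool's convention
#' for unquantified channels). Rows with a negative intensity are rejected
#' and tallied in the `n_rejected` attribute.
#'
#' @param path TSV file.
#' @param column_map `NULL` (native), `"maxquant"`, or a named character
#'   vector mapping native column names to file column names.
#' @return a `silac_evidence` data.frame.
#' @export
read_evidence <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  dialect <- !is.null(column_map)
  if (identical(column_map, "maxquant")) column_map <- MAXQUANT_COLUMN_MAP
  if (dialect) {
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols))
      stop("mapped column(s) absent from file: ",
           paste(missing_cols, collapse = ", "))
    keep <- raw[, unname(column_map), drop = FALSE]
    names(keep) <- names(column_map)
    extra <- raw[, setdiff(names(raw), unname(column_map)), drop = FALSE]
    raw <- cbind(keep, extra)
  }
  req <- c("peptide_sequence", "protein_id", "replicate_id",
           "intensity_L", "intensity_M", "intensity_H")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("evidence lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (cc in grep("^intensity_", names(raw), value = TRUE)) {
    v <- raw[[cc]]
    if (is.character(v)) {
      v[!nzchar(trimws(v))] <- NA
      v2 <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(v2)))
        stop("non-numeric intensity in column '", cc, "'")
      v <- v2
    }
    if (dialect) v[!is.na(v) & v == 0] <- NA_real_
    raw[[cc]] <- v
  }
  neg <- rowSums(sapply(raw[grep("^intensity_", names(raw))],
                        function(v) !is.na(v) & v < 0)) > 0
  n_rejected <- sum(neg)
  raw <- raw[!neg, , drop = FALSE]
  rownames(raw) <- NULL
  class(raw) <- c("silac_evidence", "data.frame")
  attr(raw, "n_rejected") <- n_rejected
  raw
}
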