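# OXPHOS complex/subcomplex annotation and per-module summaries.

COMPLEX_LEVELS <- c("CI", "CII", "CIII", "CIV", "CV", "none")
COMPLEX_REFERENCE_TOTALS <- c(CI = 45L, CII = 4L, CIII = 11L, CIV = 21L,
                              CV = 17L)
MT_ENCODED_REFERENCE <- 13L

#' Load an OXPHOS annotation table
#'
#' Reads a tab-separated annotation (columns `protein_id`, `gene`,
#' `encoding`, `complex`, `module`, optional `uncertain`), validating ids,
#' encoding and complex labels. For the packaged reference the
#' mitochondrial-encoded count (13) and per-complex totals
#' (CI 45, CII 4, CIII 11, CIV 21, CV 17) must hold; for user-supplied
#' tables a mismatch is a warning, not an error.
#'
#' @param path TSV path; default is the packaged human OXPHOS reference.
#' @param reference_totals enforce the packaged totals strictly (default
#'   only when reading the packaged file).
#' @return validated annotation `data.frame`.
#' @export
load_annotation <- function(path = NULL, reference_totals = is.null(path)) {
  if (is.null(path))
    path <- system.file("extdata", "oxphos_annotation.tsv",
                        package = "mitopulse", mustWork = TRUE)
  ann <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("protein_id", "gene", "encoding", "complex", "module")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  dup <- ann$protein_id[duplicated(ann$protein_id)]
  if (length(dup)) stop("protein listed twice in annotation: ",
                        paste(unique(dup), collapse = ", "))
  bad_enc <- which(!ann$encoding %in% c("mitochondrial", "nuclear"))
  if (length(bad_enc)) stop("invalid 'encoding' at row(s) ",
                            paste(bad_enc, collapse = ", "))
  bad_cx <- which(!ann$complex %in% COMPLEX_LEVELS)
  if (length(bad_cx)) stop("unknown complex label at row(s) ",
                           paste(bad_cx, collapse = ", "), ": ",
                           paste(unique(ann$complex[bad_cx]), collapse = ", "))
  n_mt <- sum(ann$encoding == "mitochondrial")
  totals <- table(factor(ann$complex, levels = names(COMPLEX_REFERENCE_TOTALS)))
  mismatch <- n_mt != MT_ENCODED_REFERENCE ||
    any(as.integer(totals) != COMPLEX_REFERENCE_TOTALS)
  if (mismatch) {
    msg <- paste0("annotation totals differ from the reference (",
                  n_mt, " mitochondrial-encoded; ",
                  paste(names(totals), as.integer(totals), sep = "=",
                        collapse = ", "), ")")
    if (reference_totals) stop(msg) else warning(msg)
  }
  ann
}

#' Assign the four-way protein category
#'
#' `MT-encoded OXPHOS` (mitochondrial-encoded subunits), `nuclear OXPHOS`
#' (nuclear-encoded complex subunits), `nuclear mito` (other mitochondrial
#' proteins, supplied via `mito_ids`), `nuclear non-mito` (everything else
#' when `assume_nonmito`), else `unannotated`.
#'
#' @param protein_id character vector.
#' @param annotation OXPHOS annotation table.
#' @param mito_ids ids of non-OXPHOS mitochondrial proteins (a MitoCarta-like
#'   list).
#' @param assume_nonmito treat proteins absent from both lists as
#'   `nuclear non-mito` (default) rather than `unannotated`.
#' @return character vector of categories.
#' @export
protein_category <- function(protein_id, annotation,
                             mito_ids = character(0),
                             assume_nonmito = TRUE) {
  i <- match(protein_id, annotation$protein_id)
  enc <- annotation$encoding[i]
  cx <- annotation$complex[i]
  is_ox <- !is.na(cx) & cx != "none"
  out <- rep(if (assume_nonmito) "nuclear non-mito" else "unannotated",
             length(protein_id))
  out[protein_id %in% mito_ids] <- "nuclear mito"
  out[is_ox & enc == "nuclear"] <- "nuclear OXPHOS"
  out[!is.na(enc) & enc == "mitochondrial"] <- "MT-encoded OXPHOS"
  out
}

summary_stats <- function(v) {
  v <- v[is.finite(v)]
  q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
       else rep(NA_real_, 3L)
  data.frame(n_quantified = length(v), q25 = q[1], median_log2_fc = q[2],
             q75 = q[3])
}

#' Summarize fold changes by protein category
#'
#' @param results data.frame with `protein_id` and `mean_log2_fc`
#'   (a [quantify_psilac()] table).
#' @param annotation OXPHOS annotation table.
#' @param mito_ids see [protein_category()].
#' @param assume_nonmito see [protein_category()].
#' @return `data.frame`: one row per represented category with n, median and
#'   quartiles of the mean log2 fold change.
#' @export
summarize_by_category <- function(results, annotation,
                                  mito_ids = character(0),
                                  assume_nonmito = TRUE) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  cat <- protein_category(results$protein_id, annotation, mito_ids,
                          assume_nonmito)
  parts <- split(results$mean_log2_fc, cat)
  out <- do.call(rbind, lapply(names(parts), function(nm)
    cbind(category = nm, summary_stats(parts[[nm]]))))
  lev <- c("MT-encoded OXPHOS", "nuclear OXPHOS", "nuclear mito",
           "nuclear non-mito", "unannotated")
  out[order(match(out$category, lev)), ][, c("category", "n_quantified",
                                             "q25", "median_log2_fc", "q75")]
}

#' Summarize fold changes by assembly module of one complex
#'
#' @param results data.frame with `protein_id` and `mean_log2_fc`.
#' @param annotation OXPHOS annotation table.
#' @param complex one of `"CI"`..`"CV"`.
#' @return `data.frame` with one row per module of the complex (modules
#'   with no quantified protein keep `n_quantified = 0`), columns `complex`,
#'   `module`, `n_quantified`, `q25`, `median_log2_fc`, `q75`, `n_mito`,
#'   `n_nuclear`.
#' @export
summarize_by_module <- function(results, annotation, complex) {
  if (!complex %in% setdiff(COMPLEX_LEVELS, "none"))
    stop("unknown complex: ", complex)
  ann <- annotation[annotation$complex == complex, ]
  modules <- unique(ann$module)
  out <- do.call(rbind, lapply(modules, function(md) {
    ids <- ann$protein_id[ann$module == md]
    hit <- results[results$protein_id %in% ids, ]
    st <- summary_stats(hit$mean_log2_fc)
    enc <- ann$encoding[match(hit$protein_id, ann$protein_id)]
    cbind(complex = complex, module = md, st,
          n_mito = sum(enc == "mitochondrial"),
          n_nuclear = sum(enc == "nuclear"))
  }))
  rownames(out) <- NULL
  out[, c("complex", "module", "n_quantified", "q25", "median_log2_fc",
          "q75", "n_mito", "n_nuclear")]
}

#' Per-category cross-experiment Pearson correlation
#'
#' Correlates mean log2 fold changes of two experiments over their shared
#' proteins, within each protein category (Pearson, as used for the
#' cross-cell-line comparison); categories with fewer than 3 shared
#' proteins are skipped with a warning.
#'
#' @param results_a,results_b data.frames with `protein_id`, `mean_log2_fc`.
#' @param annotation OXPHOS annotation table.
#' @param mito_ids see [protein_category()].
#' @return `data.frame` with `category`, `n_shared`, `pearson_r`.
#' @export
category_correlation <- function(results_a, results_b, annotation,
                                 mito_ids = character(0)) {
  shared <- intersect(results_a$protein_id, results_b$protein_id)
  a <- results_a$mean_log2_fc[match(shared, results_a$protein_id)]
  b <- results_b$mean_log2_fc[match(shared, results_b$protein_id)]
  cat <- protein_category(shared, annotation, mito_ids)
  out <- lapply(unique(cat), function(nm) {
    i <- cat == nm & is.finite(a) & is.finite(b)
    if (sum(i) < 3L) {
      warning("category '", nm, "' has fewer than 3 shared proteins; skipped")
      return(NULL)
    }
    data.frame(category = nm, n_shared = sum(i),
               pearson_r = stats::cor(a[i], b[i], method = "pearson"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no category has 3 or more shared proteins")
  rownames(out) <- NULL
  out
}
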