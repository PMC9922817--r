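# Peptide-to-protein SILAC ratio quantification and moderated testing.

#' Peptide-level log2 ratios for one protein/replicate
#'
#' Each evidence row contributes `log2(CAP channel / control channel)`;
#' rows with a missing or nonpositive channel are excluded and tallied.
#' Label-swapped replicates are handled by passing the replicate's actual
#' CAP channel, so a positive ratio always means higher in the drug
#' condition.
#'
#' @param rows evidence rows (`intensity_M`, `intensity_H` columns).
#' @param cap_channel `"H"` or `"M"`: which channel carries the drug
#'   condition's newly synthesized protein in these rows.
#' @return numeric vector of log2 ratios, with attribute `n_excluded`.
#' @export
peptide_log_ratios <- function(rows, cap_channel = c("H", "M")) {
  cap_channel <- match.arg(cap_channel)
  cap <- if (cap_channel == "H") rows$intensity_H else rows$intensity_M
  ctrl <- if (cap_channel == "H") rows$intensity_M else rows$intensity_H
  ok <- !is.na(cap) & !is.na(ctrl) & cap > 0 & ctrl > 0
  out <- log2(cap[ok] / ctrl[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Aggregate peptide ratios to a protein ratio
#'
#' The protein-level log2 ratio is the median of its peptide log2 ratios,
#' robust to single aberrant peptides; a protein with no usable peptide in a
#' replicate is unquantified there.
#'
#' @param ratios numeric vector of peptide log2 ratios.
#' @return list with `log2_ratio` (NA if empty) and `n_peptides`.
#' @export
aggregate_protein <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L)
    return(list(log2_ratio = NA_real_, n_peptides = 0L))
  list(log2_ratio = stats::median(ratios), n_peptides = length(ratios))
}

#' Normalize a protein x replicate log2-ratio matrix
#'
#' Default median-centering per replicate: subtracts each column's median so
#' the global median log2 ratio is exactly 0, correcting the location shift
#' introduced by mixing error between the labeled lysates. (A
#' variance-stabilizing arcsinh mode operates upstream on intensities, see
#' [quantify_psilac()].)
#'
#' @param mat numeric matrix, proteins x replicates; each column needs at
#'   least 3 finite values.
#' @return matrix of the same shape with zero median columns.
#' @export
normalize_ratios <- function(mat) {
  stopifnot(is.matrix(mat))
  n_ok <- colSums(is.finite(mat))
  if (any(n_ok == 0L))
    stop("replicate column(s) with no quantified protein: ",
         paste(colnames(mat)[n_ok == 0L], collapse = ", "))
  if (any(n_ok < 3L))
    stop("need at least 3 quantified proteins per replicate to normalize")
  sweep(mat, 2L, apply(mat, 2L, stats::median, na.rm = TRUE), "-")
}

arcsinh_transform <- function(x, scale) asinh(x / scale)

#' Quantify a pSILAC experiment
#'
#' The central fitting step: peptide evidence to protein-level CAP/control
#' log2 ratios per replicate, per-replicate normalization, the
#' all-replicates completeness filter, and an empirical-Bayes moderated
#' one-sample test of the mean log2 fold change against zero with
#' Benjamini-Hochberg FDR across all tested proteins.
#'
#' @param evidence a `silac_evidence` table (pSILAC rows). The replicate's
#'   label assignment comes from its `cap_channel` column when present,
#'   otherwise from `swap_replicates`.
#' @param annotation optional annotation table (columns `protein_id`,
#'   `encoding`, `complex`) merged into the result.
#' @param swap_replicates replicate ids whose labels are swapped (CAP in M)
#'   when the evidence has no `cap_channel` column; unlisted replicates
#'   carry CAP in H.
#' @param normalization `"median"` (default), `"arcsinh"` (affine-arcsinh
#'   variance stabilization of channel intensities before ratio formation,
#'   an approximation of variance-stabilizing normalization, followed by
#'   median-centering), or `"none"`.
#' @param min_peptides minimum usable peptides per replicate (default 1).
#' @return object of class `psilac_fit`: list with `table` (the volcano
#'   table: `protein_id`, per-replicate ratios, `n_peptides`,
#'   `mean_log2_fc`, `t`, `p_value`, `fdr`, plus annotation columns),
#'   `ratios` (normalized matrix), `n_peptides` (matrix), `prior`
#'   (the [fit_ebayes_prior()] result), `n_replicates`, and `qc`.
#' @export
quantify_psilac <- function(evidence, annotation = NULL,
                            swap_replicates = character(0),
                            normalization = c("median", "arcsinh", "none"),
                            min_peptides = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(is.data.frame(evidence))
  req <- c("peptide_sequence", "protein_id", "replicate_id",
           "intensity_M", "intensity_H")
  miss <- setdiff(req, names(evidence))
  if (length(miss)) stop("evidence lacks column(s): ", paste(miss, collapse = ", "))

  reps <- sort(unique(evidence$replicate_id))
  cap_of <- function(r, rows) {
    if ("cap_channel" %in% names(evidence)) {
      ch <- unique(rows$cap_channel)
      if (length(ch) != 1L || !ch %in% c("H", "M"))
        stop("replicate '", r, "' has an inconsistent cap_channel")
      ch
    } else if (r %in% swap_replicates) "M" else "H"
  }

  if (normalization == "arcsinh") {
    # affine-arcsinh per replicate: scale anchored well below the intensity
    # distribution (5th percentile) so asinh(I/scale) ~ log(2 I/scale) for
    # the bulk of measurements; ratios are formed on the transformed scale,
    # approaching the log2 ratio at high intensity while damping variance
    # inflation near the detection floor
    for (r in reps) {
      idx <- evidence$replicate_id == r
      vals <- c(evidence$intensity_M[idx], evidence$intensity_H[idx])
      sc <- stats::quantile(vals[is.finite(vals) & vals > 0], 0.05,
                            names = FALSE)
      evidence$intensity_M[idx] <- exp(log(2) *
        arcsinh_transform(evidence$intensity_M[idx], sc) / log(2))
      evidence$intensity_H[idx] <- exp(log(2) *
        arcsinh_transform(evidence$intensity_H[idx], sc) / log(2))
    }
  }

  prot <- sort(unique(evidence$protein_id))
  ratios <- matrix(NA_real_, length(prot), length(reps),
                   dimnames = list(prot, reps))
  npep <- matrix(0L, length(prot), length(reps), dimnames = list(prot, reps))
  n_excluded <- 0L
  split_rep <- split(seq_len(nrow(evidence)), evidence$replicate_id)
  for (r in reps) {
    rows_r <- evidence[split_rep[[r]], ]
    ch <- cap_of(r, rows_r)
    lr <- peptide_log_ratios(rows_r, ch)
    n_excluded <- n_excluded + attr(lr, "n_excluded")
    keep <- seq_along(lr)
    pid <- rows_r$protein_id[!is.na(rows_r$intensity_M) &
                             !is.na(rows_r$intensity_H) &
                             rows_r$intensity_M > 0 & rows_r$intensity_H > 0]
    agg <- tapply(as.numeric(lr), pid, function(v) {
      a <- aggregate_protein(v); c(a$log2_ratio, a$n_peptides)
    })
    if (length(agg)) {
      m <- do.call(rbind, agg)
      ratios[rownames(m), r] <- m[, 1]
      npep[rownames(m), r] <- as.integer(m[, 2])
    }
  }

  if (normalization %in% c("median", "arcsinh"))
    ratios <- normalize_ratios(ratios)

  complete <- rowSums(is.finite(ratios) & npep >= min_peptides) == length(reps)
  if (!any(complete))
    stop("no protein is quantified in all replicates")
  R <- ratios[complete, , drop = FALSE]
  mean_fc <- rowMeans(R)
  s2 <- apply(R, 1L, stats::var)
  df <- rep(length(reps) - 1L, nrow(R))
  prior <- fit_ebayes_prior(s2, df)
  mt <- moderated_test(mean_fc, s2, df, n = length(reps), prior)
  fdr <- bh_adjust(mt$p_value)

  tab <- data.frame(protein_id = rownames(R), R,
                    n_peptides = apply(npep[complete, , drop = FALSE], 1L, min),
                    mean_log2_fc = mean_fc, t = mt$t, p_value = mt$p_value,
                    fdr = fdr, row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(tab)[seq_along(reps) + 1L] <- paste0("log2_ratio_", reps)
  if (!is.null(annotation)) {
    ann <- annotation[, intersect(c("protein_id", "gene", "encoding",
                                    "complex", "module"), names(annotation)),
                      drop = FALSE]
    tab <- merge(tab, ann, by = "protein_id", all.x = TRUE, sort = FALSE)
  }
  tab <- tab[order(tab$p_value), ]
  rownames(tab) <- NULL

  structure(list(table = tab, ratios = ratios, n_peptides = npep,
                 prior = prior, n_replicates = length(reps),
                 qc = list(n_excluded_rows = n_excluded,
                           n_proteins_seen = length(prot),
                           n_proteins_tested = sum(complete),
                           normalization = normalization)),
            class = "psilac_fit")
}

#' Volcano table of a pSILAC fit
#'
#' @param fit a `psilac_fit`.
#' @return the per-protein results `data.frame` (one row per protein passing
#'   the all-replicates filter; BH FDR across all tested proteins).
#' @export
volcano_table <- function(fit) {
  stopifnot(inherits(fit, "psilac_fit"))
  fit$table
}

#' @export
print.psilac_fit <- function(x, ...) {
  cat("pSILAC quantification:", x$qc$n_proteins_tested, "of",
      x$qc$n_proteins_seen, "proteins quantified in all",
      x$n_replicates, "replicates\n")
  print(x$prior)
  cat("proteins at FDR < 0.05:", sum(x$table$fdr < 0.05), "\n")
  invisible(x)
}

#' @export
summary.psilac_fit <- function(object, fdr = 0.05, ...) {
  tab <- object$table
  sig <- tab[tab$fdr < fdr, ]
  cat("pSILAC fit over", nrow(tab), "proteins,", object$n_replicates,
      "replicates (", object$qc$normalization, "normalization )\n")
  cat(nrow(sig), "proteins at FDR <", fdr, "; of these",
      sum(sig$mean_log2_fc < 0), "down in CAP\n")
  cat("median |log2 FC|:", signif(stats::median(abs(tab$mean_log2_fc)), 3), "\n")
  invisible(tab)
}

#' @export
coef.psilac_fit <- function(object, ...) {
  stats::setNames(object$table$mean_log2_fc, object$table$protein_id)
}

#' Volcano plot of a pSILAC fit
#'
#' @param x a `psilac_fit`.
#' @param fdr significance threshold used for highlighting.
#' @param highlight optional protein ids drawn in a second colour (e.g. the
#'   mitochondrial-encoded subunits).
#' @param ... passed to [graphics::plot()].
#' @export
plot.psilac_fit <- function(x, fdr = 0.05, highlight = NULL, ...) {
  tab <- x$table
  col <- ifelse(tab$fdr < fdr, "red3", "grey50")
  if (!is.null(highlight))
    col[tab$protein_id %in% highlight] <- "seagreen3"
  graphics::plot(tab$mean_log2_fc, -log10(tab$p_value), col = col, pch = 16,
                 cex = 0.6, xlab = "mean log2 FC (CAP/control)",
                 ylab = "-log10 p", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
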