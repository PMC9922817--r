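# Degradation inference from the 4 h pulse / 4 h chase design.
#
# A decrease of the pulse cohort's H/L ratio under drug relative to vehicle
# reads out accelerated degradation of newly synthesized protein; the M/L
# ratio of the chase cohort reads out synthesis inhibition. Proteins are
# classified CAP-sensitive or unchanged from the separate pSILAC
# experiment's mean log2 H/M, and the two groups are compared with a
# one-sided Wilcoxon rank-sum test.

#' Classify CAP sensitivity from a pSILAC log2 H/M value
#'
#' The boundary is inclusive on the unchanged side: `log2 H/M >= -0.5` is
#' `"unchanged"`, `< -0.5` is `"CAP-sensitive"`; missing values are
#' `"unassigned"`.
#'
#' @param log2_hm numeric vector of mean log2 H/M (CAP/control) values.
#' @return character vector over `{"unchanged", "CAP-sensitive", "unassigned"}`.
#' @export
classify_cap_sensitivity <- function(log2_hm) {
  out <- rep("unassigned", length(log2_hm))
  fin <- is.finite(log2_hm)
  out[fin & log2_hm >= -0.5] <- "unchanged"
  out[fin & log2_hm < -0.5] <- "CAP-sensitive"
  out
}

#' Degradation score from paired H/L ratios
#'
#' `log2(H/L under drug / H/L under vehicle)`: negative means the newly
#' synthesized (pulse-labeled) cohort was lost faster under the drug.
#' Invariant to rescaling all four channel intensities by a common factor.
#'
#' @param hl_cap,hl_dmso H/L intensity ratios under drug and vehicle (> 0;
#'   nonpositive or missing values give `NA`).
#' @return numeric vector of log2 scores.
#' @export
degradation_score <- function(hl_cap, hl_dmso) {
  ok <- is.finite(hl_cap) & is.finite(hl_dmso) & hl_cap > 0 & hl_dmso > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log2(hl_cap[ok] / hl_dmso[ok])
  if (any(!ok)) attr(out, "n_flagged") <- sum(!ok)
  out
}

#' Synthesis score from paired M/L ratios
#'
#' As [degradation_score()] with the chase-label (M) channel: the degree of
#' synthesis inhibition of newly made M protein under the drug.
#'
#' @param ml_cap,ml_dmso M/L intensity ratios under drug and vehicle.
#' @return numeric vector of log2 scores.
#' @export
synthesis_score <- function(ml_cap, ml_dmso) {
  degradation_score(ml_cap, ml_dmso)
}

#' One-sided Wilcoxon rank-sum test
#'
#' Exact p-value when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param alternative `"a-less-than-b"` or `"a-greater-than-b"`.
#' @return p-value in (0, 1].
#' @export
wilcoxon_one_sided <- function(group_a, group_b,
                               alternative = c("a-less-than-b",
                                               "a-greater-than-b")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  alt <- if (alternative == "a-less-than-b") "less" else "greater"
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- n <= 12L && !ties
  p <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                           alternative = alt, exact = exact,
                                           correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Per-protein chase scores
#'
#' Aggregates chase evidence to protein-level H/L and M/L log2 ratios per
#' condition (median over peptides and replicates), optionally
#' median-centers each condition's ratio vectors (flagged in the output
#' attributes; the group comparison is invariant to this location shift),
#' and forms synthesis and degradation scores against the `"DMSO"`
#' reference. CAP sensitivity is classified from the pSILAC experiment's
#' mean log2 H/M, assigned only to nuclear-encoded OXPHOS subunits when an
#' annotation is given.
#'
#' @param evidence chase `silac_evidence` (conditions `"DMSO"` and `"CAP"`
#'   and/or `"CAP+MG132"`).
#' @param psilac data.frame with `protein_id` and `mean_log2_fc` (a
#'   [quantify_psilac()] table), the classification source.
#' @param annotation optional annotation table; when given, only
#'   nuclear-encoded proteins with an OXPHOS complex get a category.
#' @param drug which drug arm to score against DMSO (default `"CAP"`).
#' @param normalize median-center log2 H/L and M/L per condition first.
#' @return `data.frame` of class `chase_scores` with columns `protein_id`,
#'   `synthesis_score`, `degradation_score`, `psilac_log2_hm`, `category`.
#' @export
chase_scores <- function(evidence, psilac, annotation = NULL,
                         drug = c("CAP", "CAP+MG132"), normalize = TRUE) {
  drug <- match.arg(drug)
  stopifnot(is.data.frame(evidence), is.data.frame(psilac))
  need <- c(drug, "DMSO")
  if (!all(need %in% evidence$condition))
    stop("chase evidence must contain conditions: ", paste(need, collapse = ", "))

  ratio_tab <- function(cond, num_col) {
    rows <- evidence[evidence$condition == cond, ]
    num <- rows[[num_col]]; den <- rows$intensity_L
    ok <- !is.na(num) & !is.na(den) & num > 0 & den > 0
    vals <- log2(num[ok] / den[ok])
    tapply(vals, rows$protein_id[ok], stats::median)
  }
  hl_drug <- ratio_tab(drug, "intensity_H")
  hl_ref <- ratio_tab("DMSO", "intensity_H")
  ml_drug <- ratio_tab(drug, "intensity_M")
  ml_ref <- ratio_tab("DMSO", "intensity_M")
  if (normalize) {
    hl_drug <- hl_drug - stats::median(hl_drug, na.rm = TRUE)
    hl_ref <- hl_ref - stats::median(hl_ref, na.rm = TRUE)
    ml_drug <- ml_drug - stats::median(ml_drug, na.rm = TRUE)
    ml_ref <- ml_ref - stats::median(ml_ref, na.rm = TRUE)
  }

  ids <- sort(unique(evidence$protein_id))
  deg <- degradation_score(2^unname(hl_drug[ids]), 2^unname(hl_ref[ids]))
  syn <- synthesis_score(2^unname(ml_drug[ids]), 2^unname(ml_ref[ids]))
  hm <- psilac$mean_log2_fc[match(ids, psilac$protein_id)]
  category <- classify_cap_sensitivity(hm)
  if (!is.null(annotation)) {
    ann <- annotation[match(ids, annotation$protein_id), ]
    eligible <- !is.na(ann$encoding) & ann$encoding == "nuclear" &
      !is.na(ann$complex) & ann$complex != "none"
    category[!eligible] <- "unassigned"
  }
  out <- data.frame(protein_id = ids, synthesis_score = as.numeric(syn),
                    degradation_score = as.numeric(deg),
                    psilac_log2_hm = hm, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "normalized") <- normalize
  attr(out, "drug") <- drug
  class(out) <- c("chase_scores", "data.frame")
  out
}

#' Compare chase scores between CAP-sensitivity groups
#'
#' One-sided Wilcoxon rank-sum test that the CAP-sensitive group's scores
#' are smaller than the unchanged group's, applied to the degradation and
#' the synthesis score. Run it on an MG132+CAP score table to test
#' proteasome rescue (expected non-significant).
#'
#' @param scores a [chase_scores()] table.
#' @return `data.frame` with one row per score
#'   (`score`, `n_unchanged`, `n_sensitive`, `p_value`).
#' @export
chase_group_comparison <- function(scores) {
  stopifnot(is.data.frame(scores))
  one <- function(colname) {
    v <- scores[[colname]]
    sens <- v[scores$category == "CAP-sensitive" & is.finite(v)]
    unch <- v[scores$category == "unchanged" & is.finite(v)]
    if (length(sens) == 0L) stop("no scored protein in category 'CAP-sensitive'")
    if (length(unch) == 0L) stop("no scored protein in category 'unchanged'")
    data.frame(score = sub("_score$", "", colname),
               n_unchanged = length(unch), n_sensitive = length(sens),
               p_value = wilcoxon_one_sided(sens, unch, "a-less-than-b"),
               stringsAsFactors = FALSE)
  }
  rbind(one("degradation_score"), one("synthesis_score"))
}

#' @export
print.chase_scores <- function(x, ...) {
  cat("chase scores for", nrow(x), "proteins (drug arm:", attr(x, "drug"),
      ")\n  categories:", sum(x$category == "unchanged"), "unchanged,",
      sum(x$category == "CAP-sensitive"), "CAP-sensitive,",
      sum(x$category == "unassigned"), "unassigned\n")
  invisible(x)
}
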