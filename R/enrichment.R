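# Term-enrichment testing: one-sided hypergeometric (Fisher) p-values with
# Benjamini-Hochberg correction. A deliberate plain-Fisher substitution for
# web-service GO tools; the background convention is the set of proteins
# quantified across all protocols under comparison.

#' One-sided Fisher (hypergeometric) term enrichment
#'
#' For each term with `m` background proteins, `k` of which are in the
#' foreground of size `K` drawn from a background of size `N`, the
#' enrichment p-value is the upper hypergeometric tail `P[X >= k]`. Terms
#' with no foreground hit get `p = 1`. FDR is Benjamini-Hochberg across
#' terms.
#'
#' @param foreground protein ids of interest (must be a subset of
#'   `background`).
#' @param background universe of protein ids.
#' @param terms long-format table with columns `term_id`, `protein_id`
#'   (and optionally `term_name`).
#' @return `data.frame` with columns `term_id`, `term_name`, `k`, `K`, `m`,
#'   `N`, `odds_ratio`, `p_value`, `fdr`, sorted by p.
#' @export
fisher_enrichment <- function(foreground, background, terms) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  stray <- setdiff(foreground, background)
  if (length(stray))
    stop("foreground protein(s) missing from background: ",
         paste(utils::head(stray, 10L), collapse = ", "),
         if (length(stray) > 10L) ", ..." else "")
  stopifnot(is.data.frame(terms), all(c("term_id", "protein_id") %in% names(terms)))
  terms <- terms[terms$protein_id %in% background, ]
  if (length(unique(terms$term_id)) < 2L)
    stop("need at least 2 terms with background proteins")
  N <- length(background); K <- length(foreground)
  by_term <- split(terms$protein_id, terms$term_id)
  term_name <- if ("term_name" %in% names(terms))
    vapply(split(terms$term_name, terms$term_id), `[[`, "", 1L)
  else stats::setNames(names(by_term), names(by_term))
  rows <- lapply(names(by_term), function(tid) {
    hits <- unique(by_term[[tid]])
    m <- length(hits)
    k <- sum(hits %in% foreground)
    p <- if (k == 0L) 1 else stats::phyper(k - 1L, m, N - m, K,
                                           lower.tail = FALSE)
    odds <- (k * (N - m - K + k)) / ((K - k) * (m - k))
    data.frame(term_id = tid, term_name = unname(term_name[tid]),
               k = k, K = K, m = m, N = N,
               odds_ratio = odds, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_i = min_{j >= i} p_(j) m / j`, clipped at 1),
#' returned in the input order. Inputs must lie in (0, 1].
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
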