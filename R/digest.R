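# In-silico protease digestion and observable-peptide accounting.
#
# Cleavage rules: trypsin after K/R, lysC after K, chymotrypsin after the
# aromatic residues F/W/Y (the specificity relevant to SILAC labeling with
# essential amino acids). Trypsin and chymotrypsin obey the classical proline
# rule (no cut before P); lysC cleaves regardless of a following proline.

PROTEASES <- c("trypsin", "lysc", "chymotrypsin")

PROTEASE_TARGETS <- list(
  trypsin      = c("K", "R"),
  lysc         = "K",
  chymotrypsin = c("F", "W", "Y")
)

#' Digestion specification
#'
#' @param proteases character vector, non-empty subset of
#'   `c("trypsin", "lysc", "chymotrypsin")`.
#' @param missed_cleavages maximum number of missed cleavages (0..10).
#' @param min_len,max_len observable length window (defaults 6 and 30, the
#'   standard detectability window for shotgun MS).
#' @param proline_rule suppress trypsin/chymotrypsin cuts before proline
#'   (lysC is unaffected either way).
#' @return a list of class `digest_spec`.
#' @examples
#' digest_spec("trypsin")
#' digest_spec(c("lysc", "trypsin"), missed_cleavages = 2)
#' @export
digest_spec <- function(proteases, missed_cleavages = 0L, min_len = 6L,
                        max_len = 30L, proline_rule = TRUE) {
  proteases <- match.arg(as.character(proteases), PROTEASES, several.ok = TRUE)
  proteases <- unique(proteases)
  missed_cleavages <- as.integer(missed_cleavages)
  if (is.na(missed_cleavages) || missed_cleavages < 0L || missed_cleavages > 10L)
    stop("'missed_cleavages' must be an integer in 0..10")
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len > max_len) stop("'min_len' must be <= 'max_len'")
  structure(list(proteases = proteases, missed_cleavages = missed_cleavages,
                 min_len = min_len, max_len = max_len,
                 proline_rule = isTRUE(proline_rule)),
            class = "digest_spec")
}

spec_label <- function(spec) {
  paste0(paste(sort(spec$proteases), collapse = "+"), "_mc", spec$missed_cleavages)
}

#' Cleavage sites of a protease set
#'
#' Returns the 1-based after-residue cut positions, i.e. a site at position
#' `i` separates residues `i` and `i + 1`. The site list of a protease
#' combination is the union of the individual proteases' sites.
#'
#' @param sequence amino-acid string (validated).
#' @param proteases protease set as in [digest_spec()].
#' @param proline_rule see [digest_spec()].
#' @return strictly increasing integer vector of cut positions (possibly
#'   empty); the terminal residue is never a site.
#' @examples
#' cleavage_sites("AKPRA", "trypsin")      # K before P suppressed -> 4
#' cleavage_sites("AKPRA", "lysc")         # lysC ignores proline  -> 2
#' cleavage_sites("AFAYA", "chymotrypsin") # -> 2, 4
#' @export
cleavage_sites <- function(sequence, proteases, proline_rule = TRUE) {
  validate_sequence(sequence)
  proteases <- match.arg(as.character(proteases), PROTEASES, several.ok = TRUE)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  res <- chars[-n]                     # residue at each candidate position
  nxt <- chars[-1L]                    # following residue
  cut <- rep(FALSE, n - 1L)
  for (p in unique(proteases)) {
    hit <- res %in% PROTEASE_TARGETS[[p]]
    if (proline_rule && p %in% c("trypsin", "chymotrypsin"))
      hit <- hit & nxt != "P"
    cut <- cut | hit
  }
  which(cut)
}

#' Digest a protein into peptides
#'
#' With `missed_cleavages = 0` the peptides partition the sequence; with
#' `missed_cleavages = m` every run of up to `m + 1` adjacent fully-cleaved
#' fragments is additionally reported. No length filter is applied here (see
#' [observable_peptides()]).
#'
#' @param protein either a single-row `protein_set`, a list with `id` and
#'   `sequence`, or a bare sequence string.
#' @param spec a [digest_spec()].
#' @return `data.frame` with columns `protein_id`, `start`, `end`, `length`,
#'   `n_missed`, `sequence`, ordered by `(start, end)`.
#' @examples
#' digest("MKAAAAAR", digest_spec("trypsin"))
#' @export
digest <- function(protein, spec) {
  stopifnot(inherits(spec, "digest_spec"))
  pr <- as_protein_entry(protein)
  sites <- cleavage_sites(pr$sequence, spec$proteases, spec$proline_rule)
  n <- nchar(pr$sequence)
  bounds <- c(0L, sites, n)            # fragment k spans bounds[k]+1 .. bounds[k+1]
  nfrag <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (m in 0:min(spec$missed_cleavages, nfrag - 1L)) {
    i <- seq_len(nfrag - m)
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + m + 1L])
    missed <- c(missed, rep(m, length(i)))
  }
  ord <- order(starts, ends)
  out <- data.frame(
    protein_id = pr$id,
    start = starts[ord], end = ends[ord],
    length = ends[ord] - starts[ord] + 1L,
    n_missed = missed[ord],
    sequence = substring(pr$sequence, starts[ord], ends[ord]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Theoretically observable peptides
#'
#' [digest()] output restricted to the observable length window
#' (`min_len`..`max_len` of the spec, default 6-30 residues).
#'
#' @inheritParams digest
#' @return `data.frame` as in [digest()], ordered by `(start, end)`.
#' @export
observable_peptides <- function(protein, spec) {
  pep <- digest(protein, spec)
  out <- pep[pep$length >= spec$min_len & pep$length <= spec$max_len, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observable-peptide count matrix
#'
#' Counts of theoretically observable peptides per protein (rows) and
#' digestion spec (columns), the quantity underlying iBAQ divisors and the
#' comparison of protease protocols.
#'
#' @param proteins a `protein_set` (duplicate ids rejected).
#' @param specs list of [digest_spec()] objects; column labels are derived
#'   from the protease set and missed-cleavage setting and must be unique.
#' @return integer matrix, `dimnames = list(protein id, spec label)`.
#' @export
observable_count_matrix <- function(proteins, specs) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L, length(specs) > 0L)
  if (anyDuplicated(proteins$id))
    stop("duplicate protein id(s): ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  labels <- vapply(specs, spec_label, "")
  if (anyDuplicated(labels))
    stop("duplicate digestion spec label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out <- matrix(0L, nrow(proteins), length(specs),
                dimnames = list(proteins$id, labels))
  for (j in seq_along(specs))
    out[, j] <- vapply(seq_len(nrow(proteins)), function(i)
      nrow(observable_peptides(proteins[i, ], specs[[j]])), 0L)
  out
}

#' iBAQ: intensity per observable peptide
#'
#' @param protein_intensity nonnegative summed protein intensity.
#' @param n_observable number of theoretically observable peptides; a count
#'   of zero yields `NA` (undefined iBAQ, reported as missing rather than an
#'   error or infinity).
#' @return `protein_intensity / n_observable`, vectorized.
#' @export
ibaq <- function(protein_intensity, n_observable) {
  if (any(protein_intensity < 0, na.rm = TRUE))
    stop("'protein_intensity' must be nonnegative")
  if (any(n_observable < 0, na.rm = TRUE))
    stop("'n_observable' must be a nonnegative count")
  out <- protein_intensity / n_observable
  out[!is.na(n_observable) & n_observable == 0] <- NA_real_
  out
}

as_protein_entry <- function(protein) {
  if (is.character(protein) && length(protein) == 1L)
    return(list(id = "protein", sequence = toupper(protein)))
  if (is.data.frame(protein)) {
    if (nrow(protein) != 1L) stop("expected a single protein row")
    return(list(id = protein$id, sequence = protein$sequence))
  }
  if (is.list(protein) && !is.null(protein$sequence))
    return(list(id = if (is.null(protein$id)) "protein" else protein$id,
                sequence = toupper(protein$sequence)))
  stop("cannot interpret 'protein'; give a sequence string or a protein_set row")
}
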