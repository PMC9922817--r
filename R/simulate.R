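# Generative model of three-channel SILAC evidence with known ground truth.
#
# Proteins carry first-order turnover parameters (see kinetics.R); evidence
# rows are peptide x replicate intensities built from the closed-form channel
# amounts, a peptide-specific ionization factor shared across channels (so
# noiseless ratios are exact, mirroring SILAC's within-peptide ratio
# principle), independent multiplicative log-normal channel noise, a global
# per-channel mixing bias, and logistic intensity-dependent dropout.

#' Noise model for evidence generation
#'
#' @param peptide_factor_sigma sd (natural-log scale) of the log-normal
#'   peptide ionization factor, shared across channels and replicates.
#' @param channel_noise_sigma sd (natural-log scale) of independent
#'   multiplicative measurement noise per channel.
#' @param mixing_bias named multiplicative factor per channel
#'   (`c(L = , M = , H = )`), emulating mixing error between the labeled
#'   lysates; must be positive.
#' @param dropout_midpoint,dropout_slope logistic dropout on log10 intensity:
#'   `P(drop) = plogis(dropout_slope * (dropout_midpoint - log10 I))`.
#'   `dropout_midpoint = -Inf` disables dropout. Defaults drop roughly 10%
#'   of channel measurements at the default intensity scale.
#' @param seed integer seed; all randomness in [generate_evidence()] flows
#'   from it.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(peptide_factor_sigma = 0.5, channel_noise_sigma = 0.2,
                        mixing_bias = c(L = 1, M = 1, H = 1),
                        dropout_midpoint = 1.5, dropout_slope = 1.2,
                        seed = 1L) {
  if (peptide_factor_sigma < 0 || channel_noise_sigma < 0)
    stop("noise sigmas must be >= 0")
  mixing_bias <- mixing_bias[c("L", "M", "H")]
  if (anyNA(mixing_bias) || any(mixing_bias <= 0))
    stop("'mixing_bias' must give positive factors for channels L, M, H")
  if (dropout_slope < 0) stop("'dropout_slope' must be >= 0")
  structure(list(peptide_factor_sigma = peptide_factor_sigma,
                 channel_noise_sigma = channel_noise_sigma,
                 mixing_bias = mixing_bias,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free limit of the noise model
#'
#' Zero sigmas, unit mixing bias, dropout disabled: generated peptide ratios
#' equal the protein closed-form ratios exactly.
#'
#' @param seed integer seed (still consumed, for interface uniformity).
#' @return a `noise_model`.
#' @export
noiseless_model <- function(seed = 1L) {
  noise_model(peptide_factor_sigma = 0, channel_noise_sigma = 0,
              mixing_bias = c(L = 1, M = 1, H = 1),
              dropout_midpoint = -Inf, dropout_slope = 0, seed = seed)
}

#' Random protein sequences for simulation
#'
#' Uniform residue draws over the 20 canonical amino acids; the first
#' `n_mt` proteins are flagged mitochondrial-encoded (ids `MTP001`...),
#' the rest nuclear (`NUC0001`...).
#'
#' @param n number of proteins.
#' @param n_mt number flagged mitochondrial-encoded (default 13, the count
#'   of mtDNA-encoded OXPHOS subunits).
#' @param len_range inclusive range of sequence lengths.
#' @param seed integer seed.
#' @return a `protein_set`.
#' @export
sim_proteins <- function(n, n_mt = 13L, len_range = c(150L, 450L), seed = 1L) {
  stopifnot(n >= 1L, n_mt >= 0L, n_mt <= n)
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(AA_CANONICAL, l, replace = TRUE), collapse = ""), "")
  ids <- c(sprintf("MTP%03d", seq_len(n_mt)),
           sprintf("NUC%04d", seq_len(n - n_mt)))
  protein_set(id = ids, sequence = seqs,
              encoding = rep(c("mitochondrial", "nuclear"), c(n_mt, n - n_mt)))
}

#' Ground-truth turnover parameters for a protein collection
#'
#' Synthesis rates and degradation rates are log-normal across proteins
#' (median half-life about 23 h with the defaults, a realistic mammalian
#' range). Drug effects: mitochondrial-encoded proteins get `mt_f` (strong
#' direct synthesis inhibition); ids in `planted` get `planted_f`; ids in
#' `orphans` get degradation factor `orphan_g` (new-cohort destabilization);
#' everything else is unaffected (f = 1, g = 1).
#'
#' @param proteins a `protein_set`.
#' @param s_meanlog,s_sdlog log-normal parameters of the synthesis rate.
#' @param kd_meanlog,kd_sdlog log-normal parameters of the degradation rate.
#' @param mt_f synthesis factor for mitochondrial-encoded proteins.
#' @param planted ids receiving `planted_f`; `planted_f` their synthesis factor.
#' @param orphans ids receiving `orphan_g`; `orphan_g` their degradation factor.
#' @param seed integer seed.
#' @return `data.frame` with columns `protein_id, s, kd, f, g` (the
#'   ground-truth sidecar table).
#' @export
sim_truth <- function(proteins, s_meanlog = log(100), s_sdlog = 1,
                      kd_meanlog = log(0.03), kd_sdlog = 0.5,
                      mt_f = 0.05, planted = character(0), planted_f = 1,
                      orphans = character(0), orphan_g = 3, seed = 1L) {
  stopifnot(is.data.frame(proteins))
  set.seed(seed)
  n <- nrow(proteins)
  truth <- data.frame(
    protein_id = proteins$id,
    s = stats::rlnorm(n, s_meanlog, s_sdlog),
    kd = stats::rlnorm(n, kd_meanlog, kd_sdlog),
    f = 1, g = 1,
    stringsAsFactors = FALSE
  )
  truth$f[proteins$encoding == "mitochondrial"] <- mt_f
  truth$f[truth$protein_id %in% planted] <- planted_f
  truth$g[truth$protein_id %in% orphans] <- orphan_g
  truth
}

logistic_dropout <- function(intensity, noise) {
  if (!is.finite(noise$dropout_midpoint)) {
    if (noise$dropout_midpoint == -Inf) return(rep(0, length(intensity)))
    return(rep(1, length(intensity)))
  }
  l10 <- ifelse(intensity > 0, log10(intensity), -Inf)
  stats::plogis(noise$dropout_slope * (noise$dropout_midpoint - l10))
}

#' Generate synthetic SILAC evidence
#'
#' Produces one evidence row per observable peptide x replicate (pSILAC:
#' the two conditions are mixed into one MS sample per replicate, new
#' cohorts in the M/H channels per the replicate's label assignment and the
#' light channel pooling both dishes' pre-existing protein) or per peptide x
#' replicate x condition (pulse-chase: each condition dish carries its own
#' L/M/H). Intensities are channel amount x peptide factor x channel noise x
#' mixing bias; each channel is then dropped independently with logistic
#' probability on its log10 intensity (dropped values are `NA`). Proteins
#' with no observable peptide are skipped with a warning.
#'
#' @param proteins a `protein_set`.
#' @param truth ground-truth table from [sim_truth()].
#' @param design a [pulse_design()].
#' @param noise a [noise_model()]; its `seed` drives all randomness.
#' @param spec a [digest_spec()] defining observable peptides
#'   (default lysC+trypsin, 0 missed cleavages, 6-30 residues).
#' @param conditions for pulse-chase designs, the condition dishes to
#'   simulate (subset of `c("CAP", "DMSO", "CAP+MG132")`); the MG132 arm
#'   rescues the degradation effect (g = 1) while keeping the synthesis
#'   effect, emulating proteasome inhibition.
#' @return `data.frame` of class `silac_evidence` with columns
#'   `peptide_sequence, protein_id, replicate_id, condition, intensity_L,
#'   intensity_M, intensity_H` plus, for pSILAC, `cap_channel` recording
#'   which of M/H carries the drug condition's new protein in that
#'   replicate.
#' @export
generate_evidence <- function(proteins, truth, design,
                              noise = noise_model(),
                              spec = digest_spec(c("lysc", "trypsin")),
                              conditions = c("CAP", "DMSO")) {
  stopifnot(is.data.frame(proteins), is.data.frame(truth),
            inherits(design, "pulse_design"), inherits(noise, "noise_model"),
            inherits(spec, "digest_spec"))
  if (!all(proteins$id %in% truth$protein_id))
    stop("every protein needs a row in 'truth'")
  truth <- truth[match(proteins$id, truth$protein_id), ]

  peps <- lapply(seq_len(nrow(proteins)), function(i)
    observable_peptides(proteins[i, ], spec))
  npep <- vapply(peps, nrow, 0L)
  if (any(npep == 0L)) {
    warning("skipping ", sum(npep == 0L),
            " protein(s) without observable peptides: ",
            paste(utils::head(proteins$id[npep == 0L], 5L), collapse = ", "),
            if (sum(npep == 0L) > 5L) ", ..." else "")
    keep <- npep > 0L
    proteins <- proteins[keep, ]; truth <- truth[keep, ]
    peps <- peps[keep]; npep <- npep[keep]
  }
  if (nrow(proteins) == 0L) stop("no protein has an observable peptide")

  set.seed(noise$seed)
  pep_tab <- do.call(rbind, peps)
  pep_idx <- rep(seq_len(nrow(proteins)), npep)    # protein row per peptide
  pep_factor <- stats::rlnorm(nrow(pep_tab), 0, noise$peptide_factor_sigma)

  add_noise <- function(amount) {
    # amount: per-peptide channel amounts (already includes peptide factor)
    amount * stats::rlnorm(length(amount), 0, noise$channel_noise_sigma)
  }
  drop_na <- function(intensity) {
    p <- logistic_dropout(intensity, noise)
    ifelse(stats::runif(length(intensity)) < p, NA_real_, intensity)
  }

  rows <- vector("list", 0L)
  if (design$design_kind == "psilac") {
    amt <- vapply(seq_len(nrow(proteins)), function(i) {
      p <- turnover_params(truth$s[i], truth$kd[i], truth$f[i], truth$g[i])
      c(channel_amounts_psilac(p, design, drug_on = TRUE),
        channel_amounts_psilac(p, design, drug_on = FALSE))
    }, numeric(4))                      # rows: L_cap, new_cap, L_ctrl, new_ctrl
    for (r in seq_len(design$n_replicates)) {
      cap_ch <- if (design$label_swap[r]) "M" else "H"
      L_amt <- (amt[1, ] + amt[3, ])[pep_idx] * pep_factor
      cap_amt <- amt[2, pep_idx] * pep_factor
      ctrl_amt <- amt[4, pep_idx] * pep_factor
      M_amt <- if (cap_ch == "M") cap_amt else ctrl_amt
      H_amt <- if (cap_ch == "H") cap_amt else ctrl_amt
      iL <- drop_na(add_noise(L_amt) * noise$mixing_bias[["L"]])
      iM <- drop_na(add_noise(M_amt) * noise$mixing_bias[["M"]])
      iH <- drop_na(add_noise(H_amt) * noise$mixing_bias[["H"]])
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_sequence = pep_tab$sequence,
        protein_id = pep_tab$protein_id,
        replicate_id = paste0("r", r),
        condition = "mixed",
        intensity_L = iL, intensity_M = iM, intensity_H = iH,
        cap_channel = cap_ch,
        stringsAsFactors = FALSE
      )
    }
  } else {
    conditions <- match.arg(conditions, c("CAP", "DMSO", "CAP+MG132"),
                            several.ok = TRUE)
    for (r in seq_len(design$n_replicates)) {
      for (cond in conditions) {
        amt <- vapply(seq_len(nrow(proteins)), function(i) {
          g_i <- if (cond == "CAP+MG132") 1 else truth$g[i]
          p <- turnover_params(truth$s[i], truth$kd[i], truth$f[i], g_i)
          channel_amounts_chase(p, design, drug_on = cond != "DMSO")
        }, numeric(3))                  # rows: L, M, H
        L_amt <- amt[1, pep_idx] * pep_factor
        M_amt <- amt[2, pep_idx] * pep_factor
        H_amt <- amt[3, pep_idx] * pep_factor
        iL <- drop_na(add_noise(L_amt) * noise$mixing_bias[["L"]])
        iM <- drop_na(add_noise(M_amt) * noise$mixing_bias[["M"]])
        iH <- drop_na(add_noise(H_amt) * noise$mixing_bias[["H"]])
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_sequence = pep_tab$sequence,
          protein_id = pep_tab$protein_id,
          replicate_id = paste0("r", r),
          condition = cond,
          intensity_L = iL, intensity_M = iM, intensity_H = iH,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  # drop rows where every channel is missing
  all_na <- is.na(out$intensity_L) & is.na(out$intensity_M) &
    is.na(out$intensity_H)
  out <- out[!all_na, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("silac_evidence", "data.frame")
  out
}
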