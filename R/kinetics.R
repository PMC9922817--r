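# First-order protein-turnover model behind the SILAC evidence generator.
#
# Each protein has a synthesis rate s (intensity units / h) and degradation
# rate kd (/h), at steady state A0 = s / kd before the pulse. Two orthogonal
# drug knobs: f scales synthesis (the direct effect of a translation
# inhibitor), g >= 1 scales degradation of newly made cohorts only — the
# orphan-subunit effect, in which unassembled new subunits are cleared
# faster, while the assembled pre-existing pool keeps its baseline turnover.

#' Turnover parameters of one protein
#'
#' @param s synthesis rate, intensity units per hour (>= 0).
#' @param kd first-order degradation rate per hour (> 0).
#' @param f drug multiplier on synthesis (>= 0); 1 = no effect.
#' @param g drug multiplier on degradation of drug-window-synthesized and
#'   pulse-labeled cohorts (>= 1); 1 = no effect.
#' @return list of class `turnover_params`.
#' @export
turnover_params <- function(s, kd, f = 1, g = 1) {
  if (kd <= 0) stop("'kd' must be > 0")
  if (s < 0) stop("'s' must be >= 0")
  if (f < 0) stop("'f' must be >= 0")
  if (g < 1) stop("'g' must be >= 1")
  structure(list(s = s, kd = kd, f = f, g = g), class = "turnover_params")
}

#' Labeling-design description
#'
#' Two designs are supported. `"psilac"`: cells switch to labeled medium at
#' time zero, preincubate `pre_h` hours, then receive drug or vehicle for
#' `drug_h` hours (defaults 8 + 16 = 24 h of labeling); the two conditions
#' live in separate dishes carrying the M and H labels, optionally swapped
#' per replicate. `"pulse_chase"`: a single dish is pulsed with H label for
#' `pulse_h` hours, then chased in M label (plus drug or vehicle) for
#' `chase_h` hours (defaults 4 + 4).
#'
#' @param design_kind `"psilac"` or `"pulse_chase"`.
#' @param pre_h,drug_h pSILAC windows in hours.
#' @param pulse_h,chase_h pulse-chase windows in hours.
#' @param n_replicates number of replicates (>= 1).
#' @param label_swap logical vector, one entry per replicate: does that
#'   replicate exchange the condition-to-label assignment? Defaults to
#'   alternating `FALSE`, `TRUE`, ... for pSILAC (a label-swap duplicate)
#'   and all-`FALSE` for pulse-chase (labels are within-dish there).
#' @return list of class `pulse_design`.
#' @export
pulse_design <- function(design_kind = c("psilac", "pulse_chase"),
                         pre_h = 8, drug_h = 16, pulse_h = 4, chase_h = 4,
                         n_replicates = 2L, label_swap = NULL) {
  design_kind <- match.arg(design_kind)
  for (d in c(pre_h, drug_h, pulse_h, chase_h))
    if (is.na(d) || d < 0) stop("all durations must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (is.null(label_swap))
    label_swap <- if (design_kind == "psilac")
      rep_len(c(FALSE, TRUE), n_replicates) else rep(FALSE, n_replicates)
  label_swap <- rep_len(as.logical(label_swap), n_replicates)
  structure(list(design_kind = design_kind, pre_h = pre_h, drug_h = drug_h,
                 pulse_h = pulse_h, chase_h = chase_h,
                 n_replicates = n_replicates, label_swap = label_swap),
            class = "pulse_design")
}

#' Closed-form channel amounts under the pSILAC design
#'
#' The dish switches to labeled medium at t = 0; during the preincubation
#' window (`pre_h`) synthesis runs at rate `s` and degradation at `kd`;
#' during the drug window (`drug_h`) synthesis runs at `s * f` and the
#' labeled cohorts (and the residual pre-existing pool) degrade at `g * kd`
#' when `drug_on`. Returns the pre-existing (light) amount and the newly
#' synthesized (labeled) amount; which of M/H carries `new` is decided by
#' the replicate's label assignment at evidence-generation time.
#'
#' @param p [turnover_params()].
#' @param d [pulse_design()] with `design_kind = "psilac"`.
#' @param drug_on is this the drug-treated dish?
#' @return named numeric vector `c(L = ..., new = ...)`.
#' @export
channel_amounts_psilac <- function(p, d, drug_on) {
  stopifnot(inherits(p, "turnover_params"), inherits(d, "pulse_design"))
  if (d$design_kind != "psilac") stop("design_kind must be 'psilac'")
  t1 <- d$pre_h; t2 <- d$drug_h
  fp <- if (drug_on) p$f else 1
  kdp <- if (drug_on) p$g * p$kd else p$kd
  A0 <- p$s / p$kd
  L <- A0 * exp(-p$kd * t1 - kdp * t2)
  new <- (p$s / p$kd) * (1 - exp(-p$kd * t1)) * exp(-kdp * t2) +
    (p$s * fp / kdp) * (1 - exp(-kdp * t2))
  c(L = L, new = new)
}

#' Closed-form channel amounts under the pulse-chase design
#'
#' H is the pulse cohort (synthesized during `pulse_h` at baseline rates)
#' decayed through the chase at the drug-scaled rate; M is the chase cohort
#' (synthesized at `s * f`, degraded at `g * kd` when `drug_on`); the
#' pre-existing L pool always decays at baseline `kd` — assembled proteins
#' are not orphaned by a translation block.
#'
#' @inheritParams channel_amounts_psilac
#' @param d [pulse_design()] with `design_kind = "pulse_chase"`.
#' @return named numeric vector `c(L = ..., M = ..., H = ...)`.
#' @export
channel_amounts_chase <- function(p, d, drug_on) {
  stopifnot(inherits(p, "turnover_params"), inherits(d, "pulse_design"))
  if (d$design_kind != "pulse_chase") stop("design_kind must be 'pulse_chase'")
  tp <- d$pulse_h; tc <- d$chase_h
  fp <- if (drug_on) p$f else 1
  kdp <- if (drug_on) p$g * p$kd else p$kd
  A0 <- p$s / p$kd
  H <- (p$s / p$kd) * (1 - exp(-p$kd * tp)) * exp(-kdp * tc)
  M <- (p$s * fp / kdp) * (1 - exp(-kdp * tc))
  L <- A0 * exp(-p$kd * (tp + tc))
  c(L = L, M = M, H = H)
}
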