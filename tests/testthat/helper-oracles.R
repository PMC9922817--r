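# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force position scans, exhaustive
# enumeration, numerical ODE integration, and direct combinatorial sums.

random_protein_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# per-position brute-force cleavage scan
oracle_sites <- function(sequence, proteases, proline_rule = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  rules <- list(trypsin = c("K", "R"), lysc = "K",
                chymotrypsin = c("F", "W", "Y"))
  sites <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (p in proteases) {
      if (chars[i] %in% rules[[p]]) {
        blocked <- proline_rule && p %in% c("trypsin", "chymotrypsin") &&
          chars[i + 1L] == "P"
        if (!blocked) { sites <- c(sites, i); break }
      }
    }
  }
  sites
}

# exhaustive enumeration of all runs of up to m+1 adjacent fragments
oracle_digest <- function(sequence, proteases, missed, proline_rule = TRUE) {
  sites <- oracle_sites(sequence, proteases, proline_rule)
  bounds <- c(0L, sites, nchar(sequence))
  out <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:min(i + missed, length(bounds) - 1L)) {
      out <- c(out, substring(sequence, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  sort(out)
}

# ODE quadrature of the labeled-cohort kinetics with piecewise-constant
# synthesis and degradation schedules
oracle_cohort_ode <- function(s_fun, k_fun, t_end, x0 = 0) {
  deriv <- function(t, y, parms) list(s_fun(t) - k_fun(t) * y)
  times <- seq(0, t_end, length.out = 201L)
  out <- deSolve::ode(y = c(x = x0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "x"])
}

# exact one-sided Wilcoxon p by enumeration of all rank assignments
oracle_wilcoxon <- function(a, b, alternative) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  stat_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  stats <- apply(combos, 2L, function(idx) sum(r[idx]))
  if (alternative == "a-less-than-b") mean(stats <= stat_obs)
  else mean(stats >= stat_obs)
}

# upper hypergeometric tail by direct combinatorial summation
oracle_hyper_tail <- function(k, K, m, N) {
  if (k == 0L) return(1)
  j <- k:min(K, m)
  sum(choose(m, j) * choose(N - m, K - j)) / choose(N, K)
}

# direct BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

psilac_new_oracle <- function(s, kd, f, g, pre_h, drug_h, drug_on) {
  fp <- if (drug_on) f else 1
  kdp <- if (drug_on) g * kd else kd
  oracle_cohort_ode(
    s_fun = function(t) if (t < pre_h) s else s * fp,
    k_fun = function(t) if (t < pre_h) kd else kdp,
    t_end = pre_h + drug_h
  )
}

chase_oracle <- function(s, kd, f, g, pulse_h, chase_h, drug_on) {
  fp <- if (drug_on) f else 1
  kdp <- if (drug_on) g * kd else kd
  H <- oracle_cohort_ode(
    s_fun = function(t) if (t < pulse_h) s else 0,
    k_fun = function(t) if (t < pulse_h) kd else kdp,
    t_end = pulse_h + chase_h
  )
  M <- oracle_cohort_ode(
    s_fun = function(t) if (t < pulse_h) 0 else s * fp,
    k_fun = function(t) kdp,
    t_end = pulse_h + chase_h
  )
  c(M = M, H = H)
}
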