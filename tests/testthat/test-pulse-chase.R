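test_that("CAP-sensitivity boundary is inclusive on the unchanged side", {
  expect_equal(classify_cap_sensitivity(-0.5), "unchanged")
  expect_equal(classify_cap_sensitivity(-0.51), "CAP-sensitive")
  expect_equal(classify_cap_sensitivity(c(1.2, NA, -3)),
               c("unchanged", "unassigned", "CAP-sensitive"))
})

test_that("degradation and synthesis scores are log2 ratio-of-ratios", {
  expect_equal(degradation_score(0.5, 1.0), -1)
  x <- runif(5, 0.1, 4)
  expect_equal(degradation_score(x, x), rep(0, 5))
  expect_equal(synthesis_score(0.25, 1), -2)
  flagged <- degradation_score(c(1, -2, NA), c(1, 1, 1))
  expect_equal(attr(flagged, "n_flagged"), 2L)
  expect_true(all(is.na(flagged[2:3])))
  # invariant to a common rescaling of all four channels
  expect_equal(degradation_score(3 * 0.7, 3 * 1.3),
               degradation_score(0.7, 1.3))
})

test_that("noiseless simulator scores match the kinetic closed forms", {
  pr <- protein_set(id = "X", sequence = paste(c(rep("A", 8), "K",
                                                 rep("L", 8), "R",
                                                 rep("V", 8), "K",
                                                 rep("S", 8)), collapse = ""))
  d <- pulse_design("pulse_chase", pulse_h = 4, chase_h = 4,
                    n_replicates = 1)
  # g = 2, kd = 0.1: degradation score is -log2(e) * kd * (g-1) * chase_h
  tr <- data.frame(protein_id = "X", s = 100, kd = 0.1, f = 1, g = 2)
  ev <- generate_evidence(pr, tr, d, noiseless_model(),
                          spec = digest_spec("trypsin"))
  sc <- chase_scores(ev, data.frame(protein_id = "X", mean_log2_fc = -1),
                     normalize = FALSE)
  expect_equal(sc$degradation_score, -0.1 * 1 * 4 * log2(exp(1)),
               tolerance = 1e-10)
  expect_equal(sc$category, "CAP-sensitive")
  # f = 0.2, g = 1: synthesis score is log2(0.2)
  tr2 <- data.frame(protein_id = "X", s = 100, kd = 0.1, f = 0.2, g = 1)
  ev2 <- generate_evidence(pr, tr2, d, noiseless_model(),
                           spec = digest_spec("trypsin"))
  sc2 <- chase_scores(ev2, data.frame(protein_id = "X", mean_log2_fc = 0),
                      normalize = FALSE)
  expect_equal(sc2$synthesis_score, log2(0.2), tolerance = 1e-10)
  expect_equal(sc2$degradation_score, 0, tolerance = 1e-10)
})

test_that("one-sided Wilcoxon matches its textbook examples", {
  expect_equal(wilcoxon_one_sided(c(1, 2, 3), c(4, 5, 6), "a-less-than-b"),
               0.05)
  expect_equal(wilcoxon_one_sided(5, c(1, 2, 3), "a-greater-than-b"), 0.25)
  x <- c(1, 3, 5, 7)
  expect_gte(wilcoxon_one_sided(x, x, "a-less-than-b"), 0.5)
  expect_gte(wilcoxon_one_sided(x, x, "a-greater-than-b"), 0.5)
  expect_error(wilcoxon_one_sided(numeric(0), 1), "non-empty")
})

test_that("exact Wilcoxon p equals rank-assignment enumeration up to n = 8", {
  set.seed(404)
  for (na in 1:4) for (nb in 1:4) {
    vals <- sample(seq_len(40), na + nb)   # distinct -> no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    for (alt in c("a-less-than-b", "a-greater-than-b")) {
      expect_equal(wilcoxon_one_sided(a, b, alt), oracle_wilcoxon(a, b, alt),
                   info = paste(na, nb, alt))
    }
  }
})

test_that("group comparison detects planted orphan destabilization", {
  pr <- sim_proteins(60, n_mt = 0, len_range = c(100, 200), seed = 61)
  orphans <- pr$id[1:20]
  tr <- sim_truth(pr, orphans = orphans, orphan_g = 3, seed = 62)
  d <- pulse_design("pulse_chase", n_replicates = 1)
  nm <- noise_model(channel_noise_sigma = 0.1, dropout_midpoint = -Inf,
                    seed = 63)
  ev <- generate_evidence(pr, tr, d, nm)
  # classify from closed-form pSILAC values: orphans are the sensitive set
  psilac <- data.frame(protein_id = pr$id,
                       mean_log2_fc = ifelse(pr$id %in% orphans, -1, 0))
  sc <- chase_scores(ev, psilac)
  cmp <- chase_group_comparison(sc)
  expect_equal(cmp$n_sensitive, c(20L, 20L))
  expect_equal(cmp$n_unchanged, c(40L, 40L))
  expect_lt(cmp$p_value[cmp$score == "degradation"], 0.01)
  # single-category input is rejected by name
  sc_one <- sc[sc$category == "unchanged", ]
  expect_error(chase_group_comparison(sc_one), "CAP-sensitive")
})

test_that("MG132 arm rescues the degradation signal in the simulator", {
  pr <- sim_proteins(60, n_mt = 0, len_range = c(100, 200), seed = 71)
  orphans <- pr$id[1:20]
  tr <- sim_truth(pr, orphans = orphans, orphan_g = 3, seed = 72)
  d <- pulse_design("pulse_chase", n_replicates = 1)
  nm <- noise_model(channel_noise_sigma = 0.1, dropout_midpoint = -Inf,
                    seed = 73)
  ev <- generate_evidence(pr, tr, d, nm,
                          conditions = c("CAP", "DMSO", "CAP+MG132"))
  psilac <- data.frame(protein_id = pr$id,
                       mean_log2_fc = ifelse(pr$id %in% orphans, -1, 0))
  cmp_cap <- chase_group_comparison(chase_scores(ev, psilac, drug = "CAP"))
  cmp_mg <- chase_group_comparison(chase_scores(ev, psilac,
                                                drug = "CAP+MG132"))
  p_cap <- cmp_cap$p_value[cmp_cap$score == "degradation"]
  p_mg <- cmp_mg$p_value[cmp_mg$score == "degradation"]
  expect_lt(p_cap, 0.01)
  expect_gt(p_mg, 0.05)
})
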