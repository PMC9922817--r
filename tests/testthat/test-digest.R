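test_that("cleavage rules: trypsin/lysC/chymotrypsin and the proline rule", {
  expect_equal(cleavage_sites("AKPRA", "trypsin"), 4L)
  expect_equal(cleavage_sites("AKPRA", "lysc"), 2L)
  expect_equal(cleavage_sites("AFAYA", "chymotrypsin"), c(2L, 4L))
  # proline rule off restores the K site
  expect_equal(cleavage_sites("AKPRA", "trypsin", proline_rule = FALSE),
               c(2L, 4L))
  # terminal residue is never a site
  expect_equal(cleavage_sites("AAK", "trypsin"), integer(0))
  expect_error(cleavage_sites("AXK", "trypsin"), "invalid residue 'X'")
})

test_that("combined protease sites are the union of per-protease sites", {
  set.seed(42)
  for (rep in 1:5) {
    sq <- random_protein_seq(300)
    s_union <- cleavage_sites(sq, c("lysc", "trypsin"))
    s_each <- sort(union(cleavage_sites(sq, "lysc"),
                         cleavage_sites(sq, "trypsin")))
    expect_identical(s_union, s_each)
    expect_identical(s_union, oracle_sites(sq, c("lysc", "trypsin")))
    tri <- cleavage_sites(sq, c("trypsin", "chymotrypsin", "lysc"))
    expect_identical(tri, sort(Reduce(union, list(
      cleavage_sites(sq, "trypsin"), cleavage_sites(sq, "chymotrypsin"),
      cleavage_sites(sq, "lysc")))))
  }
})

test_that("digest partitions the sequence at 0 missed cleavages", {
  sp <- digest_spec("trypsin")
  expect_equal(digest("MKAAAAAR", sp)$sequence, c("MK", "AAAAAR"))
  expect_equal(digest("AAAAAA", sp)$sequence, "AAAAAA")
  set.seed(7)
  subsets <- list("trypsin", "lysc", "chymotrypsin",
                  c("trypsin", "lysc"), c("trypsin", "chymotrypsin"),
                  c("lysc", "chymotrypsin"),
                  c("trypsin", "lysc", "chymotrypsin"))
  for (rep in 1:5) {
    sq <- random_protein_seq(sample(50:300, 1))
    for (ps in subsets) {
      pep <- digest(sq, digest_spec(ps))
      expect_identical(paste(pep$sequence, collapse = ""), sq)
      expect_equal(sum(pep$length), nchar(sq))
      expect_true(all(pep$sequence ==
        substring(sq, pep$start, pep$end)))
    }
  }
})

test_that("digest with missed cleavages matches exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:10) {
    sq <- random_protein_seq(sample(30:200, 1))
    ps <- sample(list("trypsin", c("lysc", "trypsin"),
                      c("trypsin", "chymotrypsin")), 1)[[1]]
    for (m in 0:2) {
      got <- sort(digest(sq, digest_spec(ps, missed_cleavages = m))$sequence)
      expect_identical(got, oracle_digest(sq, ps, m))
    }
  }
})

test_that("observable peptides apply the 6-30 length window", {
  sp <- digest_spec("trypsin")
  expect_equal(observable_peptides("MKAAAAAR", sp)$sequence, "AAAAAR")
  # with no length filter the count equals cut positions + 1
  set.seed(3)
  for (rep in 1:5) {
    sq <- random_protein_seq(120)
    sp_all <- digest_spec("trypsin", min_len = 1, max_len = 500)
    expect_equal(nrow(observable_peptides(sq, sp_all)),
                 length(cleavage_sites(sq, "trypsin")) + 1L)
  }
})

test_that("observable count is monotone in window and missed cleavages", {
  set.seed(19)
  for (rep in 1:5) {
    sq <- random_protein_seq(250)
    base <- nrow(observable_peptides(sq, digest_spec("trypsin")))
    wider <- nrow(observable_peptides(sq, digest_spec("trypsin", max_len = 40)))
    lower <- nrow(observable_peptides(sq, digest_spec("trypsin", min_len = 4)))
    more_mc <- nrow(observable_peptides(sq, digest_spec("trypsin",
                                                        missed_cleavages = 2)))
    expect_gte(wider, base)
    expect_gte(lower, base)
    expect_gte(more_mc, base)
  }
})

test_that("observable count matrix indexes proteins by spec", {
  pr <- protein_set(id = "P1", sequence = "MKAAAAAR")
  m <- observable_count_matrix(pr, list(digest_spec("trypsin"),
                                        digest_spec("lysc")))
  expect_equal(unname(m[1, ]), c(1L, 1L))
  expect_equal(colnames(m), c("trypsin_mc0", "lysc_mc0"))
  expect_error(observable_count_matrix(pr, list(digest_spec("trypsin"),
                                                digest_spec("trypsin"))),
               "duplicate digestion spec")
  pr2 <- rbind(pr, pr)
  expect_error(observable_count_matrix(pr2, list(digest_spec("trypsin"))),
               "duplicate protein id")
})

test_that("iBAQ divides intensity by the observable count", {
  expect_equal(ibaq(1000, 4), 250)
  expect_equal(ibaq(0, 7), 0)
  x <- runif(5, 0, 1e6)
  expect_equal(ibaq(x, 1), x)
  expect_true(is.na(ibaq(100, 0)))
  expect_error(ibaq(-1, 2), "nonnegative")
})

test_that("MT-ND4L digestion reproduces the two-peptide arithmetic", {
  pr <- read_fasta(system.file("extdata", "mt_nd4l.fasta",
                               package = "mitopulse"))
  expect_equal(pr$id, "P03901")
  # exactly one arginine, no lysine: the basis of the lysC+trypsin result
  expect_equal(lengths(regmatches(pr$sequence, gregexpr("R", pr$sequence))), 1L)
  expect_equal(lengths(regmatches(pr$sequence, gregexpr("K", pr$sequence))), 0L)
  sp <- digest_spec(c("lysc", "trypsin"))
  pep <- digest(pr, sp)
  expect_equal(sort(pep$length), c(23L, 75L))
  # the arginine is not followed by proline, so the result is insensitive
  # to the proline rule
  pep2 <- digest(pr, digest_spec(c("lysc", "trypsin"), proline_rule = FALSE))
  expect_identical(pep$sequence, pep2$sequence)
  # only the 23-mer falls in the observable window
  expect_equal(observable_peptides(pr, sp)$length, 23L)
})
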