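test_that("the packaged OXPHOS annotation carries the reference totals", {
  ann <- load_annotation()
  expect_equal(sum(ann$encoding == "mitochondrial"), 13L)
  expect_equal(as.integer(table(factor(ann$complex,
                                       c("CI", "CII", "CIII", "CIV", "CV")))),
               c(45L, 4L, 11L, 21L, 17L))
  # assembly-stage structure: CIII/CIV subcomplexes and CV steps
  expect_setequal(ann$module[ann$complex == "CIII"],
                  paste("subcomplex", 1:3))
  expect_setequal(ann$module[ann$complex == "CIV"],
                  paste("subcomplex", 1:2))
  expect_setequal(ann$module[ann$complex == "CV"], paste("step", 1:3))
  # CI has the seven-module architecture
  expect_setequal(ann$module[ann$complex == "CI"],
                  c("N", "Q", "ND1", "ND2", "ND4", "ND5", "NDUFAB1"))
})

test_that("annotation validation names duplicate and unknown entries", {
  ann <- load_annotation()
  tmp <- tempfile(fileext = ".tsv")
  write.table(rbind(ann, ann[1, ]), tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_annotation(tmp), ann$protein_id[1])
  bad <- ann; bad$complex[3] <- "CVI"
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_annotation(tmp), "unknown complex")
  # user table with deviating totals warns rather than fails
  write.table(ann[1:20, ], tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(load_annotation(tmp, reference_totals = FALSE),
                 "differ from the reference")
})

test_that("category assignment partitions annotated proteins", {
  ann <- load_annotation()
  cat <- protein_category(ann$protein_id, ann)
  expect_equal(sum(cat == "MT-encoded OXPHOS"), 13L)
  expect_equal(sum(cat == "nuclear OXPHOS"), nrow(ann) - 13L)
  mixed <- protein_category(c("MT-CO1", "NDUFV1", "TOMM20", "GAPDH"), ann,
                            mito_ids = "TOMM20")
  expect_equal(mixed, c("MT-encoded OXPHOS", "nuclear OXPHOS",
                        "nuclear mito", "nuclear non-mito"))
  expect_equal(protein_category("GAPDH", ann, assume_nonmito = FALSE),
               "unannotated")
})

test_that("category summaries order the planted effect sizes correctly", {
  ann <- load_annotation()
  set.seed(9)
  ids <- c(ann$protein_id, sprintf("OTHER%02d", 1:30))
  fc <- c(ifelse(ann$encoding == "mitochondrial", -2, -0.2) + rnorm(98, 0, 0.05),
          rnorm(30, 0, 0.05))
  res <- data.frame(protein_id = ids, mean_log2_fc = fc)
  sm <- summarize_by_category(res, ann)
  med <- setNames(sm$median_log2_fc, sm$category)
  expect_lt(med["MT-encoded OXPHOS"], med["nuclear non-mito"])
  expect_equal(sum(sm$n_quantified), 128L)
  expect_error(summarize_by_category(res[0, ], ann), "nrow")
})

test_that("module summaries are per-module and order-invariant", {
  ann <- load_annotation()
  set.seed(10)
  res <- data.frame(protein_id = ann$protein_id,
                    mean_log2_fc = rnorm(nrow(ann)))
  sm <- summarize_by_module(res, ann, "CIII")
  expect_setequal(sm$module, c("subcomplex 1", "subcomplex 2", "subcomplex 3"))
  expect_equal(sum(sm$n_quantified), 11L)
  expect_equal(sm$n_mito + sm$n_nuclear, sm$n_quantified)
  sm2 <- summarize_by_module(res[sample(nrow(res)), ], ann, "CIII")
  expect_equal(sm2, sm)
  # one protein per module: median equals that value
  one <- res[match(c("UQCRFS1"), res$protein_id), ]
  sm3 <- summarize_by_module(one, ann, "CIII")
  expect_equal(sm3$median_log2_fc[sm3$module == "subcomplex 3"],
               one$mean_log2_fc)
  expect_equal(sm3$n_quantified[sm3$module == "subcomplex 1"], 0L)
  expect_error(summarize_by_module(res, ann, "CX"), "unknown complex")
})

test_that("planted subcomplex effects separate module medians", {
  ann <- load_annotation()
  sub1 <- ann$protein_id[ann$complex == "CIII" & ann$module == "subcomplex 1"]
  set.seed(12)
  res <- data.frame(protein_id = ann$protein_id,
                    mean_log2_fc = ifelse(ann$protein_id %in% sub1, -1.5, 0) +
                      rnorm(nrow(ann), 0, 0.1))
  sm <- summarize_by_module(res, ann, "CIII")
  expect_lt(sm$median_log2_fc[sm$module == "subcomplex 1"],
            min(sm$median_log2_fc[sm$module != "subcomplex 1"]))
})

test_that("cross-experiment correlation behaves at its fixed points", {
  ann <- load_annotation()
  set.seed(13)
  res <- data.frame(protein_id = ann$protein_id,
                    mean_log2_fc = rnorm(nrow(ann)))
  cc <- category_correlation(res, res, ann)
  expect_true(all(abs(cc$pearson_r - 1) < 1e-12))
  neg <- res; neg$mean_log2_fc <- -neg$mean_log2_fc
  cc2 <- category_correlation(res, neg, ann)
  expect_true(all(abs(cc2$pearson_r + 1) < 1e-12))
  small <- res[1:2, ]
  expect_warning(expect_error(category_correlation(small, small, ann),
                              "no category"),
                 "fewer than 3")
})

test_that("replicated simulations correlate within the planted category", {
  ann <- load_annotation()
  # two independent noisy measurements of the same ground truth: the
  # OXPHOS category (planted negative effects) correlates more strongly
  # than pure-noise non-mito proteins
  set.seed(14)
  ids <- c(ann$protein_id, sprintf("OTH%03d", 1:100))
  truth <- c(ifelse(ann$encoding == "mitochondrial", -2, -0.6), rep(0, 100))
  a <- data.frame(protein_id = ids, mean_log2_fc = truth + rnorm(198, 0, 0.2))
  b <- data.frame(protein_id = ids, mean_log2_fc = truth + rnorm(198, 0, 0.2))
  cc <- category_correlation(a, b, ann)
  r_ox <- cc$pearson_r[cc$category == "MT-encoded OXPHOS"]
  r_non <- cc$pearson_r[cc$category == "nuclear non-mito"]
  expect_gt(r_ox, abs(r_non))
})
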