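write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"sig\">",
              sprintf("##INFO=<ID=dbNSFP_%s_pred,Number=.,Type=Character,Description=\"p\">",
                      predictor_names()),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, lines), path)
  path
}

test_that("vocabularies cover 8 predictors and 23 categories", {
  v <- predictor_vocabularies()
  expect_length(v, 8L)
  expect_equal(sum(lengths(lapply(v, `[[`, "categories"))), 23L)
  # severity orders are permutations of the category sets
  for (p in names(v)) {
    expect_setequal(v[[p]]$severity, v[[p]]$categories)
  }
  # LRT "D" can be switched off
  expect_equal(predictor_vocabularies(lrt_d = FALSE)$LRT$categories, c("N", "U"))
})

test_that("multi-value calls collapse to the most severe category", {
  expect_equal(aggregate_multivalue_call("Polyphen2_HVAR", c("B", "P", "D")), "D")
  expect_equal(aggregate_multivalue_call("LRT", "N"), "N")
  expect_equal(aggregate_multivalue_call("MutationAssessor", c("L", "M")), "M")
  expect_equal(aggregate_multivalue_call("MutationTaster", c("P", "N", "D")), "D")
  expect_error(aggregate_multivalue_call("SIFT", character(0)), "at least one")
  expect_error(aggregate_multivalue_call("SIFT", "X"), "unknown category")
})

test_that("dbNSFP INFO keys parse with both , and & separators", {
  f <- write_mini_vcf(c(
    "1\t100\trs1\tA\tG\t.\t.\tCLNSIG=Benign;dbNSFP_SIFT_pred=D;dbNSFP_FATHMM_pred=T",
    "2\t200\t.\tC\tT\t.\t.\tCLNSIG=Pathogenic",
    "3\t300\t.\tG\tA\t.\t.\tCLNSIG=Benign;dbNSFP_SIFT_pred=T,D;dbNSFP_LRT_pred=N&U"
  ))
  v <- read_annotated_vcf(f)
  expect_equal(nrow(v), 3L)
  expect_equal(v$SIFT, c("D", NA, "D"))
  expect_equal(v$FATHMM, c("T", NA, NA))
  expect_equal(v$LRT, c(NA, NA, "N"))
  expect_true(all(is.na(as.matrix(v[2, predictor_names()]))))
  expect_equal(v$rsid, c("rs1", NA, NA))
  expect_equal(v$clnsig, c("Benign", "Pathogenic", "Benign"))
})

test_that("multi-allelic rows split per ALT with shared annotations", {
  f <- write_mini_vcf(
    "1\t500\t.\tA\tG,T\t.\t.\tCLNSIG=Benign;dbNSFP_SIFT_pred=D")
  v <- read_annotated_vcf(f)
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("G", "T"))
  expect_equal(v$SIFT, c("D", "D"))
})

test_that("unknown category codes fail loudly, naming the predictor", {
  f <- write_mini_vcf("1\t1\t.\tA\tG\t.\t.\tCLNSIG=Benign;dbNSFP_SIFT_pred=Z")
  expect_error(read_annotated_vcf(f), "SIFT.*Z")
})

test_that("write/read round-trip is the identity on calls and labels", {
  spec <- synthetic_spec(n_benign = 25, n_pathogenic = 25, n_vus = 10, n_ci = 5,
                         concordance = 0.8, missing_rate = 0.15, seed = 21)
  v <- simulate_variants(spec)
  f <- tempfile(fileext = ".vcf")
  write_synthetic_vcf(v, f)
  v2 <- read_annotated_vcf(f)
  cols <- c("chrom", "pos", "ref", "alt", "rsid", "clnsig", predictor_names())
  expect_equal(as.data.frame(v)[, cols], as.data.frame(v2)[, cols],
               ignore_attr = TRUE)
})

test_that("prediction tables round-trip through TSV", {
  res <- data.frame(chrom = c("1", "2", "X"), pos = c(10L, 20L, 30L),
                    ref = "A", alt = "T", rsid = c("rs5", NA, NA),
                    source_label = c("vus", "vus", "conflicting"),
                    prob_pathogenic = c(0.98765, 0.5, 0.12345),
                    predicted_label = c("pathogenic", "pathogenic", "benign"),
                    high_confidence = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_prediction_table(res, f)
  expect_equal(length(readLines(f)), 4L)  # header + 3 rows
  back <- read_prediction_table(f)
  expect_equal(back$prob_pathogenic, res$prob_pathogenic, tolerance = 1e-4)
  expect_equal(back$rsid, res$rsid)
  expect_equal(back$predicted_label, res$predicted_label)

  # empty input -> header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_prediction_table(res[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
})
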