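test_that("quantification tables parse values, mask and orderings", {
  path <- write_fixture_table(c(
    "# phosphosite intensities",
    "protein\tsite\ts1\ts2",
    "EGFR\tpY1172\t1\t2",
    "KIT\tpY823\t3\t4"))
  q <- read_quant_table(path)
  expect_equal(unname(q$values), matrix(c(1, 3, 2, 4), 2, 2))
  expect_true(all(q$observed))
  expect_equal(rownames(q$values), c("EGFR|pY1172", "KIT|pY823"))
  expect_equal(colnames(q$values), c("s1", "s2"))

  # comma dialect
  pcsv <- write_fixture_table(c("protein,site,s1", "EGFR,pY1172,2.5"))
  expect_equal(unname(read_quant_table(pcsv, sep = ",")$values[1, 1]), 2.5)
})

test_that("malformed quantification tables fail loudly", {
  dup <- write_fixture_table(c("protein\tsite\ts1",
                               "EGFR\tpY1172\t1", "EGFR\tpY1172\t2"))
  expect_error(read_quant_table(dup), "duplicate site ids.*EGFR\\|pY1172")

  nonnum <- write_fixture_table(c("protein\tsite\ts1\ts2",
                                  "EGFR\tpY1172\t1\tabc"))
  expect_error(read_quant_table(nonnum), "non-numeric value 'abc'.*row 1.*s2")

  nonpos <- write_fixture_table(c("protein\tsite\ts1", "EGFR\tpY1172\t0"))
  expect_error(read_quant_table(nonpos), "non-positive intensity")

  expect_error(read_quant_table(tempfile()), "not found")
})

test_that("empty cells become unobserved exactly where they occur", {
  path <- write_fixture_table(c("protein\tsite\ts1\ts2\ts3",
                                "EGFR\tpY1172\t4\t\t8",
                                "KIT\tpY823\t1\t2\t3"))
  q <- read_quant_table(path)
  expect_identical(unname(q$observed),
                   matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), 2, 3))
  expect_true(is.na(q$values[1, 2]))
  expect_equal(unname(q$values[1, c(1, 3)]), c(4, 8))
  expect_equal(unname(q$values[2, ]), c(1, 2, 3))
})

test_that("imputation floors at a fraction of the site minimum, then ln", {
  path <- write_fixture_table(c("protein\tsite\ts1\ts2\ts3",
                                "EGFR\tpY1172\t4\t\t8",
                                "KIT\tpY823\t1\t1\t1"))
  lq <- impute_and_log(read_quant_table(path), floor_fraction = 0.5)
  expect_equal(lq$log_values["EGFR|pY1172", "s2"], log(2))  # 0.5 * min(4, 8)
  expect_equal(lq$log_values["KIT|pY823", "s1"], 0)         # ln 1
  expect_equal(lq$provenance,
               data.frame(site_id = "EGFR|pY1172", sample = "s2",
                          imputed_intensity = 2, stringsAsFactors = FALSE))

  # fully observed: identity path, empty provenance
  lq2 <- impute_and_log(tiny_quant())
  expect_equal(unname(lq2$log_values), log(unname(tiny_quant()$values)))
  expect_identical(nrow(lq2$provenance), 0L)
})

test_that("imputation rejects all-missing sites and preserves observed ranks", {
  q <- quant_matrix(matrix(c(NA, 2, NA, 4), 2, 2,
                           dimnames = list(NULL, c("a", "b"))),
                    protein = c("X", "Y"), site_label = c("pY1", "pY2"))
  expect_error(impute_and_log(q), "no observed values.*X\\|pY1")

  set.seed(41)
  vals <- matrix(exp(stats::rnorm(60, 8)), 10, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
  vals[sample(60, 12)] <- NA
  vals[1, is.na(vals[1, ])] <- 1  # keep every site observed somewhere
  q2 <- quant_matrix(vals, protein = paste0("P", 1:10),
                     site_label = paste0("pY", 1:10))
  lq <- impute_and_log(q2)
  for (k in seq_len(6)) {
    obs <- which(q2$observed[, k])
    expect_equal(rank(lq$log_values[obs, k]), rank(q2$values[obs, k]))
  }
})

test_that("write/read round trip is the identity on values, mask, orderings", {
  path <- write_fixture_table(c("protein\tsite\ts1\ts2\ts3",
                                "EGFR\tpY1172\t4.25\t\t8.125",
                                "MUC1\tpY1209-pY1212\t1\t2\t3.00001"))
  q <- read_quant_table(path)
  out <- tempfile(fileext = ".tsv")
  write_quant_table(q, out)
  q2 <- read_quant_table(out)
  expect_identical(q2$values, q$values)
  expect_identical(q2$observed, q$observed)
  expect_identical(q2$protein, q$protein)
  expect_identical(q2$site_label, q$site_label)

  # full double precision survives
  q$values[2, 1] <- pi
  write_quant_table(q, out)
  expect_identical(read_quant_table(out)$values[2, 1], pi)

  empty <- tiny_quant(); empty$values <- empty$values[0, , drop = FALSE]
  empty$observed <- empty$observed[0, , drop = FALSE]
  expect_error(write_quant_table(empty, out), "empty")
})

test_that("edge lists validate confidence, drop self-loops, dedupe pairs", {
  path <- write_fixture_table(c("protein_a\tprotein_b\tconfidence",
                                "EGFR\tKIT\t0.9",
                                "KIT\tEGFR\t0.4",
                                "SRC\tSRC\t0.8",
                                "EGFR\tSRC\t0.75"))
  expect_warning(net <- read_edge_list(path), "self-loop")
  expect_s3_class(net, "interaction_network")
  expect_equal(nrow(net), 2L)  # EGFR-KIT (max conf kept), EGFR-SRC
  expect_equal(net$confidence[net$protein_b == "KIT"], 0.9)

  bad <- write_fixture_table(c("protein_a\tprotein_b\tconfidence",
                               "EGFR\tKIT\t1.5"))
  expect_error(read_edge_list(bad), "confidence outside")
})

test_that("druggable maps read as protein -> inhibitors", {
  path <- write_fixture_table(c("protein\tinhibitor",
                                "EGFR\terlotinib",
                                "EGFR\tgefitinib",
                                "KIT\timatinib"))
  m <- read_druggable_map(path)
  expect_equal(m$EGFR, c("erlotinib", "gefitinib"))
  expect_equal(m$KIT, "imatinib")
  expect_error(druggable_map(c("EGFR", ""), c("a", "b")), "empty")
})

test_that("sign matrices round-trip through the matrix writer", {
  bc <- matrix(c(1L, -1L, 0L, 0L, 1L, -1L), 3, 2,
               dimnames = list(paste0("t", 1:3), c("process1", "process2")))
  path <- tempfile(fileext = ".tsv")
  passs:::write_matrix_tsv(bc, path, "sample")
  lines <- readLines(path)
  expect_equal(lines[1], "sample\tprocess1\tprocess2")
  back <- passs:::read_matrix_tsv(path)
  expect_equal(unname(back), unname(bc) + 0)
  expect_true(all(back %in% c(-1, 0, 1)))
})
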