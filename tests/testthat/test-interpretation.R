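test_that("tail membership follows the mean +/- c*SD rule", {
  g <- c(0.7, -0.7, rep(0, 8))
  ids <- c("EGFR|pY1172", "KIT|pY823", sprintf("P%d|pY%d", 1:8, 1:8))
  d <- fake_decomposition(
    weights = cbind(rep(0.3, 10), g, deparse.level = 0) |>
      `rownames<-`(ids),
    amplitudes = rbind(rep(10, 3), c(2, -2, 0)))
  # mean 0, SD = sqrt(0.98/9) ~ 0.33; 2*SD ~ 0.66 < 0.7: exactly the two spikes
  tl <- process_tails(d, 1, c = 2)
  expect_equal(tl$site_id, c("EGFR|pY1172", "KIT|pY823"))
  expect_equal(tl$sign, c(1L, -1L))
  expect_equal(tl$weight, c(0.7, -0.7))

  expect_equal(nrow(process_tails(d, 1, c = 0)), 10L)  # threshold collapses

  # constant weight column: no spread, empty tails with a warning
  d$weights[, 2] <- 0.5
  expect_warning(tl0 <- process_tails(d, 1), "constant")
  expect_identical(nrow(tl0), 0L)

  # adding sites exactly at the column mean never changes membership
  g2 <- c(g, mean(g))
  d2 <- fake_decomposition(
    weights = cbind(rep(0.3, 11), g2, deparse.level = 0) |>
      `rownames<-`(c(ids, "NEW|pY1")),
    amplitudes = rbind(rep(10, 3), c(2, -2, 0)))
  expect_false("NEW|pY1" %in% process_tails(d2, 1, c = 2)$site_id)
})

test_that("quantile tails pick the top and bottom fractions", {
  set.seed(51)
  g <- sort(stats::rnorm(100))
  d <- fake_decomposition(
    weights = cbind(rep(0.1, 100), g, deparse.level = 0) |>
      `rownames<-`(sprintf("P%03d|pY1", 1:100)),
    amplitudes = rbind(rep(5, 2), c(1, -1)))
  tl <- process_tails(d, 1, method = "quantile", q = 0.05)
  expect_true(all(tl$site_id %in% sprintf("P%03d|pY1", c(1:6, 95:100))))
  expect_gte(nrow(tl), 10L)
})

test_that("subnetworks induce over tail proteins and track isolation", {
  tails <- data.frame(
    site_id = c("EGFR|pY1172", "EGFR|pY1197", "KIT|pY823"),
    protein = c("EGFR", "EGFR", "KIT"),
    site_label = c("pY1172", "pY1197", "pY823"),
    sign = c(1L, 1L, -1L), weight = c(0.6, 0.5, -0.4),
    stringsAsFactors = FALSE)
  net <- interaction_network(c("EGFR", "EGFR"), c("KIT", "STAT3"),
                             c(0.9, 0.95))
  proc <- process_subnetwork(tails, net, min_confidence = 0.7, alpha = 1L)
  # multi-site EGFR collapses onto one node; STAT3 not a tail protein
  expect_equal(sort(names(proc$components)), c("EGFR", "KIT"))
  expect_equal(unname(proc$components["EGFR"]), unname(proc$components["KIT"]))
  expect_identical(length(proc$isolated), 0L)
  expect_equal(nrow(proc$edges), 1L)
  expect_equal(unname(proc$degree), c(1, 1))

  # no network: everything isolated
  proc0 <- process_subnetwork(tails, NULL, alpha = 1L)
  expect_setequal(proc0$isolated, tails$site_id)

  # min_confidence at 1.0 filters the 0.9 edge out
  proc1 <- process_subnetwork(tails, net, min_confidence = 1.0, alpha = 1L)
  expect_setequal(proc1$isolated, tails$site_id)
})

test_that("subnetwork induction is monotone in min_confidence", {
  set.seed(52)
  prots <- sprintf("P%02d", 1:12)
  pairs <- t(utils::combn(prots, 2))
  keep <- sample(nrow(pairs), 30)
  net <- interaction_network(pairs[keep, 1], pairs[keep, 2],
                             stats::runif(30))
  tails <- data.frame(site_id = paste0(prots, "|pY1"), protein = prots,
                      site_label = "pY1", sign = 1L, weight = 0.2,
                      stringsAsFactors = FALSE)
  cuts <- c(0, 0.3, 0.6, 0.9)
  edge_sets <- lapply(cuts, function(mc)
    with(process_subnetwork(tails, net, mc)$edges,
         paste(protein_a, protein_b)))
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(edge_sets[[i + 1]] %in% edge_sets[[i]]))
})

test_that("induced/repressed lists follow the contribution sign and swap with it", {
  cfg <- preset_cohort("paperlike_subset")
  fit <- passs(simulate_cohort(cfg)$quant, seed = 6)
  tl <- process_tails(fit, 1)
  proc <- process_subnetwork(tl, NULL, alpha = 1L)

  # process 1 couples EGFR and KIT with opposite signs: whenever it acts,
  # the two sites always land in opposite lists
  for (s in c("tumor_A", "tumor_B", "tumor_C")) {
    dir <- sample_direction(fit, proc, s)
    egfr_in <- "EGFR|pY1172" %in% dir$induced$site_id
    kit_in <- "KIT|pY823" %in% dir$induced$site_id
    expect_true(xor(egfr_in, kit_in))
  }
  # tumor_A has positive process-1 amplitude: EGFR induced, KIT repressed
  dirA <- sample_direction(fit, proc, "tumor_A")
  expect_true("EGFR|pY1172" %in% dirA$induced$site_id)
  expect_true("KIT|pY823" %in% dirA$repressed$site_id)

  # antisymmetry: flipping the amplitude swaps the lists exactly
  fit2 <- fit
  fit2$decomposition$amplitudes[2, ] <- -fit$decomposition$amplitudes[2, ]
  for (s in colnames(fit$decomposition$amplitudes)) {
    a <- sample_direction(fit, proc, s)
    b <- sample_direction(fit2, proc, s)
    expect_equal(b$induced, a$repressed)
    expect_equal(b$repressed, a$induced)
  }

  # zero amplitude: both lists empty
  fit3 <- fit
  fit3$decomposition$amplitudes[2, 1] <- 0
  dir0 <- sample_direction(fit3, proc, 1)
  expect_identical(nrow(dir0$induced), 0L)
  expect_identical(nrow(dir0$repressed), 0L)
})
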