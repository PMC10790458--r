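test_that("target ranking keeps only induced, druggable tail members", {
  ids <- c("EGFR|pY1172", "KIT|pY823", "STAT3|pY705", "IGF1R|pY1165")
  g <- c(0.7, -0.6, 0.5, 0.4)
  d <- fake_decomposition(
    weights = cbind(rep(0.25, 4), g, deparse.level = 0) |> `rownames<-`(ids),
    amplitudes = rbind(c(20, 20), c(2, -2)))
  tails <- data.frame(site_id = ids,
                      protein = c("EGFR", "KIT", "STAT3", "IGF1R"),
                      site_label = c("pY1172", "pY823", "pY705", "pY1165"),
                      sign = as.integer(sign(g)), weight = g,
                      stringsAsFactors = FALSE)
  proc <- process_subnetwork(tails, NULL, alpha = 1L)

  # sample 1 (lambda > 0): plus-side members induced; STAT3 lacks a drug,
  # KIT is repressed -> candidates are EGFR then IGF1R by |G|
  r1 <- rank_targets(proc, 1, d)
  expect_equal(r1$protein, c("EGFR", "IGF1R"))
  expect_equal(r1$inhibitor, c("erlotinib", "AG-1024"))
  expect_equal(r1$rank, 1:2)
  expect_equal(r1$score, c(0.7, 0.4))

  # sample 2 (lambda < 0): only the minus side is induced
  r2 <- rank_targets(proc, 2, d)
  expect_equal(r2$protein, "KIT")
  expect_equal(r2$inhibitor, "imatinib")
})

test_that("equal weights break ties by subnetwork degree, then symbol", {
  ids <- c("KIT|pY823", "EGFR|pY1172", "A1|pY1", "A2|pY2", "A3|pY3")
  g <- c(0.5, 0.5, 0.3, 0.3, 0.3)
  d <- fake_decomposition(
    weights = cbind(rep(0.2, 5), g, deparse.level = 0) |> `rownames<-`(ids),
    amplitudes = rbind(c(10, 10), c(1, 1)))
  tails <- data.frame(site_id = ids,
                      protein = c("KIT", "EGFR", "A1", "A2", "A3"),
                      site_label = "x", sign = 1L, weight = g,
                      stringsAsFactors = FALSE)
  net <- interaction_network(c("EGFR", "EGFR", "EGFR"),
                             c("A1", "A2", "A3"), rep(0.9, 3))
  proc <- process_subnetwork(tails, net, alpha = 1L)
  expect_equal(unname(proc$degree["EGFR"]), 3)
  expect_equal(unname(proc$degree["KIT"]), 0)
  r <- rank_targets(proc, 1, d)
  expect_equal(r$protein[1], "EGFR")       # degree 3 beats degree 0 at equal |G|

  # degree-first mode flips the primary key
  rdeg <- rank_targets(proc, 1, d, centrality = "degree")
  expect_equal(rdeg$protein[1], "EGFR")
  # without the network both degrees are 0: alphabetical symbol decides
  proc0 <- process_subnetwork(tails, NULL, alpha = 1L)
  r0 <- rank_targets(proc0, 1, d)
  expect_equal(r0$protein[1], "EGFR")      # EGFR < KIT
})

test_that("a single EGFR-centered process yields erlotinib monotherapy", {
  fit <- passs(simulate_cohort(preset_cohort("paperlike_subset"))$quant,
               seed = 12)
  th <- predict_therapy(fit)
  planA <- th$plans$tumor_A
  expect_identical(planA$class, "monotherapy")
  expect_equal(planA$combination$protein, "EGFR")
  expect_equal(planA$combination$inhibitor, "erlotinib")
  expect_identical(length(planA$uncovered), 0L)
})

test_that("two induced processes yield the two-drug combination", {
  fit <- passs(simulate_cohort(pdx11_like_config())$quant, seed = 13)
  th <- predict_therapy(fit)
  plan <- th$plans$pdx_1   # induced in both the EGFR and IGF1R processes
  expect_identical(plan$class, "combination")
  expect_setequal(plan$combination$protein, c("EGFR", "IGF1R"))
  expect_setequal(plan$combination$inhibitor, c("erlotinib", "AG-1024"))
})

test_that("processes sharing a central protein deduplicate to monotherapy", {
  amp <- rbind(2.4 * c(1, 1, -1, -1),
               1.8 * c(1, -1, 1, -1))
  cfg <- synthetic_config(n_sites = 80, n_samples = 4, amplitudes = amp,
                          noise_sd = 0.02,
                          processes = list(
                            list(plus = "EGFR|pY1172", minus = "KIT|pY823"),
                            list(plus = "EGFR|pY1197", minus = "SRC|pY419")),
                          seed = 81)
  fit <- passs(simulate_cohort(cfg)$quant, seed = 14)
  th <- predict_therapy(fit)
  plan <- th$plans[[1]]    # both processes induced, both centered on EGFR
  expect_identical(length(plan$active), 2L)
  expect_identical(plan$class, "monotherapy")
  expect_equal(plan$combination$inhibitor, "erlotinib")
})

test_that("active processes without druggable candidates are flagged uncovered", {
  fit <- passs(simulate_cohort(preset_cohort("paperlike_subset"))$quant,
               seed = 15)
  drugs <- druggable_map("IGF1R", "AG-1024")  # nothing for process 1
  th <- predict_therapy(fit, drugs = drugs)
  for (p in th$plans)
    expect_identical(sort(unique(c(p$chosen$process, p$uncovered))),
                     sort(p$active))
  expect_true(1L %in% th$plans$tumor_A$uncovered)
  expect_identical(th$plans$tumor_A$class, "none")
})

test_that("cohort summaries count classes and EGFR usage", {
  fit <- passs(simulate_cohort(pdx11_like_config())$quant, seed = 16)
  th <- predict_therapy(fit)
  s <- th$summary
  expect_identical(s$n_samples, 4L)
  expect_identical(sum(s$by_class), 4L)
  expect_equal(s$mean_active_processes,
               mean(vapply(fit$signatures, nrow, 0L)))
  # planted design: pdx_1 EGFR+IGF1R, pdx_2 EGFR+SRC, pdx_3 KIT+IGF1R,
  # pdx_4 KIT+SRC -> EGFR never mono, twice in combination
  expect_identical(s$egfr_monotherapy, 0L)
  expect_identical(s$egfr_in_combination, 2L)

  expect_error(cohort_summary(list()), "empty cohort")
})

test_that("therapy prediction is deterministic", {
  sim <- simulate_cohort(preset_cohort("paperlike_cohort"))
  fit <- passs(sim$quant, seed = 17)
  t1 <- predict_therapy(fit)
  t2 <- predict_therapy(fit)
  expect_identical(t1$plans, t2$plans)
})
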