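test_that("penetrance follows its closed forms and display rounding", {
  expect_equal(penetrance(21, 24), 87.5)
  expect_equal(format_penetrance(penetrance(21, 24)), "88")
  expect_equal(penetrance(0, 21), 0)
  expect_equal(penetrance(21, 21), 100)
  expect_error(penetrance(5, 0), ">=")
  expect_error(penetrance(22, 21), "exceed")
})

test_that("replicate aggregation reports mean and sample sd", {
  a <- aggregate_gene(c(80, 70, 60))
  expect_equal(a$mean, 70)
  expect_equal(a$sd, 10)
  b <- aggregate_gene(c(50, 50))
  expect_equal(b$sd, 0)
  d <- aggregate_gene(c(100, 0))
  expect_equal(d$mean, 50)
  expect_equal(d$sd, 70.71068, tolerance = 1e-6)
  single <- aggregate_gene(75)
  expect_false(single$sd_defined)
  expect_true(is.na(single$sd))
})

test_that("candidate calls apply the strict all-replicates > 30% rule", {
  r1 <- data.frame(dsrna_id = "a", scored = 20, abnormal = c(7, 8, 11))
  c1 <- candidate_call(r1)  # 35, 40, 55%
  expect_true(c1$candidate)
  expect_false(c1$confirmed)
  r2 <- data.frame(dsrna_id = "a", scored = 100, abnormal = c(31, 29))
  expect_false(candidate_call(r2)$candidate)  # 29% fails the strict rule
  # exactly 30% does not exceed 30%
  r3 <- data.frame(dsrna_id = "a", scored = 10, abnormal = c(3, 4))
  expect_false(candidate_call(r3)$candidate)
  # two independent dsRNAs passing confirm the gene
  r4 <- data.frame(dsrna_id = rep(c("a", "b"), each = 2), scored = 20,
                   abnormal = c(8, 9, 10, 7))
  c4 <- candidate_call(r4)
  expect_true(c4$candidate)
  expect_true(c4$confirmed)
})

test_that("raising a replicate's penetrance never demotes a candidate", {
  set.seed(7)
  for (i in 1:25) {
    ab <- sample(0:20, 4, replace = TRUE)
    rec <- data.frame(dsrna_id = rep(c("a", "b"), each = 2), scored = 20,
                      abnormal = ab)
    before <- candidate_call(rec)$candidate
    j <- sample(1:4, 1)
    rec$abnormal[j] <- min(20, rec$abnormal[j] + sample(1:5, 1))
    after <- candidate_call(rec)$candidate
    expect_false(before && !after)
  }
})

test_that("simulated screen tables respect their degenerate limits", {
  t0 <- simulate_screen_table("g", 0, n_replicates = 6, seed = 1)
  expect_true(all(t0$abnormal == 0))
  t1 <- simulate_screen_table("g", 1, n_replicates = 6, seed = 1)
  expect_true(all(t1$abnormal == t1$scored))
  expect_error(simulate_screen_table("g", 1.4), "\\[0, 1\\]")
})

test_that("Monte-Carlo penetrance estimates converge to the truth", {
  # binomial oracle: mean of per-replicate penetrance estimates over many
  # simulated screens approaches 100 * p within 2 standard errors
  p <- 0.7; n <- 21; reps <- 4; n_sims <- 2500
  tab <- simulate_screen_table(sprintf("g%04d", seq_len(n_sims)), p,
                               n_replicates = reps, n_scored = n, seed = 3)
  est <- 100 * tab$abnormal / tab$scored
  se <- 100 * sqrt(p * (1 - p) / n) / sqrt(n_sims * reps)
  expect_lt(abs(mean(est) - 70), 2 * se)
})

test_that("screen summaries format like published penetrance tables", {
  tab <- data.frame(gene = "pbl", dsrna_id = "pbl_ds1", replicate = 1:3,
                    scored = c(20, 21, 22),
                    abnormal = c(16, 14, 15))
  s <- screen_summary(tab)
  expect_equal(s$n_replicates, 3)
  expect_match(s$display, "^\\d+\\.\\d±\\d+\\.\\d$")
  expect_true(s$candidate)
})
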