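test_that("substitutions are counted per aligned column", {
  s <- count_substitutions("AGCT", "GGCT")
  expect_equal(s$aligned_sites, 4)
  expect_equal(s$transitions, 1)
  expect_equal(s$transversions, 0)
  expect_equal(s$p, 0.25)
  expect_equal(s$q, 0)

  same <- count_substitutions(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(same$p, 0)
  expect_equal(same$q, 0)

  gapped <- count_substitutions("A-CT", "AGCT")
  expect_equal(gapped$aligned_sites, 3)
  expect_equal(gapped$transitions, 0)
  expect_equal(gapped$transversions, 0)

  ambig <- count_substitutions("ANCA", "AGCC")
  expect_equal(ambig$aligned_sites, 3)
  expect_equal(ambig$transversions, 1)  # A vs C

  expect_error(count_substitutions("ACG", "ACGT"), "length")
  expect_error(count_substitutions("--", "AC"), "aligned columns")
})

test_that("the K2P closed form matches its independent evaluation", {
  expect_equal(kimura_k2p(0, 0), 0)
  # frozen from -(1/2)*log((1 - 2p - q) * sqrt(1 - 2q)) at p=0.1, q=0.05
  expect_equal(kimura_k2p(0.1, 0.05), 0.1701811651, tolerance = 1e-9)
  expect_true(is.na(kimura_k2p(0.45, 0.2)))   # 1 - 2p - q = -0.1
  expect_true(is.na(kimura_k2p(0.1, 0.5)))    # 1 - 2q = 0
  expect_error(kimura_k2p(-0.1, 0), "non-negative")
  expect_error(kimura_k2p(0.7, 0.4), "non-negative|<=")
})

test_that("K2P dominates p+q and is monotone in both arguments", {
  ps <- seq(0, 0.4, length.out = 40)
  qs <- seq(0, 0.4, length.out = 40)
  for (p in ps) for (q in qs) {
    if (1 - 2 * p - q <= 1e-9 || 1 - 2 * q <= 1e-9) next
    k <- kimura_k2p(p, q)
    expect_gte(k, p + q - 1e-12)
    if (p + q > 0) expect_gt(k, p + q - 1e-9)
    k_p <- kimura_k2p(p + 1e-4, q)
    k_q <- kimura_k2p(p, q + 1e-4)
    if (!is.na(k_p)) expect_gt(k_p, k)
    if (!is.na(k_q)) expect_gt(k_q, k)
  }
})

test_that("K2P reduces to Jukes-Cantor under uniform substitution", {
  for (d in seq(0.01, 0.3, by = 0.01)) {
    # uniform substitution: one third transitions, two thirds transversions
    k2p <- kimura_k2p(d / 3, 2 * d / 3)
    jc <- -0.75 * log(1 - 4 * d / 3)
    expect_equal(k2p, jc, tolerance = 1e-9)
  }
})

test_that("simulated copies recover the generating divergence", {
  cfg <- simulation_config(
    seed = 33,
    superfamilies = data.frame(
      name = "ERV1", class_family = "LTR/ERV1", n_copies = 40,
      consensus_length = 5000, p_true = 0.1, q_true = 0.05,
      stringsAsFactors = FALSE
    )
  )
  te <- simulate_te_copies(cfg)
  k_est <- vapply(seq_len(nrow(te$pairs)), function(i) {
    kimura_from_pair(te$pairs$copy[i], te$pairs$consensus[i])
  }, numeric(1))
  expect_equal(k_est, te$truth$K_realized, tolerance = 1e-12)
  se <- sd(k_est) / sqrt(length(k_est))
  expect_lt(abs(mean(k_est) - 0.1701811651), 3 * se)
})

test_that("landscapes bin by percent divergence and conserve weight", {
  rec <- data.frame(
    entry_id = c("a", "b"), K = c(0.005, 0.015), weight = c(10, 20),
    te_class = "LTR", ltr_superfamily = "ERV1", stringsAsFactors = FALSE
  )
  class(rec) <- c("kimura_records", "data.frame")
  ls <- build_landscape(rec)
  expect_equal(ls$weight[ls$bin_lo == 0], 10)
  expect_equal(ls$weight[ls$bin_lo == 1], 20)
  expect_equal(sum(ls$weight), attr(ls, "total_weight"))
  expect_equal(sum(ls$percent), 100)

  # overflow bucket: K = 0.6 -> 60% divergence
  rec2 <- rbind(rec, data.frame(entry_id = "c", K = 0.6, weight = 5,
                                te_class = "LTR",
                                ltr_superfamily = "ERV1"))
  ls2 <- build_landscape(rec2)
  expect_equal(ls2$weight[is.infinite(ls2$bin_hi)], 5)
  expect_equal(sum(ls2$weight), 35)

  # saturated records excluded with a warning and reported count
  rec3 <- rbind(rec, data.frame(entry_id = "d", K = NA, weight = 99,
                                te_class = "LTR",
                                ltr_superfamily = "ERV1"))
  expect_warning(ls3 <- build_landscape(rec3), "saturated")
  expect_equal(attr(ls3, "saturated"), 1)
  expect_equal(sum(ls3$weight), 30)

  expect_error(build_landscape(rec, bin_width = 0), "bin_width")
})

test_that("grouped landscapes are the elementwise split of the pooled one", {
  withr::with_seed(4, {
    n <- 60
    rec <- data.frame(
      entry_id = paste0("e", seq_len(n)),
      K = runif(n, 0, 0.45),
      weight = sample(1:50, n, replace = TRUE),
      te_class = "LTR",
      ltr_superfamily = sample(c("ERV1", "Gypsy"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  class(rec) <- c("kimura_records", "data.frame")
  grouped <- build_landscape(rec, group_by = "ltr_superfamily")
  pooled <- build_landscape(rec, group_by = "te_class")
  pooled_from_groups <- tapply(grouped$weight, grouped$bin_lo, sum)
  by_bin <- tapply(pooled$weight, pooled$bin_lo, sum)
  expect_equal(as.numeric(pooled_from_groups[names(by_bin)]),
               as.numeric(by_bin))
  expect_equal(sum(grouped$weight), sum(rec$weight))
})
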