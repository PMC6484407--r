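# Synthetic-data generators: determinism, degenerate laws, and agreement
# between sampled data and the generative expectations.

test_that("make_genes handles degenerate laws, determinism, and errors", {
  one <- make_genes(1, log(5e4), 0, seed = 1)
  expect_equal(one$length, 5e4)

  a <- make_genes(200, seed = 1)
  b <- make_genes(200, seed = 1)
  expect_identical(a, b)

  expect_error(make_genes(0), "positive count")
})

test_that("sampled gene lengths follow the requested lognormal law", {
  # sdlog 0.6 puts the 20% band at ~3.7 sd of the sample median (n = 200)
  g <- make_genes(200, log(3e4), 0.6, seed = 7)
  expect_lt(abs(median(g$length) - 3e4) / 3e4, 0.2)
  expect_true(all(g$length >= 2e3 & g$length <= 2.5e6))
})

test_that("genes are non-overlapping and strand-balanced", {
  g <- make_genes(50, seed = 3)
  for (chr in unique(g$chrom)) {
    sub <- g[g$chrom == chr, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(diff(sub$start) >=
                                         head(sub$length, -1)))
  }
  expect_setequal(unique(g$strand), c("+", "-"))
})

test_that("noise-free wave coverage places the front at v * t", {
  g <- make_genes(1, log(5e4), 0, seed = 1)
  pre <- rate_preset("const2k", "constant", 2000)
  sim <- simulate_wave_coverage(g, pre, pulse_design(c(0, 5, 15)),
                                bin_size = 500, noise = FALSE)
  p5 <- Filter(function(p) p$time == 5, sim$profiles)[[1]]
  expect_equal(max(which(p5$counts > 0)), 20)   # bin [9500, 10000)
  p15 <- Filter(function(p) p$time == 15, sim$profiles)[[1]]
  expect_equal(max(which(p15$counts > 0)), 60)  # bin [29500, 30000)
})

test_that("t = 0 signal is confined to the promoter-proximal zone", {
  g <- make_genes(1, log(5e4), 0, seed = 1)
  pre <- rate_preset("fast", "constant", 5000)
  sim <- simulate_wave_coverage(g, pre, pulse_design(c(0, 5)),
                                bin_size = 500, noise = FALSE)
  p0 <- Filter(function(p) p$time == 0, sim$profiles)[[1]]
  expect_true(all(p0$counts[-(1:2)] == 0))  # 1 kb zone = first two bins
  expect_gt(sum(p0$counts[1:2]), 0)
})

test_that("wave geometry holds across genes and times with noise off", {
  g <- make_genes(20, log(6e4), 0.4, c(1e4, 2e5), seed = 11)
  pre <- preset_wt_front()
  sim <- simulate_wave_coverage(g, pre, pulse_design(), bin_size = 500,
                                noise = FALSE)
  for (p in sim$profiles) {
    if (p$time == 0) next
    front <- min(2200 * p$time, p$gene_length)
    last_bin <- max(which(p$counts > 0))
    expect_lte(abs(last_bin * 500 - front), 500)
  }
})

test_that("Poisson totals match the noise-free expectation and scale with depth", {
  g <- make_genes(1, log(5e4), 0, seed = 1)
  pre <- rate_preset("const2k", "constant", 2000)
  des <- pulse_design(c(5), depth = 50)
  exp_total <- sum(Filter(function(p) p$time == 5,
                          simulate_wave_coverage(g, pre, des, 500,
                                                 noise = FALSE)$profiles)[[1]]$counts)
  totals <- vapply(seq_len(500), function(i) {
    sum(Filter(function(p) p$time == 5,
               simulate_wave_coverage(g, pre, des, 500, noise = TRUE,
                                      seed = 1000 + i)$profiles)[[1]]$counts)
  }, numeric(1))
  expect_lt(abs(mean(totals) - exp_total) / exp_total, 0.05)

  des2 <- pulse_design(c(5), depth = 100)
  exp_total2 <- sum(Filter(function(p) p$time == 5,
                           simulate_wave_coverage(g, pre, des2, 500,
                                                  noise = FALSE)$profiles)[[1]]$counts)
  expect_equal(exp_total2 / exp_total, 2, tolerance = 1e-9)
})

test_that("wave simulation is deterministic given a seed and rejects bad input", {
  g <- make_genes(5, log(3e4), 0.3, seed = 2)
  pre <- preset_slow_rate()
  s1 <- simulate_wave_coverage(g, pre, pulse_design(), seed = 42)
  s2 <- simulate_wave_coverage(g, pre, pulse_design(), seed = 42)
  expect_identical(lapply(s1$profiles, `[[`, "counts"),
                   lapply(s2$profiles, `[[`, "counts"))
  expect_identical(s1$rates, s2$rates)

  expect_error(simulate_wave_coverage(g, pre, pulse_design(),
                                      bin_size = 50), ">= 100")
  tiny <- make_genes(1, log(2e3), 0, c(100, 400), seed = 1)
  expect_error(simulate_wave_coverage(tiny, pre, pulse_design(),
                                      bin_size = 500), "shorter than one bin")
})

test_that("rate presets honor their stated means and invariants", {
  expect_error(rate_preset("bad", "lognormal-mixture", 2450,
                           sdlog = 0.3, weights = c(0.6, 0.6),
                           medians = c(1, 2)), "sum to 1")
  r_wt <- draw_rates(preset_wt_rate(), 2e5, seed = 8)
  expect_lt(abs(mean(r_wt) - 2450) / 2450, 0.02)
  expect_true(all(r_wt > 0))
  r_slow <- draw_rates(preset_slow_rate(), 2e5, seed = 8)
  expect_lt(abs(mean(r_slow) - 1780) / 1780, 0.02)
  # slow distribution is narrower than wild type
  expect_lt(sd(r_slow) / mean(r_slow), sd(r_wt) / mean(r_wt))
  expect_identical(draw_rates(preset_wt_front(), 3), rep(2200, 3))
})

test_that("qPCR series cross half-plateau at d / v and are deterministic", {
  s <- simulate_qpcr_timecourse(3.325, 133, seq(0, 120, 10), noise_sd = 0)
  m <- aggregate(value ~ time_min, s, mean)
  first_half <- min(m$time_min[m$value >= 0.5])
  expect_equal(first_half, 40)

  fast <- simulate_qpcr_timecourse(1e9, c(10, 50), seq(0, 60, 10),
                                   noise_sd = 0, tau = 1)
  m2 <- aggregate(value ~ time_min, fast[fast$time_min > 0, ], mean)
  expect_true(all(m2$value > 0.99))

  a <- simulate_qpcr_timecourse(2, 50, seq(0, 60, 10), noise_sd = 0.2,
                                seed = 5)
  b <- simulate_qpcr_timecourse(2, 50, seq(0, 60, 10), noise_sd = 0.2,
                                seed = 5)
  expect_identical(a, b)
  expect_error(simulate_qpcr_timecourse(0, 50, c(0, 10)), "positive rate")
})

test_that("junction counts recover their true dPSI and respect bounds", {
  ev <- simulate_junction_counts(500, psi_base = 50, dpsi_true = -40,
                                 depth = 200, seed = 3)
  psi <- aggregate(cbind(inc, exc) ~ event_id + condition, ev, sum)
  psi$psi <- compute_psi(psi$inc, psi$exc)
  wide <- merge(psi[psi$condition == "A", c("event_id", "psi")],
                psi[psi$condition == "B", c("event_id", "psi")],
                by = "event_id", suffixes = c("_a", "_b"))
  expect_lt(abs(mean(wide$psi_b - wide$psi_a) + 40), 3)

  expect_error(simulate_junction_counts(10, depth = 0), "depth")
  expect_error(simulate_junction_counts(10, psi_base = 95, dpsi_true = 10),
               "within")
})

test_that("expression simulation follows the length-effect preset", {
  g <- make_genes(5000, log(3e4), 1.3, c(2e3, 2e6), seed = 9)
  expr <- simulate_expression(g, seed = 10)
  mid <- expr$length >= 8e3 & expr$length <= 1.2e4
  expect_gt(sum(mid), 100)
  expect_lt(abs(mean(expr$down_true[mid]) - 0.40), 0.05)

  none <- simulate_expression(g, effect = function(l) rep(0, length(l)),
                              seed = 1)
  expect_equal(sum(none$direction == "DOWN"), 0)
  all_down <- simulate_expression(g, effect = function(l) rep(1, length(l)),
                                  seed = 1)
  expect_true(all(all_down$direction == "DOWN"))
})

test_that("length-effect presets are monotone within [0, 1]", {
  eff <- preset_neuron_length_effect()
  lens <- 10^seq(3.4, 6.4, length.out = 200)
  p <- eff$p_down(lens)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  expect_equal(eff$p_down(1e4), 0.40)
  expect_gt(eff$p_down(2e6), 0.75)
})
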