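# Kinetic-coupling statistics: length comparisons, RNA maps,
# dPSI-expression regression, sliding-window length bias, overlap tests.

test_that("length_stats recovers a planted intron-length shift", {
  set.seed(61)
  bg <- data.frame(group = "unchanged",
                   exon_length = rlnorm(2000, log(120), 0.4),
                   upstream_intron_length = rlnorm(2000, log(1500), 0.7),
                   downstream_intron_length = rlnorm(2000, log(1500), 0.7))
  inc <- data.frame(group = "included",
                    exon_length = rlnorm(200, log(120), 0.4),
                    upstream_intron_length = rlnorm(200, log(1.5 * 1500),
                                                    0.7),
                    downstream_intron_length = rlnorm(200, log(1.5 * 1500),
                                                      0.7))
  st <- length_stats(rbind(bg, inc))
  up <- st[st$feature == "upstream_intron_length", ]
  expect_lt(up$p_value, 0.001)
  expect_lt(abs(up$median / up$background_median - 1.5), 0.3)

  same <- length_stats(rbind(bg, transform(bg[1:500, ],
                                           group = "included")))
  expect_true(all(same$p_value > 0.05))
  expect_error(length_stats(rbind(bg, inc[1:2, ])), ">= 3")
})

test_that("RNA map finds a planted motif with minimal permutation p", {
  set.seed(62)
  mkev <- function(n, plant) {
    data.frame(group = if (plant) "included" else "unchanged",
               upstream_intron = vapply(seq_len(n), function(i)
                 random_seq(250), character(1)),
               exon = vapply(seq_len(n), function(i) random_seq(60),
                             character(1)),
               downstream_intron = vapply(seq_len(n), function(i) {
                 s <- random_seq(250)
                 if (plant) substr(s, 20, 23) <- "TCAT"  # matches YCAY
                 s
               }, character(1)))
  }
  events <- rbind(mkev(25, TRUE), mkev(40, FALSE))
  m <- rna_map(events, "YCAY", window = 5, n_perm = 500, seed = 63)
  dn <- m$positions$region == "downstream_intron"
  pos <- which(dn)[20:23]
  expect_true(all(m$p_values[pos, "included"] <= 1 / 501 + 1e-12))
  expect_true(all(m$sig_mask[pos, "included"]))
  peak <- which.max(m$coverage[dn, "included"])
  expect_true(peak >= 17 && peak <= 26)  # smoothing spreads the peak

  expect_error(rna_map(events, ""), "empty motif")
  expect_error(rna_map(events, paste(rep("A", 300), collapse = "")),
               "longer than region")
})

test_that("RNA-map permutation p-values are calibrated under the null", {
  set.seed(64)
  pooled <- c()
  for (rep in 1:6) {
    ev <- data.frame(group = rep(c("included", "unchanged"), c(20, 30)),
                     upstream_intron = vapply(1:50, function(i)
                       random_seq(80), character(1)),
                     exon = vapply(1:50, function(i) random_seq(30),
                                   character(1)),
                     downstream_intron = vapply(1:50, function(i)
                       random_seq(80), character(1)))
    m <- rna_map(ev, "YCAY", window = 11, n_perm = 200, flank = 80,
                 exon_extent = 30, seed = 640 + rep)
    pooled <- c(pooled, as.vector(m$p_values))
  }
  pooled <- pooled[!is.na(pooled)]
  expect_gt(mean(pooled), 0.40)
  expect_lt(mean(pooled), 0.62)
  frac05 <- mean(pooled <= 0.05)
  expect_lt(frac05, 0.10)
})

test_that("dPSI-expression regression separates the three classes", {
  set.seed(65)
  n <- 500
  splice <- data.frame(gene_id = sprintf("g%d", 1:n),
                       event_id = sprintf("e%d", 1:n), type = "CE",
                       dpsi = rnorm(n, 0, 15),
                       call = sample(c("UP", "DOWN", "unchanged"), n,
                                     replace = TRUE))
  expr <- data.frame(gene_id = sprintf("g%d", 1:n),
                     log2fc = rnorm(n), sig = runif(n) < 0.4)
  fit <- dpsi_expression_correlation(splice, expr)
  expect_true(all(fit$r_squared < 0.05))
  expect_setequal(fit$class, c("changed_DE", "changed_AS", "both"))

  splice2 <- splice
  splice2$dpsi <- 10 * expr$log2fc
  # exact fits trip summary.lm's perfect-fit warning; that is the point here
  fit2 <- suppressWarnings(dpsi_expression_correlation(splice2, expr))
  expect_true(all(abs(fit2$r_squared - 1) < 1e-9))
  expect_true(all(abs(fit2$slope - 10) < 1e-9))

  splice3 <- splice
  splice3$dpsi <- 5
  fit3 <- suppressWarnings(dpsi_expression_correlation(splice3, expr))
  expect_true(all(fit3$r_squared == 0))
})

test_that("sliding-window curve counts DOWN fractions per window", {
  expr <- data.frame(length = seq_len(300) * 1000,
                     direction = c(rep(c("DOWN", "none"), c(40, 60)),
                                   rep("none", 200)))
  curve <- length_sliding_window(expr, window = 100)
  expect_equal(nrow(curve), 201)  # N - window + 1
  expect_equal(curve$fraction_down[1], 0.40)
  expect_equal(curve$fraction_down[201], 0)

  none <- expr
  none$direction <- "none"
  expect_true(all(length_sliding_window(none, 100)$fraction_down == 0))
  expect_error(length_sliding_window(expr[1:50, ], 100), "at least")
})

test_that("window fractions ignore ordering among equal-length genes", {
  expr <- data.frame(length = rep(c(1000, 2000), each = 100),
                     direction = rep(c("DOWN", "none"), 100))
  c1 <- length_sliding_window(expr, 100)
  c2 <- length_sliding_window(expr[sample(nrow(expr)), ], 100)
  expect_equal(c1$fraction_down[1], c2$fraction_down[1])
  expect_equal(c1$fraction_down[nrow(c1)], c2$fraction_down[nrow(c2)])
})

test_that("the neuron preset yields a rising curve anchored near 0.40", {
  g <- make_genes(5000, log(3e4), 1.3, c(2e3, 2e6), seed = 66)
  expr <- simulate_expression(g, seed = 67)
  curve <- length_sliding_window(expr, 100)
  rho <- suppressWarnings(cor.test(curve$median_length,
                                   curve$fraction_down,
                                   method = "spearman"))$estimate
  expect_gt(unname(rho), 0.9)
  short <- curve$median_length >= 8e3 & curve$median_length <= 1.2e4
  expect_lt(abs(mean(curve$fraction_down[short]) - 0.40), 0.05)
})

test_that("overlap_fisher reports the cross-product odds ratio and exact p", {
  u <- sprintf("g%d", 1:100)
  q <- u[1:20]             # query: first 20
  a <- u[c(1:10, 21:30)]   # annotation: 10 overlap
  ov <- overlap_fisher(q, a, u)
  expect_equal(unname(ov$table[1, 1]), 10)
  expect_equal(ov$odds_ratio, (10 * 70) / (10 * 10))
  expect_equal(ov$p_value, fisher.test(ov$table)$p.value)

  deg <- overlap_fisher(u, u, u)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(overlap_fisher(q, a, character(0)), "empty universe")
  expect_error(overlap_fisher(c(q, "zz"), a, u), "subsets")
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  set.seed(68)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c_ <- sample(0:(n - a - b), 1); d <- n - a - b - c_
    u <- sprintf("g%d", seq_len(n))
    q <- u[seq_len(a + b)]
    ann <- u[c(seq_len(a), if (c_ > 0) (a + b) + seq_len(c_))]
    ov <- overlap_fisher(q, ann, u)
    if (ov$degenerate) next
    expect_equal(ov$p_value, enumerate_fisher_p(a, b, c_, d),
                 tolerance = 1e-9)
  }
})
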