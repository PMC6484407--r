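# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exhaustive two-segment Poisson breakpoint search: plain sums per segment,
# no cumulative-sum shortcut. Returns the first (smallest) maximizing k.
brute_force_front <- function(counts) {
  n <- length(counts)
  term <- function(s, m) if (s > 0) s * log(s / m) else 0
  scores <- vapply(seq_len(n - 1L), function(k) {
    term(sum(counts[1:k]), k) + term(sum(counts[(k + 1):n]), n - k)
  }, numeric(1))
  list(k = which.max(scores), score = max(scores), scores = scores)
}

# Mann-Whitney U for group x by pairwise comparison (ties count 1/2).
brute_force_u <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
}

# Two-sided Fisher exact p by hypergeometric enumeration over the support,
# summing all tables as or less probable than the observed one.
enumerate_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Beta-posterior dPSI oracle at high draw count, for freezing expectations.
beta_dpsi_oracle <- function(inc_a, exc_a, inc_b, exc_b, n = 1e6,
                             seed = 99) {
  set.seed(seed)
  d <- 100 * (rbeta(n, inc_b + 1, exc_b + 1) -
                rbeta(n, inc_a + 1, exc_a + 1))
  list(dpsi = median(d), p_dir = mean(sign(d) == sign(median(d))))
}

# Random A/C/G/T sequence of length n.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
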