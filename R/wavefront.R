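# Wave-front detection and elongation-rate estimation.
#
# The front is modeled as a changepoint in a two-segment constant-mean
# Poisson profile: bins upstream of the breakpoint share a high mean, bins
# downstream a low one. Up to terms that do not depend on the breakpoint,
# the profile log-likelihood of breakpoint k is
#   S1 * log(S1 / k) + S2 * log(S2 / (n - k)),
# with S1, S2 the segment count sums (0 * log 0 = 0). The scan maximizes
# this exactly over all breakpoints via cumulative sums; ties take the
# smallest k (most conservative front).

front_segment_scores <- function(counts) {
  n <- length(counts)
  S <- sum(counts)
  cs <- cumsum(counts)
  k <- seq_len(n - 1L)
  s1 <- cs[k]
  s2 <- S - s1
  term <- function(s, m) ifelse(s > 0, s * log(s / m), 0)
  list(k = k, score = term(s1, k) + term(s2, n - k), s1 = s1, s2 = s2,
       null = if (S > 0) S * log(S / n) else 0)
}

#' Detect the transcription wave-front in a binned profile
#'
#' Scans all breakpoints of a two-segment Poisson model over the bins from
#' `scan_start` (bp past the TSS, excluding the promoter-proximal zone) to
#' the gene end and returns the maximum-likelihood breakpoint. The front is
#' the downstream edge of the last upstream-segment bin. A detection is
#' accepted only if the downstream mean is at most `epsilon` times the
#' upstream mean; profiles with too little signal are flagged rather than
#' scanned.
#'
#' @param profile A [binned_coverage()] object.
#' @param scan_start Scan start in bp from the TSS (default 1 kb, past the
#'   promoter-proximal zone seen at t = 0).
#' @param min_reads Minimum total counts in the scanned region (default 50).
#' @param epsilon Maximum allowed downstream/upstream mean ratio (default
#'   0.25).
#' @return A one-row data.frame (`wave_front`): `gene_id`, `time`,
#'   `genotype`, `position` (bp from TSS; `NA` unless detected), `ll_gain`
#'   (log-likelihood gain of the two-segment fit over one segment), and
#'   `qc_flag` in `ok`, `low_coverage`, `none_detected`,
#'   `front_at_gene_end`.
#' @export
detect_front <- function(profile, scan_start = 1000, min_reads = 50,
                         epsilon = 0.25) {
  stopifnot(inherits(profile, "binned_coverage"))
  bs <- profile$bin_size
  n <- length(profile$counts)
  first <- floor(scan_start / bs) + 1L
  res <- data.frame(gene_id = profile$gene_id, time = profile$time,
                    genotype = profile$genotype, position = NA_real_,
                    ll_gain = NA_real_, qc_flag = "low_coverage",
                    stringsAsFactors = FALSE)
  if (n - first + 1L < 4L) return(res)
  x <- profile$counts[first:n]
  if (sum(x) < min_reads || all(x == 0)) return(res)
  sc <- front_segment_scores(x)
  best <- which.max(sc$score)           # ties: first (smallest k)
  k <- sc$k[best]
  m1 <- sc$s1[best] / k
  m2 <- sc$s2[best] / (length(x) - k)
  res$ll_gain <- sc$score[best] - sc$null
  if (m2 > epsilon * m1 || m1 <= m2) {
    res$qc_flag <- "none_detected"
    return(res)
  }
  kg <- first - 1L + k                  # global index of last upstream bin
  res$position <- min(kg * bs, profile$gene_length)
  res$qc_flag <- if (k == length(x) - 1L) "front_at_gene_end" else "ok"
  res
}

#' Call wave-fronts for a set of profiles
#'
#' @param profiles A list of [binned_coverage()] objects or a `wave_sim`
#'   object.
#' @param times Optional subset of harvest times to call fronts at.
#' @inheritParams detect_front
#' @return A `wave_front` data.frame, one row per profile.
#' @export
call_fronts <- function(profiles, times = NULL, scan_start = 1000,
                        min_reads = 50, epsilon = 0.25) {
  if (inherits(profiles, "wave_sim")) profiles <- profiles$profiles
  if (!is.null(times))
    profiles <- Filter(function(p) p$time %in% times, profiles)
  do.call(rbind, lapply(profiles, detect_front, scan_start = scan_start,
                        min_reads = min_reads, epsilon = epsilon))
}

#' Estimate a gene's elongation rate from its wave-fronts
#'
#' With the default two-point method the rate is the front displacement
#' between the earliest and latest usable harvest times divided by the time
#' difference; the regression method (requires >= 3 usable times) is the
#' least-squares slope of front position on time. Only fronts with
#' `qc_flag == "ok"` are used, and positions must strictly increase with
#' time.
#'
#' @param fronts A `wave_front` data.frame for one gene (see
#'   [detect_front()]).
#' @param method `"two-point"` (default) or `"regression"`.
#' @return A one-row data.frame (`gene_rate`): `gene_id`, `genotype`,
#'   `rate` (bases/min), `times_used`, `method`, `exclusion_reason`. When
#'   the gene cannot be rated, `rate` is `NA` and `exclusion_reason` says
#'   why; such genes never enter downstream comparisons.
#' @export
estimate_rate <- function(fronts, method = c("two-point", "regression")) {
  method <- match.arg(method)
  ok <- fronts[fronts$qc_flag == "ok" & !is.na(fronts$position), ,
               drop = FALSE]
  fail <- function(reason) {
    data.frame(gene_id = fronts$gene_id[1], genotype = fronts$genotype[1],
               rate = NA_real_, times_used = NA_character_,
               method = method, exclusion_reason = reason,
               stringsAsFactors = FALSE)
  }
  if (nrow(ok) < 2L) return(fail("fewer than 2 usable time points"))
  ok <- ok[order(ok$time), ]
  if (any(diff(ok$position) <= 0))
    return(fail("front positions not strictly increasing with time"))
  if (method == "two-point") {
    i <- c(1L, nrow(ok))
    rate <- diff(ok$position[i]) / diff(ok$time[i])
    used <- ok$time[i]
  } else {
    if (nrow(ok) < 3L)
      return(fail("regression needs >= 3 usable time points"))
    rate <- unname(coef(lm(position ~ time, data = ok))[2])
    used <- ok$time
  }
  data.frame(gene_id = ok$gene_id[1], genotype = ok$genotype[1],
             rate = rate, times_used = paste(used, collapse = ","),
             method = method, exclusion_reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Estimate rates for all genes in a front table
#'
#' @param fronts A `wave_front` data.frame (multiple genes).
#' @inheritParams estimate_rate
#' @return A `gene_rate` data.frame; genes that could not be rated are
#'   listed in the `exclusions` attribute with their reasons.
#' @export
estimate_rates <- function(fronts, method = c("two-point", "regression")) {
  method <- match.arg(method)
  pieces <- lapply(split(fronts, fronts$gene_id), estimate_rate,
                   method = method)
  all_rows <- do.call(rbind, pieces)
  rownames(all_rows) <- NULL
  excl <- !is.na(all_rows$exclusion_reason)
  out <- all_rows[!excl, setdiff(names(all_rows), "exclusion_reason"),
                  drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(
    gene_id = all_rows$gene_id[excl],
    reason = all_rows$exclusion_reason[excl], stringsAsFactors = FALSE)
  out
}

#' Genes with usable rates in every genotype
#'
#' Cross-genotype rate comparisons are restricted to genes rated in all
#' genotypes.
#'
#' @param rate_tables A named list of `gene_rate` data.frames, one per
#'   genotype.
#' @return Character vector of common gene ids.
#' @export
common_genes <- function(rate_tables) {
  stopifnot(is.list(rate_tables), length(rate_tables) >= 1)
  sets <- lapply(rate_tables, function(r) unique(r$gene_id))
  common <- Reduce(intersect, sets)
  if (length(common) == 0)
    stop("no genes have usable rates in every genotype")
  common
}

#' Compare per-gene elongation rates between two genotypes
#'
#' Two-sided Mann-Whitney test with the normal approximation and tie
#' correction, plus per-group means and medians. Degenerate all-tied inputs
#' give p = 1 with a warning.
#'
#' @param rates_a,rates_b Numeric rate vectors (>= 3 each), or `gene_rate`
#'   data.frames.
#' @param labels Group labels for the report.
#' @return A list of class `rate_comparison`: `n`, `mean`, `median` (named
#'   per group), `U`, `p_value`.
#' @export
compare_rates <- function(rates_a, rates_b, labels = c("A", "B")) {
  if (is.data.frame(rates_a)) rates_a <- rates_a$rate
  if (is.data.frame(rates_b)) rates_b <- rates_b$rate
  stopifnot(length(rates_a) >= 3, length(rates_b) >= 3)
  pooled <- c(rates_a, rates_b)
  r <- rank(pooled)
  U <- sum(r[seq_along(rates_a)]) - length(rates_a) *
    (length(rates_a) + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("all rates tied across groups; p set to 1")
    p <- 1
  } else {
    wt <- suppressWarnings(wilcox.test(rates_a, rates_b, exact = FALSE,
                                       correct = FALSE))
    p <- wt$p.value
  }
  structure(list(
    n = setNames(c(length(rates_a), length(rates_b)), labels),
    mean = setNames(c(mean(rates_a), mean(rates_b)), labels),
    median = setNames(c(median(rates_a), median(rates_b)), labels),
    U = U, p_value = p), class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Elongation-rate comparison (Mann-Whitney, normal approximation)\n")
  for (g in names(x$n))
    cat(sprintf("  %s: n = %d, mean = %.0f, median = %.0f bases/min\n",
                g, x$n[[g]], x$mean[[g]], x$median[[g]]))
  cat(sprintf("  U = %g, two-sided p = %.3g\n", x$U, x$p_value))
  invisible(x)
}

#' Median wave-front positions per genotype and time
#'
#' @param fronts A `wave_front` data.frame.
#' @return A data.frame with `genotype`, `time`, `n`, `median_position`.
#' @export
front_medians <- function(fronts) {
  ok <- fronts[fronts$qc_flag == "ok", , drop = FALSE]
  agg <- aggregate(position ~ genotype + time, data = ok, FUN = median)
  cnt <- aggregate(position ~ genotype + time, data = ok, FUN = length)
  names(agg)[3] <- "median_position"
  agg$n <- cnt$position
  agg[order(agg$genotype, agg$time), c("genotype", "time", "n",
                                       "median_position")]
}

#' Correlate elongation rates with mean expression
#'
#' @param rates A `gene_rate` data.frame (or a data.frame with `gene_id`
#'   and `rate`).
#' @param expression A data.frame with `gene_id` and `mean_expr`.
#' @return A list: `n`, `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `r_squared`, `pearson_p`. Both the correlation coefficient and its
#'   square are reported.
#' @export
correlate_rate_expression <- function(rates, expression) {
  m <- merge(rates[, c("gene_id", "rate")],
             expression[, c("gene_id", "mean_expr")], by = "gene_id")
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3) stop("need >= 3 paired gene records")
  sp <- suppressWarnings(cor.test(m$rate, m$mean_expr, method = "spearman"))
  pe <- cor.test(m$rate, m$mean_expr, method = "pearson")
  list(n = nrow(m),
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate),
       r_squared = unname(pe$estimate)^2, pearson_p = pe$p.value)
}
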