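# PSI quantification and differential alternative-splicing calls.
#
# Events carry inclusion/exclusion junction read counts per sample. PSI is
# 100 * inc / (inc + exc). Differential calls pool counts within condition,
# place a Beta(inc + 1, exc + 1) posterior on each condition's inclusion
# ratio, and summarize Monte-Carlo draws of dPSI = PSI_B - PSI_A by the
# posterior median (point estimate) and the posterior probability that dPSI
# shares the sign of that point estimate (p_dir). An event is called UP
# when dPSI >= +dpsi_min and p_dir >= p_min, DOWN symmetrically.

#' Percent spliced in
#'
#' @param inclusion,exclusion Junction read counts (vectorized).
#' @return PSI in percent; `NA` where `inclusion + exclusion == 0` (the
#'   event is not testable, never a division error).
#' @export
compute_psi <- function(inclusion, exclusion) {
  stopifnot(all(inclusion >= 0, na.rm = TRUE),
            all(exclusion >= 0, na.rm = TRUE))
  total <- inclusion + exclusion
  ifelse(total > 0, 100 * inclusion / total, NA_real_)
}

#' Filter splice events for testability
#'
#' Coverage rules follow the quantification tool's quality scores:
#' intron-retention events need at least `min_reads_ir` reads in every
#' compared sample; all other event classes need at least
#' `min_reads_other`. When the two inclusion junctions of a cassette or
#' microexon event are provided separately (`inc1`, `inc2`), events whose
#' junctions differ by more than `max_imbalance`-fold are dropped.
#'
#' @param events Long data.frame: `event_id`, `type`, `sample`, `inc`,
#'   `exc`, optionally `inc1` and `inc2`.
#' @param min_reads_ir Minimum per-sample reads for IR events (default 15).
#' @param min_reads_other Minimum per-sample reads for other events
#'   (default 10).
#' @param max_imbalance Maximum inclusion-junction fold difference for
#'   CE/MIC events (default 5).
#' @return The testable subset of `events`; dropped event ids and reasons
#'   are in the `dropped` attribute.
#' @export
filter_events <- function(events, min_reads_ir = 15, min_reads_other = 10,
                          max_imbalance = 5) {
  stopifnot(all(c("event_id", "type", "sample", "inc", "exc") %in%
                  names(events)))
  drop <- list()
  keep_ids <- vapply(split(events, events$event_id), function(ev) {
    need <- if (ev$type[1] == "IR") min_reads_ir else min_reads_other
    if (any(ev$inc + ev$exc < need)) {
      drop[[ev$event_id[1]]] <<- "coverage"
      return(FALSE)
    }
    if (all(c("inc1", "inc2") %in% names(ev)) &&
        ev$type[1] %in% c("CE", "MIC")) {
      j1 <- ev$inc1; j2 <- ev$inc2
      bad <- (pmax(j1, j2) > max_imbalance * pmin(j1, j2)) &
        (pmax(j1, j2) > 0)
      if (any(bad)) {
        drop[[ev$event_id[1]]] <<- "junction_imbalance"
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- events[events$event_id %in% names(keep_ids)[keep_ids], ,
                drop = FALSE]
  attr(out, "dropped") <-
    data.frame(event_id = names(drop),
               reason = unlist(drop, use.names = FALSE),
               stringsAsFactors = FALSE)
  out
}

diff_splice_one <- function(inc_a, exc_a, inc_b, exc_b, n_mc, p_min,
                            dpsi_min) {
  pa <- rbeta(n_mc, inc_a + 1, exc_a + 1)
  pb <- rbeta(n_mc, inc_b + 1, exc_b + 1)
  d <- 100 * (pb - pa)
  point <- median(d)
  p_dir <- if (point == 0) 0.5 else mean(sign(d) == sign(point))
  call <- "unchanged"
  if (point >= dpsi_min && p_dir >= p_min) call <- "UP"
  if (point <= -dpsi_min && p_dir >= p_min) call <- "DOWN"
  list(dpsi = point, p_dir = p_dir, call = call)
}

#' Differential splicing between two conditions
#'
#' Counts are pooled within condition per event; see the module notes above
#' for the posterior model. Results are deterministic given `seed`.
#'
#' @param events Long data.frame with columns `event_id`, `type`,
#'   `condition` (exactly two levels), `inc`, `exc` (one row per sample);
#'   typically the output of [filter_events()] or
#'   [simulate_junction_counts()].
#' @param n_mc Monte-Carlo draws per event (>= 1000).
#' @param p_min Minimum directional posterior probability for a call
#'   (default 0.95).
#' @param dpsi_min Minimum |dPSI| point estimate for a call, in percent
#'   (default 10).
#' @param conditions Optional length-2 vector fixing which condition is A
#'   (reference) and which is B; default: sorted unique values.
#' @param seed Optional integer seed.
#' @return A `diff_splice` data.frame, one row per event: `event_id`,
#'   `type`, `psi_a`, `psi_b` (pooled empirical PSI), `dpsi` (posterior
#'   median of PSI_B - PSI_A), `p_dir`, `call` in
#'   `UP`/`DOWN`/`unchanged`/`not_testable`.
#' @export
diff_splice <- function(events, n_mc = 2000, p_min = 0.95, dpsi_min = 10,
                        conditions = NULL, seed = NULL) {
  stopifnot(all(c("event_id", "condition", "inc", "exc") %in% names(events)))
  if (n_mc < 1000) stop("'n_mc' must be >= 1000")
  if (!"type" %in% names(events)) events$type <- "CE"
  conds <- conditions %||% sort(unique(events$condition))
  if (length(conds) != 2)
    stop("exactly two conditions are required")
  with_seed(seed, {
    rows <- lapply(split(events, events$event_id), function(ev) {
      a <- ev[ev$condition == conds[1], ]
      b <- ev[ev$condition == conds[2], ]
      inc_a <- sum(a$inc); exc_a <- sum(a$exc)
      inc_b <- sum(b$inc); exc_b <- sum(b$exc)
      base <- data.frame(event_id = ev$event_id[1], type = ev$type[1],
                         psi_a = compute_psi(inc_a, exc_a),
                         psi_b = compute_psi(inc_b, exc_b),
                         dpsi = NA_real_, p_dir = NA_real_,
                         call = "not_testable", stringsAsFactors = FALSE)
      if (inc_a + exc_a == 0 || inc_b + exc_b == 0) return(base)
      r <- diff_splice_one(inc_a, exc_a, inc_b, exc_b, n_mc, p_min,
                           dpsi_min)
      base$dpsi <- r$dpsi
      base$p_dir <- r$p_dir
      base$call <- r$call
      base
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "conditions") <- conds
    out
  })
}

#' Tabulate UP/DOWN calls per event class
#'
#' @param results A `diff_splice` data.frame.
#' @param fdr If `TRUE`, Benjamini-Hochberg FDR is applied to the
#'   complement of the directional posterior (1 - `p_dir`) across events
#'   and calls additionally require `fdr_alpha`.
#' @param fdr_alpha FDR threshold when `fdr = TRUE` (default 0.05).
#' @return A data.frame of counts with one row per event type and columns
#'   `UP`, `DOWN`, `unchanged`, `not_testable`, `total`. The call vector
#'   actually tabulated (after optional FDR) is in the `calls` attribute.
#' @export
summarize_calls <- function(results, fdr = FALSE, fdr_alpha = 0.05) {
  calls <- results$call
  if (fdr) {
    q <- p.adjust(1 - results$p_dir, method = "BH")
    demote <- calls %in% c("UP", "DOWN") & (is.na(q) | q >= fdr_alpha)
    calls[demote] <- "unchanged"
  }
  lv <- c("UP", "DOWN", "unchanged", "not_testable")
  types <- sort(unique(as.character(results$type)))
  tab <- table(factor(as.character(results$type), levels = types),
               factor(calls, levels = lv))
  out <- as.data.frame.matrix(tab)
  out <- cbind(type = rownames(out), out, total = rowSums(out))
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  attr(out, "fdr") <- if (fdr) fdr_alpha else NA_real_
  out
}
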