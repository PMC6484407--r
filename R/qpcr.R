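# Elongation rates from DRB-release qPCR time courses at exon-intron
# junctions: the low-throughput validation assay. A junction "appears" when
# its pre-mRNA signal first reaches a fraction of the plateau; the rate is
# junction distance over that detection time.

#' First detection time of a junction signal
#'
#' The plateau is estimated as the mean of the final two time points (the
#' series is normalized to untreated cells and approaches 1, with noise).
#' Detection is the earliest *sampled* time whose mean replicate value is at
#' or above `threshold_fraction` of the plateau; no interpolation is done,
#' matching how such time courses are reported.
#'
#' @param series A qPCR series data.frame with columns `time_min`, `value`,
#'   and optionally `replicate` (replicates are averaged per time point).
#' @param threshold_fraction Fraction of plateau that counts as detected
#'   (default 0.5).
#' @return Detection time in minutes, or `NA` (with a `"reason"` attribute)
#'   if the series never crosses the threshold.
#' @export
detection_time <- function(series, threshold_fraction = 0.5) {
  stopifnot(all(c("time_min", "value") %in% names(series)),
            threshold_fraction > 0, threshold_fraction <= 1)
  mean_by_time <- aggregate(value ~ time_min, data = series, FUN = mean)
  mean_by_time <- mean_by_time[order(mean_by_time$time_min), ]
  nt <- nrow(mean_by_time)
  if (nt < 2) stop("series needs at least two time points")
  plateau <- mean(mean_by_time$value[c(nt - 1, nt)])
  hit <- which(mean_by_time$value >= threshold_fraction * plateau &
                 mean_by_time$value > 0)
  if (plateau <= 0 || length(hit) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "undetected"
    return(out)
  }
  mean_by_time$time_min[hit[1]]
}

#' Elongation rate from one junction's detection time
#'
#' Rate = distance / detection time. The reported value is rounded half-up
#' to one decimal (the convention of the assay's figures); the unrounded
#' rate is retained alongside.
#'
#' @param distance_kb Junction distance from the TSS in kb (> 0).
#' @param detection_min Detection time in minutes (> 0).
#' @return A list: `rate_kb_min` (unrounded), `reported` (one decimal,
#'   half-up).
#' @examples
#' rate_from_junction(133, 40)$reported  # 3.3
#' rate_from_junction(133, 90)$reported  # 1.5
#' @export
rate_from_junction <- function(distance_kb, detection_min) {
  if (!is.numeric(distance_kb) || distance_kb <= 0)
    stop("'distance_kb' must be positive")
  if (!is.numeric(detection_min) || detection_min <= 0)
    stop("'detection_min' must be positive")
  rate <- distance_kb / detection_min
  list(rate_kb_min = rate, reported = round_half_up(rate, 1))
}

#' Per-gene elongation rate from qPCR junction series
#'
#' Detection time and rate are computed per junction; the gene-level value
#' is the rate at the most distal detectable junction (default), with the
#' mean across detectable junctions reported alongside.
#'
#' @param series A qPCR series data.frame for one gene: columns `junction`,
#'   `distance_kb`, `time_min`, `value` (and optionally `replicate`).
#' @param threshold_fraction Passed to [detection_time()].
#' @return A list: `junctions` (per-junction data.frame with
#'   `distance_kb`, `detection_min`, `rate_kb_min`, `reported`),
#'   `rate_distal`, `rate_distal_reported`, `rate_mean`,
#'   `rate_mean_reported`.
#' @export
gene_rate_qpcr <- function(series, threshold_fraction = 0.5) {
  stopifnot(all(c("junction", "distance_kb", "time_min", "value") %in%
                  names(series)))
  if (nrow(series) == 0) stop("empty qPCR series")
  per <- lapply(split(series, series$junction), function(s) {
    t_det <- detection_time(s, threshold_fraction)
    data.frame(junction = s$junction[1], distance_kb = s$distance_kb[1],
               detection_min = as.numeric(t_det), stringsAsFactors = FALSE)
  })
  jt <- do.call(rbind, per)
  rownames(jt) <- NULL
  jt <- jt[!is.na(jt$detection_min), , drop = FALSE]
  if (nrow(jt) == 0) stop("no detectable junction in series")
  rates <- Map(rate_from_junction, jt$distance_kb, jt$detection_min)
  jt$rate_kb_min <- vapply(rates, `[[`, numeric(1), "rate_kb_min")
  jt$reported <- vapply(rates, `[[`, numeric(1), "reported")
  distal <- which.max(jt$distance_kb)
  list(junctions = jt,
       rate_distal = jt$rate_kb_min[distal],
       rate_distal_reported = jt$reported[distal],
       rate_mean = mean(jt$rate_kb_min),
       rate_mean_reported = round_half_up(mean(jt$rate_kb_min), 1))
}
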