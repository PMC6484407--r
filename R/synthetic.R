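# Synthetic-data generators. These define the study conditions every
# downstream stage is tested against: a DRB block released at t = 0, a
# 10-min labeling pulse before each harvest, genotype-specific elongation
# rate distributions, condition-dependent junction inclusion, and a
# length-dependent downregulation effect.

#' Generate a synthetic gene universe
#'
#' Samples gene lengths from a lognormal law (clipped to `length_range`),
#' alternates strands, and places genes without overlap along a small set of
#' chromosomes with fixed intergenic gaps. Deterministic given `seed`.
#'
#' @param n Number of genes (>= 1).
#' @param length_meanlog,length_sdlog Lognormal parameters of gene length in
#'   bp; the default gives a median of 30 kb. `length_sdlog = 0` is the
#'   degenerate law (all genes at `exp(length_meanlog)`).
#' @param length_range Lengths are clipped to this range (bp).
#' @param n_chrom Number of chromosomes to spread genes over.
#' @param gap Intergenic gap in bp.
#' @param seed Optional integer seed.
#' @return A `gene_models` data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based, half-open), `length`, `tss`.
#' @export
make_genes <- function(n, length_meanlog = log(3e4), length_sdlog = 1.3,
                       length_range = c(2e3, 2.5e6), n_chrom = 4,
                       gap = 1e4, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  stopifnot(length(length_range) == 2L, length_range[1] > 0,
            length_range[1] <= length_range[2])
  with_seed(seed, {
    len <- round(rlnorm(n, length_meanlog, length_sdlog))
    len <- pmin(pmax(len, length_range[1]), length_range[2])
    strand <- rep_len(c("+", "-"), n)
    chrom <- paste0("chr", rep_len(seq_len(n_chrom), n))
    start <- integer(n)
    offset <- setNames(rep(0, n_chrom), paste0("chr", seq_len(n_chrom)))
    for (i in seq_len(n)) {
      start[i] <- offset[[chrom[i]]]
      offset[[chrom[i]]] <- start[i] + len[i] + gap
    }
    new_gene_models(gene_id = sprintf("gene%04d", seq_len(n)),
                    chrom = chrom, strand = strand,
                    start = start, end = start + len)
  })
}

# Expected labeled-signal profile (reads per bin) for one gene at one
# harvest time. Two components end sharply at the front F = min(v*t, L):
#  - a cohort of polymerases that accumulated at the promoter during the
#    block and released together at t = 0; they sit at v*t and their
#    pulse-labeled RNA covers [v*max(0, t - pulse), F] uniformly;
#  - continuous initiation after release at a constant rate, whose labeled
#    occupancy is min(pulse, t - x/v)/pulse, a plateau decaying linearly
#    to zero at F.
# At t = 0 (harvest at release) the signal is confined to the
# promoter-proximal zone where polymerases were held during the block.
expected_wave_profile <- function(gene_length, rate, time, pulse, depth,
                                  bin_size, cohort_fraction = 0.7,
                                  promoter_zone = 1000) {
  nb <- ceiling(gene_length / bin_size)
  lo <- (seq_len(nb) - 1) * bin_size
  hi <- pmin(lo + bin_size, gene_length)
  per_base <- depth / 1000
  overlap <- function(a, b) pmax(0, pmin(hi, b) - pmax(lo, a))
  if (time == 0) {
    return(per_base * overlap(0, min(promoter_zone, gene_length)))
  }
  front <- min(rate * time, gene_length)
  pulse_start <- min(rate * max(0, time - pulse), front)
  cohort <- cohort_fraction * per_base * overlap(pulse_start, front)
  # continuous component: integral of min(pulse, t - x/v)/pulse over the bin
  plateau_end <- min(rate * max(0, time - pulse), front)
  plat <- overlap(0, plateau_end)
  # ramp on [plateau_end, front]: w(x) = (t - x/v)/pulse
  r1 <- pmax(lo, plateau_end)
  r2 <- pmin(hi, front)
  ramp_int <- function(x) (time * x - x^2 / (2 * rate)) / pulse
  ramp <- ifelse(r2 > r1, ramp_int(r2) - ramp_int(r1), 0)
  cont <- (1 - cohort_fraction) * per_base * (plat + ramp)
  cohort + cont
}

#' Simulate binned nascent coverage for a DRB-release time course
#'
#' For every gene and harvest time, computes the expected pulse-labeled
#' signal per TSS-relative bin and (optionally) draws Poisson counts from
#' it. The farthest labeled base at harvest time t is `v * t` (truncated at
#' the gene end); at t = 0 all signal lies within `promoter_zone` of the
#' TSS. The profile is the sum of a synchronized released cohort (fraction
#' `cohort_fraction` of depth, ending sharply at the front) and continuous
#' post-release initiation (a plateau decaying linearly to zero at the
#' front).
#'
#' @param genes A `gene_models` data.frame (see [make_genes()]).
#' @param preset A [rate_preset()] giving the per-gene rate law.
#' @param design A [pulse_design()].
#' @param bin_size Bin width in bp (>= 100).
#' @param noise If `TRUE`, bin counts are Poisson draws of the expected
#'   profile; if `FALSE`, the exact expectations are returned.
#' @param cohort_fraction Fraction of labeled signal carried by the
#'   released cohort (0-1).
#' @param promoter_zone Extent in bp of the promoter-proximal signal at
#'   t = 0.
#' @param rates Optional vector of true per-gene rates (bases/min),
#'   overriding draws from `preset`.
#' @param genotype Label stored on each profile.
#' @param seed Optional integer seed.
#' @return An object of class `wave_sim`: a list with `profiles` (list of
#'   [binned_coverage()] objects, one per gene x time), `rates` (data.frame
#'   of true per-gene rates), `preset`, `design`.
#' @export
simulate_wave_coverage <- function(genes, preset, design = pulse_design(),
                                   bin_size = 500, noise = TRUE,
                                   cohort_fraction = 0.7,
                                   promoter_zone = 1000, rates = NULL,
                                   genotype = preset$name, seed = NULL) {
  stopifnot(inherits(genes, "gene_models"), inherits(preset, "rate_preset"),
            inherits(design, "pulse_design"))
  if (bin_size < 100) stop("'bin_size' must be >= 100 bp")
  if (any(genes$length < bin_size))
    stop("gene shorter than one bin: ",
         paste(genes$gene_id[genes$length < bin_size], collapse = ", "))
  with_seed(seed, {
    n <- nrow(genes)
    if (is.null(rates)) rates <- draw_rates(preset, n)
    stopifnot(length(rates) == n, all(rates > 0))
    profiles <- vector("list", n * length(design$harvest_times))
    k <- 0L
    for (i in seq_len(n)) {
      for (t in design$harvest_times) {
        mu <- expected_wave_profile(genes$length[i], rates[i], t,
                                    design$pulse_length, design$depth,
                                    bin_size, cohort_fraction,
                                    promoter_zone)
        counts <- if (noise) rpois(length(mu), mu) else mu
        k <- k + 1L
        profiles[[k]] <- binned_coverage(gene_id = genes$gene_id[i],
                                         counts = counts,
                                         bin_size = bin_size,
                                         gene_length = genes$length[i],
                                         time = t, genotype = genotype)
      }
    }
    structure(list(profiles = profiles,
                   rates = data.frame(gene_id = genes$gene_id,
                                      true_rate = rates,
                                      stringsAsFactors = FALSE),
                   preset = preset, design = design,
                   bin_size = bin_size),
              class = "wave_sim")
  })
}

#' Simulate a DRB-release qPCR time course
#'
#' Pre-mRNA signal at an exon-intron junction `d` kb from the TSS,
#' normalized to untreated cells, rises from 0 toward a plateau of 1 once
#' the transcription front passes the junction. The rise is a logistic in
#' time centered at the crossing time `d / v` (the signal is exactly half
#' the plateau when the front reaches the junction), with time scale `tau`;
#' noise is multiplicative lognormal.
#'
#' @param v Elongation rate in kb/min (> 0).
#' @param junction_distances Junction positions in kb from the TSS.
#' @param times Sampled times in minutes.
#' @param noise_sd Log-scale sd of multiplicative noise (0 = noise free).
#' @param replicates Replicates per time point.
#' @param tau Logistic time scale in minutes.
#' @param gene_id Label for the output rows.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `gene_id`, `junction`, `distance_kb`,
#'   `time_min`, `replicate`, `value`.
#' @export
simulate_qpcr_timecourse <- function(v, junction_distances, times,
                                     noise_sd = 0, replicates = 3,
                                     tau = 5, gene_id = "gene", seed = NULL) {
  if (!is.numeric(v) || length(v) != 1L || v <= 0)
    stop("'v' must be a single positive rate in kb/min")
  stopifnot(all(junction_distances > 0), all(times >= 0),
            all(diff(times) > 0), replicates >= 1, noise_sd >= 0)
  with_seed(seed, {
    out <- expand.grid(replicate = seq_len(replicates), time_min = times,
                       distance_kb = junction_distances,
                       KEEP.OUT.ATTRS = FALSE)
    crossing <- out$distance_kb / v
    signal <- 1 / (1 + exp(-(out$time_min - crossing) / tau))
    if (noise_sd > 0)
      signal <- signal * rlnorm(nrow(out), -noise_sd^2 / 2, noise_sd)
    data.frame(gene_id = gene_id,
               junction = sprintf("junction_%gkb", out$distance_kb),
               distance_kb = out$distance_kb, time_min = out$time_min,
               replicate = out$replicate, value = signal,
               stringsAsFactors = FALSE)
  })
}

#' Simulate inclusion/exclusion junction counts for splice events
#'
#' Per event and sample, inclusion reads are Binomial(depth, PSI/100) and
#' exclusion reads make up the remainder. Condition A samples use the
#' event's base PSI; condition B samples use base PSI plus the event's true
#' dPSI. The true dPSI is stored with each row so recovery can be tested.
#'
#' @param n_events Number of events.
#' @param psi_base Base PSI values (percent): a single number, a vector of
#'   length `n_events`, or a function of `n` returning PSI draws. Default:
#'   uniform on \[10, 90\].
#' @param dpsi_true True PSI difference (B - A), recycled to `n_events`.
#'   `psi_base + dpsi_true` must stay within \[0, 100\].
#' @param depth Junction reads per sample (>= 1).
#' @param replicates Samples per condition.
#' @param type Event type label(s), recycled (`CE`, `MIC`, `Alt5`, `Alt3`,
#'   `IR`).
#' @param seed Optional integer seed.
#' @return A long data.frame: `event_id`, `gene_id`, `type`, `sample`,
#'   `condition` (A/B), `inc`, `exc`, `psi_true`, `dpsi_true`.
#' @export
simulate_junction_counts <- function(n_events, psi_base = NULL,
                                     dpsi_true = 0, depth = 200,
                                     replicates = 3, type = "CE",
                                     seed = NULL) {
  stopifnot(n_events >= 1, replicates >= 1)
  if (depth < 1) stop("'depth' must be >= 1 read per sample")
  with_seed(seed, {
    psi <- if (is.function(psi_base)) psi_base(n_events)
           else if (is.null(psi_base)) runif(n_events, 10, 90)
           else rep_len(psi_base, n_events)
    dpsi <- rep_len(dpsi_true, n_events)
    if (any(psi < 0 | psi > 100 | psi + dpsi < 0 | psi + dpsi > 100))
      stop("PSI and PSI + dPSI must lie within [0, 100]")
    type <- rep_len(type, n_events)
    rows <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      p <- c(rep(psi[i], replicates), rep(psi[i] + dpsi[i], replicates))
      inc <- rbinom(2 * replicates, depth, p / 100)
      rows[[i]] <- data.frame(
        event_id = sprintf("ev%05d", i),
        gene_id = sprintf("g%05d", i),
        type = type[i],
        sample = c(paste0("A", seq_len(replicates)),
                   paste0("B", seq_len(replicates))),
        condition = rep(c("A", "B"), each = replicates),
        inc = inc, exc = depth - inc,
        psi_true = psi[i], dpsi_true = dpsi[i],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate an expression table with a gene-length downregulation effect
#'
#' Each gene is flagged downregulated with probability `p_down(length)`
#' from the length-effect preset. Downregulated genes receive a negative
#' log2 fold change; a small background fraction is upregulated; the rest
#' are unchanged. True flags are kept for recovery tests.
#'
#' @param genes A `gene_models` data.frame.
#' @param effect A [length_effect_preset()], or a function of length
#'   returning downregulation probabilities.
#' @param p_up Background probability of upregulation among non-down genes.
#' @param seed Optional integer seed.
#' @return A data.frame of expression records: `gene_id`, `length`,
#'   `mean_expr`, `log2fc`, `sig`, `direction` (UP/DOWN/none),
#'   `down_true`.
#' @export
simulate_expression <- function(genes, effect = preset_neuron_length_effect(),
                                p_up = 0.05, seed = NULL) {
  stopifnot(inherits(genes, "gene_models"), nrow(genes) >= 1)
  p_down <- if (is.function(effect)) effect else effect$p_down
  with_seed(seed, {
    n <- nrow(genes)
    p <- p_down(genes$length)
    stopifnot(all(p >= 0 & p <= 1))
    down <- rbinom(n, 1, p) == 1
    up <- !down & rbinom(n, 1, p_up) == 1
    log2fc <- rnorm(n, 0, 0.25)
    log2fc[down] <- -abs(rnorm(sum(down), 1.2, 0.5))
    log2fc[up] <- abs(rnorm(sum(up), 1.2, 0.5))
    direction <- ifelse(down, "DOWN", ifelse(up, "UP", "none"))
    data.frame(gene_id = genes$gene_id, length = genes$length,
               mean_expr = rlnorm(n, log(50), 1),
               log2fc = log2fc, sig = direction != "none",
               direction = direction, down_true = down,
               stringsAsFactors = FALSE)
  })
}
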