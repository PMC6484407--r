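# End-to-end orchestration of the synthetic pipeline: simulate -> bin ->
# wave-front -> qPCR -> splicing -> coupling, with a machine-readable run
# manifest. Stage outputs are pure functions of the configuration and
# seeds, so a repeated run reproduces every file bit for bit.

#' Default pipeline configuration
#'
#' Every threshold defaults to the assay's published value where one
#' exists: dPSI call threshold 10 percent, directional posterior 0.95,
#' qPCR detection threshold 0.5 of plateau, 15-read minimum for intron
#' retention, 100-gene sliding window; bin size 500 bp and harvest times
#' 0/5/15 min with a 10-min pulse describe the labeling design.
#'
#' @return A named list of configuration keys.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_genes = 60,
    n_expr_genes = 500,
    n_events = 80,
    bin_size = 500,
    harvest_times = c(0, 5, 15),
    pulse_length = 10,
    depth = 50,
    gene_length_meanlog = log(9e4),
    gene_length_sdlog = 0.5,
    gene_length_range = c(2e4, 5e5),
    dpsi_min = 10,
    p_min = 0.95,
    n_mc = 2000,
    qpcr_threshold = 0.5,
    ir_min_reads = 15,
    window = 100
  )
}

#' Validate a pipeline configuration
#'
#' @param config A configuration list; missing keys are filled from
#'   [default_config()].
#' @return The completed configuration, invisibly; stops with a message on
#'   the first invalid key.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  check(cfg$n_genes >= 1, "n_genes must be >= 1")
  check(cfg$n_expr_genes >= cfg$window,
        "n_expr_genes must be >= window")
  check(cfg$bin_size >= 100, "bin_size must be >= 100 bp")
  check(all(cfg$harvest_times >= 0) && !is.unsorted(cfg$harvest_times,
                                                    strictly = TRUE),
        "harvest_times must be non-negative and strictly increasing")
  check(cfg$pulse_length > 0, "pulse_length must be positive")
  check(cfg$depth > 0, "depth must be positive")
  check(cfg$dpsi_min >= 0 && cfg$dpsi_min <= 100,
        "dpsi_min must lie in [0, 100]")
  check(cfg$p_min > 0.5 && cfg$p_min <= 1, "p_min must lie in (0.5, 1]")
  check(cfg$qpcr_threshold > 0 && cfg$qpcr_threshold <= 1,
        "qpcr_threshold must lie in (0, 1]")
  check(cfg$ir_min_reads >= 1, "ir_min_reads must be >= 1")
  check(cfg$window >= 1, "window must be >= 1")
  check(cfg$n_mc >= 1000, "n_mc must be >= 1000")
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Plain YAML with the keys of [default_config()]; round-trips losslessly.
#'
#' @param path YAML file.
#' @param config Configuration list.
#' @return `read_config()`: the validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

stage_seed <- function(cfg, k) (as.integer(cfg$seed) * 101L + k) %% .Machine$integer.max

#' Run the full synthetic pipeline
#'
#' Executes simulate -> bin -> wave-front -> qPCR -> splice -> coupling in
#' dependency order, writing one TSV (or JSON) per stage plus a manifest
#' recording the package version, configuration, seeds, and MD5 checksum of
#' every output. Identical configurations produce identical run
#' directories.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before any stage runs.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    if (grepl("\\.json$", name))
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    else write_tsv_table(x, path)
    files[[name]] <<- unname(tools::md5sum(path))
    path
  }

  # stage 1: gene universe
  genes <- make_genes(cfg$n_genes, cfg$gene_length_meanlog,
                      cfg$gene_length_sdlog, cfg$gene_length_range,
                      seed = stage_seed(cfg, 1L))
  write_genes(genes, file.path(out_dir, "genes.gtf"))
  files[["genes.gtf"]] <- unname(tools::md5sum(file.path(out_dir,
                                                         "genes.gtf")))

  # stage 2: nascent coverage per genotype
  design <- pulse_design(cfg$harvest_times, cfg$pulse_length, cfg$depth)
  sims <- list(wt = simulate_wave_coverage(genes, preset_wt_rate(), design,
                                           cfg$bin_size, genotype = "wt",
                                           seed = stage_seed(cfg, 2L)),
               slow = simulate_wave_coverage(genes, preset_slow_rate(),
                                             design, cfg$bin_size,
                                             genotype = "slow",
                                             seed = stage_seed(cfg, 3L)))
  bins <- do.call(rbind, lapply(sims, function(s)
    profiles_to_table(s$profiles)))
  rownames(bins) <- NULL
  emit(bins, "bins.tsv")
  truth <- do.call(rbind, lapply(names(sims), function(g)
    cbind(genotype = g, sims[[g]]$rates)))
  emit(truth, "true_rates.tsv")

  # stage 3: wave-fronts and rates
  fronts <- do.call(rbind, lapply(sims, call_fronts))
  rownames(fronts) <- NULL
  emit(fronts, "fronts.tsv")
  rates <- lapply(sims, function(s) estimate_rates(call_fronts(s)))
  rates_tab <- do.call(rbind, rates)
  rownames(rates_tab) <- NULL
  emit(rates_tab, "rates.tsv")
  common <- common_genes(rates)
  cmp <- compare_rates(rates$wt[rates$wt$gene_id %in% common, ],
                       rates$slow[rates$slow$gene_id %in% common, ],
                       labels = c("wt", "slow"))
  emit(list(n_common = length(common), mean = as.list(cmp$mean),
            median = as.list(cmp$median), U = cmp$U,
            p_value = cmp$p_value), "rate_comparison.json")

  # stage 4: qPCR validation assay (distal junction of a long gene)
  qpcr <- rbind(
    cbind(genotype = "wt",
          simulate_qpcr_timecourse(3.325, c(10, 60, 133),
                                   seq(0, 120, by = 10), noise_sd = 0.1,
                                   gene_id = "Itpr1",
                                   seed = stage_seed(cfg, 4L))),
    cbind(genotype = "slow",
          simulate_qpcr_timecourse(133 / 90, c(10, 60, 133),
                                   seq(0, 120, by = 10), noise_sd = 0.1,
                                   gene_id = "Itpr1",
                                   seed = stage_seed(cfg, 5L))))
  emit(qpcr, "qpcr_series.tsv")
  qrates <- do.call(rbind, lapply(split(qpcr, qpcr$genotype), function(q) {
    r <- gene_rate_qpcr(q, cfg$qpcr_threshold)
    data.frame(genotype = q$genotype[1], gene_id = q$gene_id[1],
               rate_distal = r$rate_distal_reported,
               rate_mean = r$rate_mean_reported, stringsAsFactors = FALSE)
  }))
  rownames(qrates) <- NULL
  emit(qrates, "qpcr_rates.tsv")

  # stage 5: differential splicing
  n_changed <- max(1L, round(cfg$n_events * 0.25))
  dpsi_true <- c(rep(-20, ceiling(n_changed / 2)),
                 rep(20, floor(n_changed / 2)),
                 rep(0, cfg$n_events - n_changed))
  ev <- simulate_junction_counts(cfg$n_events, psi_base = 50,
                                 dpsi_true = dpsi_true, depth = 200,
                                 type = c("CE", "MIC", "IR"),
                                 seed = stage_seed(cfg, 6L))
  ev <- filter_events(ev, min_reads_ir = cfg$ir_min_reads)
  ds <- diff_splice(ev, n_mc = cfg$n_mc, p_min = cfg$p_min,
                    dpsi_min = cfg$dpsi_min, seed = stage_seed(cfg, 7L))
  emit(ds, "splice_results.tsv")
  emit(summarize_calls(ds), "splice_summary.tsv")

  # stage 6: length-dependent expression bias
  egenes <- make_genes(cfg$n_expr_genes, log(3e4), 1.3, c(2e3, 2e6),
                       seed = stage_seed(cfg, 8L))
  expr <- simulate_expression(egenes, seed = stage_seed(cfg, 9L))
  emit(expr, "expression.tsv")
  curve <- length_sliding_window(expr, cfg$window)
  emit(curve, "length_bias.tsv")
  long <- egenes$gene_id[egenes$length >
                           quantile(egenes$length, 0.75)]
  ov <- overlap_fisher(expr$gene_id[expr$direction == "DOWN"], long,
                       egenes$gene_id)
  emit(list(table = as.list(as.data.frame(ov$table)),
            odds_ratio = ov$odds_ratio, p_value = ov$p_value),
       "length_overlap.json")

  manifest <- list(package = "polwave",
                   version = as.character(utils::packageVersion("polwave")),
                   config = cfg,
                   stage_seeds = setNames(
                     lapply(1:9, function(k) stage_seed(cfg, k)),
                     paste0("stage", 1:9)),
                   outputs = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' @param run_dir Directory written by [run_all()].
#' @return A list of class `polwave_report` with one summary per stage:
#'   genes, coverage, rates, qPCR, splicing, length bias.
#' @export
report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("not a completed run directory (no manifest.json): ", run_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  needed <- c("genes.gtf", "bins.tsv", "rates.tsv", "rate_comparison.json",
              "qpcr_rates.tsv", "splice_summary.tsv", "length_bias.tsv")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing))
    stop("incomplete run directory; missing: ",
         paste(missing, collapse = ", "))
  genes <- read_genes(file.path(run_dir, "genes.gtf"))
  bins <- read_tsv_table(file.path(run_dir, "bins.tsv"))
  rates <- read_tsv_table(file.path(run_dir, "rates.tsv"))
  cmp <- jsonlite::read_json(file.path(run_dir, "rate_comparison.json"),
                             simplifyVector = TRUE)
  qpcr <- read_tsv_table(file.path(run_dir, "qpcr_rates.tsv"))
  splice <- read_tsv_table(file.path(run_dir, "splice_summary.tsv"))
  curve <- read_tsv_table(file.path(run_dir, "length_bias.tsv"))
  structure(list(
    genes = list(n = nrow(genes), median_length = median(genes$length)),
    coverage = list(n_profiles = length(unique(
      paste(bins$gene_id, bins$genotype, bins$time))),
      times = sort(unique(bins$time))),
    rates = list(per_genotype = aggregate(rate ~ genotype, rates,
                                          function(r) c(n = length(r),
                                                        mean = mean(r),
                                                        median = median(r))),
                 comparison = cmp),
    qpcr = qpcr,
    splicing = splice,
    length_bias = list(n_windows = nrow(curve),
                       short_end = curve$fraction_down[1],
                       long_end = curve$fraction_down[nrow(curve)]),
    manifest = manifest), class = "polwave_report")
}

#' @export
print.polwave_report <- function(x, ...) {
  cat("polwave run report\n")
  cat(sprintf("  genes: %d (median length %.0f bp)\n", x$genes$n,
              x$genes$median_length))
  cat(sprintf("  coverage: %d profiles at times %s min\n",
              x$coverage$n_profiles,
              paste(x$coverage$times, collapse = "/")))
  cat(sprintf("  rates: Mann-Whitney p = %.3g (means %s)\n",
              x$rates$comparison$p_value,
              paste(sprintf("%s=%.0f", names(x$rates$comparison$mean),
                            unlist(x$rates$comparison$mean)),
                    collapse = ", ")))
  cat("  qPCR rates (kb/min):\n")
  print(x$qpcr, row.names = FALSE)
  cat("  splicing calls:\n")
  print(x$splicing, row.names = FALSE)
  cat(sprintf("  length bias: %d windows, down-fraction %.2f (short) -> %.2f (long)\n",
              x$length_bias$n_windows, x$length_bias$short_end,
              x$length_bias$long_end))
  invisible(x)
}
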