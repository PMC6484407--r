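#' Per-gene elongation-rate presets
#'
#' A rate preset describes the distribution from which per-gene elongation
#' rates (bases/min) are drawn in synthetic data. Three laws are supported:
#' `constant` (every gene at `mean_rate`), `lognormal` (mean `mean_rate`,
#' log-scale sd `sdlog`), and `lognormal-mixture` (components with given
#' weights and relative medians, rescaled so the mixture mean equals
#' `mean_rate` exactly).
#'
#' The stock presets mirror the genotypes of the DRB-release experiment:
#' \describe{
#'   \item{`preset_wt_rate()`}{bimodal wild-type rates, overall mean 2,450
#'     bases/min (two lognormal components, weights 0.5/0.5, relative
#'     medians 1,500 and 3,400, sdlog 0.3 each).}
#'   \item{`preset_slow_rate()`}{mutant rates, lognormal, mean 1,780
#'     bases/min, sdlog 0.25 (narrower than wild type).}
#'   \item{`preset_wt_front()`, `preset_slow_front()`}{constant 2,200 and
#'     1,780 bases/min; with these the noise-free wave-front sits at 11 kb
#'     at 5 min and 26.7 kb at 15 min respectively.}
#' }
#'
#' @param name Label stored with the preset.
#' @param rate_law One of `"constant"`, `"lognormal"`,
#'   `"lognormal-mixture"`.
#' @param mean_rate Mean elongation rate in bases/min (strictly positive).
#' @param sdlog Log-scale standard deviation(s); scalar for `lognormal`,
#'   one per component for the mixture.
#' @param weights Mixture weights (must sum to 1).
#' @param medians Relative component medians for the mixture; they are
#'   rescaled by a common factor so the mixture mean equals `mean_rate`.
#' @return An object of class `rate_preset`.
#' @examples
#' p <- preset_wt_rate()
#' r <- draw_rates(p, 5, seed = 1)
#' @export
rate_preset <- function(name, rate_law = c("constant", "lognormal",
                                           "lognormal-mixture"),
                        mean_rate, sdlog = 0, weights = NULL,
                        medians = NULL) {
  rate_law <- match.arg(rate_law)
  stopifnot(is.numeric(mean_rate), length(mean_rate) == 1L, mean_rate > 0)
  if (rate_law == "lognormal-mixture") {
    stopifnot(!is.null(weights), !is.null(medians),
              length(weights) == length(medians),
              all(weights > 0), all(medians > 0),
              length(sdlog) %in% c(1L, length(weights)))
    if (abs(sum(weights) - 1) > 1e-8)
      stop("mixture weights must sum to 1")
    sdlog <- rep(sdlog, length.out = length(weights))
    # scale relative medians so the mixture mean is exactly mean_rate
    comp_mean_rel <- medians * exp(sdlog^2 / 2)
    scale <- mean_rate / sum(weights * comp_mean_rel)
    medians <- medians * scale
  } else {
    stopifnot(length(sdlog) == 1L, sdlog >= 0)
  }
  structure(list(name = name, rate_law = rate_law, mean_rate = mean_rate,
                 sdlog = sdlog, weights = weights, medians = medians),
            class = "rate_preset")
}

#' @rdname rate_preset
#' @export
preset_wt_rate <- function() {
  rate_preset("wt_rate", "lognormal-mixture", mean_rate = 2450,
              sdlog = c(0.3, 0.3), weights = c(0.5, 0.5),
              medians = c(1500, 3400))
}

#' @rdname rate_preset
#' @export
preset_slow_rate <- function() {
  rate_preset("slow_rate", "lognormal", mean_rate = 1780, sdlog = 0.25)
}

#' @rdname rate_preset
#' @export
preset_wt_front <- function() {
  rate_preset("wt_front", "constant", mean_rate = 2200)
}

#' @rdname rate_preset
#' @export
preset_slow_front <- function() {
  rate_preset("slow_front", "constant", mean_rate = 1780)
}

#' Draw per-gene elongation rates from a preset
#'
#' @param preset A [rate_preset()].
#' @param n Number of genes.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of `n` strictly positive rates in bases/min.
#' @export
draw_rates <- function(preset, n, seed = NULL) {
  stopifnot(inherits(preset, "rate_preset"), n >= 1)
  with_seed(seed, {
    switch(preset$rate_law,
      constant = rep(preset$mean_rate, n),
      lognormal = rlnorm(n, meanlog = log(preset$mean_rate) -
                              preset$sdlog^2 / 2, sdlog = preset$sdlog),
      `lognormal-mixture` = {
        comp <- sample.int(length(preset$weights), n, replace = TRUE,
                           prob = preset$weights)
        rlnorm(n, meanlog = log(preset$medians[comp]),
               sdlog = preset$sdlog[comp])
      })
  })
}

#' DRB-release labeling design
#'
#' Harvest times after DRB washout and the length of the metabolic labeling
#' pulse applied before each harvest. The reference design releases at
#' t = 0 and harvests at 0, 5, and 15 min with a 10-min 4sU pulse ending at
#' each harvest. `depth` is the expected sequencing signal per labeled
#' kilobase at full polymerase occupancy.
#'
#' @param harvest_times Minutes after release; non-negative, strictly
#'   increasing.
#' @param pulse_length Pulse duration in minutes (> 0).
#' @param depth Expected reads per labeled kilobase.
#' @return An object of class `pulse_design`.
#' @export
pulse_design <- function(harvest_times = c(0, 5, 15), pulse_length = 10,
                         depth = 50) {
  stopifnot(is.numeric(harvest_times), length(harvest_times) >= 1,
            all(harvest_times >= 0),
            all(diff(harvest_times) > 0),
            is.numeric(pulse_length), pulse_length > 0,
            is.numeric(depth), depth > 0)
  structure(list(harvest_times = harvest_times,
                 pulse_length = pulse_length, depth = depth),
            class = "pulse_design")
}

#' Gene-length-dependent downregulation preset
#'
#' Probability that a gene is downregulated as a monotone non-decreasing
#' function of gene length, parameterized by two anchors: the probability at
#' 10 kb and the asymptotic probability for very long genes. Below 10 kb the
#' curve decays as a power of length (exponent `delta`); above 10 kb it
#' saturates toward `p_long` as a power of 10 kb / length (exponent
#' `gamma`). The neuron preset anchors 0.40 at 10 kb rising to 0.80.
#'
#' @param p_at_10kb Downregulation probability at a gene length of 10 kb.
#' @param p_long Asymptotic probability for very long genes
#'   (`>= p_at_10kb`).
#' @param gamma,delta Shape exponents above / below 10 kb.
#' @return An object of class `length_effect_preset` whose `$p_down` element
#'   is a vectorized function of gene length in bp.
#' @examples
#' eff <- preset_neuron_length_effect()
#' eff$p_down(c(1e4, 1e6))
#' @export
length_effect_preset <- function(p_at_10kb, p_long, gamma = 0.5,
                                 delta = 0.3) {
  stopifnot(p_at_10kb >= 0, p_at_10kb <= 1, p_long >= p_at_10kb,
            p_long <= 1, gamma > 0, delta >= 0)
  anchor <- 1e4
  p_down <- function(length) {
    stopifnot(all(length > 0))
    ifelse(length <= anchor,
           p_at_10kb * (length / anchor)^delta,
           p_long - (p_long - p_at_10kb) * (anchor / length)^gamma)
  }
  structure(list(p_at_10kb = p_at_10kb, p_long = p_long, gamma = gamma,
                 delta = delta, p_down = p_down),
            class = "length_effect_preset")
}

#' @rdname length_effect_preset
#' @export
preset_neuron_length_effect <- function() {
  length_effect_preset(p_at_10kb = 0.40, p_long = 0.80)
}
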