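# Kinetic-coupling characterizations: length statistics of rate-sensitive
# exons, dPSI-versus-expression regression, gene-length sliding-window
# downregulation, and gene-set overlap tests.

#' Mann-Whitney comparison with tie correction
#'
#' Two-sided test using the normal approximation with tie correction (no
#' continuity correction, so identical groups give p = 1 exactly).
#' All-tied inputs give p = 1 with a warning.
#'
#' @param x,y Numeric samples.
#' @return A list: `U` (statistic for `x`), `p_value`, `n` (c(nx, ny)).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; p set to 1")
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = FALSE)$p.value)
  }
  list(U = U, p_value = p, n = c(length(x), length(y)))
}

#' Exon / intron length statistics of event groups
#'
#' For each feature (alternative-exon length, upstream and downstream
#' intron length), compares each event group against the background group
#' with a two-sided Mann-Whitney test and reports medians and quartiles.
#'
#' @param events Data.frame with columns `group` plus one column per
#'   feature in `features`.
#' @param background Name of the background group (default
#'   `"unchanged"`).
#' @param features Feature columns to compare.
#' @return A data.frame, one row per group x feature, with `n`, `median`,
#'   `q1`, `q3`, `background_median`, `U`, `p_value`.
#' @export
length_stats <- function(events,
                         background = "unchanged",
                         features = c("exon_length",
                                      "upstream_intron_length",
                                      "downstream_intron_length")) {
  stopifnot("group" %in% names(events),
            all(features %in% names(events)),
            background %in% events$group)
  groups <- setdiff(unique(events$group), background)
  bg <- events[events$group == background, , drop = FALSE]
  rows <- list()
  for (g in groups) {
    sub <- events[events$group == g, , drop = FALSE]
    if (nrow(sub) < 3 || nrow(bg) < 3)
      stop("need >= 3 events per group (group '", g, "')")
    for (f in features) {
      mw <- mann_whitney(sub[[f]], bg[[f]])
      rows[[paste(g, f)]] <- data.frame(
        group = g, feature = f, n = nrow(sub),
        median = median(sub[[f]]),
        q1 = unname(quantile(sub[[f]], 0.25)),
        q3 = unname(quantile(sub[[f]], 0.75)),
        background_median = median(bg[[f]]),
        U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of splicing change on expression change
#'
#' Least-squares fit of dPSI on log2 fold change, per event class, to ask
#' whether differential splicing is driven by differential expression.
#'
#' @param splice A `diff_splice` data.frame with a `gene_id` column (join
#'   key) in addition to `dpsi` and `call`.
#' @param expression Expression records with `gene_id`, `log2fc`, `sig`.
#' @param min_n Classes with fewer points are skipped (default 3).
#' @return A data.frame, one row per class (`changed_DE`, `changed_AS`,
#'   `both`), with `n`, `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
dpsi_expression_correlation <- function(splice, expression, min_n = 3) {
  stopifnot(all(c("gene_id", "dpsi", "call") %in% names(splice)),
            all(c("gene_id", "log2fc", "sig") %in% names(expression)))
  m <- merge(splice, expression, by = "gene_id")
  m <- m[!is.na(m$dpsi) & !is.na(m$log2fc), , drop = FALSE]
  changed_as <- m$call %in% c("UP", "DOWN")
  changed_de <- m$sig
  classes <- list(changed_DE = changed_de & !changed_as,
                  changed_AS = changed_as & !changed_de,
                  both = changed_as & changed_de)
  rows <- list()
  for (cl in names(classes)) {
    sub <- m[classes[[cl]], , drop = FALSE]
    if (nrow(sub) < min_n) next
    fit <- lm(dpsi ~ log2fc, data = sub)
    sm <- summary(fit)
    r2 <- if (stats::var(sub$dpsi) == 0) 0 else sm$r.squared
    rows[[cl]] <- data.frame(
      class = cl, n = nrow(sub),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2,
      p_value = if (nrow(sub) > 2 && sm$r.squared < 1)
        unname(sm$coefficients[2, 4]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = character(), n = integer(),
                      slope = numeric(), intercept = numeric(),
                      r_squared = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sliding-window downregulation fraction by gene length
#'
#' Genes are sorted by length; for every contiguous window of `window`
#' genes the median gene length and the fraction called DOWN are recorded.
#' The curve has `N - window + 1` points for `N` genes.
#'
#' @param expression Expression records with `length` and `direction`
#'   columns (see [simulate_expression()]).
#' @param window Window size in genes (default 100).
#' @return A `length_bias` data.frame: `window_index`, `median_length`,
#'   `fraction_down`.
#' @export
length_sliding_window <- function(expression, window = 100) {
  stopifnot(all(c("length", "direction") %in% names(expression)),
            window >= 1)
  n <- nrow(expression)
  if (n < window)
    stop("need at least ", window, " genes (got ", n, ")")
  ord <- order(expression$length)
  len <- expression$length[ord]
  down <- as.numeric(expression$direction[ord] == "DOWN")
  cs <- c(0, cumsum(down))
  i <- seq_len(n - window + 1L)
  frac <- (cs[i + window] - cs[i]) / window
  # lengths are sorted, so the window median is the middle order statistic
  med <- if (window %% 2 == 0)
    (len[i + window / 2 - 1] + len[i + window / 2]) / 2
  else len[i + (window - 1) / 2]
  data.frame(window_index = i, median_length = med, fraction_down = frac)
}

#' Gene-set overlap by Fisher's exact test
#'
#' Builds the 2x2 table of query x annotation membership over the universe
#' and reports the sample odds ratio (cross-product) together with the
#' exact two-sided p-value.
#'
#' @param query,annotation Character vectors of gene ids (subsets of
#'   `universe`).
#' @param universe Character vector of all eligible gene ids (non-empty).
#' @return A list: `table` (2x2 matrix), `odds_ratio` (cross-product;
#'   `Inf` with a flag when a margin cell is 0), `degenerate`, `p_value`.
#' @export
overlap_fisher <- function(query, annotation, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query); annotation <- unique(annotation)
  if (!all(query %in% universe) || !all(annotation %in% universe))
    stop("query and annotation must be subsets of the universe")
  inq <- universe %in% query
  ina <- universe %in% annotation
  tab <- matrix(c(sum(inq & ina), sum(inq & !ina),
                  sum(!inq & ina), sum(!inq & !ina)),
                nrow = 2, byrow = TRUE,
                dimnames = list(query = c("in", "out"),
                                annotation = c("in", "out")))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- (b == 0 && c_ == 0) || (a == 0 && d == 0)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c_)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, degenerate = degenerate, p_value = p)
}
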