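# Motif RNA maps: positional motif-coverage profiles around regulated
# versus unchanged exons, with pointwise one-sided permutation p-values.

# Align one region of every event into a fixed-width character matrix.
# Upstream introns are right-aligned (positions end at the exon), exons and
# downstream introns are left-aligned; sequences shorter than the extent
# are NA-padded on the far side.
region_matrix <- function(seqs, extent, align = c("left", "right")) {
  align <- match.arg(align)
  mat <- matrix(NA_character_, nrow = length(seqs), ncol = extent)
  for (i in seq_along(seqs)) {
    s <- toupper(chartr("U", "T", seqs[i]))
    n <- nchar(s)
    if (align == "right") {
      take <- min(n, extent)
      chars <- strsplit(substr(s, n - take + 1, n), "")[[1]]
      mat[i, (extent - take + 1):extent] <- chars
    } else {
      take <- min(n, extent)
      mat[i, seq_len(take)] <- strsplit(substr(s, 1, take), "")[[1]]
    }
  }
  mat
}

# Positions covered by any match of an IUPAC motif, per sequence row of an
# aligned character matrix. Matching is on the given strand only.
motif_cover_matrix <- function(mat, motif) {
  nc <- ncol(mat)
  cover <- matrix(0, nrow = nrow(mat), ncol = nc)
  width <- nchar(motif)
  if (width > nc) stop("motif longer than region")
  for (i in seq_len(nrow(mat))) {
    known <- !is.na(mat[i, ])
    if (!any(known)) next
    idx <- which(known)
    s <- paste(mat[i, idx], collapse = "")
    hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(s),
                                     fixed = FALSE)
    if (length(hits)) {
      for (j in seq_along(hits)) {
        span <- idx[IRanges::start(hits)[j]:IRanges::end(hits)[j]]
        cover[i, span] <- 1
      }
    }
    cover[i, !known] <- NA
  }
  cover
}

running_mean <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    mean(x[w], na.rm = TRUE)
  }, numeric(1))
}

#' Motif RNA map with permutation significance
#'
#' For each position of a fixed analysis geometry (upstream intron flank,
#' exon, downstream intron flank) computes the fraction of events whose
#' IUPAC motif match covers the position, per event group, smoothed by a
#' centered running mean. Pointwise one-sided p-values (enrichment of each
#' regulated group over the control group) come from permuting event-group
#' labels; positions with p below `sig_level` form the significance mask
#' (drawn bold in the field's conventional display).
#'
#' @param events Data.frame with columns `group` (e.g. `included`,
#'   `skipped`, `unchanged`) and sequence columns `upstream_intron`,
#'   `exon`, `downstream_intron` (RNA or DNA alphabet).
#' @param motif IUPAC motif string (e.g. `"YCAY"`, `"TGCATG"`).
#' @param window Smoothing width in nt (default 31).
#' @param n_perm Number of label permutations (>= 100; default 1000).
#' @param flank Intron flank extent in nt (default 200).
#' @param exon_extent Fixed exon extent in nt; exons are truncated or
#'   NA-padded to it (default 50).
#' @param control Name of the control group (default `"unchanged"`).
#' @param sig_level Pointwise significance mask level (default 0.1).
#' @param seed Optional integer seed.
#' @return An object of class `rna_map`: `positions` (data.frame with
#'   `region` and within-region position), `coverage` (matrix positions x
#'   groups of smoothed coverage fractions), `p_values` (matrix positions x
#'   regulated groups), `sig_mask`, plus the call parameters.
#' @export
rna_map <- function(events, motif, window = 31, n_perm = 1000,
                    flank = 200, exon_extent = 50, control = "unchanged",
                    sig_level = 0.1, seed = NULL) {
  stopifnot(all(c("group", "upstream_intron", "exon",
                  "downstream_intron") %in% names(events)))
  if (!nzchar(motif)) stop("empty motif")
  if (n_perm < 100) stop("'n_perm' must be >= 100")
  if (!control %in% events$group)
    stop("control group '", control, "' not present")
  groups <- unique(events$group)
  reg_groups <- setdiff(groups, control)
  if (any(table(events$group) < 2))
    stop("each group needs >= 2 events")
  cover <- cbind(
    motif_cover_matrix(region_matrix(events$upstream_intron, flank,
                                     "right"), motif),
    motif_cover_matrix(region_matrix(events$exon, exon_extent, "left"),
                       motif),
    motif_cover_matrix(region_matrix(events$downstream_intron, flank,
                                     "left"), motif))
  npos <- ncol(cover)
  positions <- data.frame(
    region = rep(c("upstream_intron", "exon", "downstream_intron"),
                 c(flank, exon_extent, flank)),
    position = c(-(flank:1), seq_len(exon_extent), seq_len(flank)))
  smooth_rows <- function(m) {
    frac <- colMeans(m, na.rm = TRUE)
    frac[is.nan(frac)] <- NA
    running_mean(frac, window)
  }
  grp <- as.character(events$group)
  coverage <- vapply(groups, function(g)
    smooth_rows(cover[grp == g, , drop = FALSE]), numeric(npos))
  with_seed(seed, {
    pvals <- vapply(reg_groups, function(g) {
      sel <- grp %in% c(g, control)
      sub <- cover[sel, , drop = FALSE]
      lab <- grp[sel] == g
      obs <- smooth_rows(sub[lab, , drop = FALSE]) -
        smooth_rows(sub[!lab, , drop = FALSE])
      exceed <- numeric(npos)
      for (p in seq_len(n_perm)) {
        pl <- sample(lab)
        d <- smooth_rows(sub[pl, , drop = FALSE]) -
          smooth_rows(sub[!pl, , drop = FALSE])
        exceed <- exceed + as.numeric(!is.na(d) & !is.na(obs) & d >= obs)
      }
      p <- (1 + exceed) / (n_perm + 1)
      p[is.na(obs)] <- NA_real_
      p
    }, numeric(npos))
    structure(list(positions = positions, coverage = coverage,
                   p_values = pvals, sig_mask = pvals < sig_level,
                   motif = motif, window = window, n_perm = n_perm,
                   flank = flank, exon_extent = exon_extent,
                   control = control, sig_level = sig_level),
              class = "rna_map")
  })
}

#' @export
print.rna_map <- function(x, ...) {
  cat(sprintf("rna_map: motif %s, %d positions, groups: %s\n", x$motif,
              nrow(x$positions), paste(colnames(x$coverage),
                                       collapse = ", ")))
  nsig <- colSums(x$sig_mask)
  for (g in colnames(x$p_values))
    cat(sprintf("  %s vs %s: %d positions with p < %g\n", g, x$control,
                nsig[[g]], x$sig_level))
  invisible(x)
}
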