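# Gene annotation and coverage IO. Internal coordinates are 0-based,
# half-open; GTF is written/read as 1-based closed and BED/bedGraph as
# 0-based half-open, via rtracklayer.

#' Construct a table of gene models
#'
#' @param gene_id,chrom,strand Character vectors.
#' @param start,end 0-based half-open coordinates (start < end).
#' @return A `gene_models` data.frame with derived `length` and `tss`
#'   columns (TSS = `start` on `+`, `end - 1` on `-`).
#' @export
new_gene_models <- function(gene_id, chrom, strand, start, end) {
  stopifnot(length(gene_id) == length(chrom),
            length(chrom) == length(strand),
            length(strand) == length(start),
            length(start) == length(end),
            all(strand %in% c("+", "-")))
  if (any(end <= start)) stop("zero-length feature: start must be < end")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  class(df) <- c("gene_models", "data.frame")
  df
}

empty_gene_models <- function() {
  new_gene_models(character(), character(), character(),
                  numeric(), numeric() + 1)[0, ]
}

#' Read gene models from GTF or BED
#'
#' The dialect is auto-detected from the file extension (`.gtf`/`.gff` vs
#' `.bed`). GTF coordinates (1-based, closed) and BED coordinates (0-based,
#' half-open) are both normalized to the internal 0-based half-open
#' convention. For GTF, rows with `type == "gene"` are used when present.
#'
#' @param path Annotation file.
#' @return A `gene_models` data.frame (see [new_gene_models()]).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    warning("empty annotation file: ", path)
    return(empty_gene_models())
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("malformed GTF '", path, "': ",
                                            conditionMessage(e)))
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) gr$gene_id
           else as.character(seq_along(gr))
  } else if (ext == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("malformed BED '", path, "': ",
                                            conditionMessage(e)))
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name
           else as.character(seq_along(gr))
  } else {
    stop("unrecognized annotation extension: ", ext)
  }
  new_gene_models(gene_id = ids,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  strand = as.character(GenomicRanges::strand(gr)),
                  start = GenomicRanges::start(gr) - 1,
                  end = GenomicRanges::end(gr))
}

#' Write gene models to GTF or BED
#'
#' Format chosen by extension. GTF rows carry `type = "gene"` and the
#' `gene_id` attribute; BED uses the 6-column dialect with `gene_id` as the
#' name.
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path ending in `.gtf` or `.bed`.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gtf") {
    gr$source <- "polwave"
    gr$type <- "gene"
    gr$gene_id <- genes$gene_id
    rtracklayer::export(gr, path, format = "gtf")
  } else if (ext == "bed") {
    gr$name <- genes$gene_id
    gr$score <- 0
    rtracklayer::export(gr, path, format = "bed")
  } else {
    stop("unrecognized annotation extension: ", ext)
  }
  invisible(path)
}

#' Read / write bedGraph coverage
#'
#' bedGraph intervals are 0-based half-open; `read_bedgraph()` returns them
#' in that convention as a data.frame.
#'
#' @param path bedGraph file.
#' @param coverage Data.frame with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open).
#' @return `read_bedgraph()`: a coverage data.frame; `write_bedgraph()`:
#'   `path` invisibly.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(coverage, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(coverage)))
  gr <- GenomicRanges::GRanges(
    coverage$chrom,
    IRanges::IRanges(start = coverage$start + 1, end = coverage$end),
    score = coverage$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Per-gene binned nascent coverage
#'
#' A TSS-relative binned profile: bin 1 is anchored at the TSS and bins
#' increase in the direction of transcription, regardless of strand.
#'
#' @param gene_id Gene label.
#' @param counts Non-negative bin signal, length `ceiling(gene_length /
#'   bin_size)`.
#' @param bin_size Bin width in bp.
#' @param gene_length Gene length in bp.
#' @param time Harvest time in minutes (or `NA`).
#' @param genotype Sample label (or `NA`).
#' @param library_size Total mapped reads, for normalization (or `NA`).
#' @return An object of class `binned_coverage`.
#' @export
binned_coverage <- function(gene_id, counts, bin_size, gene_length,
                            time = NA_real_, genotype = NA_character_,
                            library_size = NA_real_) {
  stopifnot(is.numeric(counts), all(counts >= 0), bin_size > 0,
            gene_length >= bin_size || length(counts) == 1L)
  if (length(counts) != ceiling(gene_length / bin_size))
    stop("counts length must equal ceiling(gene_length / bin_size)")
  structure(list(gene_id = gene_id, counts = as.numeric(counts),
                 bin_size = bin_size, gene_length = gene_length,
                 time = time, genotype = genotype,
                 library_size = library_size),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("binned_coverage: %s, %d bins x %g bp, t = %s min, total = %g\n",
              x$gene_id, length(x$counts), x$bin_size,
              format(x$time), sum(x$counts)))
  invisible(x)
}

#' Bin genome coverage into a TSS-relative per-gene profile
#'
#' Coverage intervals overlapping the gene are accumulated into fixed-width
#' bins anchored at the TSS and ordered in the direction of transcription
#' (for `-` strand genes bin 1 sits at the gene end, so reverse-strand
#' profiles read TSS-outward like forward-strand ones). An interval
#' partially overlapping a bin contributes in proportion to the overlap
#' length; overlapping input intervals are summed. A partial final bin (far
#' from the TSS) is allowed.
#'
#' @param coverage A coverage data.frame (`chrom`, `start`, `end`, `value`;
#'   0-based half-open) as returned by [read_bedgraph()].
#' @param gene A single-row `gene_models` data.frame (or a list with the
#'   same fields).
#' @param bin_size Bin width in bp.
#' @param time,genotype,library_size Metadata stored on the result.
#' @return A [binned_coverage()] object.
#' @export
bin_coverage <- function(coverage, gene, bin_size = 500, time = NA_real_,
                         genotype = NA_character_,
                         library_size = NA_real_) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(coverage)))
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L)
    gene <- as.list(gene)
  }
  len <- gene$end - gene$start
  if (len < bin_size) stop("gene shorter than one bin: ", gene$gene_id)
  nb <- ceiling(len / bin_size)
  vals <- numeric(nb)
  cov <- coverage[coverage$chrom == gene$chrom &
                    coverage$end > gene$start &
                    coverage$start < gene$end, , drop = FALSE]
  if (!any(coverage$chrom == gene$chrom))
    warning("chromosome ", gene$chrom, " absent from coverage; ",
            "returning an empty profile for ", gene$gene_id)
  if (nrow(cov)) {
    s <- pmax(cov$start, gene$start)
    e <- pmin(cov$end, gene$end)
    # TSS-relative half-open positions in transcription direction
    if (gene$strand == "+") {
      p1 <- s - gene$start; p2 <- e - gene$start
    } else {
      p1 <- gene$end - e; p2 <- gene$end - s
    }
    for (i in seq_len(nrow(cov))) {
      b1 <- floor(p1[i] / bin_size) + 1
      b2 <- ceiling(p2[i] / bin_size)
      for (b in b1:b2) {
        ov <- min(p2[i], b * bin_size) - max(p1[i], (b - 1) * bin_size)
        if (ov > 0) vals[b] <- vals[b] + cov$value[i] * ov
      }
    }
  }
  binned_coverage(gene_id = gene$gene_id, counts = vals,
                  bin_size = bin_size, gene_length = len, time = time,
                  genotype = genotype, library_size = library_size)
}

#' Counts-per-million normalization of a binned profile
#'
#' @param profile A [binned_coverage()] object with a `library_size`.
#' @param library_size Optional override of the stored library size.
#' @return The profile with counts scaled to counts per million mapped
#'   reads.
#' @export
normalize_cpm <- function(profile, library_size = NULL) {
  stopifnot(inherits(profile, "binned_coverage"))
  ls <- library_size %||% profile$library_size
  if (is.na(ls) || ls <= 0) stop("a positive library_size is required")
  profile$counts <- profile$counts * 1e6 / ls
  profile$library_size <- ls
  profile
}

#' Convert wave-simulation profiles to / from a long table
#'
#' The long format (one row per gene x time x bin) is the TSV interchange
#' used by the command-line pipeline.
#'
#' @param profiles A list of [binned_coverage()] objects.
#' @param bins A long data.frame as produced by `profiles_to_table()`.
#' @return `profiles_to_table()`: a data.frame with columns `gene_id`,
#'   `genotype`, `time`, `bin`, `bin_size`, `gene_length`, `count`;
#'   `table_to_profiles()`: a list of [binned_coverage()] objects.
#' @export
profiles_to_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(gene_id = p$gene_id, genotype = p$genotype, time = p$time,
               bin = seq_along(p$counts), bin_size = p$bin_size,
               gene_length = p$gene_length, count = p$counts,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname profiles_to_table
#' @export
table_to_profiles <- function(bins) {
  needed <- c("gene_id", "time", "bin", "bin_size", "gene_length", "count")
  stopifnot(all(needed %in% names(bins)))
  if (!"genotype" %in% names(bins)) bins$genotype <- NA_character_
  key <- interaction(bins$gene_id, bins$genotype, bins$time, drop = TRUE)
  lapply(split(bins, key), function(d) {
    d <- d[order(d$bin), ]
    binned_coverage(gene_id = d$gene_id[1], counts = d$count,
                    bin_size = d$bin_size[1], gene_length = d$gene_length[1],
                    time = d$time[1], genotype = d$genotype[1])
  })
}
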