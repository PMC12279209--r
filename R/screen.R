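# Promoter-window chromatin-accessibility screen: per-gene summation of
# ATAC peak abundance within +/-3 kb of the TSS and ratio-threshold
# classification into Group I (MI-opened) / Group II (MI-closed) genes.

#' Screen configuration
#'
#' Thresholds of the ratio screen: a gene is Group I when
#' `sum(MI)/sum(Sham) > 1.2` or `sum(MI)/sum(Patch) > 1.1`, Group II when
#' `sum(MI)/sum(Sham) < 0.8` or `sum(MI)/sum(Patch) < 0.9` (inclusive "or");
#' genes satisfying both rule sets are labeled `conflict`, genes with a zero
#' denominator are handled per `zero_policy`.
#'
#' @param window_kb promoter half-window around the TSS, kb (default 3)
#' @param up_sham,up_patch Group I thresholds (must be > 1)
#' @param down_sham,down_patch Group II thresholds (must be < 1)
#' @param zero_policy `"exclude"` (default) labels genes with zero Sham or
#'   Patch sum as `excluded`; `"classify"` treats the ratio as `Inf` (or 0/0
#'   as 1) and classifies normally
#' @return a `screen_config`
#' @export
screen_config <- function(window_kb = 3, up_sham = 1.2, up_patch = 1.1,
                          down_sham = 0.8, down_patch = 0.9,
                          zero_policy = c("exclude", "classify")) {
  stopifnot_scalar(window_kb, "window_kb", positive = TRUE)
  if (up_sham <= 1 || up_patch <= 1)
    stop("up-regulation thresholds must be > 1", call. = FALSE)
  if (down_sham >= 1 || down_patch >= 1)
    stop("down-regulation thresholds must be < 1", call. = FALSE)
  structure(list(window_kb = window_kb, up_sham = up_sham,
                 up_patch = up_patch, down_sham = down_sham,
                 down_patch = down_patch,
                 zero_policy = match.arg(zero_policy)),
            class = "screen_config")
}

check_peaks_df <- function(peaks, what) {
  need <- c("chrom", "start", "end", "abundance")
  if (!all(need %in% names(peaks)))
    stop(sprintf("%s must have columns: %s", what,
                 paste(need, collapse = ", ")), call. = FALSE)
  bad <- which(!(peaks$start < peaks$end) | peaks$abundance < 0 |
                 !is.finite(peaks$start) | !is.finite(peaks$end))
  if (length(bad))
    stop(sprintf("%s: malformed interval(s) at line(s) %s", what,
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  peaks
}

#' Per-gene promoter-window peak sums
#'
#' For each gene, sums the abundance of all peaks overlapping the closed
#' promoter window `[tss - w, tss + w]` (any overlap counts, full peak
#' abundance, no pro-rating; `w = window_kb * 1000`). The window is
#' symmetric, so strand does not change it. Coordinates are 1-based
#' inclusive.
#'
#' @param peaks named list of per-condition peak data.frames (columns
#'   `chrom`, `start`, `end`, `abundance`), e.g.
#'   `list(sham = ..., mi = ..., patch = ...)`
#' @param tss data.frame with columns `gene_id`, `chrom`, `tss`, `strand`
#' @param cfg a [screen_config()]
#' @return data.frame: `gene_id` plus one `sum_<condition>` column per
#'   condition
#' @export
promoter_window_sum <- function(peaks, tss, cfg = screen_config()) {
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  if (!all(c("gene_id", "chrom", "tss") %in% names(tss)))
    stop("'tss' must have columns gene_id, chrom, tss", call. = FALSE)
  if (anyDuplicated(tss$gene_id))
    stop("duplicate gene_id in TSS table", call. = FALSE)
  if (any(tss$tss < 1)) stop("tss coordinates must be >= 1", call. = FALSE)
  w <- cfg$window_kb * 1000
  win <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(1, tss$tss - w),
                              end = tss$tss + w))
  out <- data.frame(gene_id = tss$gene_id)
  for (cond in names(peaks)) {
    pk <- check_peaks_df(peaks[[cond]], sprintf("peaks[['%s']]", cond))
    gr <- GenomicRanges::GRanges(
      seqnames = pk$chrom,
      ranges = IRanges::IRanges(start = pk$start, end = pk$end))
    # disjoint chromosome sets between window and peak tables are normal
    hits <- suppressWarnings(GenomicRanges::findOverlaps(win, gr))
    sums <- rep(0, nrow(tss))
    if (length(hits)) {
      agg <- tapply(pk$abundance[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
      sums[as.integer(names(agg))] <- as.numeric(agg)
    }
    out[[paste0("sum_", cond)]] <- sums
  }
  out
}

#' Classify genes into Group I / Group II by promoter-accessibility ratios
#'
#' Applies the ratio thresholds of the screen to per-gene condition sums.
#' Group I: `mi/sham > up_sham` or `mi/patch > up_patch` (promoter opened by
#' MI, closed again by the patch); Group II: `mi/sham < down_sham` or
#' `mi/patch < down_patch`. Genes firing both rule sets are `conflict`;
#' zero denominators give `excluded` under the default policy; everything
#' else is `neither`.
#'
#' @param sums data.frame with columns `gene_id`, `sum_sham`, `sum_mi`,
#'   `sum_patch` (non-negative)
#' @param cfg a [screen_config()]
#' @return the input with `ratio_sham`, `ratio_patch` and a `label` factor
#'   (`group1`, `group2`, `neither`, `conflict`, `excluded`)
#' @export
#' @examples
#' classify_groups(data.frame(gene_id = "g", sum_sham = 100,
#'                            sum_mi = 130, sum_patch = 125))$label  # group1
classify_groups <- function(sums, cfg = screen_config()) {
  need <- c("gene_id", "sum_sham", "sum_mi", "sum_patch")
  if (!all(need %in% names(sums)))
    stop("'sums' must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  s <- sums$sum_sham; m <- sums$sum_mi; p <- sums$sum_patch
  if (any(c(s, m, p) < 0)) stop("negative sums", call. = FALSE)
  rs <- ifelse(s > 0, m / s, ifelse(m > 0, Inf, 1))
  rp <- ifelse(p > 0, m / p, ifelse(m > 0, Inf, 1))
  up <- (rs > cfg$up_sham) | (rp > cfg$up_patch)
  dn <- (rs < cfg$down_sham) | (rp < cfg$down_patch)
  lab <- ifelse(up & dn, "conflict",
                ifelse(up, "group1", ifelse(dn, "group2", "neither")))
  if (cfg$zero_policy == "exclude")
    lab[s == 0 | p == 0] <- "excluded"
  out <- sums
  out$ratio_sham <- rs
  out$ratio_patch <- rp
  out$label <- factor(lab, levels = c("group1", "group2", "neither",
                                      "conflict", "excluded"))
  out
}

#' Tabulate screen labels
#'
#' @param labels output of [classify_groups()] (or a factor of labels)
#' @return named integer vector of counts per label; counts sum to the
#'   number of genes
#' @export
screen_summary <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- factor(labels, levels = c("group1", "group2", "neither",
                                      "conflict", "excluded"))
  table(labels)
}

#' Run the full promoter screen from tables
#'
#' Convenience wrapper: window sums, classification and summary in one call;
#' optionally writes the per-gene TSV and a JSON summary.
#'
#' @inheritParams promoter_window_sum
#' @param out_tsv,out_json optional output paths
#' @return list with `genes` (per-gene table incl. labels) and `counts`
#' @export
run_screen <- function(peaks, tss, cfg = screen_config(), out_tsv = NULL,
                       out_json = NULL) {
  sums <- promoter_window_sum(peaks, tss, cfg)
  names(sums) <- sub("^sum_sham$", "sum_sham", names(sums))
  genes <- classify_groups(sums, cfg)
  counts <- screen_summary(genes)
  if (!is.null(out_tsv))
    write.table(genes, out_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(as.list(counts), out_json, auto_unbox = TRUE)
  list(genes = genes, counts = counts)
}

#' Read a BED-like peak TSV
#'
#' Tab-separated columns `chrom`, `start`, `end`, `abundance`, 1-based
#' inclusive coordinates; malformed rows are reported with line numbers.
#'
#' @param file path
#' @return data.frame of peaks
#' @export
read_peak_tsv <- function(file) {
  d <- read.delim(file)
  check_peaks_df(d, file)
}

#' Read a TSS TSV
#'
#' Tab-separated columns `gene_id`, `chrom`, `tss`, `strand`.
#'
#' @param file path
#' @return data.frame
#' @export
read_tss_tsv <- function(file) {
  d <- read.delim(file)
  if (!all(c("gene_id", "chrom", "tss") %in% names(d)))
    stop("TSS TSV must have columns gene_id, chrom, tss", call. = FALSE)
  d
}
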