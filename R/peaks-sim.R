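# Synthetic per-gene promoter peak-count tables with designed Group I/II
# effects, for exercising the ratio screen with known truth.

#' Ground truth for a synthetic peak-count table
#'
#' @param n_genes number of genes
#' @param frac_group1,frac_group2 fractions of genes with designed MI
#'   up-/down-regulation (sum must be <= 1)
#' @param effect_up multiplicative MI inflation for Group I genes (> 1.2 so
#'   designed effects straddle the classification threshold)
#' @param effect_down multiplicative MI deflation for Group II genes (< 0.8)
#' @param dispersion gamma-Poisson overdispersion (0 = Poisson)
#' @param base_mean,base_sdlog log-normal distribution of per-gene baseline
#'   abundance
#' @param seed integer seed
#' @return a `screen_truth`
#' @export
screen_truth <- function(n_genes = 2000, frac_group1 = 0.05,
                         frac_group2 = 0.08, effect_up = 1.6,
                         effect_down = 0.5, dispersion = 0.02,
                         base_mean = 300, base_sdlog = 0.7, seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1) stop("'n_genes' must be >= 1", call. = FALSE)
  stopifnot_scalar(frac_group1, "frac_group1", nonneg = TRUE)
  stopifnot_scalar(frac_group2, "frac_group2", nonneg = TRUE)
  if (frac_group1 + frac_group2 > 1)
    stop("frac_group1 + frac_group2 must be <= 1", call. = FALSE)
  if (frac_group1 > 0 && effect_up <= 1.2)
    stop("'effect_up' must exceed the 1.2 classification threshold", call. = FALSE)
  if (frac_group2 > 0 && effect_down >= 0.8)
    stop("'effect_down' must be below the 0.8 classification threshold", call. = FALSE)
  stopifnot_scalar(dispersion, "dispersion", nonneg = TRUE)
  structure(list(n_genes = n_genes, frac_group1 = frac_group1,
                 frac_group2 = frac_group2, effect_up = effect_up,
                 effect_down = effect_down, dispersion = dispersion,
                 base_mean = base_mean, base_sdlog = base_sdlog,
                 seed = as.integer(seed)),
            class = "screen_truth")
}

# gamma-Poisson (negative-binomial) counts with mean mu and dispersion d
rnbin <- function(n, mu, d) {
  if (d < 1e-8) return(rpois(n, mu))
  rpois(n, rgamma(n, shape = 1 / d, scale = mu * d))
}

#' Synthetic promoter peak-count table with known labels
#'
#' Per-gene promoter sums for Sham, MI and Patch drawn from a seeded
#' gamma-Poisson model: baseline abundance is log-normal across genes; the
#' Sham and Patch means equal the baseline (the patch restores the Sham
#' state); designed Group I genes have the MI mean inflated by `effect_up`
#' relative to both, Group II deflated by `effect_down`.
#'
#' @param truth a [screen_truth()]
#' @return list with `table` (data.frame `gene_id`, `sum_sham`, `sum_mi`,
#'   `sum_patch`) and `labels` (the designed truth: `group1`, `group2`,
#'   `neither`)
#' @export
#' @examples
#' d <- make_peak_table(screen_truth(n_genes = 500, seed = 7))
#' table(d$labels)
make_peak_table <- function(truth = screen_truth()) {
  stopifnot(inherits(truth, "screen_truth"))
  n <- truth$n_genes
  n1 <- round(truth$frac_group1 * n)
  n2 <- round(truth$frac_group2 * n)
  with_seed(truth$seed, {
    labels <- sample(rep(c("group1", "group2", "neither"),
                         c(n1, n2, n - n1 - n2)))
    base <- exp(rnorm(n, log(truth$base_mean), truth$base_sdlog))
    mult <- ifelse(labels == "group1", truth$effect_up,
                   ifelse(labels == "group2", truth$effect_down, 1))
    tab <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n)),
      sum_sham = rnbin(n, base, truth$dispersion),
      sum_mi = rnbin(n, base * mult, truth$dispersion),
      sum_patch = rnbin(n, base, truth$dispersion))
    list(table = tab,
         labels = factor(labels, levels = c("group1", "group2", "neither")))
  })
}

#' Write or read a per-gene peak-sum TSV
#'
#' Columns `gene_id`, `sum_sham`, `sum_mi`, `sum_patch`.
#'
#' @param table data.frame of per-gene sums
#' @param file path
#' @return `write_peak_sums_tsv` returns `file` invisibly;
#'   `read_peak_sums_tsv` returns the data.frame.
#' @export
write_peak_sums_tsv <- function(table, file) {
  write.table(table, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_peak_sums_tsv
#' @export
read_peak_sums_tsv <- function(file) {
  d <- read.delim(file)
  need <- c("gene_id", "sum_sham", "sum_mi", "sum_patch")
  if (!all(need %in% names(d)))
    stop("peak-sum TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}
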