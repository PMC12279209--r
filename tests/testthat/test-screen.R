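toy_tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000,
                      strand = "+")

test_that("promoter window sums follow the closed +/-3 kb overlap rule", {
  tss <- toy_tss$tss
  peaks <- list(mi = data.frame(
    chrom = "chr1",
    start = tss + c(-2500, 100, 3500),
    end = tss + c(-2500, 100, 3500) + 80,
    abundance = c(4, 7, 9)))
  s <- promoter_window_sum(peaks, toy_tss)
  expect_equal(s$sum_mi, 11)  # the +3500 peak lies outside the window
  # peak exactly touching the window edge is included (closed interval)
  edge <- list(mi = data.frame(chrom = "chr1", start = tss - 3200,
                               end = tss - 3000, abundance = 5))
  expect_equal(promoter_window_sum(edge, toy_tss)$sum_mi, 5)
  # one base further out: excluded
  out <- list(mi = data.frame(chrom = "chr1", start = tss - 3200,
                              end = tss - 3001, abundance = 5))
  expect_equal(promoter_window_sum(out, toy_tss)$sum_mi, 0)
  # no peaks in the window, wrong chromosome
  off <- list(mi = data.frame(chrom = "chr2", start = tss, end = tss + 10,
                              abundance = 5))
  expect_equal(promoter_window_sum(off, toy_tss)$sum_mi, 0)
})

test_that("malformed peak intervals are rejected with line numbers", {
  bad <- list(mi = data.frame(chrom = "chr1", start = c(10, 300),
                              end = c(20, 200), abundance = c(1, 1)))
  expect_error(promoter_window_sum(bad, toy_tss), "line\\(s\\) 2")
  neg <- list(mi = data.frame(chrom = "chr1", start = 10, end = 20,
                              abundance = -1))
  expect_error(promoter_window_sum(neg, toy_tss), "malformed")
})

test_that("classification follows the published thresholds", {
  ex <- data.frame(gene_id = c("a", "b", "c", "d"),
                   sum_sham = c(100, 100, 100, 0),
                   sum_mi = c(130, 100, 70, 50),
                   sum_patch = c(125, 100, 100, 50))
  lab <- classify_groups(ex)
  expect_equal(as.character(lab$label),
               c("group1", "neither", "group2", "excluded"))
  expect_error(classify_groups(transform(ex, sum_mi = -1)), "negative")
})

test_that("classifier agrees with the brute-force legend on random tables", {
  set.seed(31)
  n <- 1000
  tab <- data.frame(gene_id = sprintf("g%04d", 1:n),
                    sum_sham = rpois(n, 120),
                    sum_mi = rpois(n, 120),
                    sum_patch = rpois(n, 120))
  # sprinkle zeros to exercise the exclusion rule
  tab$sum_sham[sample(n, 10)] <- 0
  tab$sum_patch[sample(n, 10)] <- 0
  got <- as.character(classify_groups(tab)$label)
  want <- brute_force_classify(tab$sum_sham, tab$sum_mi, tab$sum_patch)
  expect_identical(got, want)
})

test_that("classification is scale-invariant and monotone in MI signal", {
  set.seed(32)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    sum_sham = rpois(200, 80) + 1,
                    sum_mi = rpois(200, 80) + 1,
                    sum_patch = rpois(200, 80) + 1)
  l0 <- classify_groups(tab)$label
  for (c in c(0.25, 3, 17)) {
    sc <- transform(tab, sum_sham = sum_sham * c, sum_mi = sum_mi * c,
                    sum_patch = sum_patch * c)
    expect_identical(classify_groups(sc)$label, l0)
  }
  # increasing mi with sham/patch fixed never moves group1 -> group2
  rank_of <- function(l) c(group2 = 1, neither = 2, conflict = 2, group1 = 3,
                           excluded = NA)[as.character(l)]
  up <- transform(tab, sum_mi = sum_mi * 1.7)
  r0 <- rank_of(l0); r1 <- rank_of(classify_groups(up)$label)
  keep <- !is.na(r0) & !is.na(r1)
  expect_true(all(r1[keep] >= r0[keep]))
})

test_that("screen summary counts are complete and permutation-invariant", {
  expect_equal(sum(screen_summary(factor(character(0),
    levels = c("group1", "group2", "neither", "conflict", "excluded")))), 0)
  # deep counts and near-zero dispersion: the tight MI/Patch threshold
  # (1.1) needs ratio noise well below 10% for clean designed counts
  d <- make_peak_table(screen_truth(n_genes = 1000, frac_group1 = 0.05,
                                    frac_group2 = 0.08, dispersion = 1e-4,
                                    base_mean = 5e4, base_sdlog = 0.3,
                                    seed = 9))
  lab <- classify_groups(d$table)
  cnt <- screen_summary(lab)
  expect_equal(sum(cnt), 1000)
  # designed 50 group1 / 80 group2 recovered within +/-10%
  expect_lt(abs(cnt[["group1"]] - 50) / 50, 0.10)
  expect_lt(abs(cnt[["group2"]] - 80) / 80, 0.10)
  perm <- lab[sample(nrow(lab)), ]
  expect_equal(screen_summary(perm), cnt)
})

test_that("full screen runs from peak tables through TSV/JSON outputs", {
  set.seed(33)
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(50000, 90000), strand = c("+", "-"))
  mkpeaks <- function(ab1, ab2) data.frame(
    chrom = "chr1", start = c(49000, 89500), end = c(49500, 89900),
    abundance = c(ab1, ab2))
  peaks <- list(sham = mkpeaks(100, 100), mi = mkpeaks(150, 60),
                patch = mkpeaks(105, 95))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  out <- run_screen(peaks, tss, out_tsv = tsv, out_json = js)
  expect_equal(as.character(out$genes$label), c("group1", "group2"))
  expect_true(file.exists(tsv) && file.exists(js))
  back <- read_peak_sums_tsv(tsv)
  expect_equal(back$sum_mi, c(150, 60))
})
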