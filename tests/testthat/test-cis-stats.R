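test_that("average position is the first/last midpoint", {
  expect_equal(average_position(c(100, 200, 300, 400)), 250)
  expect_equal(average_position(c(100, 110, 400)), 250)   # blind to interior skew
  expect_equal(average_position(500), 500)
})

test_that("median position takes the central site(s) and tracks the dense side", {
  expect_equal(median_position(c(100, 110, 400)), 110)
  expect_equal(median_position(c(100, 200, 300, 400)), 250)
  expect_equal(median_position(500), 500)
  # directional property: skew toward small positions pulls median below midpoint
  set.seed(5)
  for (rep in 1:20) {
    pos <- sort(c(stats::runif(15, 0, 100), stats::runif(3, 5000, 10000)))
    expect_lt(median_position(pos), average_position(pos))
    sym <- sort(c(pos, 10100 - pos))   # mirrored layout: the two agree
    expect_equal(median_position(sym), average_position(sym))
  }
})

test_that("dimension is the inclusive span (singletons occupy one base pair)", {
  expect_equal(cis_dimension(c(100, 150)), 51)
  expect_equal(cis_dimension(500), 1)
  expect_equal(cis_dimension(c(200, 200)), 1)
  expect_equal(cis_dimension(c(100, 150), inclusive = FALSE), 50)
})

test_that("CIS entropy matches hand-computed values and its defined limits", {
  expect_equal(cis_entropy(c(A = 2, B = 2)), 1)
  expect_equal(cis_entropy(c(A = 4)), 0)
  expect_equal(cis_entropy(c(A = 3, B = 1)), 0.811278, tolerance = 1e-6)
  expect_error(cis_entropy(c(2, 2), order = 5), class = "cisgraph_contract_error")
})

test_that("normalized entropy uses the dataset-wide label count", {
  expect_equal(normalized_entropy(c(2, 2), n_dataset_labels = 4), 0.5)
  expect_equal(normalized_entropy(c(2, 2), n_dataset_labels = 2), 1)  # N = n reduces to E
  expect_equal(normalized_entropy(c(4), n_dataset_labels = 5), 0)
  expect_error(normalized_entropy(c(2, 2), n_dataset_labels = 1),
               class = "cisgraph_contract_error")
})

test_that("entropy bounds and base-invariance hold over random count vectors", {
  set.seed(17)
  for (rep in 1:200) {
    O <- sample(1:50, 1)
    n <- sample(1:min(O, 6), 1)
    counts <- as.integer(table(sample.int(n, O, replace = TRUE)))
    N <- length(counts) + sample(0:3, 1)
    E <- cis_entropy(counts)
    NE <- normalized_entropy(counts, max(N, 1))
    expect_gte(E, 0); expect_lte(E, 1 + 1e-12)
    expect_gte(NE, 0)
    expect_lte(NE, E + 1e-12)   # N >= n  =>  NE <= E
    if (length(counts) > 1 && N == length(counts))
      expect_equal(NE, E)
    # maximal iff uniform; zero iff one label
    if (length(counts) == 1) expect_equal(E, 0)
    if (length(counts) > 1 && length(unique(counts)) == 1)
      expect_equal(E, 1)
    # base cancels: recompute in bits
    if (length(counts) > 1) {
      p <- counts / sum(counts)
      expect_equal(E, -sum(p * log2(p)) / log2(length(counts)))
    }
  }
})

test_that("the uniform-placement p-value has its closed forms and monotonicity", {
  # order 1: complement of nobody landing in the window
  expect_equal(cis_pvalue(1, 1e4, 100, 1e6), 1 - (1 - 1e-2)^100)
  # certain event: every site, window = genome
  expect_equal(cis_pvalue(10, 1e6, 10, 1e6), 1)
  # decreasing in order, increasing in dimension
  p_by_order <- vapply(2:8, cis_pvalue, numeric(1), dimension = 1e4,
                       total_is = 100, genome_size = 1e6)
  expect_true(all(diff(p_by_order) < 0))
  p_by_dim <- vapply(c(1e3, 1e4, 1e5), function(d) cis_pvalue(5, d, 100, 1e6),
                     numeric(1))
  expect_true(all(diff(p_by_dim) > 0))
  expect_error(cis_pvalue(5, 2e6, 100, 1e6), class = "cisgraph_param_error")
})

test_that("p-value agrees with Monte-Carlo uniform placement", {
  set.seed(29)
  M <- 100; G <- 1e6; d <- 1e4; O <- 5; reps <- 2e4
  hits <- colSums(matrix(stats::runif(M * reps) < d / G, nrow = M))
  p_hat <- mean(hits >= O)
  p <- cis_pvalue(O, d, M, G)
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(p - p_hat), 3 * se)
})

test_that("the log-likelihood ratio is zero at the global rate, else positive", {
  expect_equal(cis_loglik_ratio(10, 1e5, 100, 1e6), 0)   # local rate = global rate
  expect_equal(cis_loglik_ratio(10, 1e3, 100, 1e6),
               2 * (10 * log(10 / 0.1) - (10 - 0.1)))     # closed form, by hand
  set.seed(3)
  for (rep in 1:20) {
    O <- sample(2:30, 1); d <- sample(100:10000, 1)
    expect_gte(cis_loglik_ratio(O, d, 500, 1e8), 0)
  }
})

test_that("compute_cis_stats fills a coherent record for every CIS", {
  sites <- sort_sites(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100, 110, 400, 5000, 900000),
    label = c("a", "b", "a", "c", "c")))
  cis <- compute_cis_stats(cis_components(sites, threshold = 1000), sites)
  st <- cis[[1]]$stats
  expect_equal(st$order, 3)
  expect_equal(st$dimension, 301)
  expect_equal(st$avg_pos, 250)
  expect_equal(st$median_pos, 110)
  expect_equal(st$n_labels, 2)
  expect_equal(st$label_counts, c(a = 2L, b = 1L))
  expect_equal(st$entropy, cis_entropy(c(2, 1)))
  expect_equal(st$norm_entropy, normalized_entropy(c(2, 1), 3))  # N = 3 dataset-wide
  # default genome size: sum of per-chromosome max positions
  expect_equal(st$p_value, cis_pvalue(3, 301, 5, 400 + 900000))
  expect_equal(st$loglik_ratio, cis_loglik_ratio(3, 301, 5, 400 + 900000))
  # positional invariants
  for (c in cis) {
    expect_gte(c$stats$avg_pos, min(c$members$pos))
    expect_lte(c$stats$avg_pos, max(c$members$pos))
    expect_gte(c$stats$median_pos, min(c$members$pos))
    expect_lte(c$stats$median_pos, max(c$members$pos))
  }
  # FDR column appears on request and is monotone in p
  cis_fdr <- compute_cis_stats(cis_components(sites, threshold = 1000), sites,
                               fdr = TRUE)
  p <- vapply(cis_fdr, function(x) x$stats$p_value, numeric(1))
  padj <- vapply(cis_fdr, function(x) x$stats$p_adj, numeric(1))
  expect_equal(padj, stats::p.adjust(p, "BH"))
  # per-chromosome null uses chromosome-local counts
  cis_pc <- compute_cis_stats(cis_components(sites, threshold = 1000), sites,
                              per_chromosome = TRUE)
  expect_equal(cis_pc[[1]]$stats$p_value, cis_pvalue(3, 301, 3, 400))
})
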