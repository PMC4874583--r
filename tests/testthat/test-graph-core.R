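test_that("edges join exactly the same-chromosome pairs below the threshold", {
  s <- make_sites(c(100, 150, 5000))
  g <- build_is_graph(s, threshold = 1000)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sort(c(g$sites$pos[g$edges$from], g$sites$pos[g$edges$to])),
               c(100, 150))

  # cross-chromosome pairs are never edged
  s2 <- sort_sites(data.frame(chrom = c("chr1", "chr2"), pos = c(100, 100), label = "t"))
  expect_equal(nrow(build_is_graph(s2, 1e6)$edges), 0)

  # strict threshold: distance exactly equal to it does not edge
  s3 <- make_sites(c(100, 1100))
  expect_equal(nrow(build_is_graph(s3, 1000)$edges), 0)
  expect_equal(nrow(build_is_graph(s3, 1000, inclusive = TRUE)$edges), 1)

  # same-position duplicates are at distance 0 and always edged
  s4 <- make_sites(c(200, 200))
  expect_equal(nrow(build_is_graph(s4, 1)$edges), 1)
})

test_that("sliding-window edge construction equals all-pairs enumeration", {
  # includes the evenly spaced grid (step 10, threshold 11: adjacent pairs only)
  grid <- make_sites(seq(1, 91, by = 10))
  g <- build_is_graph(grid, 11)
  o <- oracle_edges(grid, 11)
  expect_equal(nrow(g$edges), length(o$from))
  expect_equal(nrow(g$edges), 9)

  set.seed(11)
  for (rep in 1:25) {
    s <- random_sites(sample(5:120, 1), max_pos = 5000)
    thr <- sample(1:1500, 1)
    incl <- rep %% 2 == 0
    g <- build_is_graph(s, thr, inclusive = incl)
    o <- oracle_edges(s, thr, inclusive = incl)
    got <- sort(paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to)))
    want <- sort(paste(o$from, o$to))
    expect_identical(got, want)
  }
})

test_that("contract violations are rejected", {
  unsorted <- data.frame(chrom = "chr1", pos = c(500, 100), label = "t",
                         row_id = 1:2)
  expect_error(build_is_graph(unsorted, 100), class = "cisgraph_contract_error")
  expect_error(build_is_graph(make_sites(100), 0), class = "cisgraph_param_error")
  expect_error(cis_components(make_sites(100)), class = "cisgraph_param_error")
})

test_that("components chain through intermediates (stretchy single linkage)", {
  s <- make_sites(c(0, 900, 1800, 2700) + 1)
  cis <- cis_components(s, threshold = 1000)
  expect_length(cis, 1)
  expect_equal(nrow(cis[[1]]$members), 4)   # 1..2701 linked although 2700 >= threshold

  s2 <- make_sites(c(100, 150, 5000))
  cis2 <- cis_components(s2, threshold = 1000)
  expect_equal(vapply(cis2, function(x) nrow(x$members), integer(1)), c(2L, 1L))
})

test_that("graph components, gap scan and BFS oracle agree on random data", {
  set.seed(23)
  for (rep in 1:30) {
    s <- random_sites(sample(10:200, 1), max_pos = 2e4)
    thr <- sample(c(1, 10, 100, 500, 2000, 10000), 1)
    g <- build_is_graph(s, thr)
    via_graph <- cis_components(g)
    via_scan <- cis_components(s, threshold = thr)
    expect_identical(cis_set_signature(via_graph), cis_set_signature(via_scan))
    bfs <- oracle_bfs(nrow(s), g$edges$from, g$edges$to)
    expect_identical(cis_set_signature(via_scan),
                     partition_signature(s$row_id, bfs))
  }
})

test_that("union-find partition matches igraph components (independent library)", {
  skip_if_not_installed("igraph")
  set.seed(7)
  s <- random_sites(150, max_pos = 3e4)
  g <- build_is_graph(s, 800)
  ig <- igraph::graph_from_edgelist(cbind(g$edges$from, g$edges$to), directed = FALSE)
  ig <- igraph::add_vertices(ig, nrow(s) - igraph::gorder(ig))
  memb <- igraph::components(ig)$membership
  expect_identical(cis_set_signature(cis_components(g)),
                   partition_signature(s$row_id, memb))
})

test_that("CIS numbering follows (chrom, first position) and names compose", {
  s <- sort_sites(data.frame(chrom = c("chr2", "chr1", "chr1"),
                             pos = c(500, 100, 5000), label = "t"))
  cis <- cis_components(s, threshold = 1000)
  expect_equal(vapply(cis, `[[`, character(1), "name"),
               c("chr1_1", "chr1_2", "chr2_3"))
})

test_that("order filtering keeps >= min_order and renumbers sequentially", {
  s <- make_sites(c(100, 150, 180, 5000, 9000, 9100))
  cis <- cis_components(s, threshold = 500)   # orders 3, 1, 2
  expect_equal(vapply(cis, function(x) nrow(x$members), integer(1)), c(3L, 1L, 2L))
  f <- filter_by_order(cis, 2)
  expect_length(f, 2)
  expect_equal(vapply(f, `[[`, integer(1), "number"), 1:2)
  expect_equal(vapply(f, `[[`, character(1), "name"), c("chr1_1", "chr1_2"))
  expect_length(filter_by_order(cis, 1), 3)    # identity
  expect_length(filter_by_order(cis, 10), 0)   # nothing qualifies
})

test_that("threshold monotonicity and node conservation hold", {
  set.seed(41)
  for (rep in 1:10) {
    s <- random_sites(sample(20:150, 1), max_pos = 1e4)
    thrs <- sort(sample(1:5000, 4))
    n_comp <- vapply(thrs, function(t) length(cis_components(s, threshold = t)),
                     integer(1))
    expect_true(all(diff(n_comp) <= 0))   # raising threshold never splits
    for (t in thrs) {
      cis <- cis_components(s, threshold = t)
      expect_equal(sum(vapply(cis, function(x) nrow(x$members), integer(1))),
                   nrow(s))               # every site in exactly one CIS
    }
  }
})

test_that("graph exports write edge lists and GraphML", {
  s <- make_sites(c(100, 150, 5000))
  g <- build_is_graph(s, 1000)
  ep <- tempfile(fileext = ".tsv")
  write_edge_list(g, ep)
  e <- utils::read.table(ep, header = TRUE, sep = "\t")
  expect_equal(nrow(e), 1)
  expect_equal(e$distance, 50)
  skip_if_not_installed("igraph")
  gp <- tempfile(fileext = ".graphml")
  write_graphml(g, gp)
  gg <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::gorder(gg), 3)
  expect_equal(igraph::gsize(gg), 1)
})
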