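te_table <- function(chrom, tss, name) {
  data.frame(chrom = chrom, tss = tss, name = name, stringsAsFactors = FALSE)
}

test_that("IS link to TEs strictly within the threshold, same chromosome only", {
  sites <- make_sites(1000)
  tes <- te_table("chr1", c(1500, 90000), c("GeneA", "GeneB"))
  links <- link_is_to_te(sites, tes, 10000)
  expect_equal(nrow(links), 1)
  expect_equal(links$te_name, "GeneA")
  expect_equal(links$distance, 500)

  # chromosome mismatch: never linked
  expect_equal(nrow(link_is_to_te(sites, te_table("chr2", 1000, "G"), 1e6)), 0)

  # strict boundary: distance exactly the threshold is out, inclusive brings it in
  tes2 <- te_table("chr1", 3000, "Edge")
  expect_equal(nrow(link_is_to_te(sites, tes2, 2000)), 0)
  expect_equal(nrow(link_is_to_te(sites, tes2, 2000, inclusive = TRUE)), 1)
})

test_that("sweep linking equals the all-pairs filter on random data", {
  set.seed(31)
  for (rep in 1:15) {
    sites <- random_sites(100, max_pos = 2e5)
    tes <- te_table(paste0("chr", sample.int(3, 50, replace = TRUE)),
                    sample.int(2e5, 50), paste0("G", 1:50))
    thr <- sample(c(100, 1000, 5000, 50000), 1)
    links <- link_is_to_te(sites, tes, thr)
    # brute force over all (IS, TE) pairs
    want <- 0L
    pairs <- character(0)
    for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(tes))) {
      if (sites$chrom[i] == tes$chrom[j] && abs(sites$pos[i] - tes$tss[j]) < thr) {
        want <- want + 1L
        pairs <- c(pairs, paste(sites$row_id[i], tes$name[j], tes$tss[j]))
      }
    }
    expect_equal(nrow(links), want)
    expect_setequal(paste(links$row_id, links$te_name, links$tss), pairs)
  }
})

test_that("link sets grow monotonically with the threshold", {
  set.seed(37)
  sites <- random_sites(60, max_pos = 1e5)
  tes <- te_table(paste0("chr", sample.int(3, 40, replace = TRUE)),
                  sample.int(1e5, 40), paste0("G", 1:40))
  prev <- character(0)
  for (thr in c(100, 1000, 10000, 100000)) {
    cur <- paste(link_is_to_te(sites, tes, thr)$row_id,
                 link_is_to_te(sites, tes, thr)$te_name)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("gene atmospheres aggregate per CIS with deduplicated gene sets", {
  sites <- make_sites(c(1000, 1200, 50000), label = c("a", "a", "b"))
  cis <- cis_components(sites, threshold = 5000)   # {1000,1200} and {50000}
  tes <- te_table("chr1", c(1500, 49000, 200000), c("GeneA", "GeneB", "GeneFar"))
  links <- link_is_to_te(sites, tes, 10000)
  ga <- build_gene_atmosphere(cis, links)
  expect_length(ga, 2)
  expect_equal(ga[[1]]$genes, "GeneA")            # both member IS near GeneA: dedup
  expect_equal(nrow(ga[[1]]$links), 2)
  expect_equal(ga[[2]]$genes, "GeneB")

  # a CIS with no nearby TE keeps an empty atmosphere, not dropped
  ga2 <- build_gene_atmosphere(cis, link_is_to_te(sites, tes, 10)[0, ])
  expect_length(ga2, 2)
  expect_equal(ga2[[1]]$genes, character(0))

  # union over CIS equals the pooled link gene set
  expect_equal(dataset_gene_set(ga), sort(unique(links$te_name)))
})

test_that("the dataset gene set is the union of per-CIS gene lists", {
  ga <- structure(list(list(cis_name = "x", links = NULL, genes = c("A", "B")),
                       list(cis_name = "y", links = NULL, genes = c("B", "C"))),
                  class = "gene_atmosphere")
  expect_equal(dataset_gene_set(ga), c("A", "B", "C"))
  expect_equal(dataset_gene_set(structure(list(), class = "gene_atmosphere")),
               character(0))
})

test_that("GA tables flatten to one row per link and write/read cleanly", {
  sites <- make_sites(c(1000, 1200), label = "a")
  cis <- cis_components(sites, threshold = 5000)
  tes <- te_table("chr1", 1500, "GeneA")
  ga <- build_gene_atmosphere(cis, link_is_to_te(sites, tes, 10000))
  df <- as.data.frame(ga)
  expect_equal(names(df), c("cis_name", "row_id", "pos", "te_name", "tss", "distance"))
  expect_equal(nrow(df), 2)
  p <- tempfile(fileext = ".tsv")
  write_ga_table(ga, p, params = list(ga_threshold = 10000))
  back <- utils::read.table(p, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(back), 2)
  expect_equal(back$te_name, c("GeneA", "GeneA"))
})
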