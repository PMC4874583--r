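# Standard window method (SWM) baseline: the classic fixed-window CIS
# definition (k sites within w_k base pairs), next-gene assignment, and the
# three-way gene-set comparison against the graph-based caller.  The
# baseline exists to expose the contrast between rigid windows and the
# "stretchy" single-linkage components: a chain of sites each within the
# threshold of its neighbour forms one graph component but can never fit a
# fixed window.

#' Default standard-window rules
#'
#' The classic fixed-window definition: 2 sites within 30 kb, 3 within
#' 50 kb, 4 or more within 100 kb.  Fully overridable — pass any
#' data.frame of rules to [swm_call()].
#'
#' @return data.frame with columns `k` (order) and `window` (bp),
#'   sorted by `k`.
#' @export
default_window_rules <- function() {
  data.frame(k = c(2L, 3L, 4L), window = c(30000, 50000, 100000))
}

.validate_rules <- function(rules) {
  if (!is.data.frame(rules) || !all(c("k", "window") %in% names(rules)) || !nrow(rules))
    stop_param("rules must be a data.frame with columns k and window")
  rules <- rules[order(rules$k), , drop = FALSE]
  if (any(rules$k < 2)) stop_param("window rules need k >= 2")
  if (is.unsorted(rules$window)) stop_param("windows must be non-decreasing in k")
  rules
}

#' Call CIS with the standard window method
#'
#' Greedy left-to-right scan per chromosome over the sorted positions: at
#' each site, each rule is tested (window anchored at the site, sites
#' within `window` bp counted, largest `k` first); if at least `k` sites
#' fall in `w_k`, the densest qualifying window is reported as a CIS and
#' the scan advances past its members, otherwise the site is left
#' unclustered.  Reported windows never overlap.  Only qualifying windows
#' are returned — lone sites are not CIS under this method.
#'
#' @param sites site table (sorted canonically; resorted if not).
#' @param rules window rules, see [default_window_rules()].
#' @return a `cis_set` (statistics unset), numbered in scan order.
#' @examples
#' s <- sort_sites(data.frame(chrom = "chr1", pos = c(1, 901, 1801, 2701),
#'                            label = "t"))
#' # rigid 1-kb window captures at most 2 consecutive sites ...
#' vapply(swm_call(s, data.frame(k = 2, window = 1000)),
#'        function(x) nrow(x$members), integer(1))
#' # ... where the graph caller chains all 4 into one CIS
#' length(cis_components(s, threshold = 1000))
#' @export
swm_call <- function(sites, rules = default_window_rules()) {
  sites <- validate_sites(sites)
  rules <- .validate_rules(rules)
  out <- list()
  for (chrom in unique(sites$chrom)) {
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    pos <- s$pos
    n <- nrow(s)
    i <- 1L
    while (i <= n) {
      best_j <- NA_integer_
      best_m <- 0L
      for (r in rev(seq_len(nrow(rules)))) {   # largest k first
        w <- rules$window[r]
        j <- findInterval(pos[i] + w - 1, pos)  # sites in [pos_i, pos_i + w)
        m <- j - i + 1L
        if (m >= rules$k[r] && m > best_m) { best_m <- m; best_j <- j }
      }
      if (!is.na(best_j)) {
        members <- s[i:best_j, , drop = FALSE]
        rownames(members) <- NULL
        out[[length(out) + 1L]] <- list(number = length(out) + 1L,
                                        name = NA_character_, chrom = chrom,
                                        members = members, stats = NULL)
        i <- best_j + 1L
      } else i <- i + 1L
    }
  }
  for (k in seq_along(out)) out[[k]]$name <- paste0(out[[k]]$chrom, "_", k)
  structure(out, class = "cis_set")
}

#' Next-gene assignment for a CIS
#'
#' The next-gene approach: the transcriptional element whose TSS is closest
#' to the CIS median position (the median tracks the dense side of an
#' asymmetric component, making it the better anchor).  Ties break toward
#' the smaller TSS, then the lexicographically smaller name.
#'
#' @param cis a single CIS (element of a `cis_set`).
#' @param tes transcriptional-element table.
#' @return the gene name, or `NA_character_` when no element lies on the
#'   CIS chromosome (the no-gene sentinel).
#' @export
next_gene <- function(cis, tes) {
  tes <- validate_tes(tes)
  t <- tes[tes$chrom == cis$chrom, , drop = FALSE]
  if (!nrow(t)) return(NA_character_)
  med <- median_position(sort(cis$members$pos))
  d <- abs(t$tss - med)
  t$name[order(d, t$tss, t$name)[1L]]
}

#' Three-way comparison of two gene sets
#'
#' Partitions the union of the two gene lists into genes found only by the
#' graph-based caller, only by the window-method baseline, and by both —
#' the Venn-diagram view of method concordance.
#'
#' @param gbf_genes,swm_genes character vectors of gene names.
#' @return object of class `gene_set_comparison`: list with sorted
#'   `only_gbf`, `only_swm`, `both` (pairwise disjoint, union = input
#'   union) and a `counts` vector.
#' @export
compare_gene_sets <- function(gbf_genes, swm_genes) {
  g <- unique(as.character(gbf_genes))
  s <- unique(as.character(swm_genes))
  out <- list(only_gbf = sort(setdiff(g, s)),
              only_swm = sort(setdiff(s, g)),
              both = sort(intersect(g, s)))
  out$counts <- c(only_gbf = length(out$only_gbf), only_swm = length(out$only_swm),
                  both = length(out$both))
  structure(out, class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf("gene-set comparison: %d GBF-only, %d SWM-only, %d shared\n",
              x$counts["only_gbf"], x$counts["only_swm"], x$counts["both"]))
  invisible(x)
}
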