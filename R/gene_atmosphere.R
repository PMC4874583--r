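# Gene atmosphere: link integration sites to nearby transcriptional
# elements (each represented by its TSS point) and aggregate the linked
# elements per CIS.  The IS-TE link graph is strictly bipartite — same-type
# edges belong to the proximity graph, not here.

#' Link integration sites to transcriptional elements
#'
#' Finds every same-chromosome (IS, TE) pair whose genomic distance
#' `|pos - tss|` is strictly below `ga_threshold` (set `inclusive = TRUE`
#' for `<=`).  Distance is measured to the TSS point only, not to gene
#' bodies.  An IS may link zero, one or many TEs and vice versa.
#'
#' Implemented as a sweep over the two sorted tables (binary search of the
#' TSS window around each site), equivalent to the all-pairs filter.
#'
#' @param sites site table (sorted canonically; resorted if not).
#' @param tes transcriptional-element table from [read_te_table()].
#' @param ga_threshold annotation distance threshold in bp, >= 1.
#' @param inclusive use `<=` instead of strict `<`.
#' @return data.frame with one row per link: `row_id`, `chrom`, `pos`,
#'   `te_name`, `tss`, `distance`, ordered by (chrom, pos, tss).
#' @export
link_is_to_te <- function(sites, tes, ga_threshold, inclusive = FALSE) {
  sites <- validate_sites(sites)
  tes <- validate_tes(tes)
  if (!is.numeric(ga_threshold) || ga_threshold < 1)
    stop_param("ga_threshold must be >= 1")
  out <- vector("list", 0L)
  for (chrom in intersect(unique(sites$chrom), unique(tes$chrom))) {
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    t <- tes[tes$chrom == chrom, , drop = FALSE]
    tss <- t$tss
    # integer coordinates: strict |pos - tss| < thr  <=>  tss in [pos-thr+1, pos+thr-1]
    slack <- if (inclusive) 0 else 1
    lo <- findInterval(s$pos - ga_threshold + slack - 1, tss) + 1L
    hi <- findInterval(s$pos + ga_threshold - slack, tss)
    n_hits <- pmax(hi - lo + 1L, 0L)
    if (!any(n_hits > 0)) next
    is_idx <- rep.int(seq_len(nrow(s)), n_hits)
    te_idx <- unlist(lapply(which(n_hits > 0), function(i) lo[i]:hi[i]), use.names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      row_id = s$row_id[is_idx], chrom = chrom, pos = s$pos[is_idx],
      te_name = t$name[te_idx], tss = tss[te_idx],
      distance = abs(s$pos[is_idx] - tss[te_idx]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(row_id = integer(0), chrom = character(0), pos = numeric(0),
                      te_name = character(0), tss = numeric(0), distance = numeric(0)))
  }
  links <- do.call(rbind, out)
  links <- links[canonical_order(links$chrom, links$pos, links$tss), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Build the gene atmosphere of each CIS
#'
#' Gathers, per CIS, the IS-TE links of its member sites; the CIS gene set
#' is the deduplicated, lexicographically sorted list of linked element
#' names.  A CIS with no nearby element keeps an empty atmosphere (it is
#' retained, not dropped).
#'
#' @param cis_set a `cis_set`.
#' @param links link table from [link_is_to_te()] computed over the same
#'   site set.
#' @return object of class `gene_atmosphere`: a list with one entry per
#'   CIS, each a list of `cis_name`, `links` (the member rows of the link
#'   table) and `genes`.
#' @export
build_gene_atmosphere <- function(cis_set, links) {
  ga <- lapply(cis_set, function(cis) {
    l <- links[links$row_id %in% cis$members$row_id, , drop = FALSE]
    rownames(l) <- NULL
    list(cis_name = cis$name, links = l,
         genes = sort(unique(l$te_name)))
  })
  structure(ga, class = "gene_atmosphere")
}

#' @export
print.gene_atmosphere <- function(x, ...) {
  cat(sprintf("gene_atmosphere: %d CIS, %d links, %d distinct genes\n",
              length(x), sum(vapply(x, function(g) nrow(g$links), integer(1))),
              length(dataset_gene_set(x))))
  invisible(x)
}

#' Flatten a gene atmosphere to one row per (CIS, IS, TE) link
#'
#' @param x a `gene_atmosphere`.
#' @param row.names,optional,... ignored.
#' @return data.frame with columns `cis_name`, `row_id`, `pos`, `te_name`,
#'   `tss`, `distance`.
#' @export
as.data.frame.gene_atmosphere <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x, function(g) {
    if (!nrow(g$links)) return(NULL)
    cbind(cis_name = g$cis_name,
          g$links[c("row_id", "pos", "te_name", "tss", "distance")])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(cis_name = character(0), row_id = integer(0), pos = numeric(0),
                      te_name = character(0), tss = numeric(0), distance = numeric(0)))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Union of all CIS gene atmospheres
#'
#' @param ga_list a `gene_atmosphere`.
#' @return sorted unique gene names over every CIS atmosphere.
#' @export
dataset_gene_set <- function(ga_list) {
  sort(unique(as.character(unlist(lapply(ga_list, `[[`, "genes"),
                                  use.names = FALSE))))
}
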