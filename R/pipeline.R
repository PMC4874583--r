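# High-level workflow wrappers mirroring the analysis steps: identify
# (graph -> components -> statistics), enhance (gene atmosphere), compare
# (graph caller vs window-method baseline on the gene level).  These are
# what the command-line front-end (inst/cli/gbf.R) drives; further steps
# are optional but must follow this order, and enhance/compare start from
# an identified CIS set.

#' Identify CIS and compute their statistics
#'
#' The first analysis step: build the proximity graph over the (sorted)
#' integration sites, extract connected components, optionally drop
#' components below a minimum order, and compute every per-CIS statistic.
#'
#' @param sites site table from [read_is_table()] (resorted if needed).
#' @param threshold clustering distance threshold in bp (default 30 kb,
#'   the classic fixed-window scale, which keeps graph/window comparisons
#'   commensurable).
#' @param min_order drop components with fewer member sites (default 1:
#'   keep everything; a CIS in the strict sense has order >= 2).
#' @param inclusive edge rule `<=` instead of strict `<`.
#' @param genome_size,per_chromosome,fdr,span_inclusive passed to
#'   [compute_cis_stats()].
#' @return a `cis_set` with statistics populated.
#' @export
gbf_identify <- function(sites, threshold = 30000, min_order = 1L,
                         inclusive = FALSE, genome_size = NULL,
                         per_chromosome = FALSE, fdr = FALSE,
                         span_inclusive = TRUE) {
  sites <- validate_sites(sites)
  cis <- cis_components(sites, threshold = threshold, inclusive = inclusive)
  if (min_order > 1) cis <- filter_by_order(cis, min_order)
  compute_cis_stats(cis, sites, genome_size = genome_size,
                    per_chromosome = per_chromosome, fdr = fdr,
                    span_inclusive = span_inclusive)
}

#' Enhance a CIS set with its gene atmosphere
#'
#' The second, optional step: link every member integration site to the
#' transcriptional elements within `ga_threshold` bp of its position and
#' aggregate the linked elements per CIS.
#'
#' @param cis_set identified `cis_set`.
#' @param tes transcriptional-element table from [read_te_table()].
#' @param ga_threshold annotation distance threshold in bp (default
#'   100 kb, a regulatory-neighbourhood scale distinct from the clustering
#'   scale).
#' @param inclusive `<=` link rule.
#' @return a `gene_atmosphere`.
#' @export
gbf_enhance <- function(cis_set, tes, ga_threshold = 100000, inclusive = FALSE) {
  members <- do.call(rbind, lapply(cis_set, `[[`, "members"))
  if (is.null(members) || !nrow(members))
    return(structure(list(), class = "gene_atmosphere"))
  members <- members[c("chrom", "pos", "label", "row_id")]
  links <- link_is_to_te(members, tes, ga_threshold, inclusive = inclusive)
  build_gene_atmosphere(cis_set, links)
}

#' Compare graph-based and window-method gene discoveries
#'
#' Runs both callers on the same dataset and compares them on the gene
#' level, the Venn-diagram view: the graph caller contributes the union of
#' its CIS gene atmospheres; the window-method baseline contributes the
#' next gene of each of its CIS (the annotation strategy of the classic
#' window-method databases).
#'
#' @param sites site table.
#' @param tes transcriptional-element table.
#' @param threshold graph clustering threshold (bp).
#' @param min_order minimum CIS order on the graph side (default 2, the
#'   natural reading of "common"; the window method requires >= 2 by
#'   construction).
#' @param rules window rules for [swm_call()].
#' @param ga_threshold gene-atmosphere distance threshold (bp).
#' @param inclusive `<=` rule for both graph edges and atmosphere links.
#' @return list with `comparison` (a `gene_set_comparison`), `gbf_cis`,
#'   `swm_cis`, `gbf_genes`, `swm_genes`.
#' @export
gbf_compare <- function(sites, tes, threshold = 30000, min_order = 2L,
                        rules = default_window_rules(), ga_threshold = 100000,
                        inclusive = FALSE) {
  sites <- validate_sites(sites)
  gbf_cis <- gbf_identify(sites, threshold = threshold, min_order = min_order,
                          inclusive = inclusive)
  ga <- gbf_enhance(gbf_cis, tes, ga_threshold = ga_threshold, inclusive = inclusive)
  gbf_genes <- dataset_gene_set(ga)
  swm_cis <- swm_call(sites, rules)
  swm_genes <- vapply(swm_cis, next_gene, character(1), tes = tes)
  swm_genes <- sort(unique(swm_genes[!is.na(swm_genes)]))
  list(comparison = compare_gene_sets(gbf_genes, swm_genes),
       gbf_cis = gbf_cis, swm_cis = swm_cis,
       gbf_genes = gbf_genes, swm_genes = swm_genes)
}
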