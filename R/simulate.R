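# Seeded synthetic-data generator: uniform background integration sites
# plus planted hotspots with known label mixtures, and a uniform
# transcriptional-element annotation — so clustering, statistics,
# annotation and the window-method comparison are all testable against a
# known truth table without any external download.

#' Build a simulation configuration
#'
#' The defaults describe a compact but realistic insertional-mutagenesis
#' screen: three chromosomes totalling 300 Mb, 200 background integrations,
#' six planted hotspots of 2 kb spread (15 sites each, mixtures ranging
#' from single-virus to three-way mixes over MLV/HIV/MCV labels) separated
#' by far more than any clustering threshold in use, and 300 annotated
#' elements.
#'
#' @param genome data.frame with columns `chrom`, `length` (bp).
#' @param n_background number of uniformly placed background sites
#'   (allocated across chromosomes proportionally to length).
#' @param hotspots list of hotspots, each a list with `chrom`, `center`
#'   (bp), `spread` (bp; sites are uniform on `center +- spread`), `n_is`,
#'   and `mixture` (named probability vector over entropy labels, summing
#'   to 1).
#' @param n_te number of uniformly placed transcriptional elements.
#' @param background_labels labels assigned (uniformly) to background
#'   sites; defaults to the labels appearing in the hotspot mixtures.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(genome = data.frame(chrom = c("1", "2", "3"),
                                                  length = c(120e6, 100e6, 80e6)),
                              n_background = 200,
                              hotspots = default_hotspots(),
                              n_te = 300,
                              background_labels = NULL,
                              seed = 1L) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome)) ||
      !nrow(genome))
    stop_param("genome must be a data.frame with columns chrom and length")
  if (any(genome$length < 1)) stop_param("chromosome lengths must be >= 1")
  if (n_background < 0 || n_te < 0) stop_param("counts must be >= 0")
  for (h in hotspots) {
    if (!all(c("chrom", "center", "spread", "n_is", "mixture") %in% names(h)))
      stop_param("each hotspot needs chrom, center, spread, n_is, mixture")
    len <- genome$length[match(h$chrom, genome$chrom)]
    if (is.na(len)) stop_param(sprintf("hotspot chromosome '%s' not in genome", h$chrom))
    if (h$center - h$spread < 1 || h$center + h$spread > len)
      stop_param(sprintf("hotspot at %s:%s extends outside the chromosome",
                         h$chrom, format(h$center, scientific = FALSE)))
    if (h$n_is < 0) stop_param("hotspot n_is must be >= 0")
    if (is.null(names(h$mixture)) || abs(sum(h$mixture) - 1) > 1e-9)
      stop_param("hotspot mixture must be a named probability vector summing to 1")
  }
  if (is.null(background_labels)) {
    background_labels <- unique(unlist(lapply(hotspots, function(h) names(h$mixture))))
    if (!length(background_labels)) background_labels <- "background"
  }
  structure(list(genome = genome, n_background = n_background, hotspots = hotspots,
                 n_te = n_te, background_labels = background_labels,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted hotspots
#'
#' Six hotspots (two per chromosome) with 2 kb spread and 15 sites each,
#' placed tens of megabases apart, with label mixtures covering the
#' spectrum from zero to maximal diversity.
#'
#' @return list of hotspot definitions for [simulation_config()].
#' @export
default_hotspots <- function() {
  list(
    list(chrom = "1", center = 20e6, spread = 2000, n_is = 15,
         mixture = c(MLV = 1)),
    list(chrom = "1", center = 60e6, spread = 2000, n_is = 15,
         mixture = c(MLV = 0.5, HIV = 0.5)),
    list(chrom = "2", center = 30e6, spread = 2000, n_is = 15,
         mixture = c(MLV = 0.25, HIV = 0.25, MCV = 0.5)),
    list(chrom = "2", center = 70e6, spread = 2000, n_is = 15,
         mixture = c(HIV = 1)),
    list(chrom = "3", center = 25e6, spread = 2000, n_is = 15,
         mixture = c(MLV = 0.7, MCV = 0.3)),
    list(chrom = "3", center = 55e6, spread = 2000, n_is = 15,
         mixture = c(MLV = 1 / 3, HIV = 1 / 3, MCV = 1 / 3)))
}

# Normalized Shannon entropy of a mixture (base-invariant), the planted
# truth that cis_entropy() should recover in a pure hotspot.
.mixture_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}

#' Simulate an integration-site dataset with planted hotspots
#'
#' Background sites are uniform per chromosome (chromosomes drawn
#' proportionally to length); each hotspot contributes `n_is` sites uniform
#' on `center +- spread` with labels drawn from its mixture;
#' transcriptional elements are uniform across the genome.  Fully
#' reproducible: the same config (including seed) yields byte-identical
#' tables.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with `sites` (canonical site table, plus a `hotspot` column
#'   giving the planted hotspot index or `NA` for background), `tes`
#'   (element table), `truth` (one row per hotspot: interval actually
#'   realized, expected order, number of mixture labels, mixture entropy)
#'   and the `config`.
#' @export
simulate_is_data <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_param("config must be built with simulation_config()")
  set.seed(config$seed)
  genome <- config$genome
  glen <- as.numeric(genome$length)
  parts <- list()
  if (config$n_background > 0) {
    chrom_idx <- sample.int(nrow(genome), config$n_background, replace = TRUE,
                            prob = glen / sum(glen))
    pos <- floor(stats::runif(config$n_background) * glen[chrom_idx]) + 1
    parts[["bg"]] <- data.frame(
      chrom = genome$chrom[chrom_idx], pos = pos,
      label = sample(config$background_labels, config$n_background, replace = TRUE),
      hotspot = NA_integer_, stringsAsFactors = FALSE)
  }
  for (h in seq_along(config$hotspots)) {
    hs <- config$hotspots[[h]]
    if (hs$n_is == 0) next
    pos <- round(stats::runif(hs$n_is, hs$center - hs$spread, hs$center + hs$spread))
    parts[[paste0("hs", h)]] <- data.frame(
      chrom = hs$chrom, pos = pos,
      label = sample(names(hs$mixture), hs$n_is, replace = TRUE, prob = hs$mixture),
      hotspot = h, stringsAsFactors = FALSE)
  }
  if (!length(parts)) stop_param("configuration generates no integration sites")
  sites <- do.call(rbind, parts)
  sites <- sites[canonical_order(sites$chrom, sites$pos), , drop = FALSE]
  sites$row_id <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites <- sites[c("chrom", "pos", "label", "row_id", "hotspot")]

  tes <- NULL
  if (config$n_te > 0) {
    chrom_idx <- sample.int(nrow(genome), config$n_te, replace = TRUE,
                            prob = glen / sum(glen))
    tss <- floor(stats::runif(config$n_te) * glen[chrom_idx]) + 1
    tes <- data.frame(chrom = genome$chrom[chrom_idx], tss = tss,
                      name = NA_character_, stringsAsFactors = FALSE)
    tes <- tes[canonical_order(tes$chrom, tes$tss), , drop = FALSE]
    tes$name <- paste0("TE_", seq_len(nrow(tes)))
    rownames(tes) <- NULL
  } else {
    tes <- data.frame(chrom = character(0), tss = numeric(0), name = character(0))
  }

  truth <- do.call(rbind, lapply(seq_along(config$hotspots), function(h) {
    hs <- config$hotspots[[h]]
    realized <- sites$pos[!is.na(sites$hotspot) & sites$hotspot == h]
    data.frame(hotspot = h, chrom = hs$chrom, center = hs$center,
               spread = hs$spread, n_is = hs$n_is,
               start = if (length(realized)) min(realized) else NA_real_,
               end = if (length(realized)) max(realized) else NA_real_,
               n_labels = length(hs$mixture[hs$mixture > 0]),
               mixture_entropy = .mixture_entropy(hs$mixture),
               stringsAsFactors = FALSE)
  }))

  list(sites = sites, tes = tes, truth = truth, config = config)
}

#' Write the simulated tables to TSV fixture files
#'
#' Emits the same dialect [read_is_table()] / [read_te_table()] read.
#'
#' @param sim result of [simulate_is_data()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of `is.tsv`, `te.tsv`, `truth.tsv`.
#' @export
write_sim_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(is = file.path(dir, "is.tsv"), te = file.path(dir, "te.tsv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(sim$sites[c("chrom", "pos", "label")], paths["is"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tes, paths["te"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
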