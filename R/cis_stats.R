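# Per-CIS statistics: positional summaries, label-diversity entropies, and
# clustering significance under a uniform-placement null.
#
# The significance model: given M integration sites placed independently and
# uniformly on a genome of G base pairs, the p-value of a CIS of order O and
# dimension d is the binomial tail P[X >= O], X ~ Binomial(M, d/G) — the
# chance of seeing at least that many sites in a window of that length at
# the CIS locus.  The log-likelihood ratio contrasts the Poisson likelihood
# of O counts in d bp at the local MLE rate O/d against the global rate M/G.

#' Average CIS position
#'
#' The midpoint of the component: `(first + last) / 2` over the member
#' positions — insensitive to how the interior sites are distributed.
#'
#' @param pos sorted member positions (bp).
#' @return midpoint in bp (half-integers possible).
#' @export
average_position <- function(pos) {
  if (!length(pos)) stop_contract("a CIS has at least one member")
  (pos[1L] + pos[length(pos)]) / 2
}

#' Median CIS position
#'
#' The central member position (odd order) or the mean of the two central
#' positions (even order).  For components with an asymmetric spread of
#' sites this tracks the dense side, giving a more faithful locus estimate
#' than the midpoint.
#'
#' @param pos sorted member positions (bp).
#' @return median position in bp.
#' @export
median_position <- function(pos) {
  if (!length(pos)) stop_contract("a CIS has at least one member")
  stats::median(as.numeric(pos))
}

#' CIS dimension
#'
#' The number of base pairs containing all member sites: the inclusive span
#' `last - first + 1`, so a singleton CIS occupies 1 bp (a 0-bp interval
#' contains nothing).  `inclusive = FALSE` gives the open span
#' `last - first`.
#'
#' @param pos sorted member positions (bp).
#' @param inclusive use the inclusive span (default).
#' @return span in bp.
#' @export
cis_dimension <- function(pos, inclusive = TRUE) {
  if (!length(pos)) stop_contract("a CIS has at least one member")
  span <- pos[length(pos)] - pos[1L]
  if (inclusive) span + 1 else span
}

#' CIS entropy of the label mixture
#'
#' Shannon entropy of the entropy-label counts within a CIS, normalized by
#' `log(n)` where `n` is the number of distinct labels present, so the value
#' lies in `[0, 1]`: 0 for a single label, 1 when all labels are equally
#' frequent.  The log base cancels between numerator and normalizer.
#'
#' @param counts integer vector of per-label member counts (`n_i`), one
#'   entry per distinct label in the CIS.
#' @param order total member count `O`; defaults to `sum(counts)` and must
#'   equal it.
#' @return entropy in `[0, 1]`.
#' @examples
#' cis_entropy(c(A = 3, B = 1))   # 0.811278
#' cis_entropy(c(A = 2, B = 2))   # 1
#' @export
cis_entropy <- function(counts, order = sum(counts)) {
  counts <- counts[counts > 0]
  if (!length(counts) || any(counts != floor(counts)))
    stop_contract("label counts must be positive integers")
  if (!isTRUE(all.equal(sum(counts), order)))
    stop_contract("label counts must sum to the CIS order")
  n <- length(counts)
  if (n == 1L) return(0)          # log(1) = 0: no diversity, defined limit
  p <- counts / order
  -sum(p * log(p)) / log(n)
}

#' Normalized CIS entropy
#'
#' As [cis_entropy()], but normalized by `log(N)` where `N` is the number of
#' distinct labels in the *entire dataset*; labels absent from the CIS
#' contribute `0 * log 0 := 0`.  Since `N >= n`, the normalized entropy
#' never exceeds the CIS entropy, with equality iff `N = n` (or the CIS is
#' single-labelled, both being 0).
#'
#' @inheritParams cis_entropy
#' @param n_dataset_labels dataset-wide distinct label count `N`, `>= n`.
#' @return normalized entropy in `[0, 1]`.
#' @export
normalized_entropy <- function(counts, n_dataset_labels, order = sum(counts)) {
  counts <- counts[counts > 0]
  if (!isTRUE(all.equal(sum(counts), order)))
    stop_contract("label counts must sum to the CIS order")
  n <- length(counts)
  if (n_dataset_labels < n)
    stop_contract("dataset-wide label count N cannot be smaller than the CIS label count n")
  if (n_dataset_labels == 1L) return(0)
  p <- counts / order
  -sum(p * log(p)) / log(n_dataset_labels)
}

#' CIS clustering p-value (uniform-placement null)
#'
#' Probability, under independent uniform placement of all `total_is`
#' integration sites on a genome of `genome_size` bp, that a window of
#' length `dimension` at the CIS locus captures at least `order` sites:
#' the binomial tail `P[X >= order]`, `X ~ Binomial(total_is,
#' dimension / genome_size)`.  Decreasing in the order at fixed dimension,
#' increasing in the dimension at fixed order.
#'
#' @param order CIS order `O` (>= 1).
#' @param dimension CIS dimension `d` in bp (>= 1).
#' @param total_is dataset-wide integration-site count `M` (>= order).
#' @param genome_size genome length `G` in bp (>= dimension).
#' @return p-value in `(0, 1]`.
#' @export
cis_pvalue <- function(order, dimension, total_is, genome_size) {
  if (dimension > genome_size) stop_param("dimension cannot exceed the genome size")
  if (order < 1 || dimension < 1) stop_param("order and dimension must be >= 1")
  if (total_is < order) stop_param("total_is must be at least the CIS order")
  stats::pbinom(order - 1, size = total_is, prob = dimension / genome_size,
                lower.tail = FALSE)
}

#' CIS log-likelihood ratio (Poisson local vs global rate)
#'
#' `2 * [l1 - l0]` where `l0` is the Poisson log-likelihood of `order`
#' counts in `dimension` bp at the global rate `total_is / genome_size` and
#' `l1` the same at the local MLE rate `order / dimension`.  Zero exactly
#' when the local rate equals the global rate; positive otherwise.
#'
#' @inheritParams cis_pvalue
#' @return log-likelihood ratio, `>= 0`.
#' @export
cis_loglik_ratio <- function(order, dimension, total_is, genome_size) {
  if (dimension > genome_size) stop_param("dimension cannot exceed the genome size")
  if (order < 1 || dimension < 1) stop_param("order and dimension must be >= 1")
  mu0 <- total_is * dimension / genome_size
  max(0, 2 * (order * log(order / mu0) - (order - mu0)))
}

#' Compute the statistics record of every CIS
#'
#' Fills each CIS's `stats` slot with: order, dimension, average and median
#' position, distinct-label count, per-label counts, entropy, normalized
#' entropy, p-value and log-likelihood ratio.  Dataset-wide quantities (the
#' distinct label count `N`, total site count `M`, genome size `G`) come
#' from `sites` — the full dataset the CIS were called from — so that
#' normalized entropy and significance are computed against the whole
#' experiment, not just the clustered subset.
#'
#' @param cis_set a `cis_set` from [cis_components()].
#' @param sites the full site table the components were extracted from.
#' @param genome_size genome length in bp; defaults to the sum over
#'   chromosomes of the maximum observed position (a conservative
#'   data-driven proxy when the true assembly size is not supplied).
#' @param per_chromosome if `TRUE`, significance uses the chromosome-local
#'   site count and chromosome length instead of the genome-wide ones.
#' @param fdr if `TRUE`, add a Benjamini-Hochberg adjusted p-value
#'   (`p_adj`) across the CIS set.
#' @param span_inclusive dimension convention, see [cis_dimension()].
#' @return the `cis_set` with `stats` populated.
#' @export
compute_cis_stats <- function(cis_set, sites, genome_size = NULL,
                              per_chromosome = FALSE, fdr = FALSE,
                              span_inclusive = TRUE) {
  sites <- validate_sites(sites)
  N <- length(unique(sites$label))
  chrom_max <- tapply(sites$pos, sites$chrom, max)
  if (is.null(genome_size)) genome_size <- sum(chrom_max)
  if (genome_size < max(sites$pos))
    stop_param("genome_size is smaller than the largest observed position")
  M_total <- nrow(sites)
  chrom_n <- table(sites$chrom)
  for (k in seq_along(cis_set)) {
    cis <- cis_set[[k]]
    pos <- sort(cis$members$pos)
    counts <- table(cis$members$label)
    O <- length(pos)
    d <- cis_dimension(pos, inclusive = span_inclusive)
    d_eff <- max(d, 1)            # exclusive-span singletons still need d >= 1 for the null
    if (per_chromosome) {
      M <- as.integer(chrom_n[[cis$chrom]])
      G <- as.numeric(chrom_max[[cis$chrom]])
    } else {
      M <- M_total
      G <- genome_size
    }
    cis$stats <- list(
      order = O,
      dimension = d,
      avg_pos = average_position(pos),
      median_pos = median_position(pos),
      n_labels = length(counts),
      label_counts = stats::setNames(as.integer(counts), names(counts)),
      entropy = cis_entropy(as.integer(counts), O),
      norm_entropy = normalized_entropy(as.integer(counts), N, O),
      p_value = cis_pvalue(O, d_eff, M, G),
      loglik_ratio = cis_loglik_ratio(O, d_eff, M, G))
    cis_set[[k]] <- cis
  }
  if (fdr) {
    p <- vapply(cis_set, function(x) x$stats$p_value, numeric(1))
    p_adj <- stats::p.adjust(p, method = "BH")
    for (k in seq_along(cis_set)) cis_set[[k]]$stats$p_adj <- p_adj[k]
  }
  cis_set
}

#' Flatten a `cis_set` to a one-row-per-CIS data.frame
#'
#' @param x a `cis_set` (statistics computed; basic columns only otherwise).
#' @param row.names,optional,... ignored (base-generic signature).
#' @return data.frame with the CIS result-table columns, including the
#'   member positions as a comma-separated string.
#' @export
as.data.frame.cis_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!length(x)) {
    return(data.frame(cis_number = integer(0), cis_name = character(0),
                      chrom = character(0), order = integer(0),
                      dimension = numeric(0), avg_pos = numeric(0),
                      median_pos = numeric(0), n_labels = integer(0),
                      entropy = numeric(0), norm_entropy = numeric(0),
                      p_value = numeric(0), loglik_ratio = numeric(0),
                      is_positions = character(0)))
  }
  has_stats <- !is.null(x[[1]]$stats)
  getstat <- function(field) vapply(x, function(c) c$stats[[field]], numeric(1))
  df <- data.frame(
    cis_number = vapply(x, `[[`, integer(1), "number"),
    cis_name = vapply(x, `[[`, character(1), "name"),
    chrom = vapply(x, `[[`, character(1), "chrom"),
    order = vapply(x, function(c) nrow(c$members), integer(1)),
    stringsAsFactors = FALSE)
  if (has_stats) {
    df$dimension <- getstat("dimension")
    df$avg_pos <- getstat("avg_pos")
    df$median_pos <- getstat("median_pos")
    df$n_labels <- vapply(x, function(c) as.integer(c$stats$n_labels), integer(1))
    df$entropy <- getstat("entropy")
    df$norm_entropy <- getstat("norm_entropy")
    df$p_value <- getstat("p_value")
    df$loglik_ratio <- getstat("loglik_ratio")
    if (!is.null(x[[1]]$stats$p_adj)) df$p_adj <- getstat("p_adj")
  }
  df$is_positions <- vapply(x, function(c)
    paste(format(c$members$pos, scientific = FALSE, trim = TRUE), collapse = ","),
    character(1))
  df
}
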