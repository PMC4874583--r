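# The graph-based CIS caller.  A node per integration site; an edge joins
# two same-chromosome sites whose distance is below the threshold; a CIS is
# a connected component.  Because the sites are sorted per chromosome, the
# components are equivalently determined by consecutive gaps (single-linkage
# at the cut height = threshold), so two routes are provided and must agree:
#   - build_is_graph() materializes the explicit edge list (sliding window
#     over the sorted positions, identical output to the all-pairs loop);
#     cis_components() on the graph runs union-find over those edges;
#   - cis_components() on a plain site table runs the linear gap scan.

#' Build the integration-site proximity graph
#'
#' One node per integration site; an undirected edge for every
#' same-chromosome pair at distance strictly below `threshold` base pairs
#' (`|pos_u - pos_v| < threshold`; set `inclusive = TRUE` for `<=`
#' semantics).  Sites must already be in canonical (chrom, pos) order; the
#' construction slides a window over the sorted positions and is exactly
#' equivalent to comparing all pairs.
#'
#' @param sites site table sorted by (chrom, pos), as returned by
#'   [read_is_table()] or [sort_sites()].
#' @param threshold edge distance threshold in base pairs, >= 1.
#' @param inclusive if `TRUE`, a pair at distance exactly `threshold` is
#'   also edged.
#' @return an object of class `is_graph`: list with `sites`, `edges`
#'   (data.frame of node index pairs `from` < `to`, plus their `row_id`s and
#'   `distance`), `threshold`, `inclusive`.
#' @examples
#' s <- sort_sites(data.frame(chrom = "chr1", pos = c(100, 150, 5000), label = "t"))
#' g <- build_is_graph(s, threshold = 1000)
#' g$edges   # single edge: 100--150
#' @export
build_is_graph <- function(sites, threshold, inclusive = FALSE) {
  sites <- validate_sites(sites, require_sorted = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 1)
    stop_param("threshold must be a single number >= 1")
  n <- nrow(sites)
  from <- vector("list", n)
  key <- chrom_sort_key(sites$chrom)
  pos <- sites$pos
  lo <- 1L
  for (i in seq_len(n)) {
    if (i > 1L && key[i] != key[i - 1L]) lo <- i
    while (lo < i && (if (inclusive) pos[i] - pos[lo] > threshold
                      else pos[i] - pos[lo] >= threshold)) lo <- lo + 1L
    if (lo < i) from[[i]] <- lo:(i - 1L)
  }
  to <- rep.int(seq_len(n), lengths(from))
  from <- unlist(from, use.names = FALSE)
  if (is.null(from)) from <- integer(0)
  edges <- data.frame(from = from, to = to,
                      from_row_id = sites$row_id[from], to_row_id = sites$row_id[to],
                      distance = pos[to] - pos[from])
  structure(list(sites = sites, edges = edges, threshold = threshold,
                 inclusive = inclusive),
            class = "is_graph")
}

#' @export
print.is_graph <- function(x, ...) {
  cat(sprintf("is_graph: %d integration sites, %d edges (distance %s %s bp)\n",
              nrow(x$sites), nrow(x$edges), if (x$inclusive) "<=" else "<",
              format(x$threshold, big.mark = ",")))
  invisible(x)
}

# Union-find with path compression + union by size, over an explicit edge list.
.union_find <- function(n, from, to) {
  parent <- seq_len(n)
  size <- rep.int(1L, n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (e in seq_along(from)) {
    ra <- find(from[e]); rb <- find(to[e])
    if (ra != rb) {
      if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      parent[rb] <- ra
      size[ra] <- size[ra] + size[rb]
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Linear gap scan over canonically sorted sites: a new component starts at a
# chromosome change or where the consecutive gap reaches the threshold.
.gap_scan <- function(sites, threshold, inclusive) {
  n <- nrow(sites)
  if (n == 0L) return(integer(0))
  key <- chrom_sort_key(sites$chrom)
  gap <- c(Inf, sites$pos[-1L] - sites$pos[-n])
  new_chrom <- c(TRUE, key[-1L] != key[-n])
  breaks <- new_chrom | (if (inclusive) gap > threshold else gap >= threshold)
  cumsum(breaks)
}

#' Extract common integration sites as connected components
#'
#' Partitions the proximity graph into its maximal connected components;
#' each component is one CIS.  Singleton components are returned too —
#' restricting to truly "common" sites (order >= 2) is the separate,
#' explicit [filter_by_order()] step.
#'
#' Accepts either an `is_graph` (components found by union-find over the
#' explicit edge list) or a sorted site table plus `threshold` (linear
#' consecutive-gap scan, the single-linkage shortcut valid on a sorted 1-D
#' axis).  The two routes produce identical partitions.
#'
#' @param x an `is_graph` from [build_is_graph()], or a site table.
#' @param threshold required when `x` is a site table; see [build_is_graph()].
#' @param inclusive see [build_is_graph()]; ignored when `x` is an `is_graph`.
#' @return an object of class `cis_set`: a list of CIS, each a list with
#'   `number`, `name` (`"<chrom>_<number>"`), `chrom`, `members` (site rows
#'   sorted by position) and `stats` (`NULL` until [compute_cis_stats()]).
#'   Components are ordered by (chromosome, first member position) and
#'   numbered sequentially from 1.
#' @examples
#' s <- sort_sites(data.frame(chrom = "chr1", pos = c(0, 900, 1800, 2700) + 1,
#'                            label = "t"))
#' length(cis_components(s, threshold = 1000))  # one chained component of 4
#' @export
cis_components <- function(x, threshold = NULL, inclusive = FALSE) {
  if (inherits(x, "is_graph")) {
    sites <- x$sites
    comp <- .union_find(nrow(sites), x$edges$from, x$edges$to)
  } else {
    sites <- validate_sites(x, require_sorted = TRUE)
    if (is.null(threshold)) stop_param("threshold is required when passing a site table")
    if (!is.numeric(threshold) || threshold < 1) stop_param("threshold must be >= 1")
    comp <- .gap_scan(sites, threshold, inclusive)
  }
  if (!nrow(sites)) return(structure(list(), class = "cis_set"))
  # order component ids by (chrom, min member position); sites are sorted, so
  # the first occurrence index of each id gives that ordering
  first_idx <- match(unique(comp), comp)
  ids <- unique(comp)[order(first_idx)]
  cis <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    members <- sites[comp == ids[k], , drop = FALSE]
    rownames(members) <- NULL
    cis[[k]] <- list(number = k,
                     name = paste0(members$chrom[1], "_", k),
                     chrom = members$chrom[1],
                     members = members,
                     stats = NULL)
  }
  structure(cis, class = "cis_set")
}

#' Keep CIS of at least a given order
#'
#' A component of order 1 is a lone integration site, not a *common* one;
#' this explicit filter retains components with `order >= min_order` and
#' renumbers them sequentially (preserving their order), regenerating names.
#'
#' @param cis_set a `cis_set`.
#' @param min_order minimum number of member integration sites, >= 1.
#' @return filtered, renumbered `cis_set`.
#' @export
filter_by_order <- function(cis_set, min_order = 2L) {
  if (!is.numeric(min_order) || min_order < 1) stop_param("min_order must be >= 1")
  keep <- vapply(cis_set, function(x) nrow(x$members) >= min_order, logical(1))
  out <- cis_set[keep]
  for (k in seq_along(out)) {
    out[[k]]$number <- k
    out[[k]]$name <- paste0(out[[k]]$chrom, "_", k)
  }
  structure(out, class = "cis_set")
}

#' @export
print.cis_set <- function(x, ...) {
  orders <- vapply(x, function(c) nrow(c$members), integer(1))
  cat(sprintf("cis_set: %d CIS over %d chromosome(s); orders: %s\n",
              length(x), length(unique(vapply(x, `[[`, character(1), "chrom"))),
              if (length(x)) paste(range(orders), collapse = "-") else "-"))
  invisible(x)
}

#' Component membership vector of a `cis_set`
#'
#' @param cis_set a `cis_set`.
#' @return named integer vector mapping each member `row_id` to its CIS
#'   number — convenient for partition comparisons.
#' @export
cis_membership <- function(cis_set) {
  if (!length(cis_set)) return(stats::setNames(integer(0), character(0)))
  ids <- unlist(lapply(cis_set, function(x) x$members$row_id), use.names = FALSE)
  num <- rep.int(vapply(cis_set, `[[`, integer(1), "number"),
                 vapply(cis_set, function(x) nrow(x$members), integer(1)))
  stats::setNames(num, ids)
}

#' Export the proximity graph as an edge-list TSV
#'
#' @param graph an `is_graph`.
#' @param path output path.  Columns: from_row_id, to_row_id, chrom,
#'   from_pos, to_pos, distance.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  df <- data.frame(from_row_id = e$from_row_id, to_row_id = e$to_row_id,
                   chrom = graph$sites$chrom[e$from],
                   from_pos = graph$sites$pos[e$from],
                   to_pos = graph$sites$pos[e$to],
                   distance = e$distance)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export the proximity graph as GraphML (Cytoscape interoperability)
#'
#' @param graph an `is_graph`.
#' @param path output path (`.graphml`).
#' @export
write_graphml <- function(graph, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop_param("GraphML export requires the 'igraph' package")
  s <- graph$sites
  vertices <- data.frame(name = as.character(s$row_id), chrom = s$chrom,
                         pos = s$pos, label = s$label)
  edges <- data.frame(from = as.character(s$row_id[graph$edges$from]),
                      to = as.character(s$row_id[graph$edges$to]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
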