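# Reading and writing the tabular interchange formats: integration-site
# tables (TSV/CSV/BED), transcriptional-element (TSS) tables, and the CIS /
# gene-atmosphere result tables.
#
# Internal coordinates are 1-based inclusive base-pair positions (the base
# pair where the provirus sits).  BED input, being 0-based half-open, is
# converted on read: position = start + 1; for annotation BED on the minus
# strand the TSS is the end coordinate.

# Header synonyms accepted for each mandatory column, after lower-casing and
# squashing non-alphanumerics to "_" (covers e.g. "Chromosome number",
# "Insertion site position", BioMart-style export headers).
.is_col_synonyms <- list(
  chrom = c("chrom", "chr", "chromosome", "chromosome_number", "chromosome_name", "seqnames"),
  pos   = c("pos", "position", "insertion_site_position", "insertion_position",
            "integration_position", "location", "start"),
  label = c("label", "entropy_label", "entropy_label_e_g_kind_of_tumor_virus_type",
            "tumor_type", "tumor_model", "virus_type", "kind_of_tumor")
)

.te_col_synonyms <- list(
  chrom = c("chrom", "chr", "chromosome", "chromosome_number", "chromosome_name", "seqnames"),
  tss   = c("tss", "transcription_start_site", "transcript_start_bp", "transcription_start",
            "start", "txstart"),
  name  = c("name", "gene", "gene_name", "gene_symbol", "symbol", "associated_gene_name",
            "external_gene_name", "te_name")
)

.norm_header <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(trimws(x))))

# Resolve mandatory columns by header synonym or explicit col_map
# (named character/integer vector, e.g. c(chrom = 1, pos = 2, label = "Tumor")).
.resolve_columns <- function(header, synonyms, col_map = NULL, required = names(synonyms)) {
  idx <- stats::setNames(rep(NA_integer_, length(synonyms)), names(synonyms))
  norm <- .norm_header(header)
  for (field in names(synonyms)) {
    if (!is.null(col_map) && field %in% names(col_map)) {
      v <- col_map[[field]]
      idx[field] <- if (is.numeric(v)) as.integer(v) else match(.norm_header(v), norm)
    } else {
      hit <- which(norm %in% synonyms[[field]])
      if (length(hit)) idx[field] <- hit[1]
    }
  }
  miss <- intersect(required, names(idx)[is.na(idx)])
  if (length(miss))
    stop_schema(sprintf("cannot resolve mandatory column '%s' (header: %s)",
                        miss[1], paste(header, collapse = ", ")))
  idx
}

.read_delim <- function(path, dialect) {
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  df
}

.read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_param("BED input requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),   # rtracklayer shifts to 1-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$name <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  df
}

#' Read an integration-site table
#'
#' Reads a delimited (TSV/CSV, with header) or BED file of viral integration
#' events into the canonical site table: one row per event with columns
#' `chrom`, `pos` (1-based base pair), `label` (the entropy label, e.g.
#' tumour model or virus type) and `row_id` (origin row index).  Rows are
#' returned sorted by (chromosome, position) — the data-preparation ordering
#' the downstream sliding-window graph construction exploits — so the output
#' order is independent of the input row order.
#'
#' Duplicate (chrom, pos, label) rows are retained as distinct events and
#' reported via a message (set `quiet = TRUE` to silence).
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"csv"`, `"bed"`.  For BED, the 0-based
#'   half-open `start` is converted to a 1-based position (`start + 1`).
#' @param col_map optional named vector mapping `chrom`/`pos`/`label` to a
#'   header name or column index, overriding header-synonym matching.
#' @param label_from for BED input, where the entropy label comes from:
#'   `"name"` (the BED name field, default) or a constant string to assign
#'   to every row.
#' @param normalize_chrom drop a leading `"chr"` prefix so mixed-source
#'   datasets compare on equal names.
#' @param quiet suppress the duplicate-row report.
#' @return data.frame with columns `chrom`, `pos`, `label`, `row_id`, sorted
#'   by (chrom, pos).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tlabel", "chr2\t500\ttumA",
#'              "chr1\t100\ttumA", "chr1\t900\ttumB"), tf)
#' read_is_table(tf)
#' @export
read_is_table <- function(path, dialect = c("tsv", "csv", "bed"), col_map = NULL,
                          label_from = "name", normalize_chrom = FALSE,
                          quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_param(sprintf("file not found: %s", path))
  if (dialect == "bed") {
    bed <- .read_bed(path)
    if (nrow(bed) == 0L) stop_schema("integration-site dataset is empty")
    label <- if (identical(label_from, "name")) {
      if (all(is.na(bed$name)))
        stop_schema("BED input has no name field to take the entropy label from; pass a constant via label_from")
      bed$name
    } else rep(as.character(label_from), nrow(bed))
    sites <- data.frame(chrom = bed$chrom, pos = bed$start, label = label,
                        stringsAsFactors = FALSE)
  } else {
    df <- .read_delim(path, dialect)
    if (nrow(df) == 0L) stop_schema("integration-site dataset is empty")
    idx <- .resolve_columns(names(df), .is_col_synonyms, col_map)
    sites <- data.frame(chrom = df[[idx["chrom"]]], pos = df[[idx["pos"]]],
                        label = df[[idx["label"]]], stringsAsFactors = FALSE)
  }
  sites$chrom <- normalize_chrom(sites$chrom, normalize_chrom)
  sites$row_id <- seq_len(nrow(sites))
  sites <- validate_sites(sites)
  dup <- duplicated(sites[c("chrom", "pos", "label")])
  if (any(dup) && !quiet)
    message(sprintf("%d duplicate (chrom, pos, label) row(s) retained as distinct integration events",
                    sum(dup)))
  sites
}

#' Read a transcriptional-element (TSS) table
#'
#' Reads an annotation table in the shape of a BioMart export — one row per
#' transcriptional element with its chromosome and transcription start site —
#' or a BED file.  For BED input the TSS is the 1-based start on the `+` (or
#' unstranded) strand and the end coordinate on the `-` strand.
#'
#' @inheritParams read_is_table
#' @param col_map optional named vector mapping `chrom`/`tss`/`name` to a
#'   header name or column index.
#' @return data.frame with columns `chrom`, `tss`, `name`, sorted by
#'   (chrom, tss).  Missing names are auto-generated as `TE_<k>`.
#' @export
read_te_table <- function(path, dialect = c("tsv", "csv", "bed"), col_map = NULL,
                          normalize_chrom = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_param(sprintf("file not found: %s", path))
  if (dialect == "bed") {
    bed <- .read_bed(path)
    if (nrow(bed) == 0L) stop_schema("annotation dataset is empty")
    tss <- ifelse(bed$strand == "-", bed$end, bed$start)
    tes <- data.frame(chrom = bed$chrom, tss = tss, name = bed$name,
                      stringsAsFactors = FALSE)
  } else {
    df <- .read_delim(path, dialect)
    if (nrow(df) == 0L) stop_schema("annotation dataset is empty")
    idx <- .resolve_columns(names(df), .te_col_synonyms, col_map,
                            required = c("chrom", "tss"))
    tes <- data.frame(chrom = df[[idx["chrom"]]], tss = df[[idx["tss"]]],
                      name = if (!is.na(idx["name"])) df[[idx["name"]]] else NA_character_,
                      stringsAsFactors = FALSE)
  }
  tes$chrom <- normalize_chrom(tes$chrom, normalize_chrom)
  validate_tes(tes)
}

# Format a parameter header block ("# key=value" lines) for result tables.
.param_header <- function(params) {
  if (is.null(params) || !length(params)) return(character())
  vapply(names(params), function(k) sprintf("# %s=%s", k, as.character(params[[k]])),
         character(1))
}

#' Write a CIS result table
#'
#' One row per CIS with the computed statistics: number, name, chromosome,
#' order, dimension, average and median position, entropy, normalized
#' entropy, p-value, log-likelihood ratio, and the member integration-site
#' positions (comma-separated).  Run parameters passed via `params` are
#' echoed as `# key=value` header lines for provenance; the significance
#' columns carry the `null=uniform-binomial` tag there.
#'
#' @param cis_set a `cis_set` with statistics computed (see
#'   [compute_cis_stats()]).
#' @param path output file path.
#' @param params optional named list echoed into `#` comment headers.
#' @param sep field separator (default TAB).
#' @return invisibly, the data.frame written.
#' @export
write_cis_table <- function(cis_set, path, params = NULL, sep = "\t") {
  df <- as.data.frame(cis_set)
  hdr <- .param_header(c(list(null = "uniform-binomial"), params))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(df)) {
    df$avg_pos <- sprintf("%.1f", df$avg_pos)
    df$median_pos <- sprintf("%.1f", df$median_pos)
    for (col in c("entropy", "norm_entropy", "loglik_ratio"))
      df[[col]] <- sprintf("%.6g", df[[col]])
    df$p_value <- sprintf("%.6e", df$p_value)
  }
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read back a CIS result table written by [write_cis_table()]
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame with one row per CIS; numeric columns parsed.
#' @export
read_cis_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  num <- c("cis_number", "order", "dimension", "n_labels", "avg_pos", "median_pos",
           "entropy", "norm_entropy", "p_value", "loglik_ratio")
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a gene-atmosphere link table
#'
#' One row per (CIS, integration site, transcriptional element) link with the
#' IS position, the TSS and their distance.
#'
#' @param ga_list a `gene_atmosphere` list (see [build_gene_atmosphere()]).
#' @param path output file path.
#' @param params optional named list echoed into `#` comment headers.
#' @param sep field separator.
#' @return invisibly, the data.frame written.
#' @export
write_ga_table <- function(ga_list, path, params = NULL, sep = "\t") {
  df <- as.data.frame(ga_list)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.param_header(params), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a plain gene list (one symbol per line)
#'
#' The deduplicated gene-atmosphere gene set in the plain-text shape that
#' functional-annotation web tools accept as input.
#'
#' @param genes character vector of gene names.
#' @param path output file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(as.character(genes))), path)
  invisible(genes)
}

#' Write CIS intervals as BED for genome-browser use
#'
#' Each CIS becomes one BED feature spanning its first to last member
#' integration site (`chromStart = first - 1`, 0-based half-open), named
#' after the CIS, scored by its order.
#'
#' @param cis_set a `cis_set`.
#' @param path output file path.
#' @export
write_cis_bed <- function(cis_set, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_param("BED output requires the 'rtracklayer' package")
  if (!length(cis_set)) {
    writeLines(character(), path)
    return(invisible(NULL))
  }
  chrom <- vapply(cis_set, function(x) x$chrom, character(1))
  first <- vapply(cis_set, function(x) min(x$members$pos), numeric(1))
  last <- vapply(cis_set, function(x) max(x$members$pos), numeric(1))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(first, last),
                               name = vapply(cis_set, function(x) x$name, character(1)),
                               score = vapply(cis_set, function(x) nrow(x$members), numeric(1)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(gr)
}
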