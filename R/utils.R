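# Shared internal helpers: classed error conditions, chromosome ordering,
# table validation.  Every user-facing function funnels its input through
# validate_sites()/validate_tes() so the canonical (chrom, pos) ordering is
# a package-wide invariant rather than a per-function convention.

stop_schema <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("cisgraph_schema_error", "cisgraph_error", "error"),
                      call = call))
}

stop_param <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("cisgraph_param_error", "cisgraph_error", "error"),
                      call = call))
}

stop_contract <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("cisgraph_contract_error", "cisgraph_error", "error"),
                      call = call))
}

#' Canonical chromosome sort key
#'
#' Orders chromosome names the way genome browsers do: numeric chromosomes
#' first in numeric order, then X, Y, M/MT, then any other names
#' alphabetically.  An optional "chr" prefix is ignored for ranking (but
#' preserved in the data).
#'
#' @param chrom character vector of chromosome names.
#' @return a character vector of sort keys; `order(chrom_sort_key(x))` gives
#'   the canonical ordering.
#' @keywords internal
chrom_sort_key <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.integer(core))
  spec <- match(toupper(core), c("X", "Y", "M", "MT"))
  grp <- ifelse(!is.na(num), 0L, ifelse(!is.na(spec), 1L, 2L))
  within <- ifelse(!is.na(num), sprintf("%09d", num),
                   ifelse(!is.na(spec), sprintf("%09d", spec), toupper(core)))
  paste0(grp, "_", within)
}

#' Strip or keep the "chr" prefix of chromosome names
#'
#' @param chrom character vector.
#' @param normalize if `TRUE`, drop a leading "chr"/"Chr" so that mixed-source
#'   inputs (e.g. RTCGD-style "12" vs BioMart-style "chr12") compare equal.
#' @return character vector.
#' @keywords internal
normalize_chrom <- function(chrom, normalize = FALSE) {
  chrom <- as.character(chrom)
  if (normalize) sub("^chr", "", chrom, ignore.case = TRUE) else chrom
}

# Order rows of a site/TE table canonically by (chromosome, position).
canonical_order <- function(chrom, pos, tiebreak = seq_along(pos)) {
  order(chrom_sort_key(chrom), pos, tiebreak)
}

#' Validate an integration-site table
#'
#' Checks the mandatory columns (`chrom`, `pos`, `label`, `row_id`), their
#' invariants (positions >= 1, non-empty chromosome and label, unique row
#' ids) and, optionally, that rows are in canonical (chrom, pos) order.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `label` and
#'   optionally `row_id` (added as the current row index when absent).
#' @param require_sorted error (contract violation) if rows are not in
#'   canonical order instead of silently reordering.
#' @return the validated data.frame, sorted canonically.
#' @keywords internal
validate_sites <- function(sites, require_sorted = FALSE) {
  if (!is.data.frame(sites))
    stop_schema("integration-site input must be a data.frame")
  for (col in c("chrom", "pos", "label")) {
    if (!col %in% names(sites))
      stop_schema(sprintf("missing mandatory column '%s' in integration-site table", col))
  }
  if (nrow(sites) == 0L)
    stop_schema("integration-site dataset is empty")
  if (!"row_id" %in% names(sites)) sites$row_id <- seq_len(nrow(sites))
  sites$chrom <- as.character(sites$chrom)
  sites$label <- trimws(as.character(sites$label))
  pos <- suppressWarnings(as.numeric(sites$pos))
  bad <- which(!is.finite(pos) | pos != floor(pos))
  if (length(bad))
    stop_schema(sprintf("non-integer insertion position at row %d ('%s')",
                        bad[1], as.character(sites$pos[bad[1]])))
  sites$pos <- as.numeric(pos)
  if (any(sites$pos < 1))
    stop_schema(sprintf("insertion position < 1 at row %d", which(sites$pos < 1)[1]))
  if (any(!nzchar(sites$chrom)))
    stop_schema(sprintf("empty chromosome at row %d", which(!nzchar(sites$chrom))[1]))
  if (any(!nzchar(sites$label)))
    stop_schema(sprintf("empty entropy label at row %d", which(!nzchar(sites$label))[1]))
  if (anyDuplicated(sites$row_id))
    stop_schema("row_id values must be unique within a dataset")
  ord <- canonical_order(sites$chrom, sites$pos, sites$row_id)
  if (require_sorted && !identical(ord, seq_len(nrow(sites))))
    stop_contract("sites must be sorted by (chrom, pos); call read_is_table() or sort_sites() first")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Validate a transcriptional-element table
#'
#' @param tes data.frame with columns `chrom`, `tss` and optionally `name`
#'   (auto-filled as `TE_<k>` when absent or empty).
#' @return validated data.frame sorted by (chrom, tss).
#' @keywords internal
validate_tes <- function(tes) {
  if (!is.data.frame(tes))
    stop_schema("annotation input must be a data.frame")
  for (col in c("chrom", "tss")) {
    if (!col %in% names(tes))
      stop_schema(sprintf("missing mandatory column '%s' in annotation table", col))
  }
  tes$chrom <- as.character(tes$chrom)
  tss <- suppressWarnings(as.numeric(tes$tss))
  bad <- which(!is.finite(tss) | tss != floor(tss))
  if (length(bad))
    stop_schema(sprintf("non-integer transcription start site at row %d", bad[1]))
  tes$tss <- as.numeric(tss)
  if (any(tes$tss < 1))
    stop_schema(sprintf("transcription start site < 1 at row %d", which(tes$tss < 1)[1]))
  if (!"name" %in% names(tes)) tes$name <- NA_character_
  tes$name <- trimws(as.character(tes$name))
  missing_name <- is.na(tes$name) | !nzchar(tes$name)
  tes$name[missing_name] <- paste0("TE_", which(missing_name))
  ord <- canonical_order(tes$chrom, tes$tss)
  tes <- tes[ord, , drop = FALSE]
  rownames(tes) <- NULL
  tes
}

#' Sort an integration-site table canonically
#'
#' Orders rows by chromosome (numeric first, then X, Y, M) and position,
#' the preparation step that the sliding-window edge construction relies on.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `label`.
#' @return the same rows sorted by (chrom, pos), with a `row_id` column.
#' @export
sort_sites <- function(sites) validate_sites(sites)
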