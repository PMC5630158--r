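#' Sequence origin groups
#'
#' The seven origin groups of the assayed library: human sequences split by
#' transcript location (5' UTR, 3' UTR, CDS) and viral sequences split by
#' Baltimore class ((+) ssRNA, (-) ssRNA, dsRNA, retroviruses).  The
#' pseudo-group `"all"` denotes the union and is accepted wherever a group
#' label selects sequences, but is never a valid record label.
#'
#' @return character vector of the 7 group labels.
#' @export
ires_groups <- function() {
  c("human_5utr", "human_3utr", "human_cds",
    "ssrna_plus", "ssrna_minus", "dsrna", "retro")
}

#' Construct a validated IRES sequence library
#'
#' Builds the standard library container: one row per assayed RNA sequence
#' with its measured activity, origin group, activity call against the
#' detection threshold, and the AUG anchor (`aug_offset`, the number of
#' bases 5' of the reporter start AUG; by default the whole sequence lies
#' upstream, i.e. its 3' end abuts the AUG).
#'
#' DNA input (T) is transliterated to RNA (U).  Records whose sequence
#' contains characters outside ACGU(T) are dropped with a warning and
#' reported in the `"rejected"` attribute.  Unknown group labels are an
#' error.
#'
#' @param id character vector of unique sequence identifiers.
#' @param rna character vector of sequences (RNA or DNA alphabet).
#' @param group character vector of group labels (see [ires_groups()]).
#' @param activity numeric measured IRES activity (assay expression units).
#' @param threshold detection floor; `active` is `activity > threshold`.
#' @param aug_offset integer position immediately 5' of the start AUG
#'   (defaults to sequence length).
#' @return a `data.frame` of class `ires_library` with columns `id`, `rna`,
#'   `group`, `activity`, `active`, `aug_offset`; the threshold is kept in
#'   the `"threshold"` attribute.
#' @export
ires_library <- function(id, rna, group, activity, threshold,
                         aug_offset = NULL) {
  id <- as.character(id)
  rna <- as_rna(as.character(rna))
  group <- as.character(group)
  stopifnot(length(rna) == length(id), length(group) == length(id),
            length(activity) == length(id))
  if (anyDuplicated(id)) stop("duplicate sequence ids")
  bad_group <- setdiff(unique(group), ires_groups())
  if (length(bad_group) > 0)
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold))
    stop("threshold must be a single finite number")
  if (is.null(aug_offset)) aug_offset <- nchar(rna)
  aug_offset <- as.integer(aug_offset)

  ok <- is_valid_rna(rna) & is.finite(activity) &
    aug_offset >= 1 & aug_offset <= nchar(rna)
  rejected <- data.frame(
    id = id[!ok],
    reason = ifelse(!is_valid_rna(rna[!ok]), "non-ACGUT character",
                    ifelse(!is.finite(activity[!ok]), "non-finite activity",
                           "aug_offset out of range")),
    stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " record(s) rejected: ",
            paste(utils::head(rejected$id, 5), collapse = ", "),
            if (nrow(rejected) > 5) ", ...")

  out <- data.frame(id = id[ok], rna = rna[ok], group = group[ok],
                    activity = as.numeric(activity[ok]),
                    active = activity[ok] > threshold,
                    aug_offset = aug_offset[ok],
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "rejected") <- rejected
  class(out) <- c("ires_library", "data.frame")
  out
}

#' Load a sequence/activity library from TSV (+ optional FASTA)
#'
#' The table must carry columns `id`, `group` and `activity`; sequences come
#' either from a `sequence` column or from a companion FASTA keyed by `id`.
#' Every table row must have a sequence (a missing FASTA cross-reference is
#' an error).  Validation and alphabet handling are as in [ires_library()].
#'
#' @param table_path path to the TSV library table.
#' @param fasta_path optional path to a FASTA file with the sequences.
#' @param threshold detection floor in activity units.
#' @return an `ires_library` (see [ires_library()]).
#' @export
load_library <- function(table_path, fasta_path = NULL, threshold) {
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("id", "group", "activity")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("library table lacks column(s): ", paste(miss, collapse = ", "))
  tab$id <- as.character(tab$id)
  if (!is.null(fasta_path)) {
    fa <- Biostrings::readBStringSet(fasta_path)
    seqs <- as.character(fa)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    hit <- match(tab$id, names(seqs))
    if (anyNA(hit))
      stop("sequence id(s) missing from FASTA: ",
           paste(utils::head(tab$id[is.na(hit)], 5), collapse = ", "))
    rna <- unname(seqs[hit])
  } else if ("sequence" %in% names(tab)) {
    rna <- tab$sequence
  } else {
    stop("no `sequence` column and no FASTA file given")
  }
  aug <- if ("aug_offset" %in% names(tab)) tab$aug_offset else NULL
  ires_library(tab$id, rna, tab$group, tab$activity, threshold,
               aug_offset = aug)
}

#' Write a library back to TSV (+ optional FASTA)
#'
#' Activities are written with 17 significant digits so that a
#' load/write/load round trip reproduces them to full double precision.
#'
#' @param records an `ires_library`.
#' @param table_path output TSV path.
#' @param fasta_path optional output FASTA path; when given, the TSV omits
#'   the `sequence` column.
#' @return `table_path`, invisibly.
#' @export
write_library <- function(records, table_path, fasta_path = NULL) {
  tab <- data.frame(id = records$id, group = records$group,
                    activity = sprintf("%.17g", records$activity),
                    aug_offset = records$aug_offset,
                    stringsAsFactors = FALSE)
  if (is.null(fasta_path)) {
    tab$sequence <- records$rna
  } else {
    rs <- Biostrings::RNAStringSet(records$rna)
    names(rs) <- records$id
    Biostrings::writeXStringSet(rs, fasta_path)
  }
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table_path)
}

#' Partition a library by origin group
#'
#' @param records an `ires_library` (or compatible data.frame).
#' @return a named list with one `ires_library` per group in
#'   [ires_groups()] (possibly empty) plus the `all` pseudo-group holding
#'   every record.
#' @export
partition_by_group <- function(records) {
  out <- lapply(ires_groups(), function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    attr(sub, "threshold") <- attr(records, "threshold")
    sub
  })
  names(out) <- ires_groups()
  out$all <- records
  out
}
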