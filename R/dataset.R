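#' Splice-site datasets
#'
#' A `splice_dataset` is a data.frame with one row per intron record,
#' carrying the sequence elements the analysis consumes (all stored in
#' uppercase DNA alphabet; normalized to RNA in memory when pairing):
#'
#' * `junction11`: the 11-nt splice junction, last 8 nt of the upstream
#'   exon joined to the first 3 nt of the downstream exon (boundary at 8|9);
#' * `intron_start10`: first 10 nt of the intron;
#' * `intron_end60`: last 60 nt of the intron (the whole intron, flagged,
#'   when shorter);
#' * `spliceosome_class`: `major`, `atypical_plus2` (substituted +2U),
#'   `minor` (U12-type 5' motif) or `unclassified` (unusual termini);
#' * conserved-position flags `has_plus5G`, `has_minus1G`, `has_minus3C`
#'   and bookkeeping flags `truncated`, `short_intron`.
#'
#' @name splice_dataset
NULL

DATASET_COLUMNS <- c("gene_id", "transcript_id", "intron_index",
                     "junction11", "intron_start10", "intron_end60",
                     "intron_length", "spliceosome_class",
                     "truncated", "short_intron",
                     "has_plus5G", "has_minus1G", "has_minus3C")

.as_splice_dataset <- function(df, provenance = list()) {
  stopifnot(all(DATASET_COLUMNS %in% names(df)))
  df <- df[, DATASET_COLUMNS, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("splice_dataset", "data.frame"),
            provenance = provenance)
}

#' @export
as.data.frame.splice_dataset <- function(x, ...) {
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.splice_dataset <- function(x, ...) {
  cat(sprintf("splice_dataset: %d intron records\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$spliceosome_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

## Character at a signed junction position (-8..-1 exon end, +1..+3 exon
## start) of the standard 11-mer; the labelled accessor used downstream.
junction_base <- function(junction11, position) {
  stopifnot(all(position >= -8 & position <= 3 & position != 0))
  idx <- ifelse(position < 0L, position + 9L, position + 8L)
  substr(junction11, idx, idx)
}

.conserved_flags <- function(junction11, intron_start10, intron_end60) {
  end_n <- nchar(intron_end60)
  list(
    has_plus5G  = substr(intron_start10, 5L, 5L) == "G",
    has_minus1G = junction_base(junction11, -1L) == "G",
    has_minus3C = substring(intron_end60, end_n - 2L, end_n - 2L) == "C"
  )
}

#' Classify an intron by its 5' splice-site sequence
#'
#' Routes each intron to the spliceosome expected to process it:
#' `minor` when intron positions +3..+8 match the U12-type 5' core
#' complementary to the U6atac box (default motif `ATCCTT`, exact match),
#' otherwise `atypical_plus2` when the near-universal +2U is substituted
#' (GC-AG and GA-AG introns), otherwise `major` for GT...AG termini and
#' `unclassified` for anything else (flagged, never dropped silently).
#'
#' @param intron_start10 character vector of intron 5' ends (>= 8 nt).
#' @param intron_last2 character vector of the final two intron bases
#'   (defaults to `"AG"` when unknown, i.e. termini are trusted).
#' @param minor_motif the +3..+8 motif identifying U12-type introns.
#' @return character vector of classes.
#' @export
classify_intron <- function(intron_start10, intron_last2 = "AG",
                            minor_motif = "ATCCTT") {
  s <- normalize_seq(intron_start10, "DNA", allow_n = TRUE)
  last2 <- normalize_seq(rep_len(intron_last2, length(s)), "DNA",
                         allow_n = TRUE)
  minor_motif <- normalize_seq(minor_motif, "DNA")
  ifelse(substr(s, 3L, 8L) == minor_motif, "minor",
  ifelse(substr(s, 2L, 2L) != "T", "atypical_plus2",
  ifelse(substr(s, 1L, 1L) == "G" & last2 == "AG", "major",
         "unclassified")))
}

#' Extract per-intron splice elements from one transcript
#'
#' Slices the 11-nt splice junctions (8 nt of 5' exon end + 3 nt of 3'
#' exon start), 10-nt intron starts and 60-nt intron ends out of a
#' transcript given as its ordered exon and intron sequences, then
#' classifies each intron. Exons too short to fill their junction flank
#' yield records padded with `N` and flagged `truncated` (or are skipped
#' when `on_short = "skip"`); introns shorter than 60 nt keep their whole
#' sequence as `intron_end60` and are flagged `short_intron`.
#'
#' @param exons character vector of exon sequences in transcript order
#'   (at least two).
#' @param introns character vector of intron sequences,
#'   `length(exons) - 1`.
#' @param gene_id,transcript_id identifiers stored with each record.
#' @param on_short what to do with records whose junction cannot be filled:
#'   `"flag"` (default) or `"skip"`.
#' @param minor_motif passed to [classify_intron()].
#' @return a [splice_dataset] with one record per intron, in transcript
#'   order.
#' @examples
#' extract_splice_elements(
#'   exons = c("AAACCCAG", "GTTAAA"),
#'   introns = c("GTAAGTATTTTTTTTTTTCAG"),
#'   gene_id = "toy", transcript_id = "toy-1")
#' @export
extract_splice_elements <- function(exons, introns, gene_id = "gene",
                                    transcript_id = "tx",
                                    on_short = c("flag", "skip"),
                                    minor_motif = "ATCCTT") {
  on_short <- match.arg(on_short)
  if (length(exons) < 2L)
    stop("a transcript needs at least two exons to contain an intron")
  if (length(introns) != length(exons) - 1L)
    stop(sprintf("expected %d introns for %d exons, got %d",
                 length(exons) - 1L, length(exons), length(introns)))
  exons <- normalize_seq(exons, "DNA")
  introns <- normalize_seq(introns, "DNA")
  if (any(nchar(introns) < 10L))
    stop("introns shorter than 10 nt are not supported")

  pad_left  <- function(x, n) paste0(strrep("N", pmax(0L, n - nchar(x))),
                                     substring(x, pmax(1L, nchar(x) - n + 1L)))
  pad_right <- function(x, n) paste0(substr(x, 1L, n),
                                     strrep("N", pmax(0L, n - nchar(x))))
  up <- exons[-length(exons)]
  dn <- exons[-1L]
  junction11 <- paste0(pad_left(up, 8L), pad_right(dn, 3L))
  truncated <- nchar(up) < 8L | nchar(dn) < 3L
  intron_start10 <- substr(introns, 1L, 10L)
  short_intron <- nchar(introns) < 60L
  intron_end60 <- substring(introns, pmax(1L, nchar(introns) - 59L))

  cls <- classify_intron(intron_start10,
                         substring(introns, nchar(introns) - 1L),
                         minor_motif)
  flags <- .conserved_flags(junction11, intron_start10, intron_end60)
  df <- data.frame(gene_id = gene_id, transcript_id = transcript_id,
                   intron_index = seq_along(introns),
                   junction11 = junction11,
                   intron_start10 = intron_start10,
                   intron_end60 = intron_end60,
                   intron_length = nchar(introns),
                   spliceosome_class = cls,
                   truncated = truncated, short_intron = short_intron,
                   has_plus5G = flags$has_plus5G,
                   has_minus1G = flags$has_minus1G,
                   has_minus3C = flags$has_minus3C)
  if (on_short == "skip") df <- df[!df$truncated, , drop = FALSE]
  .as_splice_dataset(df, provenance = list(source = "extract_splice_elements"))
}

#' Partition a dataset at a conserved splice-site position
#'
#' Splits the eligible records of a dataset into the subset conserving a
#' key position and the subset substituting it. Eligibility follows the
#' analysis design: the 5' splice-site criteria (`plus5G`, `minus1G`)
#' admit only major GT_AG introns, while `minus3C` admits all introns
#' processed by the major spliceosome, i.e. major plus +2-substituted
#' atypical introns.
#'
#' @param ds a [splice_dataset].
#' @param criterion one of `"plus5G"`, `"minus1G"`, `"minus3C"`.
#' @param drop_truncated drop records whose junction is incomplete.
#' @return a list with elements `conserved` and `substituted` (both
#'   [splice_dataset]s), disjoint and jointly covering the eligible
#'   records.
#' @export
partition_dataset <- function(ds, criterion = c("plus5G", "minus1G",
                                                "minus3C"),
                              drop_truncated = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(ds, "splice_dataset"))
  eligible_classes <- switch(criterion,
                             plus5G = "major", minus1G = "major",
                             minus3C = c("major", "atypical_plus2"))
  keep <- ds$spliceosome_class %in% eligible_classes
  if (drop_truncated) keep <- keep & !ds$truncated
  if (!any(keep))
    stop(sprintf("no eligible records for criterion '%s'", criterion))
  flag <- switch(criterion, plus5G = "has_plus5G", minus1G = "has_minus1G",
                 minus3C = "has_minus3C")
  sub <- ds[keep, , drop = FALSE]
  prov <- attr(ds, "provenance")
  list(conserved = .as_splice_dataset(sub[sub[[flag]], , drop = FALSE], prov),
       substituted = .as_splice_dataset(sub[!sub[[flag]], , drop = FALSE],
                                        prov))
}

#' Report excluded (non-major) intron records
#'
#' @param ds a [splice_dataset].
#' @return data.frame of records not routed to the major-spliceosome
#'   GT_AG class, with an exclusion reason column.
#' @export
exclusion_report <- function(ds) {
  stopifnot(inherits(ds, "splice_dataset"))
  excl <- ds[ds$spliceosome_class != "major", , drop = FALSE]
  reason <- c(minor = "U12-type (U6atac-complementary 5' motif)",
              atypical_plus2 = "substituted +2U at intron start",
              unclassified = "unusual intron termini")
  data.frame(as.data.frame(excl)[, c("gene_id", "transcript_id",
                                     "intron_index", "intron_start10",
                                     "spliceosome_class")],
             reason = unname(reason[excl$spliceosome_class]))
}

#' Read and write splice datasets as TSV
#'
#' Plain tab-separated text with one header line; re-reading yields the
#' identical dataset, and re-writing an unchanged dataset is
#' byte-identical.
#'
#' @param ds a [splice_dataset].
#' @param path file path.
#' @return `read_splice_dataset()` returns a [splice_dataset];
#'   `write_splice_dataset()` returns `path` invisibly.
#' @export
write_splice_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "splice_dataset"))
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_splice_dataset
#' @export
read_splice_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ## tolerate the prepared-TSV interface: exon5_end8 / intron_seq /
  ## exon3_start3 columns instead of precomputed elements
  if (!all(DATASET_COLUMNS %in% names(df)) &&
      all(c("gene_id", "transcript_id", "intron_index", "exon5_end8",
            "intron_seq", "exon3_start3") %in% names(df))) {
    parts <- lapply(seq_len(nrow(df)), function(i)
      extract_splice_elements(c(df$exon5_end8[i], df$exon3_start3[i]),
                              df$intron_seq[i],
                              gene_id = df$gene_id[i],
                              transcript_id = df$transcript_id[i]))
    out <- do.call(rbind, lapply(parts, as.data.frame))
    out$intron_index <- df$intron_index
    return(.as_splice_dataset(out, provenance = list(source = path)))
  }
  .as_splice_dataset(df, provenance = list(source = path))
}
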