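#' Build a splice dataset from a genome FASTA and a GTF/GFF3 annotation
#'
#' Selects one transcript per gene (the isoform with the most exons, ties
#' broken lexicographically by transcript identifier), assembles each
#' transcript's exon and intron sequences (minus-strand transcripts are
#' reverse-complemented) and extracts the splice elements with
#' [extract_splice_elements()]. Annotation coordinates are treated as
#' 1-based inclusive, the GTF convention.
#'
#' Requires the `rtracklayer`, `GenomicRanges` and `S4Vectors` packages.
#'
#' @param genome_fasta path to a (multi-)FASTA of the reference sequences.
#' @param annotation path to a GTF/GFF3 file with `exon` features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @param on_short,minor_motif passed to [extract_splice_elements()].
#' @return a [splice_dataset] covering every internal intron of every
#'   selected transcript, in gene order.
#' @export
build_dataset_from_annotation <- function(genome_fasta, annotation,
                                          on_short = "flag",
                                          minor_motif = "ATCCTT") {
  for (pkg in c("rtracklayer", "GenomicRanges", "S4Vectors"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(sprintf("package '%s' is required to read annotations", pkg))
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(annotation)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stop("no exon features found in ", annotation)
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$gene_id) || is.null(meta$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")

  exon_df <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id))

  ## one isoform per gene: maximum exon count, then lexicographic id
  counts <- stats::aggregate(start ~ gene_id + transcript_id, exon_df,
                             FUN = length)
  counts <- counts[order(counts$gene_id, -counts$start,
                         counts$transcript_id), ]
  chosen <- counts[!duplicated(counts$gene_id), c("gene_id",
                                                  "transcript_id")]

  out <- vector("list", nrow(chosen))
  for (i in seq_len(nrow(chosen))) {
    tx <- exon_df[exon_df$transcript_id == chosen$transcript_id[i], ]
    if (nrow(tx) < 2L) next
    if (length(unique(tx$seqname)) != 1L || length(unique(tx$strand)) != 1L)
      stop("transcript ", chosen$transcript_id[i],
           " spans multiple sequences or strands")
    tx <- tx[order(tx$start), ]
    if (any(tx$start[-1L] <= tx$end[-nrow(tx)]))
      stop("overlapping or unordered exons in transcript ",
           chosen$transcript_id[i])
    chrom <- genome[[tx$seqname[1L]]]
    if (is.null(chrom)) stop("sequence ", tx$seqname[1L],
                             " absent from ", genome_fasta)
    slice <- function(s, e) as.character(Biostrings::subseq(chrom, s, e))
    exon_seq <- mapply(slice, tx$start, tx$end)
    intr_seq <- mapply(slice, tx$end[-nrow(tx)] + 1L, tx$start[-1L] - 1L)
    if (tx$strand[1L] == "-") {
      rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
      exon_seq <- rev(rc(exon_seq))
      intr_seq <- rev(rc(intr_seq))
    }
    out[[i]] <- as.data.frame(
      extract_splice_elements(exon_seq, intr_seq,
                              gene_id = chosen$gene_id[i],
                              transcript_id = chosen$transcript_id[i],
                              on_short = on_short,
                              minor_motif = minor_motif))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) stop("no multi-exon transcripts found")
  .as_splice_dataset(do.call(rbind, out),
                     provenance = list(genome = genome_fasta,
                                       annotation = annotation))
}
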