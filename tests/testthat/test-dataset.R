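test_that("splice elements are sliced at the documented coordinates", {
  intron <- paste0("GTAAGTATTT", strrep("CT", 30), "TTAAAG")
  ds <- extract_splice_elements(c("AAACCCAG", "GTTAAA"), intron,
                                gene_id = "toy", transcript_id = "toy-1")
  expect_s3_class(ds, "splice_dataset")
  expect_equal(nrow(ds), 1L)       # 2 exons -> exactly 1 intron record
  expect_equal(ds$junction11, "AAACCCAGGTT")
  expect_equal(ds$intron_start10, substr(intron, 1, 10))
  expect_equal(nchar(ds$intron_end60), 60L)
  expect_equal(ds$intron_end60,
               substr(intron, nchar(intron) - 59, nchar(intron)))
  expect_false(ds$truncated)
  expect_true(ds$has_plus5G)       # GTAAGT -> +5 G
  expect_true(ds$has_minus1G)
  expect_false(ds$has_minus3C)     # ...AAAG -> -3 A
  ## junction position labels: chars 1..8 = exon -8..-1, 9..11 = +1..+3
  expect_equal(splicepairs:::junction_base(ds$junction11, -1L), "G")
  expect_equal(splicepairs:::junction_base(ds$junction11, -8L), "A")
  expect_equal(splicepairs:::junction_base(ds$junction11, 1L), "G")
  expect_equal(splicepairs:::junction_base(ds$junction11, 3L), "T")
})

test_that("short flanks are flagged or skipped and short introns kept whole", {
  intron <- paste0("GTAAGTATTT", strrep("A", 20), "TTACAG")  # 36 nt
  ds <- extract_splice_elements(c("AAACCCAG", "GTACGTAC", "AA"),
                                c(intron, intron))
  expect_equal(nrow(ds), 2L)
  expect_false(ds$truncated[1L])
  expect_true(ds$truncated[2L])    # downstream exon of intron 2 is 2 nt
  expect_match(ds$junction11[2L], "N$")
  expect_true(all(ds$short_intron))
  expect_equal(nchar(ds$intron_end60[1L]), nchar(intron))
  skipped <- extract_splice_elements(c("AAACCCAG", "GTACGTAC", "AA"),
                                     c(intron, intron), on_short = "skip")
  expect_equal(nrow(skipped), 1L)
  expect_error(extract_splice_elements("AAACCCAG", character(0)),
               "at least two exons")
  expect_error(extract_splice_elements(c("AAACCCAG", "GTT"), character(0)),
               "expected 1 introns")
})

test_that("introns are routed to the correct spliceosome class", {
  expect_equal(classify_intron("GTATCCTTTC"), "minor")
  expect_equal(classify_intron("GCAAGTATTT"), "atypical_plus2")
  expect_equal(classify_intron("GAAAGTATTT"), "atypical_plus2")
  expect_equal(classify_intron("GTAAGTATTT"), "major")
  expect_equal(classify_intron("ATAAGTATTT"), "unclassified")
  expect_equal(classify_intron("GTAAGTATTT", intron_last2 = "AC"),
               "unclassified")
  ## the motif rule is configurable
  expect_equal(classify_intron("GTCCCCCCTC", minor_motif = "CCCCCC"),
               "minor")
})

test_that("partitions are disjoint, exhaustive and respect eligibility", {
  ds <- toy_dataset()
  expect_equal(as.vector(table(ds$spliceosome_class)[c("major",
                                                       "atypical_plus2")]),
               c(2L, 1L))
  p5 <- partition_dataset(ds, "plus5G")
  ## only the 2 major records are eligible; +5 = {G, T}
  expect_equal(nrow(p5$conserved) + nrow(p5$substituted), 2L)
  expect_equal(nrow(p5$conserved), 1L)
  m3 <- partition_dataset(ds, "minus3C")
  ## minus3C admits major + atypical_plus2
  expect_equal(nrow(m3$conserved) + nrow(m3$substituted), 3L)
  expect_length(intersect(m3$conserved$gene_id, character(0)), 0L)

  ## property: on generated data the split covers all eligible records
  gen <- generate_dataset(site_frequency_model(), 300, seed = 11)
  for (crit in c("plus5G", "minus1G", "minus3C")) {
    pp <- partition_dataset(gen, crit)
    ids <- c(pp$conserved$transcript_id, pp$substituted$transcript_id)
    expect_false(anyDuplicated(ids) > 0)
    eligible <- gen$spliceosome_class %in%
      if (crit == "minus3C") c("major", "atypical_plus2") else "major"
    expect_equal(length(ids), sum(eligible & !gen$truncated))
  }
  empty <- generate_dataset(site_frequency_model(), 0)
  expect_error(partition_dataset(empty, "plus5G"), "no eligible records")
})

test_that("a 3-record +5 split of {G, A, G} has sizes (2, 1)", {
  rows <- do.call(rbind, lapply(c("G", "A", "G"), function(b) {
    as.data.frame(extract_splice_elements(
      c("AAAACCAG", "GTTA"),
      paste0("GTAA", b, "TATTT", strrep("T", 40), "TTTCAG")))
  }))
  rows$intron_index <- 1:3
  ds <- splicepairs:::.as_splice_dataset(rows)
  p <- partition_dataset(ds, "plus5G")
  expect_equal(c(nrow(p$conserved), nrow(p$substituted)), c(2L, 1L))
})

test_that("dataset TSV round trips byte-identically", {
  ds <- toy_dataset()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_splice_dataset(ds, f1)
  back <- read_splice_dataset(f1)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  write_splice_dataset(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("prepared per-intron TSV input is accepted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttranscript_id\tintron_index\texon5_end8\tintron_seq\texon3_start3",
               paste("g1", "t1", 1, "AAACCCAG",
                     paste0("GTAAGTATTT", strrep("T", 44), "TTTCAG"),
                     "GTT", sep = "\t")), f)
  ds <- read_splice_dataset(f)
  expect_equal(ds$junction11, "AAACCCAGGTT")
  expect_equal(ds$spliceosome_class, "major")
})

test_that("the exclusion report lists non-major records with reasons", {
  ds <- toy_dataset()
  rep <- exclusion_report(ds)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$reason, "\\+2U")
})

test_that("annotation-based extraction handles both strands", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  dir <- withr::local_tempdir()
  ## plus-strand gene: exon1 1-8, intron 9-28, exon2 29-34
  exon1 <- "AAACCCAG"; intron <- "GTAAGTATTTCCCCCTACAG"; exon2 <- "GTTAAA"
  chr1 <- paste0(exon1, intron, exon2)
  ## minus-strand gene on chr2: same transcript structure on the reverse
  ## strand, so the genomic sequence is the reverse complement
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  chr2 <- revcomp(chr1)
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", chr1, ">chr2", chr2), fa)
  gtf <- file.path(dir, "genes.gtf")
  attr1 <- 'gene_id "g1"; transcript_id "g1.t1";'
  attr2 <- 'gene_id "g2"; transcript_id "g2.t1";'
  writeLines(c(
    paste("chr1", "test", "exon", 1, 8, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "test", "exon", 29, 34, ".", "+", ".", attr1, sep = "\t"),
    paste("chr2", "test", "exon", 1, 6, ".", "-", ".", attr2, sep = "\t"),
    paste("chr2", "test", "exon", 27, 34, ".", "-", ".", attr2, sep = "\t")),
    gtf)
  ds <- build_dataset_from_annotation(fa, gtf)
  expect_equal(nrow(ds), 2L)
  expect_equal(sort(unique(ds$gene_id)), c("g1", "g2"))
  ## both strands must recover the identical transcript-level elements
  expect_equal(ds$junction11[ds$gene_id == "g2"],
               ds$junction11[ds$gene_id == "g1"])
  expect_equal(ds$intron_start10[ds$gene_id == "g2"],
               ds$intron_start10[ds$gene_id == "g1"])
  expect_equal(ds$junction11[1L], "AAACCCAGGTT")
})
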