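## Shared fixtures and independent oracles for the test suite. Oracles
## re-derive expectations from explicit tables/formulas and never call the
## package functions they check.

## independent 16-pair lookup, spelled out pair by pair
oracle_pair_class <- function(b1, b2) {
  tab <- c(AA = "non_isosteric", AC = "isosteric",     AG = "non_isosteric",
           AU = "watson_crick",  CA = "isosteric",     CC = "non_isosteric",
           CG = "watson_crick",  CU = "isosteric",     GA = "non_isosteric",
           GC = "watson_crick",  GG = "non_isosteric", GU = "isosteric",
           UA = "watson_crick",  UC = "isosteric",     UG = "isosteric",
           UU = "isosteric")
  unname(tab[paste0(b1, b2)])
}

## brute-force register scorer: enumerate every boundary split with a
## longer-or-equal 5' side and recount Watson-Crick pairs from the raw
## table. `loop_bases` are canonical bases 5'->3'.
oracle_scan <- function(window15, loop_bases) {
  chars <- strsplit(chartr("T", "U", toupper(window15)), "")[[1]]
  counts <- integer(0)
  for (s in 6:10) {
    t <- 11L - s
    wc <- 0L
    for (k in seq_len(s)) {      # upstream position -k pairs loop index t+k
      b <- chars[10L - k + 1L]
      if (oracle_pair_class(b, loop_bases[t + k]) == "watson_crick")
        wc <- wc + 1L
    }
    if (t > 0) for (k in seq_len(t)) { # downstream +k pairs loop index t-k+1
      b <- chars[10L + k]
      if (oracle_pair_class(b, loop_bases[t - k + 1L]) == "watson_crick")
        wc <- wc + 1L
    }
    counts[sprintf("%d+%d", s, t)] <- wc
  }
  counts
}

## textbook Welch ANOVA (two groups) and Kruskal-Wallis, from formulas
oracle_welch <- function(x, g) {
  groups <- split(x, g)
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  A <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  f <- A / B
  df2 <- (k^2 - 1) / (3 * lam)
  list(statistic = f, df1 = k - 1, df2 = df2,
       p = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

oracle_kruskal <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  groups <- split(r, g)
  H <- 12 / (N * (N + 1)) *
    sum(lengths(groups) * vapply(groups, mean, 0)^2) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(statistic = H, df = length(groups) - 1,
       p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

## build a junction fully Watson-Crick-complementary to a loop model's
## exon pairing map (from the map itself, by base complementation)
complementary_junction <- function(model) {
  map <- model$pairing
  stopifnot(all(map$site == "exon"))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  n5 <- sum(map$position < 0)
  chars <- character(n5 + sum(map$position > 0))
  for (i in seq_len(nrow(map))) {
    pos <- map$position[i]
    idx <- if (pos < 0) n5 + 1L + pos else n5 + pos
    chars[idx] <- comp[[map$loop_base[i]]]
  }
  paste(chars, collapse = "")
}

## a small deterministic hand-made dataset: junctions/introns chosen so
## that each classification branch occurs
toy_dataset <- function() {
  mk <- function(junction11, intron) {
    extract_splice_elements(
      exons = c(substr(junction11, 1, 8),
                paste0(substr(junction11, 9, 11), "AAAA")),
      introns = intron, gene_id = "toy", transcript_id = "toy-1")
  }
  rows <- rbind(
    as.data.frame(mk("AAACCCAGGTT",
                     paste0("GTAAGTATTT", strrep("CT", 30), "TTACAG"))),
    as.data.frame(mk("CCCCCCAGGCA",
                     paste0("GCAAGTATTT", strrep("CT", 30), "TTTCAG"))),
    as.data.frame(mk("GGGGGGAAGTT",
                     paste0("GTAAATATTT", strrep("CT", 30), "CTACAG"))))
  rows$intron_index <- seq_len(nrow(rows))
  splicepairs:::.as_splice_dataset(rows)
}

## dataset with a fixed base at one junction position, everything else "A"
uniform_dataset <- function(n, junction = "AAAAAAAGGTT") {
  intron <- paste0("GTAAGTATTT", strrep("T", 44), "TTTCAG")
  rows <- do.call(rbind, replicate(n, {
    as.data.frame(extract_splice_elements(
      exons = c(substr(junction, 1, 8), paste0(substr(junction, 9, 11), "A")),
      introns = intron))
  }, simplify = FALSE))
  rows$intron_index <- seq_len(nrow(rows))
  splicepairs:::.as_splice_dataset(rows)
}

## dataset whose exon -1 bases are given explicitly
minus1_dataset <- function(bases) {
  rows <- do.call(rbind, lapply(bases, function(b) {
    as.data.frame(extract_splice_elements(
      exons = c(paste0("AAAAAAA", b), "GTTA"),
      introns = paste0("GTAAGTATTT", strrep("T", 44), "TTTCAG")))
  }))
  rows$intron_index <- seq_len(nrow(rows))
  splicepairs:::.as_splice_dataset(rows)
}

random_window <- function() paste(sample(c("A", "C", "G", "T"), 15,
                                         replace = TRUE), collapse = "")
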