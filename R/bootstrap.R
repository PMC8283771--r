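## 0/1 indicator matrix (records x (positions * 3 classes)) from a class
## code matrix; column order position-major, class-minor.
.one_hot <- function(codes) {
  n <- nrow(codes)
  P <- ncol(codes)
  out <- matrix(0, n, 3L * P)
  for (j in seq_len(P))
    out[cbind(seq_len(n), (j - 1L) * 3L + codes[, j])] <- 1
  colnames(out) <- paste(rep(colnames(codes), each = 3L), PAIR_CLASSES,
                         sep = ":")
  out
}

## resampled frequency matrix (iterations x columns of H): each iteration
## resamples `n` records with replacement; implemented as multinomial
## weights times the indicator matrix, in chunks to bound memory.
.bootstrap_freqs <- function(H, iterations, chunk = 1000L) {
  n <- nrow(H)
  out <- matrix(NA_real_, iterations, ncol(H))
  done <- 0L
  while (done < iterations) {
    k <- min(chunk, iterations - done)
    W <- vapply(seq_len(k), function(i)
      tabulate(sample.int(n, n, replace = TRUE), nbins = n), numeric(n))
    out[done + seq_len(k), ] <- crossprod(W, H) / n
    done <- done + k
  }
  out
}

## smaller-tail null probability of a bootstrap-difference sample; ties
## (differences exactly 0) are counted in both tails before the minimum
## is taken, so P(H0) can reach 0.5 + ties/iterations in degenerate cases.
.p_h0 <- function(bd) pmin(colMeans(bd <= 0), colMeans(bd >= 0))

#' Bootstrap-difference test of positional base-pair frequencies
#'
#' Tests, for every defined (position, pair-class) cell of a loop model's
#' pairing map, the null hypothesis that two record sets have the same
#' base-pair frequency. Each iteration resamples set A at size `|A|` and
#' set B at size `|B|` with replacement and records the bootstrap
#' difference `BD = freq_A* - freq_B*`; positive BD means the class is more
#' frequent in A. `P(H0)` is the proportion of the smaller part of the BD
#' distribution lying beyond the zero line (so `P(H0)` is at most ~0.5);
#' the two-sided p-value `2 * P(H0)` is reported alongside for calibrated
#' type-I error control. Cells whose class cannot occur (uridine loop
#' partners admit no non-isosteric pair) are marked undefined and not
#' tested.
#'
#' @param setA,setB [splice_dataset]s (e.g. the substituted and conserved
#'   partitions); BD above zero reports an increase in `setA`.
#' @param model a [loop_model()].
#' @param iterations bootstrap iterations (default 10000).
#' @param seed optional integer seed.
#' @param keep_distributions keep the full BD matrix in the result.
#' @return object of class `bootstrap_result`: list with `table` (one row
#'   per (position, class): observed frequencies and difference, `p_h0`,
#'   `p_two_sided`, `defined`), optionally `bd` (iterations x cells), and
#'   a `provenance` block (sizes, iterations, seed).
#' @export
bootstrap_differences <- function(setA, setB, model, iterations = 10000L,
                                  seed = NULL, keep_distributions = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  codesA <- .class_code_matrix(setA, model)
  codesB <- .class_code_matrix(setB, model)
  map <- attr(codesA, "map")
  HA <- .one_hot(codesA)
  HB <- .one_hot(codesB)
  bd <- .bootstrap_freqs(HA, iterations) - .bootstrap_freqs(HB, iterations)
  defined <- as.vector(.defined_matrix(map))
  p0 <- .p_h0(bd)
  p0[!defined] <- NA_real_
  tab <- data.frame(site = rep(map$site, each = 3L),
                    position = rep(map$position, each = 3L),
                    pair_class = rep(PAIR_CLASSES, nrow(map)),
                    freq_A = colMeans(HA), freq_B = colMeans(HB),
                    observed_diff = colMeans(HA) - colMeans(HB),
                    p_h0 = p0,
                    p_two_sided = pmin(1, 2 * p0),
                    defined = defined)
  rownames(tab) <- NULL
  structure(list(table = tab, bd = if (keep_distributions) bd,
                 provenance = list(n_A = nrow(codesA), n_B = nrow(codesB),
                                   iterations = iterations, seed = seed,
                                   model = model$name)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("bootstrap differences (%s): n_A=%d vs n_B=%d, %d iterations\n",
              p$model, p$n_A, p$n_B, p$iterations))
  print(x$table[x$table$defined,
                c("site", "position", "pair_class", "observed_diff",
                  "p_h0", "p_two_sided")],
        digits = 4L)
  invisible(x)
}

#' @describeIn bootstrap_differences box-and-whisker rendering of the BD
#'   distributions (one panel per pair class), the plain-graphics
#'   counterpart of the violin summaries.
#' @param x a `bootstrap_result` with kept distributions.
#' @param ... ignored.
#' @export
plot.bootstrap_result <- function(x, ...) {
  if (is.null(x$bd)) stop("result was built with keep_distributions = FALSE")
  old <- graphics::par(mfrow = c(3L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cls in PAIR_CLASSES) {
    sel <- x$table$pair_class == cls & x$table$defined
    if (!any(sel)) next
    graphics::boxplot(x$bd[, sel, drop = FALSE],
                      names = x$table$position[sel], main = cls,
                      ylab = "bootstrap difference", outline = FALSE)
    graphics::abline(h = 0, lty = 2L)
  }
  invisible(x)
}

#' Nucleotide-level bootstrap at one substrate position
#'
#' The same resampling scheme as [bootstrap_differences()], applied to the
#' four nucleotide frequencies at a single substrate position instead of
#' the pair-class frequencies -- used to separate interactions that select
#' different bases at a shared position (e.g. exon -3, where a
#' Watson-Crick pair needs A against U5 but C against U1).
#'
#' @param setA,setB [splice_dataset]s.
#' @param position signed substrate position label.
#' @param site `"exon"` (junction coordinates) or `"intron"`.
#' @param iterations,seed,keep_distributions as in
#'   [bootstrap_differences()].
#' @return object of class `nucleotide_bootstrap`: `table` with one row
#'   per nucleotide (observed frequencies, difference, `p_h0`,
#'   `p_two_sided`), optional `bd`, and provenance.
#' @export
nucleotide_bootstrap <- function(setA, setB, position, site = "exon",
                                 iterations = 10000L, seed = NULL,
                                 keep_distributions = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(position) == 1L, site %in% c("exon", "intron"))
  one_hot_nt <- function(ds) {
    ds <- .usable_records(ds, quiet = TRUE)
    if (nrow(ds) == 0L) stop("no usable records in dataset")
    b <- substrate_bases(site, position,
                         junction = normalize_seq(ds$junction11, "RNA"),
                         intron_start = normalize_seq(ds$intron_start10,
                                                      "RNA"),
                         intron_end = normalize_seq(ds$intron_end60,
                                                    "RNA"))[, 1L]
    H <- matrix(0, length(b), 4L, dimnames = list(NULL, RNA_BASES))
    H[cbind(seq_along(b), match(b, RNA_BASES))] <- 1
    H
  }
  HA <- one_hot_nt(setA)
  HB <- one_hot_nt(setB)
  bd <- .bootstrap_freqs(HA, iterations) - .bootstrap_freqs(HB, iterations)
  p0 <- .p_h0(bd)
  tab <- data.frame(nucleotide = RNA_BASES,
                    freq_A = colMeans(HA), freq_B = colMeans(HB),
                    observed_diff = colMeans(HA) - colMeans(HB),
                    p_h0 = p0, p_two_sided = pmin(1, 2 * p0))
  rownames(tab) <- NULL
  structure(list(table = tab, bd = if (keep_distributions) bd,
                 provenance = list(n_A = nrow(HA), n_B = nrow(HB),
                                   site = site, position = position,
                                   iterations = iterations, seed = seed)),
            class = "nucleotide_bootstrap")
}

#' @export
print.nucleotide_bootstrap <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("nucleotide bootstrap at %s %+d: n_A=%d vs n_B=%d (%d iter)\n",
              p$site, p$position, p$n_A, p$n_B, p$iterations))
  print(x$table, digits = 4L)
  invisible(x)
}
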