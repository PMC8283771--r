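## Default positional nucleotide probability vectors (DNA alphabet,
## A/C/G/T). These are configuration data approximating the human
## splice-site consensus qualitatively -- anchored at the marginals that
## matter for the analysis (exon -1 G = 0.82, intron +5 G = 0.80,
## exon +1 G = 0.50, intron -3 C = 0.61, +6T below 0.5, +1A about twice
## +1T) -- not measurements of the genome.
.default_vectors <- function() {
  v <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  list(
    exon5 = rbind("-8" = v(.27, .23, .27, .23), "-7" = v(.27, .23, .27, .23),
                  "-6" = v(.27, .23, .27, .23), "-5" = v(.28, .24, .26, .22),
                  "-4" = v(.28, .24, .26, .22), "-3" = v(.34, .36, .18, .12),
                  "-2" = v(.60, .12, .16, .12), "-1" = v(.08, .04, .82, .06)),
    exon3 = rbind("1" = v(.24, .14, .50, .12), "2" = v(.28, .24, .24, .24),
                  "3" = v(.26, .22, .30, .22)),
    intron_start = rbind("1" = v(0, 0, 1, 0), "2" = v(0, 0, 0, 1),
                         "3" = v(.60, .04, .30, .06),
                         "4" = v(.70, .08, .12, .10),
                         "5" = v(.07, .05, .80, .08),
                         "6" = v(.16, .16, .23, .45),
                         "7" = v(.30, .22, .22, .26),
                         "8" = v(.25, .22, .26, .27),
                         "9" = v(.25, .25, .25, .25),
                         "10" = v(.25, .25, .25, .25)),
    intron_end = rbind("-6" = v(.10, .30, .12, .48),
                       "-5" = v(.10, .32, .10, .48),
                       "-4" = v(.22, .28, .12, .38),
                       "-3" = v(.22, .61, .02, .15),
                       "-2" = v(1, 0, 0, 0), "-1" = v(0, 0, 1, 0)),
    background = v(.12, .30, .13, .45)
  )
}

#' Positional frequency model for synthetic splice sites
#'
#' Defines the joint distribution the synthetic generator draws from:
#' independent per-position nucleotide vectors for exon -8..-1, exon
#' +1..+3, intron +1..+10 and intron -6..-1 (GT/AG termini enforced, the
#' wider intron end filled from a pyrimidine-rich background), plus two
#' tunable dependencies mirroring the compensation structure under test:
#'
#' * `delta_5ss`: conditional on intron +5 not being G, the guanine mass
#'   at exon -1 is raised so that
#'   `P(-1G | +5 substituted) - P(-1G | +5G) = delta_5ss` while the
#'   marginal `P(-1G)` is preserved;
#' * `delta_3ss`: the same construction between intron -3 C and exon +1 G.
#'
#' With both deltas 0 all positions are drawn independently. Shifted
#' vectors are renormalized over the remaining nucleotides proportionally
#' and clipped into the simplex with a warning if a delta is too large.
#'
#' @param delta_5ss,delta_3ss dependency strengths in [0, 1) (total
#'   variation shift of the Watson-Crick-forming nucleotide).
#' @param vectors optional replacement for the default probability
#'   vectors: a list with elements `exon5` (8 x 4), `exon3` (3 x 4),
#'   `intron_start` (10 x 4), `intron_end` (6 x 4) and `background`
#'   (length 4), columns/entries ordered A, C, G, T.
#' @return object of class `site_frequency_model`.
#' @export
site_frequency_model <- function(delta_5ss = 0, delta_3ss = 0,
                                 vectors = NULL) {
  v <- .default_vectors()
  if (!is.null(vectors)) v[names(vectors)] <- vectors
  dims <- c(exon5 = 8L, exon3 = 3L, intron_start = 10L, intron_end = 6L)
  for (nm in names(dims)) {
    mat <- v[[nm]]
    if (!is.matrix(mat) || nrow(mat) != dims[[nm]] || ncol(mat) != 4L)
      stop(sprintf("vector block '%s' must be a %d x 4 matrix", nm,
                   dims[[nm]]))
    bad <- abs(rowSums(mat) - 1) > 1e-8 | apply(mat < 0, 1L, any)
    if (any(bad))
      stop(sprintf("probability vector '%s' row %s does not lie in the simplex",
                   nm, rownames(mat)[bad][1L]))
  }
  if (abs(sum(v$background) - 1) > 1e-8 || any(v$background < 0))
    stop("probability vector 'background' does not lie in the simplex")
  stopifnot(delta_5ss >= 0, delta_5ss < 1, delta_3ss >= 0, delta_3ss < 1)
  structure(list(vectors = v, delta_5ss = delta_5ss, delta_3ss = delta_3ss),
            class = "site_frequency_model")
}

#' @export
print.site_frequency_model <- function(x, ...) {
  cat("site frequency model\n")
  cat(sprintf("  P(-1G) = %.2f, P(+5G) = %.2f, P(+1G exon) = %.2f, P(-3C) = %.2f\n",
              x$vectors$exon5["-1", "G"], x$vectors$intron_start["5", "G"],
              x$vectors$exon3["1", "G"], x$vectors$intron_end["-3", "C"]))
  cat(sprintf("  delta_5ss = %g, delta_3ss = %g\n", x$delta_5ss, x$delta_3ss))
  invisible(x)
}

## shift `delta` of probability mass onto nucleotide `target`, taking it
## from the others proportionally; negative delta removes mass likewise.
.shift_vector <- function(p, target, delta) {
  q <- p
  new_t <- p[target] + delta
  if (new_t < 0 || new_t > 1) {
    warning("dependency shift clipped to keep the vector in the simplex")
    new_t <- min(1, max(0, new_t))
  }
  rest <- sum(p[-match(target, names(p))])
  q[target] <- new_t
  if (rest > 0)
    q[names(p) != target] <- p[names(p) != target] * (1 - new_t) / rest
  q
}

.sample_base <- function(n, p) sample(names(p), n, replace = TRUE, prob = p)

## draw a dependent position: `cond` TRUE = conditioning base substituted.
## Guarantees P(target | sub) - P(target | cons) = delta with the marginal
## preserved: conditional shifts +delta*q_cons and -delta*(1-q_cons).
.sample_dependent <- function(cond_sub, p, target, delta) {
  q_cons <- 1 - mean(cond_sub)
  out <- character(length(cond_sub))
  n_sub <- sum(cond_sub)
  if (n_sub) out[cond_sub] <-
      .sample_base(n_sub, .shift_vector(p, target, delta * q_cons))
  if (n_sub < length(cond_sub)) out[!cond_sub] <-
      .sample_base(length(cond_sub) - n_sub,
                   .shift_vector(p, target, -delta * (1 - q_cons)))
  out
}

#' Generate a synthetic splice-site dataset
#'
#' Draws `n` intron records from a [site_frequency_model()]: GT...AG
#' termini enforced, all other positions drawn from their positional
#' vectors, the intron end beyond -6 filled from the pyrimidine-rich
#' background, and the configured exon/intron dependencies applied
#' (intron +5 and intron -3 are drawn first; exon -1 and exon +1 are then
#' drawn from the matching conditional vectors). Output has exactly the
#' [splice_dataset] schema of the annotation-based builder, so every
#' downstream analysis accepts either source.
#'
#' @param model a [site_frequency_model()].
#' @param n number of records (>= 0).
#' @param seed optional integer seed.
#' @param intron_length length of the generated introns (>= 70 so the
#'   start and end fragments do not overlap).
#' @return a [splice_dataset] with `n` records.
#' @export
generate_dataset <- function(model, n, seed = NULL, intron_length = 100L) {
  stopifnot(inherits(model, "site_frequency_model"), n >= 0,
            intron_length >= 70L)
  if (!is.null(seed)) set.seed(seed)
  v <- model$vectors
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      intron_index = integer(), junction11 = character(),
                      intron_start10 = character(),
                      intron_end60 = character(), intron_length = integer(),
                      spliceosome_class = character(), truncated = logical(),
                      short_intron = logical(), has_plus5G = logical(),
                      has_minus1G = logical(), has_minus3C = logical())
  if (n == 0L)
    return(.as_splice_dataset(empty,
                              provenance = list(source = "generate_dataset",
                                                n = 0L, seed = seed)))

  start_m <- vapply(rownames(v$intron_start), function(r)
    .sample_base(n, v$intron_start[r, ]), character(n))
  if (n == 1L) start_m <- matrix(start_m, nrow = 1L,
                                 dimnames = list(NULL,
                                                 rownames(v$intron_start)))
  end_m <- vapply(rownames(v$intron_end), function(r)
    .sample_base(n, v$intron_end[r, ]), character(n))
  if (n == 1L) end_m <- matrix(end_m, nrow = 1L,
                               dimnames = list(NULL, rownames(v$intron_end)))

  exon5_m <- matrix("", n, 8L, dimnames = list(NULL, rownames(v$exon5)))
  for (r in rownames(v$exon5))
    exon5_m[, r] <- if (r == "-1" && model$delta_5ss > 0)
      .sample_dependent(start_m[, "5"] != "G", v$exon5[r, ], "G",
                        model$delta_5ss)
    else .sample_base(n, v$exon5[r, ])
  exon3_m <- matrix("", n, 3L, dimnames = list(NULL, rownames(v$exon3)))
  for (r in rownames(v$exon3))
    exon3_m[, r] <- if (r == "1" && model$delta_3ss > 0)
      .sample_dependent(end_m[, "-3"] != "C", v$exon3[r, ], "G",
                        model$delta_3ss)
    else .sample_base(n, v$exon3[r, ])

  paste_rows <- function(m) do.call(paste0, asplit(m, 2L))
  junction11 <- paste0(paste_rows(exon5_m), paste_rows(exon3_m))
  intron_start10 <- paste_rows(start_m)
  n_bg <- 60L - 6L
  bg <- matrix(.sample_base(n * n_bg, v$background), n, n_bg)
  intron_end60 <- paste0(paste_rows(bg), paste_rows(end_m))

  cls <- classify_intron(intron_start10, "AG")
  flags <- .conserved_flags(junction11, intron_start10, intron_end60)
  df <- data.frame(gene_id = sprintf("SYNG%05d", seq_len(n)),
                   transcript_id = sprintf("SYNT%05d", seq_len(n)),
                   intron_index = 1L,
                   junction11 = junction11,
                   intron_start10 = intron_start10,
                   intron_end60 = intron_end60,
                   intron_length = intron_length,
                   spliceosome_class = cls,
                   truncated = FALSE, short_intron = FALSE,
                   has_plus5G = flags$has_plus5G,
                   has_minus1G = flags$has_minus1G,
                   has_minus3C = flags$has_minus3C)
  .as_splice_dataset(df, provenance = list(source = "generate_dataset",
                                           n = n, seed = seed,
                                           delta_5ss = model$delta_5ss,
                                           delta_3ss = model$delta_3ss))
}

#' Draw a matched pair of null datasets
#'
#' Generates two datasets from one identical [site_frequency_model()] --
#' the construction behind type-I-error calibration of the
#' bootstrap-difference test, emulating the unequal group sizes of real
#' conserved/substituted partitions.
#'
#' @param model a [site_frequency_model()].
#' @param nA,nB sizes of the two datasets (>= 1).
#' @param seed optional integer seed; the pair is a deterministic
#'   function of it.
#' @return list with [splice_dataset]s `A` and `B`.
#' @export
make_null_pair <- function(model, nA, nB, seed = NULL) {
  stopifnot(nA >= 1L, nB >= 1L)
  if (!is.null(seed)) set.seed(seed)
  list(A = generate_dataset(model, nA), B = generate_dataset(model, nB))
}
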