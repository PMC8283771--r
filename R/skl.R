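#' Symmetrized Kullback-Leibler divergence
#'
#' Computes `sum(p * log2(p/q) + q * log2(q/p))` over all entries of two
#' probability tables after adding a small increment to every probability
#' (without renormalization) to avoid division by zero -- the convention
#' used throughout the splice-site comparisons here. Symmetric,
#' non-negative, and zero when the tables are identical.
#'
#' @param p,q numeric vectors, matrices or arrays of identical shape
#'   (probabilities per position x pair class), or two
#'   `pair_class_distribution` objects from [position_frequencies()].
#' @param increment added to every entry of both tables (default 1e-4).
#' @return a single non-negative number (bits).
#' @examples
#' skl_divergence(c(1, 0), c(0.5, 0.5))
#' @export
skl_divergence <- function(p, q, increment = 1e-4) {
  if (inherits(p, "pair_class_distribution")) p <- p$freq
  if (inherits(q, "pair_class_distribution")) q <- q$freq
  if (length(p) != length(q) || !identical(dim(p), dim(q)))
    stop("p and q must have identical shape")
  p <- as.numeric(p) + increment
  q <- as.numeric(q) + increment
  sum(p * log2(p / q) + q * log2(q / p))
}

#' Default splice-junction and intron-start subsites
#'
#' Position groups over which sKL divergences are evaluated: for the
#' U5-bound splice junction, 5' exon positions -8..-6, -5..-3, -2..-1 and
#' 3' exon positions +1..+3; for the U6-bound intron start, dinucleotides
#' +5/+6, +7/+8 and +9/+10.
#'
#' @return named list of signed position vectors with a `site` attribute.
#' @export
u5_subsites <- function() {
  structure(list("exon_-8_-6" = -(8:6), "exon_-5_-3" = -(5:3),
                 "exon_-2_-1" = -(2:1), "exon_+1_+3" = 1:3),
            site = "exon")
}

#' @rdname u5_subsites
#' @export
u6_subsites <- function() {
  structure(list("intron_+5_+6" = 5:6, "intron_+7_+8" = 7:8,
                 "intron_+9_+10" = 9:10),
            site = "intron")
}

## column indices of a code matrix covered by each subsite
.subsite_columns <- function(map, subsites) {
  site <- attr(subsites, "site")
  if (is.null(site)) site <- "exon"
  lapply(subsites, function(pos) {
    cols <- which(map$site == site & map$position %in% pos)
    if (length(cols) != length(pos))
      stop("subsite positions not all covered by the pairing map: ",
           paste(pos, collapse = ", "))
    cols
  })
}

## frequency table (3 x length(cols)) for a row subset of a code matrix
.subset_freq <- function(codes, rows, cols) {
  vapply(cols, function(j) tabulate(codes[rows, j], nbins = 3L),
         numeric(3L)) / length(rows)
}

#' sKL divergence of a case subset against resampled reference controls
#'
#' The resampling control for "no difference": at each iteration two
#' disjoint, non-redundant subsets of the case-set size are drawn (indices
#' sampled without replacement, jointly for all subsites) from the larger
#' reference set. The sKL divergence between their subsite base-pair
#' distributions forms the control distribution, and the divergence
#' between the first subset and the case set forms the case distribution.
#' Well-separated distributions (mean ratio far above 1) indicate a real
#' composition difference at that subsite.
#'
#' @param reference a [splice_dataset]: the larger, conserved group.
#' @param case a [splice_dataset]: the smaller, substituted group; needs
#'   `nrow(reference) >= 2 * nrow(case)`.
#' @param model a [loop_model()].
#' @param subsites position groups, e.g. [u5_subsites()].
#' @param iterations number of subset pairs drawn.
#' @param increment passed to [skl_divergence()].
#' @param seed optional integer seed for reproducibility.
#' @return object of class `skl_result`: list with matrices `case` and
#'   `control` (iterations x subsites), `mean_ratio` per subsite, and a
#'   `provenance` block recording sizes, iteration count and seed.
#' @export
skl_control_experiment <- function(reference, case, model,
                                   subsites = u5_subsites(),
                                   iterations = 10000L, increment = 1e-4,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes_ref <- .class_code_matrix(reference, model)
  codes_case <- .class_code_matrix(case, model)
  map <- attr(codes_ref, "map")
  cols <- .subsite_columns(map, subsites)
  n_ref <- nrow(codes_ref)
  n_case <- nrow(codes_case)
  if (n_ref < 2L * n_case)
    stop(sprintf(paste0("reference too small: need at least %d records to ",
                        "draw two disjoint sets of %d, got %d"),
                 2L * n_case, n_case, n_ref))
  case_freq <- lapply(cols, function(cl)
    .subset_freq(codes_case, seq_len(n_case), cl))
  case_m <- control_m <- matrix(NA_real_, iterations, length(subsites),
                                dimnames = list(NULL, names(subsites)))
  for (it in seq_len(iterations)) {
    idx <- sample.int(n_ref, 2L * n_case)
    a <- idx[seq_len(n_case)]
    b <- idx[(n_case + 1L):(2L * n_case)]
    for (s in seq_along(cols)) {
      fa <- .subset_freq(codes_ref, a, cols[[s]])
      fb <- .subset_freq(codes_ref, b, cols[[s]])
      control_m[it, s] <- skl_divergence(fa, fb, increment)
      case_m[it, s] <- skl_divergence(fa, case_freq[[s]], increment)
    }
  }
  structure(list(case = case_m, control = control_m,
                 mean_ratio = colMeans(case_m) / colMeans(control_m),
                 provenance = list(n_reference = n_ref, n_case = n_case,
                                   subset_size = n_case,
                                   iterations = iterations, seed = seed,
                                   increment = increment,
                                   model = model$name)),
            class = "skl_result")
}

#' @export
print.skl_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("sKL control experiment: case n=%d vs reference n=%d (%s)\n",
              p$n_case, p$n_reference, p$model))
  cat(sprintf("  %d iterations of disjoint reference subset pairs\n",
              p$iterations))
  out <- data.frame(mean_case = colMeans(x$case),
                    mean_control = colMeans(x$control),
                    mean_ratio = x$mean_ratio)
  print(round(out, 4L))
  invisible(x)
}

#' @describeIn skl_control_experiment histograms of the case and control
#'   sKL distributions per subsite.
#' @param x an `skl_result`.
#' @param ... ignored.
#' @export
plot.skl_result <- function(x, ...) {
  old <- graphics::par(mfrow = c(1L, ncol(x$case)))
  on.exit(graphics::par(old))
  for (s in colnames(x$case)) {
    rng <- range(x$case[, s], x$control[, s])
    hc <- graphics::hist(x$control[, s], plot = FALSE)
    ha <- graphics::hist(x$case[, s], plot = FALSE)
    graphics::plot(hc, col = grDevices::adjustcolor("steelblue", 0.6),
                   xlim = rng, main = s, xlab = "sKL (bits)")
    graphics::plot(ha, col = grDevices::adjustcolor("darkorange", 0.6),
                   add = TRUE)
  }
  invisible(x)
}
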