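## Records usable for pairing: complete junctions (and, for intron-end
## positions, a long-enough intron end). Truncated records are dropped
## with a message rather than silently.
.usable_records <- function(ds, quiet = FALSE) {
  drop <- ds$truncated
  if (any(drop) && !quiet)
    message(sum(drop), " truncated record(s) dropped from pairing analysis")
  ds[!drop, , drop = FALSE]
}

## Integer class-code matrix (records x mapped positions), codes indexing
## PAIR_CLASSES. The workhorse behind frequencies, sKL and the bootstrap.
.class_code_matrix <- function(ds, model, quiet = FALSE) {
  stopifnot(inherits(ds, "splice_dataset"), inherits(model, "loop_model"))
  ds <- .usable_records(ds, quiet)
  if (nrow(ds) == 0L) stop("no usable records in dataset")
  map <- model$pairing
  bases <- substrate_bases(map$site, map$position,
                           junction = normalize_seq(ds$junction11, "RNA"),
                           intron_start = normalize_seq(ds$intron_start10,
                                                        "RNA"),
                           intron_end = normalize_seq(ds$intron_end60, "RNA"))
  codes <- matrix(0L, nrow(bases), ncol(bases))
  for (j in seq_len(ncol(bases)))
    codes[, j] <- match(classify_pair(bases[, j], map$loop_base[j]),
                        PAIR_CLASSES)
  colnames(codes) <- paste0(map$site, map$position)
  attr(codes, "map") <- map
  codes
}

## logical (3 x P): which classes are attainable at each mapped position
.defined_matrix <- function(map) {
  out <- vapply(map$loop_base,
                function(b) PAIR_CLASSES %in% defined_classes(b),
                logical(3L))
  dimnames(out) <- list(PAIR_CLASSES, paste0(map$site, map$position))
  out
}

#' Positional base-pair class frequencies of a dataset
#'
#' Pairs every record of a dataset with a loop model and returns, for each
#' mapped substrate position, the frequency of Watson-Crick, isosteric and
#' non-isosteric pairs. Classes that cannot occur at a position (uridine
#' loop partners admit no non-isosteric pair) are marked undefined.
#'
#' @param ds a [splice_dataset] (non-empty).
#' @param model a [loop_model()].
#' @return object of class `pair_class_distribution`: list with `freq`
#'   (3 x positions matrix of frequencies), `defined` (logical matrix of
#'   the same shape), `map` (the pairing map) and `n` (records used).
#' @export
position_frequencies <- function(ds, model) {
  codes <- .class_code_matrix(ds, model)
  map <- attr(codes, "map")
  freq <- apply(codes, 2L, tabulate, nbins = 3L) / nrow(codes)
  dimnames(freq) <- list(PAIR_CLASSES, colnames(codes))
  structure(list(freq = freq, defined = .defined_matrix(map),
                 map = map, n = nrow(codes)),
            class = "pair_class_distribution")
}

#' @export
print.pair_class_distribution <- function(x, digits = 3L, ...) {
  cat(sprintf("pair-class frequencies over %d records\n", x$n))
  print(round(x$freq, digits))
  invisible(x)
}

#' Write a positional frequency table as TSV
#'
#' @param x a `pair_class_distribution` from [position_frequencies()].
#' @param path file path.
#' @export
write_frequencies <- function(x, path) {
  stopifnot(inherits(x, "pair_class_distribution"))
  df <- data.frame(site = rep(x$map$site, each = 3L),
                   position = rep(x$map$position, each = 3L),
                   pair_class = rep(PAIR_CLASSES, nrow(x$map)),
                   frequency = as.vector(x$freq),
                   defined = as.vector(x$defined))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
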