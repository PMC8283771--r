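## Resolve substrate bases for (site, position) labels from the sequence
## fragments of a record. Fragments follow the dataset conventions:
##   junction  : 5' exon end joined to 3' exon start, boundary after
##               `junction_exon5` characters (8 for the standard 11-mer)
##   intron_start : intron 5' end, position +k = k-th character
##   intron_end   : intron 3' end, position -k = k-th character from the end
## Vectorized over records; returns a character matrix (records x labels).
substrate_bases <- function(site, position, junction = NULL,
                            intron_start = NULL, intron_end = NULL,
                            junction_exon5 = 8L) {
  stopifnot(length(site) == length(position))
  n <- max(length(junction), length(intron_start), length(intron_end))
  out <- matrix(NA_character_, nrow = n, ncol = length(site))
  for (j in seq_along(site)) {
    pos <- position[j]
    if (site[j] == "exon") {
      if (is.null(junction))
        stop(sprintf("substrate lacks a junction: no base at exon %+d", pos))
      idx <- if (pos < 0L) junction_exon5 + 1L + pos else junction_exon5 + pos
      if (pos == 0L || any(idx < 1L | idx > nchar(junction)))
        stop(sprintf("substrate too short: no base at exon %+d", pos))
      out[, j] <- substr(junction, idx, idx)
    } else if (pos > 0L) {
      if (is.null(intron_start) || any(pos > nchar(intron_start)))
        stop(sprintf("substrate too short: no base at intron %+d", pos))
      out[, j] <- substr(intron_start, pos, pos)
    } else {
      if (is.null(intron_end))
        stop(sprintf("substrate lacks an intron end: no base at intron %d",
                     pos))
      idx <- nchar(intron_end) + 1L + pos
      if (pos == 0L || any(idx < 1L))
        stop(sprintf("substrate too short: no base at intron %d", pos))
      out[, j] <- substring(intron_end, idx, idx)
    }
  }
  out
}

#' Base-pair profile of a substrate against a recognition loop
#'
#' Pairs a splice-site substrate in silico with a loop model and classifies
#' every mapped base pair by its geometry. The substrate is given as the
#' sequence fragments the pairing map draws on: a junction (5' exon end
#' joined to 3' exon start) for exon-site maps such as U5 Loop1, and/or an
#' intron start (and intron end) for intron-site maps such as the U6
#' ACAGAGA box. DNA or RNA alphabet, either case.
#'
#' @param model a [loop_model()].
#' @param junction junction string; the boundary sits after
#'   `junction_exon5` characters (default 8, the standard 11-mer layout).
#' @param intron_start,intron_end intron 5'/3' fragments.
#' @param junction_exon5 number of junction characters upstream of the
#'   exon-exon boundary.
#' @return a data.frame of class `pair_profile`, one row per mapped
#'   substrate position in substrate 5' to 3' order, with columns `site`,
#'   `position`, `substrate_base`, `loop_position`, `loop_base` and
#'   `pair_class`.
#' @examples
#' pair_profile(u5_loop1(), junction = "AAACCCAGGUA")
#' @export
pair_profile <- function(model, junction = NULL, intron_start = NULL,
                         intron_end = NULL, junction_exon5 = 8L) {
  stopifnot(inherits(model, "loop_model"))
  norm <- function(x) if (is.null(x)) NULL else {
    stopifnot(length(x) == 1L)
    normalize_seq(x, "RNA")
  }
  junction <- norm(junction)
  intron_start <- norm(intron_start)
  intron_end <- norm(intron_end)
  map <- model$pairing
  bases <- substrate_bases(map$site, map$position, junction, intron_start,
                           intron_end, junction_exon5)[1L, ]
  out <- data.frame(site = map$site, position = map$position,
                    substrate_base = bases,
                    loop_position = map$loop_position,
                    loop_base = map$loop_base,
                    pair_class = classify_pair(bases, map$loop_base))
  class(out) <- c("pair_profile", "data.frame")
  out
}
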