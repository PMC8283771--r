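#' Enumerate the candidate binding registers of a 15-nt window
#'
#' A scan window holds the last 10 nt of the upstream sequence joined to
#' the first 5 nt of the downstream sequence (declared boundary at 10|11).
#' An 11-residue recognition loop can be superimposed on it in the five
#' registers that keep the 5'-side helix at least as long as the 3'-side:
#' splits 6+5, 7+4, 8+3, 9+2 and 10+1 (5'-side + 3'-side lengths). Each
#' register pairs exactly 11 window positions with the 11 loop residues:
#' upstream positions -1..-s with the loop residues following the split
#' point (read towards the loop 3' end) and downstream positions +1..+t
#' with the residues before it (read towards the loop 5' end).
#'
#' @param loop a [loop_model()] with 11 residues.
#' @param window_len window length (fixed at 15).
#' @return named list of five data.frames (`"6+5"` ... `"10+1"`), each with
#'   columns `window_pos` (1..15), `side_position` (signed, relative to the
#'   boundary), `loop_position` and `loop_base`.
#' @export
enumerate_registers <- function(loop, window_len = 15L) {
  stopifnot(inherits(loop, "loop_model"), window_len == 15L)
  if (length(loop$positions) != 11L)
    stop("register scanning requires an 11-residue loop")
  registers <- lapply(6:10, function(s) {
    t <- 11L - s
    up <- data.frame(window_pos = (10L - s + 1L):10L,
                     side_position = -(s:1),
                     loop_index = (t + s):(t + 1L))
    dn <- data.frame(window_pos = 11L:(10L + t),
                     side_position = seq_len(t),
                     loop_index = t:1L)
    m <- rbind(up, dn)
    m <- m[order(m$window_pos), ]
    m$loop_position <- loop$positions[m$loop_index]
    m$loop_base <- loop$bases[m$loop_index]
    rownames(m) <- NULL
    m[, c("window_pos", "side_position", "loop_position", "loop_base")]
  })
  names(registers) <- sprintf("%d+%d", 6:10, 5:1)
  registers
}

## secondary mismatch-preference score: counts of the pair types in the
## grid's preference order; reported, never used to break ties.
.preference_vector <- function(b1, b2) {
  key <- paste0(canonical_base(b1), canonical_base(b2))
  c(watson_crick = sum(key %in% c("GC", "CG", "AU", "UA")),
    GU_UG = sum(key %in% c("GU", "UG")),
    UU = sum(key == "UU"),
    CU_UC = sum(key %in% c("CU", "UC")))
}

#' Scan a 15-nt window against a loop in all five binding registers
#'
#' Scores every register by its number of Watson-Crick pairs and reports
#' all registers attaining the maximum; ties are reported, never broken.
#' A secondary score vector records the counts of the grid's preferred
#' pair types (Watson-Crick, G-U/U-G, U-U, C-U/U-C) for each register
#' without influencing the choice.
#'
#' @param window a 15-nt sequence (DNA or RNA, either case) with the
#'   declared boundary between positions 10 and 11, or a length-2 vector
#'   `c(upstream10, downstream5)`.
#' @param loop a [loop_model()] with 11 residues.
#' @return an object of class `scan_result`: list with `alignments`
#'   (per-register data.frames with a `pair_class` column and
#'   `wc_count`/`preference` attributes), `wc_counts`, `best_registers`,
#'   `unambiguous` and `window`.
#' @examples
#' scan_registers("TTACCCAGGTAAGTC", u5_loop1())
#' @export
scan_registers <- function(window, loop) {
  if (length(window) == 2L) window <- paste0(window[1L], window[2L])
  stopifnot(length(window) == 1L)
  window <- normalize_seq(window, "RNA")
  if (nchar(window) != 15L)
    stop(sprintf("window must be 15 nt (declared boundary at 10|11), got %d",
                 nchar(window)))
  chars <- strsplit(window, "")[[1L]]
  registers <- enumerate_registers(loop)
  alignments <- lapply(registers, function(m) {
    m$substrate_base <- chars[m$window_pos]
    m$pair_class <- classify_pair(m$substrate_base, m$loop_base)
    attr(m, "wc_count") <- sum(m$pair_class == "watson_crick")
    attr(m, "preference") <- .preference_vector(m$substrate_base,
                                                m$loop_base)
    attr(m, "loop_name") <- loop$name
    m
  })
  wc_counts <- vapply(alignments, attr, 0L, which = "wc_count")
  best <- names(wc_counts)[wc_counts == max(wc_counts)]
  structure(list(alignments = alignments, wc_counts = wc_counts,
                 best_registers = best,
                 unambiguous = length(best) == 1L,
                 window = window, loop = loop$name),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("register scan of %s against %s\n", x$window, x$loop))
  print(x$wc_counts)
  cat(sprintf("best: %s (%s)\n", paste(x$best_registers, collapse = ", "),
              if (x$unambiguous) "unambiguous" else "ambiguous"))
  invisible(x)
}

#' Scan many windows and tabulate best registers
#'
#' @param windows character vector of 15-nt windows.
#' @param loop a [loop_model()].
#' @return data.frame with one row per window: `best_registers`
#'   (comma-separated when tied), `wc_count` and `unambiguous`.
#' @export
scan_windows <- function(windows, loop) {
  res <- lapply(windows, scan_registers, loop = loop)
  data.frame(window = vapply(res, `[[`, "", "window"),
             best_registers = vapply(res, function(r)
               paste(r$best_registers, collapse = ","), ""),
             wc_count = vapply(res, function(r) max(r$wc_counts), 0L),
             unambiguous = vapply(res, `[[`, TRUE, "unambiguous"))
}

#' Base-pair composition of a set of chosen alignments
#'
#' Summarizes the pair-type content of a collection of 11-bp alignments
#' (e.g. the unambiguously aligned windows of a scan), overall and per
#' loop position, both at geometry-class resolution and for the individual
#' unordered pair types (G:C, G:U, ...). All alignments must come from the
#' same loop.
#'
#' @param alignments a list of alignment data.frames as found in
#'   `scan_result$alignments`, or of [pair_profile()]s.
#' @return list with elements `n_pairs`, `n_alignments`, `by_class`,
#'   `by_pair` (overall counts and percentages) and `per_position`
#'   (class counts per loop position).
#' @export
composition_summary <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments supplied")
  loops <- unique(vapply(alignments, function(a) {
    ln <- attr(a, "loop_name")
    if (is.null(ln)) "unknown" else ln
  }, ""))
  if (length(loops) > 1L)
    stop("alignments from different loops cannot be summarized together: ",
         paste(loops, collapse = ", "))
  all_df <- do.call(rbind, lapply(alignments, function(a)
    data.frame(loop_position = a$loop_position,
               substrate_base = canonical_base(a$substrate_base),
               loop_base = a$loop_base, pair_class = a$pair_class)))
  n <- nrow(all_df)
  by_class <- as.data.frame(table(factor(all_df$pair_class,
                                         levels = PAIR_CLASSES)),
                            responseName = "count")
  names(by_class)[1L] <- "pair_class"
  by_class$percent <- 100 * by_class$count / n
  pair_label <- apply(cbind(all_df$substrate_base, all_df$loop_base), 1L,
                      function(p) paste(sort(p), collapse = ":"))
  by_pair <- as.data.frame(table(pair_label), responseName = "count")
  names(by_pair)[1L] <- "pair"
  by_pair <- by_pair[order(-by_pair$count), ]
  rownames(by_pair) <- NULL
  by_pair$percent <- 100 * by_pair$count / n
  per_position <- as.data.frame.matrix(
    table(all_df$loop_position, factor(all_df$pair_class,
                                       levels = PAIR_CLASSES)))
  list(n_pairs = n, n_alignments = length(alignments),
       by_class = by_class, by_pair = by_pair,
       per_position = per_position)
}

#' Read 15-nt scan windows from a FASTA file
#'
#' @param path FASTA of 15-nt windows (the description line is kept as the
#'   window name; the boundary is the declared 10|11 split).
#' @return named character vector of windows.
#' @export
read_windows_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
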