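## Canonical RNA alphabet used throughout the package.
RNA_BASES <- c("A", "C", "G", "U")

## The three geometry classes, in the fixed order used by every table.
PAIR_CLASSES <- c("watson_crick", "isosteric", "non_isosteric")

## Ordered-pair -> class lookup, built once at load time.
## Watson-Crick: the four canonical pairs. Isosteric: mismatches that can
## adopt Watson-Crick-like geometry through tautomerization or protonation
## (G-U, U-U, C-U, A-C). Non-isosteric: purine-purine pairs and C-C, which
## cannot. The three sets partition all 16 ordered pairs (4 / 7 / 5).
.pair_class_table <- local({
  wc  <- c("GC", "CG", "AU", "UA")
  iso <- c("GU", "UG", "UU", "CU", "UC", "AC", "CA")
  all16 <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  cls <- ifelse(all16 %in% wc, "watson_crick",
                ifelse(all16 %in% iso, "isosteric", "non_isosteric"))
  names(cls) <- all16
  cls
})

#' Normalize residue symbols to their parent RNA base
#'
#' Maps an input residue symbol to one of `A`, `C`, `G`, `U`. DNA thymidine
#' (`T`) maps to `U`, pseudouridine (`\u03a8`) maps to `U`, and
#' modification-annotated residues such as `Gm` (2'-O-methylguanosine) or
#' `Am6` (N6-methyladenosine) are stripped to their parent base: base
#' modifications change neither the Watson-Crick edge used here nor the
#' geometry class of the pairs a residue can form.
#'
#' @param raw_code character vector of residue symbols. Accepted symbols are
#'   `A`, `C`, `G`, `T`, `U` (either case), `\u03a8`, and any of these
#'   followed by a modification annotation matching `[m0-9']+` (e.g. `Um`,
#'   `Am6`, `Gm2`).
#' @return character vector of the same length over `A`, `C`, `G`, `U`.
#' @examples
#' canonical_base(c("\u03a8", "T", "Gm", "a"))
#' @export
canonical_base <- function(raw_code) {
  if (length(raw_code) == 0L) return(character(0))
  if (!is.character(raw_code)) stop("residue symbols must be character")
  parent <- toupper(substr(raw_code, 1L, 1L))
  suffix <- substr(raw_code, 2L, nchar(raw_code))
  ok <- (parent %in% c("A", "C", "G", "T", "U", "\u03a8")) &
    (suffix == "" | grepl("^[m0-9',]+$", suffix))
  ok[is.na(raw_code)] <- FALSE
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("unknown residue symbol '%s' at position %d",
                 raw_code[bad], bad))
  }
  out <- parent
  out[out == "T" | out == "\u03a8"] <- "U"
  out
}

#' Classify a substrate:snRNA base pair by its geometry
#'
#' Assigns one of three geometry classes to each base pair:
#' `watson_crick` (G=C/C=G, A-U/U-A), `isosteric` (G-U/U-G, U-U, C-U/U-C,
#' A-C/C-A -- mismatches that can mimic Watson-Crick geometry via rare
#' tautomers or protonation) or `non_isosteric` (A-G/G-A, A-A, G-G, C-C).
#' Classification is symmetric and total over the 16 ordered pairs.
#'
#' @param b1,b2 character vectors of residue symbols (recycled to a common
#'   length); normalized internally with [canonical_base()].
#' @return character vector of geometry class labels.
#' @examples
#' classify_pair("G", "C")
#' classify_pair("G", "G")
#' classify_pair("\u03a8", "A")
#' @export
classify_pair <- function(b1, b2) {
  b1 <- canonical_base(b1)
  b2 <- canonical_base(b2)
  unname(.pair_class_table[paste0(b1, b2)])
}

#' Geometry classes a loop residue can form
#'
#' The set of pair classes that are possible at a substrate position given
#' its loop partner. A uridine partner can never yield a non-isosteric pair
#' (uracil forms Watson-Crick or isosteric pairs with every base), which is
#' why those positions carry only two testable frequency classes.
#'
#' @param loop_base a single residue symbol.
#' @return character vector: subset of
#'   `c("watson_crick", "isosteric", "non_isosteric")`.
#' @export
defined_classes <- function(loop_base) {
  stopifnot(length(loop_base) == 1L)
  cls <- classify_pair(RNA_BASES, rep(canonical_base(loop_base), 4L))
  PAIR_CLASSES[PAIR_CLASSES %in% cls]
}

## Normalize a nucleic-acid string: uppercase and, for RNA, T -> U.
## "N" is tolerated when allow_n = TRUE (used for flagged truncated records).
normalize_seq <- function(x, to = c("RNA", "DNA"), allow_n = FALSE) {
  to <- match.arg(to)
  x <- toupper(x)
  x <- if (to == "RNA") chartr("T", "U", x) else chartr("U", "T", x)
  alphabet <- if (to == "RNA") "ACGUN" else "ACGTN"
  if (!allow_n) alphabet <- substr(alphabet, 1L, 4L)
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(x[i], regexpr(sprintf("[^%s]", alphabet), x[i]))
    stop(sprintf("sequence %d contains unexpected symbol '%s'", i, ch))
  }
  x
}

## Watson-Crick complement in RNA alphabet (used to build fully
## complementary substrates in tests and examples).
rna_complement <- function(x) chartr("ACGU", "UGCA", normalize_seq(x, "RNA"))
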