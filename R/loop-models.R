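#' Recognition loop models
#'
#' A `loop_model` describes an snRNA (or group II intron) recognition
#' element: its ordered residues (with modification annotations kept as raw
#' symbols) and a pairing map from substrate position labels to loop
#' position labels. Substrate positions are signed integers on one of two
#' coordinate systems: `site = "exon"` uses splice-junction coordinates
#' (negative = 5' exon end counted back from the junction, positive =
#' 3' exon start) and `site = "intron"` uses intron coordinates (positive
#' from the 5' end, negative from the 3' end).
#'
#' @param name identifier for the loop.
#' @param positions integer vector of loop position labels, 5' to 3'.
#' @param residues character vector of raw residue symbols, same length as
#'   `positions` (e.g. `"Gm"` for 2'-O-methylguanosine).
#' @param pairing data.frame with columns `site` (`"exon"` or `"intron"`),
#'   `position` (signed integer substrate label) and `loop_position`
#'   (must be one of `positions`).
#' @return an object of class `loop_model` with elements `name`,
#'   `positions`, `residues` (raw), `bases` (canonical) and `pairing`
#'   (with an added `loop_base` column, ordered substrate 5' to 3').
#' @seealso [u5_loop1()], [u6_acagaga()], [u1_5prime()], [ltrb_id3()]
#' @export
loop_model <- function(name, positions, residues, pairing) {
  stopifnot(is.character(name), length(name) == 1L,
            length(positions) == length(residues),
            !anyDuplicated(positions))
  positions <- as.integer(positions)
  bases <- canonical_base(residues)
  stopifnot(is.data.frame(pairing),
            all(c("site", "position", "loop_position") %in% names(pairing)))
  if (!all(pairing$site %in% c("exon", "intron")))
    stop("pairing sites must be 'exon' or 'intron'")
  if (!all(pairing$loop_position %in% positions))
    stop("pairing map refers to loop positions absent from the model")
  key <- paste(pairing$site, pairing$position)
  if (anyDuplicated(key))
    stop("duplicated substrate position in pairing map: ",
         key[duplicated(key)][1L])
  pairing$position <- as.integer(pairing$position)
  pairing$loop_position <- as.integer(pairing$loop_position)
  pairing$loop_base <- bases[match(pairing$loop_position, positions)]
  ## canonical substrate order: 5' exon end (most upstream first), then
  ## 3' exon start; intron positions ascending with 3'-end labels last.
  ord <- order(match(pairing$site, c("exon", "intron")),
               sign(pairing$position) >= 0,
               pairing$position)
  pairing <- pairing[ord, , drop = FALSE]
  rownames(pairing) <- NULL
  structure(list(name = name, positions = positions, residues = residues,
                 bases = bases, pairing = pairing),
            class = "loop_model")
}

#' @export
print.loop_model <- function(x, ...) {
  cat(sprintf("Loop model '%s' (%d residues)\n", x$name, length(x$positions)))
  cat(" ", paste(sprintf("%d=%s", x$positions, x$residues), collapse = " "),
      "\n")
  cat(sprintf("  pairing map: %d substrate positions (%s)\n",
              nrow(x$pairing),
              paste(unique(x$pairing$site), collapse = ", ")))
  invisible(x)
}

.pairing_df <- function(site, position, loop_position) {
  data.frame(site = site, position = as.integer(position),
             loop_position = as.integer(loop_position))
}

#' Default U5 snRNA Loop1 model
#'
#' The invariant 11-nt loop of human U5 snRNA, positions 36-46, with its
#' post-transcriptional modifications (2'-O-methyl G37 and U41,
#' pseudouridine 43). Five of the eleven residues are uracils. The default
#' pairing map is the proposed fixed binding register that places the exon
#' junction at loop C39|C38: 5' exon positions -1..-8 pair loop 39..46 and
#' 3' exon positions +1..+3 pair loop 38..36, so the conserved exon-end
#' guanine forms G=C with loop C39.
#'
#' Residues 45 and 46 are not directly readable from published loop
#' diagrams; the defaults (`A`, `C`) are fixed by internal consistency
#' (exactly five uracils, and uridine partners only at exon -2..-6) and can
#' be overridden.
#'
#' @param residues_45_46 residues at loop positions 45 and 46.
#' @return a [loop_model()].
#' @export
u5_loop1 <- function(residues_45_46 = c("A", "C")) {
  stopifnot(length(residues_45_46) == 2L)
  res <- c("C", "Gm", "C", "C", "U", "Um", "U", "\u03a8", "U",
           residues_45_46)
  pairing <- rbind(
    .pairing_df("exon", -(1:8), 39:46),
    .pairing_df("exon", 1:3, 38:36)
  )
  loop_model("U5_loop1", 36:46, res, pairing)
}

#' Default U6 snRNA ACAGAGA-box model
#'
#' U6 snRNA positions 37-47 (5' to 3': C G A U A C A G A G A), whose
#' 42..37 stretch pairs intron positions +5..+10 in the pre-catalytic
#' spliceosome; the conserved intron +5G forms G=C with U6 C42. Position
#' +7 faces the single uridine partner (U40).
#'
#' @return a [loop_model()].
#' @export
u6_acagaga <- function() {
  res <- c("C", "G", "A", "U", "A", "C", "A", "G", "A", "G", "A")
  pairing <- .pairing_df("intron", 5:10, 42:37)
  loop_model("U6_acagaga", 37:47, res, pairing)
}

#' Default U1 snRNA 5'-end model
#'
#' The 11 5'-terminal residues of human U1 snRNA (A U A C \u03a8 \u03a8 A C C U G,
#' positions 1-11). In the early spliceosome the exon/intron boundary pairs
#' antiparallel across it: exon -3..-1 with C9 U10 G11 (read as
#' exon -1 with C9) and intron +1..+8 with positions 8..1.
#'
#' @return a [loop_model()].
#' @export
u1_5prime <- function() {
  res <- c("A", "U", "A", "C", "\u03a8", "\u03a8", "A", "C", "C", "U", "G")
  pairing <- rbind(
    .pairing_df("exon", -(1:3), 9:11),
    .pairing_df("intron", 1:8, 8:1)
  )
  loop_model("U1_5prime", 1:11, res, pairing)
}

#' Default Ll.LtrB group IIA intron Id3 loop model
#'
#' The 11-nt Id3 loop of domain I of the Lactococcus lactis Ll.LtrB intron,
#' positions 275-285. Seven residues (EBS1, 279-285) pair the 5' exon end
#' and four (delta, 275-278) pair the 3' exon start, so the canonical
#' register split is 7+4 with the junction coordinated by G278|G279.
#'
#' The loop sequence is not available in machine-readable form; this
#' default is a reconstruction consistent with the stated constraints
#' (11 nt with five uracils; guanines at 278/279 coordinating the junction
#' C=G pairs; G282 facing substrate position -4) and should be overridden
#' with the true sequence where available.
#'
#' @param residues optional replacement character vector of 11 residues
#'   for positions 275-285.
#' @return a [loop_model()].
#' @export
ltrb_id3 <- function(residues = NULL) {
  res <- c("A", "U", "U", "G", "G", "U", "U", "G", "U", "A", "C")
  if (!is.null(residues)) {
    stopifnot(length(residues) == 11L)
    res <- residues
  }
  pairing <- rbind(
    .pairing_df("exon", -(1:7), 279:285),
    .pairing_df("exon", 1:4, 278:275)
  )
  loop_model("LtrB_Id3", 275:285, res, pairing)
}

#' Read or write a loop model as a structured text config
#'
#' Loop models are serialized as YAML with the loop name, ordered residues
#' keyed by integer position label (modification annotations preserved) and
#' pairing entries of the form `"exon:-1 -> 39"`.
#'
#' @param model a [loop_model()].
#' @param path file path.
#' @return `read_loop_model()` returns a [loop_model()];
#'   `write_loop_model()` returns `path` invisibly.
#' @export
write_loop_model <- function(model, path) {
  stopifnot(inherits(model, "loop_model"))
  obj <- list(
    name = model$name,
    residues = stats::setNames(as.list(model$residues),
                               as.character(model$positions)),
    pairing = sprintf("%s:%+d -> %d", model$pairing$site,
                      model$pairing$position, model$pairing$loop_position)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_loop_model
#' @export
read_loop_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$name) || is.null(obj$residues) || is.null(obj$pairing))
    stop("loop model config must contain 'name', 'residues' and 'pairing'")
  positions <- as.integer(names(obj$residues))
  m <- regmatches(obj$pairing,
                  regexec("^\\s*(exon|intron):([+-]?\\d+)\\s*->\\s*(\\d+)\\s*$",
                          obj$pairing))
  if (any(lengths(m) != 4L))
    stop("malformed pairing entry: ", obj$pairing[which(lengths(m) != 4L)[1L]])
  pairing <- .pairing_df(vapply(m, `[`, "", 2L),
                         as.integer(vapply(m, `[`, "", 3L)),
                         as.integer(vapply(m, `[`, "", 4L)))
  loop_model(obj$name, positions, unlist(obj$residues, use.names = FALSE),
             pairing)
}
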