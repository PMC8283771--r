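#' Bonferroni-Dunn significance threshold
#'
#' Dunn's alpha-splitting for `m` simultaneous tests: `alpha' = alpha / m`.
#'
#' @param m number of tests (>= 1).
#' @param alpha base significance level (default 0.05).
#' @param digits optional rounding of the returned threshold (the
#'   conventional presentation uses 4 decimals).
#' @return the corrected threshold `alpha / m`.
#' @examples
#' dunn_threshold(28, digits = 4)  # 0.0018
#' dunn_threshold(76, digits = 4)  # 0.0007
#' @export
dunn_threshold <- function(m, alpha = 0.05, digits = NULL) {
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a single integer >= 1")
  out <- alpha / m
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Correlation-adjusted effective number of tests
#'
#' Tests of pair-class frequencies at one position are strongly
#' correlated (the frequencies sum to one), so the plain Bonferroni count
#' overcorrects. For a group of `m` correlated tests with interclass
#' correlation `R`, the effective count is
#' `m' = (m + 1) - [1 + (m - 1) * R]`, i.e. `m - (m - 1) * R`: two
#' perfectly correlated tests (`R = 1`) count as one. Each group's `m'`
#' is rounded to the nearest integer before summation.
#'
#' @param groups correlated test groups: a list of `c(size, R)` pairs or a
#'   data.frame/matrix with columns `size` and `R`.
#' @return integer: the summed adjusted test count.
#' @examples
#' adjusted_m(list(c(2, 1)))              # 1
#' adjusted_m(list(c(3, 0.5)))            # 2
#' adjusted_m(c(rep(list(c(3, 0.5)), 5), list(c(2, 1))))  # 11
#' @export
adjusted_m <- function(groups) {
  if (is.data.frame(groups) || is.matrix(groups))
    groups <- lapply(seq_len(nrow(groups)),
                     function(i) unlist(groups[i, c("size", "R")]))
  sizes <- vapply(groups, function(g) as.numeric(g[[1L]]), 0)
  R <- vapply(groups, function(g) as.numeric(g[[2L]]), 0)
  if (any(sizes < 1)) stop("group sizes must be >= 1")
  if (any(R < 0 | R > 1)) stop("interclass correlation R must be in [0, 1]")
  m_prime <- (sizes + 1) - (1 + (sizes - 1) * R)
  as.integer(sum(round(m_prime)))
}

#' Multiple-testing correction plan for a bootstrap experiment
#'
#' Counts the tests implied by a loop model's pairing map -- positions with
#' a uridine loop partner carry two pair-class tests (no non-isosteric
#' pair exists there), all others three -- groups them per position with
#' default interclass correlations (R = 1 for two tests, 0.5 for three,
#' 0.33 for four), and derives both the plain Dunn threshold `alpha / m`
#' and the correlation-adjusted `alpha / m'`. Extra test groups (e.g. the
#' four nucleotide-level tests at exon -3) can be appended.
#'
#' @param model a [loop_model()].
#' @param extra_tests optional additional groups in the [adjusted_m()]
#'   format.
#' @param alpha base significance level.
#' @param default_R named vector mapping group size to its default R.
#' @return object of class `correction_plan`: list with `m`, `m_prime`,
#'   `alpha`, `alpha_prime`, `alpha_prime_adjusted` and the `groups`
#'   data.frame.
#' @examples
#' build_correction_plan(u6_acagaga())  # m = 17, m' = 11
#' build_correction_plan(u5_loop1())    # m = 28, m' = 17
#' @export
build_correction_plan <- function(model, extra_tests = NULL, alpha = 0.05,
                                  default_R = c("2" = 1, "3" = 0.5,
                                                "4" = 0.33)) {
  stopifnot(inherits(model, "loop_model"))
  sizes <- vapply(model$pairing$loop_base,
                  function(b) length(defined_classes(b)), 0L)
  groups <- data.frame(group = paste0(model$pairing$site,
                                      model$pairing$position),
                       size = sizes,
                       R = unname(default_R[as.character(sizes)]))
  if (anyNA(groups$R))
    stop("no default R for a group of size ",
         groups$size[which(is.na(groups$R))[1L]])
  if (!is.null(extra_tests)) {
    if (is.data.frame(extra_tests) || is.matrix(extra_tests))
      extra_tests <- lapply(seq_len(nrow(extra_tests)), function(i)
        unlist(extra_tests[i, c("size", "R")]))
    extra <- data.frame(group = sprintf("extra%d",
                                        seq_along(extra_tests)),
                        size = vapply(extra_tests,
                                      function(g) as.numeric(g[[1L]]), 0),
                        R = vapply(extra_tests,
                                   function(g) as.numeric(g[[2L]]), 0))
    groups <- rbind(groups, extra)
  }
  m <- as.integer(sum(groups$size))
  m_prime <- adjusted_m(groups)
  structure(list(m = m, m_prime = m_prime, alpha = alpha,
                 alpha_prime = alpha / m,
                 alpha_prime_adjusted = alpha / m_prime,
                 groups = groups),
            class = "correction_plan")
}

#' @export
print.correction_plan <- function(x, ...) {
  cat(sprintf("correction plan: m = %d tests in %d groups\n",
              x$m, nrow(x$groups)))
  cat(sprintf("  alpha' = %.4g (plain Dunn, alpha = %g)\n",
              x$alpha_prime, x$alpha))
  cat(sprintf("  m' = %d correlation-adjusted, alpha' = %.4g\n",
              x$m_prime, x$alpha_prime_adjusted))
  invisible(x)
}
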