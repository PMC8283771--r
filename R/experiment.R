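#' Run a full conserved-position substitution experiment
#'
#' Orchestrates the pipeline for one conserved splice-site position:
#' partitions the dataset ([partition_dataset()]), computes positional
#' base-pair frequencies for both groups ([position_frequencies()]), runs
#' the sKL control experiment ([skl_control_experiment()]) and the
#' bootstrap-difference tests ([bootstrap_differences()]), builds the
#' multiple-testing correction plan ([build_correction_plan()]) and flags
#' significance at both the plain and the correlation-adjusted Dunn
#' thresholds. The `plus5G` and `minus3C` experiments examine the U5-bound
#' splice junction; `minus1G` examines the U6-bound intron start. For
#' `plus5G`, the nucleotide-level bootstrap at exon -3 (the position where
#' U5 and U1 select different bases) is run as well and its four tests are
#' appended to the correction plan.
#'
#' @param ds a [splice_dataset].
#' @param criterion `"plus5G"`, `"minus1G"` or `"minus3C"`.
#' @param iterations resampling iterations for both the sKL control and
#'   the bootstrap (default 10000).
#' @param seed integer seed; subsidiary seeds for the sKL, bootstrap and
#'   nucleotide stages are derived from it by fixed offsets so each stage
#'   is independently reproducible.
#' @param skl run the sKL control stage (skipped when the reference is
#'   smaller than twice the case set).
#' @param model optional [loop_model()] override.
#' @return object of class `substitution_experiment`: list with
#'   `partition` sizes, `frequencies` (per group), `skl`, `bootstrap`
#'   (table gains `significant_plain` / `significant_adjusted` columns),
#'   `nucleotide` (exon -3, `plus5G` only), `plan` and `provenance`.
#' @export
run_substitution_experiment <- function(ds,
                                        criterion = c("plus5G", "minus1G",
                                                      "minus3C"),
                                        iterations = 10000L, seed = 1L,
                                        skl = TRUE, model = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(model))
    model <- if (criterion == "minus1G") u6_acagaga() else u5_loop1()
  parts <- partition_dataset(ds, criterion)
  conserved <- parts$conserved
  substituted <- parts$substituted
  if (nrow(conserved) == 0L || nrow(substituted) == 0L)
    stop("both partitions must be non-empty to compare them")

  freq_sub <- position_frequencies(substituted, model)
  freq_con <- position_frequencies(conserved, model)

  subsites <- if (criterion == "minus1G") u6_subsites() else u5_subsites()
  skl_res <- NULL
  if (skl && nrow(conserved) >= 2L * nrow(substituted))
    skl_res <- skl_control_experiment(conserved, substituted, model,
                                      subsites, iterations,
                                      seed = seed + 1000L)

  extra <- NULL
  nt_res <- NULL
  if (criterion == "plus5G") {
    nt_res <- nucleotide_bootstrap(substituted, conserved, position = -3L,
                                   site = "exon", iterations = iterations,
                                   seed = seed + 3000L)
    extra <- list(c(4, 0.33))
  }
  plan <- build_correction_plan(model, extra_tests = extra)

  boot <- bootstrap_differences(substituted, conserved, model, iterations,
                                seed = seed + 2000L)
  boot$table$significant_plain <- boot$table$p_h0 < plan$alpha_prime
  boot$table$significant_adjusted <-
    boot$table$p_h0 < plan$alpha_prime_adjusted
  if (!is.null(nt_res)) {
    nt_res$table$significant_plain <- nt_res$table$p_h0 < plan$alpha_prime
    nt_res$table$significant_adjusted <-
      nt_res$table$p_h0 < plan$alpha_prime_adjusted
  }

  structure(list(criterion = criterion,
                 n_conserved = nrow(conserved),
                 n_substituted = nrow(substituted),
                 frequencies = list(substituted = freq_sub,
                                    conserved = freq_con),
                 skl = skl_res, bootstrap = boot, nucleotide = nt_res,
                 plan = plan,
                 provenance = list(criterion = criterion,
                                   iterations = iterations, seed = seed,
                                   model = model$name,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "splicepairs")))),
            class = "substitution_experiment")
}

#' @export
print.substitution_experiment <- function(x, ...) {
  cat(sprintf("substitution experiment '%s': %d substituted vs %d conserved\n",
              x$criterion, x$n_substituted, x$n_conserved))
  if (!is.null(x$skl)) {
    cat("sKL mean ratios by subsite:\n")
    print(round(x$skl$mean_ratio, 3L))
  }
  print(x$plan)
  sig <- x$bootstrap$table
  sig <- sig[sig$defined & sig$significant_adjusted, , drop = FALSE]
  cat(sprintf("%d (position, class) cells significant at alpha/m'\n",
              nrow(sig)))
  if (nrow(sig))
    print(sig[, c("site", "position", "pair_class", "observed_diff",
                  "p_h0")], digits = 3L)
  invisible(x)
}

#' Write the tables of a substitution experiment as TSV files
#'
#' Emits `frequencies_substituted.tsv`, `frequencies_conserved.tsv`,
#' `skl_distributions.tsv` (when run), `bootstrap_tests.tsv` and, when
#' present, `nucleotide_tests.tsv` into a directory.
#'
#' @param x a `substitution_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "substitution_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_frequencies(x$frequencies$substituted,
                    file.path(dir, "frequencies_substituted.tsv"))
  write_frequencies(x$frequencies$conserved,
                    file.path(dir, "frequencies_conserved.tsv"))
  if (!is.null(x$skl)) {
    skl_df <- data.frame(iteration = seq_len(nrow(x$skl$case)))
    for (s in colnames(x$skl$case)) {
      skl_df[[paste0("case_", s)]] <- x$skl$case[, s]
      skl_df[[paste0("control_", s)]] <- x$skl$control[, s]
    }
    utils::write.table(skl_df, file.path(dir, "skl_distributions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(x$bootstrap$table,
                     file.path(dir, "bootstrap_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$nucleotide))
    utils::write.table(x$nucleotide$table,
                       file.path(dir, "nucleotide_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
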