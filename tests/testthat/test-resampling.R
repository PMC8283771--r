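test_that("positional frequencies count classes per position", {
  ## two records, both G at exon -1 (partner C39): P(watson_crick) = 1
  ds2 <- minus1_dataset(c("G", "G"))
  f <- position_frequencies(ds2, u5_loop1())
  expect_equal(f$n, 2L)
  expect_equal(f$freq["watson_crick", "exon-1"], 1)
  expect_equal(colSums(f$freq), rep(1, 11), ignore_attr = TRUE)

  ## four records with -1 = {G, G, A, U} vs C39: WC 0.5, isosteric 0.5
  ds4 <- minus1_dataset(c("G", "G", "A", "U"))
  f4 <- position_frequencies(ds4, u5_loop1())
  expect_equal(f4$freq["watson_crick", "exon-1"], 0.5)
  expect_equal(f4$freq["isosteric", "exon-1"], 0.5)
  expect_equal(f4$freq["non_isosteric", "exon-1"], 0)

  ## defined classes at exon -4 (partner U42): no non-isosteric
  expect_true(f4$defined["watson_crick", "exon-4"])
  expect_true(f4$defined["isosteric", "exon-4"])
  expect_false(f4$defined["non_isosteric", "exon-4"])

  expect_error(position_frequencies(generate_dataset(site_frequency_model(),
                                                     0),
                                    u5_loop1()),
               "no usable records")
})

test_that("sKL divergence matches its direct evaluation and properties", {
  ## frozen from an independent evaluation of the two-term sum with the
  ## 0.0001 increment: P = (1, 0), Q = (0.5, 0.5)
  expect_equal(skl_divergence(c(1, 0), c(0.5, 0.5)), 6.643928320920272,
               tolerance = 1e-12)
  expect_equal(skl_divergence(c(0.5, 0.5), c(1, 0)),
               skl_divergence(c(1, 0), c(0.5, 0.5)))
  set.seed(31)
  for (i in 1:25) {
    p <- matrix(stats::runif(12), 3L)
    p <- sweep(p, 2L, colSums(p), "/")
    q <- matrix(stats::runif(12), 3L)
    q <- sweep(q, 2L, colSums(q), "/")
    expect_gte(skl_divergence(p, q), 0)
    expect_equal(skl_divergence(p, q), skl_divergence(q, p))
    expect_equal(skl_divergence(p, p), 0)
  }
  expect_error(skl_divergence(c(1, 0), c(1, 0, 0)), "identical shape")
})

test_that("the sKL control experiment is reproducible and sized", {
  model <- site_frequency_model()
  ref <- generate_dataset(model, 150, seed = 21)
  case <- generate_dataset(model, 40, seed = 22)
  r1 <- skl_control_experiment(ref, case, u5_loop1(), iterations = 3L,
                               seed = 7)
  r2 <- skl_control_experiment(ref, case, u5_loop1(), iterations = 3L,
                               seed = 7)
  expect_equal(dim(r1$case), c(3L, 4L))
  expect_equal(dim(r1$control), c(3L, 4L))
  expect_identical(r1$case, r2$case)
  expect_identical(r1$control, r2$control)
  expect_true(all(r1$case >= 0) && all(r1$control >= 0))
  expect_equal(r1$provenance$subset_size, 40L)
  expect_error(skl_control_experiment(case, ref, u5_loop1()),
               "reference too small")
})

test_that("null case sets give mean sKL ratios near 1", {
  ## one fixed case draw makes the per-subsite ratio noisy (its own
  ## sampling deviation dominates the numerator), so the null property
  ## is checked on the geometric mean across independent case draws
  model <- site_frequency_model()
  set.seed(61)
  ratios <- replicate(8, {
    ref <- generate_dataset(model, 200)
    case <- generate_dataset(model, 80)
    skl_control_experiment(ref, case, u5_loop1(),
                           iterations = 250L)$mean_ratio
  })
  expect_true(all(is.finite(ratios) & ratios > 0))
  gm <- exp(mean(log(ratios)))
  expect_gt(gm, 0.8)
  expect_lt(gm, 1.25)
})

test_that("an injected shift raises the ratio only at its subsite", {
  model <- site_frequency_model()
  ref <- generate_dataset(model, 400, seed = 71)
  case <- generate_dataset(model, 120, seed = 72)
  ## shift exon -1 and -2 towards all-G: hits the exon -2..-1 subsite
  case$junction11 <- paste0(substr(case$junction11, 1, 6), "GG",
                            substr(case$junction11, 9, 11))
  res <- skl_control_experiment(ref, case, u5_loop1(), iterations = 500L,
                                seed = 73)
  shifted <- res$mean_ratio[["exon_-2_-1"]]
  expect_gt(shifted, res$mean_ratio[["exon_-8_-6"]])
  expect_gt(shifted, res$mean_ratio[["exon_+1_+3"]])
})

test_that("bootstrap differences behave on degenerate inputs", {
  ds <- minus1_dataset(rep(c("G", "A", "U", "C"), 10))
  same <- bootstrap_differences(ds, ds, u5_loop1(), iterations = 400L,
                                seed = 5)
  tab <- same$table[same$table$defined, ]
  ## identical sets: BD distributions centered at 0, P(H0) near 0.5
  expect_true(all(tab$p_h0 > 0.25))
  expect_true(all(abs(tab$observed_diff) < 1e-12))

  ## constant case: all-G vs all-A at exon -1
  a <- minus1_dataset(rep("G", 12))
  b <- minus1_dataset(rep("A", 12))
  res <- bootstrap_differences(a, b, u5_loop1(), iterations = 200L,
                               seed = 6)
  row <- res$table[res$table$position == -1 &
                     res$table$pair_class == "watson_crick", ]
  expect_equal(row$observed_diff, 1)
  expect_equal(row$p_h0, 0)
  wc_col <- which(res$table$position == -1 &
                    res$table$pair_class == "watson_crick")
  expect_true(all(res$bd[, wc_col] == 1))
})

test_that("bootstrap runs are seed-reproducible and frequencies conserve", {
  model <- site_frequency_model()
  a <- generate_dataset(model, 60, seed = 81)
  b <- generate_dataset(model, 90, seed = 82)
  r1 <- bootstrap_differences(a, b, u5_loop1(), iterations = 100L, seed = 9)
  r2 <- bootstrap_differences(a, b, u5_loop1(), iterations = 100L, seed = 9)
  expect_identical(r1$bd, r2$bd)
  expect_identical(r1$table, r2$table)
  ## class frequencies sum to 1 in each resample of each set, so the BDs
  ## at one position sum to 0 across classes, every iteration
  for (pos in c(-8L, -3L, 1L)) {
    cols <- which(r1$table$position == pos)
    expect_equal(rowSums(r1$bd[, cols, drop = FALSE]), rep(0, 100L),
                 tolerance = 1e-12)
  }
  ## undefined cells are never tested; ties can push P(H0) slightly
  ## above 0.5 (they are counted in both tails before the minimum)
  expect_true(all(is.na(r1$table$p_h0[!r1$table$defined])))
  p <- r1$table$p_h0[r1$table$defined]
  expect_true(all(p >= 0 & p <= 1))
  ties <- colMeans(r1$bd[, r1$table$defined, drop = FALSE] == 0)
  expect_true(all(p <= (1 + ties) / 2 + 1e-9))
})

test_that("nucleotide bootstrap tracks single-position composition", {
  a <- minus1_dataset(rep("G", 15))   # exon -3 is "A" in every record
  b_rows <- do.call(rbind, lapply(1:15, function(i) {
    as.data.frame(extract_splice_elements(
      exons = c("AAAAACAG", "GTTA"),
      introns = paste0("GTAAGTATTT", strrep("T", 44), "TTTCAG")))
  }))
  b_rows$intron_index <- seq_len(nrow(b_rows))
  b <- splicepairs:::.as_splice_dataset(b_rows)  # exon -3 is "C"
  res <- nucleotide_bootstrap(a, b, position = -3L, iterations = 150L,
                              seed = 4)
  expect_equal(res$table$observed_diff[res$table$nucleotide == "A"], 1)
  expect_equal(res$table$observed_diff[res$table$nucleotide == "C"], -1)
  expect_equal(res$table$p_h0[res$table$nucleotide == "A"], 0)
  expect_equal(res$table$p_h0[res$table$nucleotide == "C"], 0)
  ## per-iteration nucleotide frequencies sum to 1 in each resample
  expect_equal(rowSums(res$bd), rep(0, 150L), tolerance = 1e-12)
  ## identical sets: every nucleotide near 0.5
  same <- nucleotide_bootstrap(a, a, position = -3L, iterations = 150L,
                               seed = 4)
  expect_true(all(same$table$p_h0[same$table$freq_A > 0] > 0.25))
})

test_that("Dunn thresholds reproduce the printed corrections", {
  expect_equal(dunn_threshold(1), 0.05)
  expect_equal(dunn_threshold(28, digits = 4), 0.0018)
  expect_equal(dunn_threshold(76, digits = 4), 0.0007)
  expect_error(dunn_threshold(0), "m must be")
})

test_that("correlation-adjusted test counts follow the groupwise formula", {
  expect_equal(adjusted_m(list(c(2, 1))), 1L)
  expect_equal(adjusted_m(list(c(3, 0.5))), 2L)
  expect_equal(adjusted_m(c(rep(list(c(3, 0.5)), 5), list(c(2, 1)))), 11L)
  expect_error(adjusted_m(list(c(3, 1.5))), "R must be in")
  expect_error(adjusted_m(list(c(0, 0.5))), "sizes must be")
})

test_that("correction plans count defined cells from the pairing map", {
  p6 <- build_correction_plan(u6_acagaga())
  expect_equal(p6$m, 17L)          # five 3-class positions + one uridine
  expect_equal(p6$m_prime, 11L)
  expect_equal(round(p6$alpha_prime, 4), 0.0029)
  expect_equal(round(p6$alpha_prime_adjusted, 4), 0.0045)

  p5 <- build_correction_plan(u5_loop1())
  expect_equal(p5$m, 28L)          # six 3-class + five uridine positions
  expect_equal(p5$m_prime, 17L)
  expect_equal(round(p5$alpha_prime, 4), 0.0018)
  expect_equal(round(p5$alpha_prime_adjusted, 4), 0.0029)

  px <- build_correction_plan(u5_loop1(), extra_tests = list(c(4, 0.33)))
  expect_equal(px$m, 32L)          # + the four nucleotide tests at -3
  expect_equal(px$m_prime, 20L)
  expect_equal(round(px$alpha_prime_adjusted, 4), 0.0025)
})
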