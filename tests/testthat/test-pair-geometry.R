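test_that("residue symbols normalize to their parent RNA base", {
  expect_equal(canonical_base(c("A", "C", "G", "U")), c("A", "C", "G", "U"))
  expect_equal(canonical_base("T"), "U")
  expect_equal(canonical_base("\u03a8"), "U")
  expect_equal(canonical_base(c("Gm", "Um", "Am6", "a", "t")),
               c("G", "U", "A", "A", "U"))
  expect_error(canonical_base(c("A", "X")), "unknown residue symbol 'X'")
  expect_error(canonical_base(c("A", "X")), "position 2")
  expect_error(canonical_base("mG"), "unknown residue symbol")
})

test_that("the three geometry classes partition the 16 ordered pairs 4/7/5", {
  pairs <- expand.grid(b1 = RNA_BASES <- c("A", "C", "G", "U"),
                       b2 = RNA_BASES, stringsAsFactors = FALSE)
  cls <- classify_pair(pairs$b1, pairs$b2)
  expect_false(anyNA(cls))
  expect_equal(unname(table(factor(cls, c("watson_crick", "isosteric",
                                          "non_isosteric")))[1:3]),
               c(4L, 7L, 5L), ignore_attr = TRUE)
  ## symmetry and agreement with the independent lookup
  expect_equal(cls, classify_pair(pairs$b2, pairs$b1))
  expect_equal(cls, oracle_pair_class(pairs$b1, pairs$b2))
})

test_that("classification sees through modifications and alphabets", {
  expect_equal(classify_pair("G", "C"), "watson_crick")
  expect_equal(classify_pair("G", "G"), "non_isosteric")
  expect_equal(classify_pair("\u03a8", "A"), "watson_crick")
  expect_equal(classify_pair("t", "Gm"), "isosteric")
})

test_that("default loop models match their documented structure", {
  u5 <- u5_loop1()
  expect_length(u5$positions, 11L)
  expect_equal(sum(u5$bases == "U"), 5L)
  map <- u5$pairing
  expect_equal(map$loop_position[map$site == "exon" & map$position == -1], 39L)
  expect_equal(map$loop_position[map$site == "exon" & map$position == -8], 46L)
  expect_equal(map$loop_position[map$site == "exon" & map$position == 1], 38L)
  expect_equal(map$loop_position[map$site == "exon" & map$position == 3], 36L)
  ## uridine partners exactly at exon -2..-6: the five positions where
  ## non-isosteric pairs cannot exist
  upos <- map$position[map$loop_base == "U"]
  expect_setequal(upos, -(2:6))
  for (p in upos)
    expect_setequal(defined_classes(map$loop_base[map$position == p]),
                    c("watson_crick", "isosteric"))

  u6 <- u6_acagaga()
  expect_equal(paste(u6$bases, collapse = ""), "CGAUACAGAGA")
  expect_equal(u6$pairing$loop_position[u6$pairing$position == 5], 42L)
  expect_equal(u6$pairing$loop_position[u6$pairing$position == 10], 37L)
  expect_equal(sum(u6$pairing$loop_base == "U"), 1L)
  expect_equal(u6$pairing$position[u6$pairing$loop_base == "U"], 7L)

  u1 <- u1_5prime()
  expect_equal(u1$pairing$loop_position[u1$pairing$site == "exon" &
                                          u1$pairing$position == -1], 9L)
  expect_equal(u1$pairing$loop_base[u1$pairing$site == "intron" &
                                      u1$pairing$position == 1], "C")

  id3 <- ltrb_id3()
  expect_length(id3$positions, 11L)
  expect_equal(sum(id3$bases == "U"), 5L)
  expect_equal(id3$bases[id3$positions %in% c(278, 279, 282)],
               c("G", "G", "G"))
  ## 7+4 split: seven EBS1 residues on the 5' exon, four delta residues
  expect_equal(sum(id3$pairing$position < 0), 7L)
  expect_equal(sum(id3$pairing$position > 0), 4L)
})

test_that("loop models survive a config round trip", {
  path <- withr::local_tempfile(fileext = ".yml")
  u5 <- u5_loop1()
  write_loop_model(u5, path)
  back <- read_loop_model(path)
  expect_equal(back$name, u5$name)
  expect_equal(back$residues, u5$residues)
  expect_equal(back$pairing, u5$pairing)
})

test_that("pair_profile classifies a junction position by position", {
  prof <- pair_profile(u5_loop1(), junction = "AAACCCAGGUA")
  expect_equal(nrow(prof), 11L)
  ## substrate 5'->3' order
  expect_equal(prof$position, c(-(8:1), 1:3))
  ## the conserved exon-end G pairs loop C39 as Watson-Crick
  expect_equal(prof$pair_class[prof$position == -1], "watson_crick")
  expect_equal(prof$loop_position[prof$position == -1], 39L)

  ## poly-A junction: expectations derived independently from the table
  polyA <- pair_profile(u5_loop1(), junction = "AAAAAAAAAAA")
  expect_equal(prof$position, polyA$position)
  expect_equal(polyA$pair_class,
               oracle_pair_class(rep("A", 11), polyA$loop_base))
  ## A against the five uridine partners (-2..-6) is Watson-Crick,
  ## against A-45 (-7) and Gm37 (+2) non-isosteric, against the
  ## cytosines (-8, -1, +1, +3) isosteric
  expect_equal(polyA$pair_class[polyA$position == -7], "non_isosteric")
  expect_equal(polyA$pair_class[polyA$position == 2], "non_isosteric")
  expect_true(all(polyA$pair_class[polyA$position %in% -(2:6)] ==
                    "watson_crick"))
  expect_true(all(polyA$pair_class[polyA$position %in% c(-8, -1, 1, 3)] ==
                    "isosteric"))
})

test_that("fully complementary substrates give all-Watson-Crick profiles", {
  for (model_fn in list(u5_loop1, ltrb_id3)) {
    model <- model_fn()
    junction <- complementary_junction(model)
    n5 <- sum(model$pairing$position < 0)
    prof <- pair_profile(model, junction = junction, junction_exon5 = n5)
    expect_true(all(prof$pair_class == "watson_crick"))
  }
})

test_that("too-short substrates are rejected naming the missing position", {
  expect_error(pair_profile(u5_loop1(), junction = "AAAGGUA"),
               "no base at exon -1")
  expect_error(pair_profile(u6_acagaga(), intron_start = "GUAAG"),
               "no base at intron \\+6")
  expect_error(pair_profile(u6_acagaga()), "no base at intron")
})
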