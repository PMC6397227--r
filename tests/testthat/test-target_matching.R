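test_that("window extraction pads, converts and re-indexes correctly", {
  s <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")  # 60 nt
  w <- extract_window(s, 0, W = 33, D = 5)
  expect_equal(nchar(w$sequence), 39)
  expect_equal(substr(w$sequence, 1, 33), strrep("N", 33))
  expect_equal(w$site_nt, "A")
  w2 <- extract_window(s, 57, W = 33, D = 5)
  expect_equal(substr(w2$sequence, 38, 39), "NN")  # 2 nt right padding
  expect_false(grepl("T", w2$sequence))            # DNA converted to RNA
  expect_error(extract_window(s, 0, require_site_c = TRUE), "not C")
  expect_silent(extract_window(s, 1, require_site_c = TRUE))
  expect_error(extract_window(s, 60), "site_index")
})

test_that("minus-strand extraction equals plus-strand on the reverse complement", {
  withr::with_seed(7, {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in c(0, 40, 77, 119)) {
    wm <- extract_window(s, i, W = 10, D = 3, strand = "-")
    wp <- extract_window(rc, nchar(s) - 1 - i, W = 10, D = 3, strand = "+")
    expect_equal(wm$sequence, wp$sequence)
  }
})

test_that("pair classification follows the code shading exhaustively", {
  cases <- list(
    list(e = expected_nucleotides("T", "N"),   # A
         A = "MATCH", G = "PURINE_TRANSITION", C = "MISMATCH", U = "MISMATCH"),
    list(e = expected_nucleotides("T", "D"),   # G
         G = "MATCH", A = "PURINE_TRANSITION", C = "MISMATCH", U = "MISMATCH"),
    list(e = expected_nucleotides("N", "N"),   # C/U unranked
         C = "MATCH", U = "MATCH", A = "MISMATCH", G = "MISMATCH"),
    list(e = expected_nucleotides("N", "S"),   # C>U
         C = "MATCH", U = "PYRIMIDINE_TRANSITION",
         A = "MISMATCH", G = "MISMATCH"),
    list(e = expected_nucleotides("N", "D"),   # U>C
         U = "MATCH", C = "PYRIMIDINE_TRANSITION",
         A = "MISMATCH", G = "MISMATCH")
  )
  for (cs in cases) {
    for (nt in c("A", "C", "G", "U")) {
      expect_equal(classify_pair(cs$e, nt), cs[[nt]],
                   label = paste(format(cs$e), "vs", nt))
    }
    expect_equal(classify_pair(cs$e, "N"), "NO_EXPECTATION")
  }
  none <- expected_nucleotides("A", "E")
  for (nt in c("A", "C", "G", "U", "N")) {
    expect_equal(classify_pair(none, nt), "NO_EXPECTATION")
  }
  expect_equal(classify_pair(expected_nucleotides("T", "D"), "T"), "MISMATCH")
})

test_that("the native target profile reproduces the worked example", {
  ex <- ppr65_example()
  prof <- match_profile(ex$array, ex$native)
  counts <- count_perfect_PS_matches(prof)
  expect_equal(counts$n_match, 6L)
  expect_equal(counts$n_coded, 8L)
  # the coded L repeat matches its expected guanosine at -8
  l5 <- prof[prof$repeat_label == "L-5TD", ]
  expect_equal(l5$nt, "G")
  expect_equal(l5$category, "MATCH")
  # the native purine mismatch at -9
  expect_equal(prof$category[prof$position == -9], "PURINE_TRANSITION")
  expect_equal(attr(prof, "score"), 9.5)
  expect_equal(score_profile(prof), 9.5)
})

test_that("scores follow the weight configuration arithmetic", {
  a <- parse_array_spec("P-4TN;P-3TN;P-2TN;P-1TN", name = "toy4")
  w <- perfect_window(a)
  prof <- match_profile(a, w)
  expect_equal(attr(prof, "score"), 8)  # 4 purine matches x 2
  # all-N window scores zero with only NO_EXPECTATION pairs
  nw <- as_target_window(paste(c(rep("N", 33), "C", rep("N", 5)),
                               collapse = ""))
  pn <- match_profile(toy_array(), nw)
  expect_true(all(pn$category == "NO_EXPECTATION"))
  expect_equal(attr(pn, "score"), 0)
  # promoting L repeats raises the score of an L match
  ex <- ppr65_example()
  s_l <- attr(match_profile(ex$array, ex$native,
                            default_match_weights(promote_l = TRUE)), "score")
  expect_equal(s_l, 11)  # L-5TD match 0.5 -> 2
})

test_that("single window mutations change exactly one pair and lower matched scores", {
  ex <- ppr65_example()
  base <- match_profile(ex$array, ex$native)
  withr::with_seed(11, {
    for (rep in 1:10) {
      pos <- sample(-18:-1, 1)
      old <- window_nt(ex$native, pos)
      nt <- sample(setdiff(c("A", "C", "G", "U"), old), 1)
      prof <- match_profile(ex$array, mutate_window(ex$native, pos, nt))
      expect_equal(sum(prof$category != base$category |
                         prof$nt != base$nt), 1L)
    }
  })
  # mutating any MATCH pair into a MISMATCH strictly decreases the score
  for (pos in base$position[base$category == "MATCH"]) {
    e <- array_expectations(ex$array)
    e <- e[e$position == pos, ]
    bad_nt <- if (e$primary %in% c("A", "G")) "C" else "A"
    prof <- match_profile(ex$array, mutate_window(ex$native, pos, bad_nt))
    expect_lt(attr(prof, "score"), attr(base, "score"))
    expect_equal(prof$category[prof$position == pos], "MISMATCH")
  }
})

test_that("an improved-match purine mutation still lowers the default score", {
  # converting the matched A at -12 to G turns a purine MATCH into a
  # penalised purine transition
  ex <- ppr65_example()
  native <- attr(match_profile(ex$array, ex$native), "score")
  mut <- match_profile(ex$array, mutate_window(ex$native, -12, "G"))
  expect_equal(mut$category[mut$position == -12], "PURINE_TRANSITION")
  expect_lt(attr(mut, "score"), native)
  expect_equal(attr(mut, "score"), native - 3)
})

test_that("profiles demand windows covering the full repeat span", {
  ex <- ppr65_example()
  small <- as_target_window(paste(rep("A", 16), collapse = ""), W = 12, D = 3)
  expect_error(match_profile(ex$array, small), "P-15")
})
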