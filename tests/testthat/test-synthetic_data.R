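test_that("generators are pure functions of their seed", {
  ex <- ppr65_example()
  s1 <- simulate_transcriptome(ex$array, n_offtargets = 3, length = 2000,
                               seed = 42, levels = c(0.2, 0.5, 0.8),
                               n_dna_variant = 1, n_control_shared = 1)
  s2 <- simulate_transcriptome(ex$array, n_offtargets = 3, length = 2000,
                               seed = 42, levels = c(0.2, 0.5, 0.8),
                               n_dna_variant = 1, n_control_shared = 1)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_transcriptome(ex$array, n_offtargets = 3, length = 2000,
                               seed = 43, levels = c(0.2, 0.5, 0.8))
  expect_false(identical(s1$sequences, s3$sequences))
  c1 <- simulate_counts(s1$truth, seed = 9)
  c2 <- simulate_counts(s1$truth, seed = 9)
  expect_identical(c1, c2)
  # generators do not disturb the caller's RNG stream
  withr::with_seed(1, {
    invisible(simulate_counts(s1$truth, seed = 9))
    a <- runif(1)
  })
  withr::with_seed(1, b <- runif(1))
  expect_identical(a, b)
})

test_that("planted windows realise the requested match degradations", {
  ex <- ppr65_example()
  spec <- list(mismatch = 2, pur_transition = 1, pyr_transition = 1)
  sim <- simulate_transcriptome(ex$array, n_offtargets = 4, length = 4000,
                                seed = 8, similarity = spec)
  for (i in 1:4) {
    w <- as_target_window(sim$truth$window[i])
    prof <- match_profile(ex$array, w)
    tab <- table(factor(prof$category,
                        levels = c("MATCH", "PYRIMIDINE_TRANSITION",
                                   "PURINE_TRANSITION", "MISMATCH",
                                   "NO_EXPECTATION")))
    expect_equal(unname(tab[["MISMATCH"]]), 2)
    expect_equal(unname(tab[["PURINE_TRANSITION"]]), 1)
    expect_equal(unname(tab[["PYRIMIDINE_TRANSITION"]]), 1)
    expect_equal(unname(tab[["MATCH"]]), 5)  # 9 coded repeats minus 4 degraded
    # the planted window really sits in the sequence at the truth coordinate
    w2 <- extract_window(sim$sequences[[1]], sim$truth$pos[i], id = "x")
    expect_equal(w2$sequence, w$sequence)
  }
  # infeasible requests name the violated constraint
  expect_error(
    simulate_transcriptome(ex$array, n_offtargets = 1, length = 2000, seed = 1,
                           similarity = list(pyr_transition = 5)),
    "infeasible")
})

test_that("plants can share a fixed -3..-1 context for consensus experiments", {
  ex <- ppr65_example()
  ctx <- c(rep("CUU", 6), "AGG")
  sim <- simulate_transcriptome(ex$array, n_offtargets = 7, length = 6000,
                                seed = 31, fixed_context = ctx)
  wins <- lapply(sim$truth$window, as_target_window)
  expect_equal(identity_count(wins, c(-1, -2, -3), ex$native), 6L)
})

test_that("degenerate count parameters behave exactly", {
  truth <- data.frame(seq_id = "s", pos = 100, strand = "+", kind = "edited",
                      level = 1, window = NA, stringsAsFactors = FALSE)
  cc <- simulate_counts(truth, coverage = 50, error = 0, n_replicates = 2,
                        seed = 2)
  rna <- cc[cc$role == "RNA", ]
  expect_true(all(rna$nT == 50))
  expect_true(all(cc$nC[cc$role == "DNA"] == 50))
  expect_true(all(cc$nC[cc$role == "CONTROL"] == 50))
  truth$level <- 0
  c0 <- simulate_counts(truth, coverage = 50, error = 0, seed = 2)
  calls <- suppressWarnings(call_sites(c0))
  expect_equal(nrow(calls), 0L)
})

test_that("chromatogram simulation matches its noise model", {
  expect_equal(peak_editing_fraction(
    simulate_chromatogram(0.7, noise = 0, seed = 1)$T_height,
    simulate_chromatogram(0.7, noise = 0, seed = 1)$C_height), 0.7)
  z <- simulate_chromatogram(0, noise = 0.3, seed = 4)
  expect_equal(z$T_height, 0)
  draws <- simulate_chromatogram(0.5, noise = 0.05, seed = 6, n = 100)
  fr <- peak_editing_fraction(draws$T_height, draws$C_height)
  expect_lt(abs(mean(fr) - 0.5), 0.02)
})

test_that("the full loop recovers planted edits and rejects decoys", {
  ex <- ppr65_example()
  sim <- simulate_transcriptome(ex$array, n_offtargets = 3, length = 2500,
                                seed = 11, levels = c(0.2, 0.5, 0.9),
                                n_dna_variant = 1, n_control_shared = 1)
  counts <- simulate_counts(sim$truth, coverage = 300, error = 0.002,
                            n_replicates = 2, seed = 12)
  cfg <- call_config(max_control_alt = stats::qbinom(0.999, 300, 0.002 / 3))
  calls <- suppressWarnings(call_sites(counts, cfg))
  edited <- sim$truth[sim$truth$kind == "edited", ]
  expect_setequal(calls$pos, edited$pos)
  m <- merge(as.data.frame(calls)[c("pos", "level_mean")],
             edited[c("pos", "level")])
  p_eff <- m$level * (1 - 0.002) + (1 - m$level) * 0.002 / 3
  tol <- 3 * sqrt(p_eff * (1 - p_eff) / 300)
  expect_true(all(abs(m$level_mean - m$level) <= tol))
})
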