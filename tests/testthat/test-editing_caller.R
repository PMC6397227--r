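cts <- function(A = 0, C = 0, G = 0, T = 0) c(A = A, C = C, G = G, T = T)

count_row <- function(seq_id, pos, sample, replicate, role,
                      A = 0, C = 0, G = 0, T = 0) {
  data.frame(seq_id = seq_id, pos = pos, sample = sample,
             replicate = replicate, role = role,
             nA = A, nC = C, nG = G, nT = T, stringsAsFactors = FALSE)
}

test_that("site ratios and editing levels follow the count definitions", {
  expect_equal(site_ratio(cts(C = 13, T = 87), "U"), 0.87)
  expect_equal(site_ratio(cts(C = 50), "U"), 0)
  expect_equal(site_ratio(cts(C = 1, T = 1), "T"), 0.5)
  expect_warning(r <- site_ratio(cts(), "T"), "zero coverage")
  expect_true(is.na(r))
  expect_equal(editing_level(cts(C = 13, T = 87), cts(C = 100), "U"), 0.87)
  expect_equal(editing_level(cts(C = 50, T = 50), cts(C = 50, T = 50), "U"), 0)
  # the difference is not clipped
  expect_equal(editing_level(cts(C = 80, T = 20), cts(C = 75, T = 25), "U"),
               -0.05)
  # identical RNA and DNA vectors give exactly zero
  v <- cts(A = 3, C = 140, G = 2, T = 55)
  expect_identical(editing_level(v, v, "U"), 0)
})

test_that("purity thresholds are strict at 98%", {
  expect_true(passes_purity(cts(C = 1, T = 98, A = 1),
                            cts(C = 99, T = 1), "sense"))
  # exactly 98% fails on either side
  expect_false(passes_purity(cts(T = 100), cts(C = 98, T = 2), "sense"))
  expect_false(passes_purity(cts(T = 98, G = 2), cts(C = 100), "sense"))
  expect_true(passes_purity(cts(G = 60, A = 40), cts(G = 100), "antisense"))
  expect_false(passes_purity(cts(G = 98, C = 2), cts(G = 100), "antisense"))
})

test_that("replicate concordance and control filters apply detection counts", {
  r1 <- cts(C = 97, T = 3); r2 <- cts(C = 95, T = 5); r0 <- cts(C = 100)
  expect_true(replicate_concordant(list(r1, r2), "T"))
  expect_false(replicate_concordant(list(r1, r0), "T"))
  expect_false(replicate_concordant(list(cts(C = 99, T = 1),
                                         cts(C = 99, T = 1)), "T",
                                    min_alt = 2))
  expect_error(replicate_concordant(list(r1), "T"), "2 replicates")
  expect_true(replicate_concordant(list(r1), "T", allow_single = TRUE))
  expect_true(control_clean(list(cts(C = 200)), "T"))
  expect_false(control_clean(list(cts(C = 195, T = 5)), "T"))
  expect_true(control_clean(list(cts(C = 195, T = 5)), "T", max_alt = 5))
  expect_true(control_clean(list(cts()), "T"))  # uncovered control ignored
  expect_warning(ok <- control_clean(list(), "T"), "vacuously")
  expect_true(ok)
})

test_that("the cascade calls planted sites and rejects decoys", {
  tab <- rbind(
    # genuinely edited site, level 0.5
    count_row("c", 10, "s", 1, "RNA", C = 100, T = 100),
    count_row("c", 10, "s", 2, "RNA", C = 95, T = 105),
    count_row("c", 10, "s", 1, "DNA", C = 200),
    count_row("c", 10, "ctl", 1, "CONTROL", C = 200),
    # DNA C->T variant: rejected by DNA purity
    count_row("c", 20, "s", 1, "RNA", C = 100, T = 100),
    count_row("c", 20, "s", 2, "RNA", C = 100, T = 100),
    count_row("c", 20, "s", 1, "DNA", C = 100, T = 100),
    count_row("c", 20, "ctl", 1, "CONTROL", C = 200),
    # edited in the control as well: rejected by the control filter
    count_row("c", 30, "s", 1, "RNA", C = 100, T = 100),
    count_row("c", 30, "s", 2, "RNA", C = 100, T = 100),
    count_row("c", 30, "s", 1, "DNA", C = 200),
    count_row("c", 30, "ctl", 1, "CONTROL", C = 150, T = 50),
    # antisense site (G -> A on the reference strand)
    count_row("c", 40, "s", 1, "RNA", G = 120, A = 80),
    count_row("c", 40, "s", 2, "RNA", G = 130, A = 70),
    count_row("c", 40, "s", 1, "DNA", G = 200),
    count_row("c", 40, "ctl", 1, "CONTROL", G = 200)
  )
  calls <- call_sites(tab)
  expect_s3_class(calls, "editing_calls")
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$pos, c(10, 40))
  sense <- calls[calls$pos == 10, ]
  expect_false(sense$antisense)
  expect_equal(sense$level_mean, mean(c(0.5, 0.525)))
  expect_equal(sense$level_reps[[1]], c(0.5, 0.525))
  expect_equal(sense$coverage, 400)
  anti <- calls[calls$pos == 40, ]
  expect_true(anti$antisense)
  expect_equal(anti$strand, "-")
  expect_equal(anti$level_mean, mean(c(0.4, 0.35)))
  # calls are sorted by decreasing mean level
  expect_equal(calls$level_mean, sort(calls$level_mean, decreasing = TRUE))
})

test_that("a missing DNA sample is an error, not a silent skip", {
  tab <- rbind(count_row("c", 10, "s", 1, "RNA", C = 100, T = 100),
               count_row("c", 10, "s", 2, "RNA", C = 100, T = 100))
  expect_error(call_sites(tab), "DNA")
})

test_that("single-replicate tables error unless explicitly allowed", {
  tab <- rbind(count_row("c", 10, "s", 1, "RNA", C = 100, T = 100),
               count_row("c", 10, "s", 1, "DNA", C = 200))
  expect_error(call_sites(tab), "replicate")
  calls <- suppressWarnings(
    call_sites(tab, call_config(allow_single_replicate = TRUE)))
  expect_equal(nrow(calls), 1L)
})

test_that("relaxing thresholds never removes an emitted call", {
  pre <- simulate_recovery_preset(seed = 404)
  strict <- suppressWarnings(call_sites(pre$counts, pre$config))
  relaxed_cfgs <- list(
    utils::modifyList(pre$config, list(min_coverage = 1L)),
    utils::modifyList(pre$config, list(min_alt = 0L)),
    utils::modifyList(pre$config, list(max_control_alt =
                                         pre$config$max_control_alt + 5L)),
    utils::modifyList(pre$config, list(purity_threshold = 0.90))
  )
  key <- function(x) paste(x$seq_id, x$pos, x$strand)
  for (cfg in relaxed_cfgs) {
    relaxed <- suppressWarnings(call_sites(pre$counts, cfg))
    expect_true(all(key(strict) %in% key(relaxed)))
  }
})
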