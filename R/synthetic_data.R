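# Ground-truth generators: planted target windows, base counts, peak pairs.

#' Simulate a transcriptome with planted target windows
#'
#' Builds a random background sequence and plants non-overlapping editing-site
#' windows whose match profiles against `array` have controlled numbers of
#' degraded pairs, emulating the structure of off-target sets: coded repeats
#' match by default, and the requested numbers of pyrimidine transitions,
#' purine transitions and mismatches are introduced at randomly chosen coded
#' repeats. Additional decoy sites (DNA variants, control-shared edits, clean
#' cytidines) can be planted at background cytidines for caller-recovery
#' experiments. All output is a pure function of the parameters and `seed`.
#'
#' @param array A `ppr_array`.
#' @param n_offtargets Number of planted target windows.
#' @param similarity `NULL` for all-MATCH plants, or a list
#'   `list(pyr_transition =, pur_transition =, mismatch =)` (single spec
#'   recycled, or an unnamed list with one spec per plant). Infeasible
#'   requests (more degradations than eligible coded repeats) are an error.
#' @param length Background sequence length (nt).
#' @param gc Background GC fraction.
#' @param seed Integer seed; fully determines the output.
#' @param W,D Window extent.
#' @param levels Optional true editing levels of the planted sites (recycled).
#' @param fixed_context Optional per-plant 3-character strings forced at
#'   positions -3, -2, -1 (NA entries leave the repeat-derived context).
#' @param n_dna_variant,n_control_shared,n_clean Decoy sites planted at
#'   background cytidines.
#' @param decoy_level Editing level of control-shared decoys.
#' @param seq_id Sequence identifier.
#' @return List with `sequences` (named character, DNA alphabet), `truth`
#'   (data frame: `seq_id`, `pos` (0-based site), `strand`, `kind`, `level`,
#'   `window`), `W`, `D`.
#' @export
simulate_transcriptome <- function(array, n_offtargets = 7L, similarity = NULL,
                                   length = 10000L, gc = 0.5, seed = 1L,
                                   W = 33L, D = 5L, levels = NULL,
                                   fixed_context = NULL,
                                   n_dna_variant = 0L, n_control_shared = 0L,
                                   n_clean = 0L, decoy_level = 0.5,
                                   seq_id = "synth1") {
  stopifnot(inherits(array, "ppr_array"), gc >= 0, gc <= 1)
  win_len <- W + 1L + D
  if (n_offtargets * win_len > length) {
    stop("requested windows do not fit in sequence length ", length)
  }
  specs <- .recycle_similarity(similarity, n_offtargets)
  if (!is.null(levels)) levels <- rep_len(levels, n_offtargets)
  if (!is.null(fixed_context)) {
    fixed_context <- rep_len(fixed_context, n_offtargets)
  }
  ex <- array_expectations(array)
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bg <- sample(names(probs), length, replace = TRUE, prob = probs)
    # non-overlapping plant start positions (0-based)
    starts <- integer(0)
    for (j in seq_len(n_offtargets)) {
      placed <- FALSE
      for (try in 1:1000) {
        st <- sample.int(length - win_len + 1L, 1L) - 1L
        if (!any(abs(st - starts) < win_len)) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place non-overlapping windows")
      starts <- c(starts, st)
    }
    truth <- vector("list", n_offtargets)
    for (j in seq_len(n_offtargets)) {
      wchars <- .plant_window(ex, specs[[j]], W, D)
      if (!is.null(fixed_context) && !is.na(fixed_context[j])) {
        ctx <- strsplit(chartr("T", "U", toupper(fixed_context[j])), "")[[1]]
        stopifnot(length(ctx) == 3L)
        wchars[W + 1L + (-3:-1)] <- ctx
      }
      pos0 <- starts[j] + W
      bg[(starts[j] + 1L):(starts[j] + win_len)] <- chartr("U", "T", wchars)
      truth[[j]] <- data.frame(seq_id = seq_id, pos = pos0, strand = "+",
                               kind = "edited",
                               level = if (is.null(levels)) NA_real_ else levels[j],
                               window = paste(wchars, collapse = ""),
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    n_decoy <- n_dna_variant + n_control_shared + n_clean
    if (n_decoy > 0L) {
      in_plant <- unlist(lapply(starts, function(st) st:(st + win_len - 1L)))
      cand <- which(bg == "C") - 1L
      cand <- setdiff(cand, c(in_plant, truth$pos))
      if (base::length(cand) < n_decoy) {
        stop("not enough background cytidines for decoys")
      }
      dpos <- cand[sample.int(base::length(cand), n_decoy)]
      kinds <- rep(c("dna_variant", "control_shared", "clean"),
                   times = c(n_dna_variant, n_control_shared, n_clean))
      truth <- rbind(truth, data.frame(
        seq_id = seq_id, pos = dpos, strand = "+", kind = kinds,
        level = ifelse(kinds == "control_shared", decoy_level,
                       ifelse(kinds == "clean", 0, NA_real_)),
        window = NA_character_, stringsAsFactors = FALSE))
    }
    list(sequences = stats::setNames(paste(bg, collapse = ""), seq_id),
         truth = truth, W = W, D = D)
  })
}

.recycle_similarity <- function(similarity, n) {
  default <- list(pyr_transition = 0L, pur_transition = 0L, mismatch = 0L)
  if (is.null(similarity)) return(rep(list(default), n))
  per_plant <- is.list(similarity) && length(similarity) > 0 &&
    is.null(names(similarity)) && all(vapply(similarity, is.list, TRUE))
  specs <- if (per_plant) rep_len(similarity, n) else rep(list(similarity), n)
  lapply(specs, function(sp) {
    bad <- setdiff(names(sp), names(default))
    if (length(bad)) stop("unknown similarity class: ", paste(bad, collapse = ", "))
    utils::modifyList(default, sp)
  })
}

# Build one window (RNA chars) realising the requested per-class degradations.
.plant_window <- function(ex, spec, W, D) {
  wchars <- sample(c("A", "C", "G", "U"), W + 1L + D, replace = TRUE)
  coded <- which(!is.na(ex$primary) & !ex$ptype %in% .TRIPLET)
  elig_purt <- coded[ex$primary[coded] %in% c("A", "G")]
  elig_pyrt <- coded[ex$ranked[coded] & !is.na(ex$secondary[coded])]
  avail <- coded
  pick <- function(elig, n, what) {
    elig <- intersect(elig, avail)
    if (n > base::length(elig)) {
      stop("infeasible similarity request: ", n, " ", what,
           " but only ", base::length(elig), " eligible coded repeats")
    }
    sel <- if (n > 0) elig[sample.int(base::length(elig), n)] else integer(0)
    avail <<- setdiff(avail, sel)
    sel
  }
  i_purt <- pick(elig_purt, spec$pur_transition, "purine transitions")
  i_pyrt <- pick(elig_pyrt, spec$pyr_transition, "pyrimidine transitions")
  i_mism <- pick(coded, spec$mismatch, "mismatches")
  nt_for <- function(i, cat) {
    p <- ex$primary[i]; s <- ex$secondary[i]
    switch(cat,
           match = if (!ex$ranked[i] && !is.na(s)) "C" else p,
           pur_transition = setdiff(c("A", "G"), p),
           pyr_transition = s,
           mismatch = if (p %in% c("A", "G")) sample(c("C", "U"), 1)
                      else sample(c("A", "G"), 1))
  }
  for (i in coded) {
    cat <- if (i %in% i_purt) "pur_transition" else
      if (i %in% i_pyrt) "pyr_transition" else
        if (i %in% i_mism) "mismatch" else "match"
    wchars[ex$position[i] + W + 1L] <- nt_for(i, cat)
  }
  wchars[W + 1L] <- "C"
  wchars
}

#' Simulate base counts for a truth table
#'
#' Draws multinomial base counts at every truth site for RNA replicates, the
#' DNA sample and control RNA replicates. A true base is read correctly with
#' probability 1 - error and as each other base with probability error / 3.
#' Edited sites mix T (at the editing level) into a C background in RNA only;
#' `dna_variant` sites carry a 50% C/T mixture in DNA (and RNA);
#' `control_shared` sites carry their level also in the control RNA; `clean`
#' sites are background error only.
#'
#' @param truth Truth table from [simulate_transcriptome()].
#' @param coverage Reads per sample at every site.
#' @param error Per-base miscall rate (uniform over the three other bases).
#' @param n_replicates RNA (and control) replicates.
#' @param seed Integer seed.
#' @param sample_id,control_id Sample identifiers written to the table.
#' @return Count data frame with columns `seq_id`, `pos`, `sample`,
#'   `replicate`, `role`, `nA`, `nC`, `nG`, `nT`.
#' @export
simulate_counts <- function(truth, coverage = 200L, error = 0.005,
                            n_replicates = 2L, seed = 1L,
                            sample_id = "ppr_clone", control_id = "control") {
  stopifnot(coverage > 0, error >= 0, error < 1)
  err_vec <- function(b) {
    p <- stats::setNames(rep(error / 3, 4), c("A", "C", "G", "T"))
    p[b] <- 1 - error
    p
  }
  mix <- function(level) level * err_vec("T") + (1 - level) * err_vec("C")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      kind <- truth$kind[i]
      level <- truth$level[i]
      p_rna <- switch(kind,
                      edited = , control_shared = mix(level),
                      dna_variant = mix(0.5),
                      clean = mix(0))
      p_dna <- if (kind == "dna_variant") mix(0.5) else err_vec("C")
      p_ctl <- if (kind == "control_shared") mix(level) else err_vec("C")
      draw <- function(p, sample, replicate, role) {
        cts <- as.integer(stats::rmultinom(1, coverage, p))
        data.frame(seq_id = truth$seq_id[i], pos = truth$pos[i],
                   sample = sample, replicate = replicate, role = role,
                   nA = cts[1], nC = cts[2], nG = cts[3], nT = cts[4],
                   stringsAsFactors = FALSE)
      }
      do.call(rbind, c(
        lapply(seq_len(n_replicates), function(r)
          draw(p_rna, sample_id, r, "RNA")),
        list(draw(p_dna, sample_id, 1L, "DNA")),
        lapply(seq_len(n_replicates), function(r)
          draw(p_ctl, control_id, r, "CONTROL"))
      ))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a Sanger peak pair
#'
#' T and C peak heights proportional to the editing level with multiplicative
#' Gaussian noise: `T = level * height * (1 + e1)`,
#' `C = (1 - level) * height * (1 + e2)`, heights truncated at zero.
#'
#' @param level True editing fraction in `[0, 1]`.
#' @param noise Standard deviation of the multiplicative noise.
#' @param seed Integer seed.
#' @param n Number of replicate draws.
#' @param height Nominal total peak height.
#' @return Data frame with columns `replicate`, `T_height`, `C_height`.
#' @export
simulate_chromatogram <- function(level, noise = 0, seed = 1L, n = 1L,
                                  height = 1000) {
  stopifnot(level >= 0, level <= 1, noise >= 0)
  withr::with_seed(seed, {
    e <- matrix(stats::rnorm(2L * n, 0, noise), ncol = 2)
    data.frame(replicate = seq_len(n),
               T_height = pmax(0, level * height * (1 + e[, 1])),
               C_height = pmax(0, (1 - level) * height * (1 + e[, 2])))
  })
}

#' Fixed study-like recovery preset
#'
#' The end-to-end validation scenario: ten planted edited sites with true
#' levels evenly spaced from 0.05 to 1.0 (spanning barely-detectable to
#' complete editing), three DNA-variant and two control-shared decoys, two RNA
#' replicates at 200x coverage with a 0.5% per-base error. The caller
#' configuration derives the control tolerance from the error model
#' (`max_control_alt = qbinom(0.999, coverage, error / 3)`), so that the
#' control filter rejects shared editing but not sequencing error.
#'
#' @param seed Integer seed (drives both the transcriptome and the counts).
#' @param array Optional `ppr_array` for the planted windows (default: the
#'   bundled PPR65-like example array).
#' @return List with `sim` (see [simulate_transcriptome()]), `counts`,
#'   `truth`, `config` (see [call_config()]), `coverage`, `error`,
#'   `n_replicates`.
#' @export
simulate_recovery_preset <- function(seed = 1L, array = NULL) {
  if (is.null(array)) array <- ppr65_example()$array
  coverage <- 200L
  error <- 0.005
  n_replicates <- 2L
  levels <- seq(0.05, 1, length.out = 10)
  sim <- simulate_transcriptome(array, n_offtargets = 10L, length = 6000L,
                                seed = seed, levels = levels,
                                n_dna_variant = 3L, n_control_shared = 2L)
  counts <- simulate_counts(sim$truth, coverage = coverage, error = error,
                            n_replicates = n_replicates,
                            seed = (seed %% 1000000000L) + 1L)
  config <- call_config(
    max_control_alt = stats::qbinom(0.999, coverage, error / 3))
  list(sim = sim, counts = counts, truth = sim$truth, config = config,
       coverage = coverage, error = error, n_replicates = n_replicates)
}
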