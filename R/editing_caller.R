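# Strict RNA-vs-DNA C-to-U editing-site calling from base-count tables.

.BASES <- c("A", "C", "G", "T")

.as_counts <- function(x) {
  if (is.data.frame(x)) {
    x <- stats::setNames(as.numeric(x[1, c("nA", "nC", "nG", "nT")]), .BASES)
  }
  nm <- chartr("U", "T", toupper(names(x)))
  nm <- sub("^N", "", nm)
  out <- stats::setNames(numeric(4), .BASES)
  out[nm] <- as.numeric(x)
  if (any(out < 0)) stop("negative base counts")
  out
}

#' Fraction of reads carrying a given base
#'
#' @param counts Named count vector (names among `A`, `C`, `G`, `T`/`U`; the
#'   TSV column style `nA`..`nT` also works), or a one-row data frame with
#'   columns `nA`, `nC`, `nG`, `nT`.
#' @param alt Base whose fraction is returned.
#' @return `alt` count / total; `NA` with a warning when the total is zero.
#' @examples
#' site_ratio(c(A = 0, C = 13, G = 0, T = 87), "U")  # 0.87
#' @export
site_ratio <- function(counts, alt) {
  counts <- .as_counts(counts)
  alt <- chartr("U", "T", toupper(alt))
  stopifnot(alt %in% .BASES)
  total <- sum(counts)
  if (total == 0) {
    warning("zero coverage; ratio undefined")
    return(NA_real_)
  }
  unname(counts[alt] / total)
}

#' Editing level of a site
#'
#' The editing level is the fraction of altered RNA reads minus the same
#' fraction among the DNA reads (nearly always zero); the difference is not
#' clipped, so a DNA-only variant yields a level near zero and sampling noise
#' can produce small negative values.
#'
#' @param rna,dna Count vectors (see [site_ratio()]).
#' @param alt Altered base (`"U"`/`"T"` for sense calls, `"A"` for antisense).
#' @return RNA alt ratio minus DNA alt ratio.
#' @export
editing_level <- function(rna, dna, alt) {
  site_ratio(rna, alt) - site_ratio(dna, alt)
}

#' Purity filter for one site
#'
#' A site is considered only on a clean background: for sense calls the DNA
#' reads must be C in more than 98% and the RNA reads T + C in more than 98%
#' of the total; for antisense calls, G and G + A respectively. The
#' inequalities are strict.
#'
#' @param rna,dna Count vectors.
#' @param orientation `"sense"` (C-to-U on the reported strand) or
#'   `"antisense"` (G-to-A on the reference strand).
#' @param threshold Purity threshold (default 0.98).
#' @return Logical.
#' @export
passes_purity <- function(rna, dna, orientation = c("sense", "antisense"),
                          threshold = 0.98) {
  orientation <- match.arg(orientation)
  rna <- .as_counts(rna)
  dna <- .as_counts(dna)
  if (sum(rna) == 0 || sum(dna) == 0) return(FALSE)
  if (orientation == "sense") {
    dna["C"] / sum(dna) > threshold &&
      (rna["T"] + rna["C"]) / sum(rna) > threshold
  } else {
    dna["G"] / sum(dna) > threshold &&
      (rna["G"] + rna["A"]) / sum(rna) > threshold
  }
}

#' Replicate concordance filter
#'
#' A site counts as detected only when seen in every RNA replicate.
#'
#' @param replicates List of count vectors, one per RNA replicate.
#' @param alt Altered base.
#' @param min_alt Minimum altered-read count per replicate for "detected"
#'   (default 1).
#' @param allow_single Permit a single replicate (otherwise fewer than two is
#'   an error).
#' @return Logical.
#' @export
replicate_concordant <- function(replicates, alt, min_alt = 1L,
                                 allow_single = FALSE) {
  if (length(replicates) < 2L && !allow_single) {
    stop("need at least 2 replicates (set allow_single to override)")
  }
  alt <- chartr("U", "T", toupper(alt))
  all(vapply(replicates, function(r) .as_counts(r)[alt] >= min_alt,
             logical(1)))
}

#' Control exclusion filter
#'
#' Sites also altered in control RNA (untransformed host, or the other
#' editing-factor clone) are rejected.
#'
#' @param controls List of control count vectors (possibly empty: vacuously
#'   clean, with a warning).
#' @param alt Altered base.
#' @param max_alt Maximum tolerated altered-read count in any covered control
#'   (default 0).
#' @return Logical.
#' @export
control_clean <- function(controls, alt, max_alt = 0L) {
  if (length(controls) == 0L) {
    warning("no control samples supplied; control filter vacuously true")
    return(TRUE)
  }
  alt <- chartr("U", "T", toupper(alt))
  all(vapply(controls, function(r) {
    r <- .as_counts(r)
    sum(r) == 0 || r[alt] <= max_alt
  }, logical(1)))
}

#' Caller configuration
#'
#' @param min_coverage Minimum total reads per RNA replicate and for the DNA
#'   sample.
#' @param purity_threshold Strict purity threshold (see [passes_purity()]).
#' @param min_alt Detection threshold per replicate (see
#'   [replicate_concordant()]).
#' @param max_control_alt Control tolerance (see [control_clean()]).
#' @param allow_single_replicate Permit single-replicate tables.
#' @return Named list of thresholds.
#' @export
call_config <- function(min_coverage = 10L, purity_threshold = 0.98,
                        min_alt = 1L, max_control_alt = 0L,
                        allow_single_replicate = FALSE) {
  list(min_coverage = min_coverage, purity_threshold = purity_threshold,
       min_alt = min_alt, max_control_alt = max_control_alt,
       allow_single_replicate = isTRUE(allow_single_replicate))
}

#' Read a per-site base-count table
#'
#' @param path TSV with columns `seq_id`, `pos`, `sample`, `replicate`,
#'   `role` (`RNA`/`DNA`/`CONTROL`), `nA`, `nC`, `nG`, `nT`.
#' @return Data frame.
#' @export
read_site_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "pos", "sample", "replicate", "role",
            "nA", "nC", "nG", "nT")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' Call C-to-U editing sites from a base-count table
#'
#' Applies the filter cascade at every site and orientation: minimum coverage
#' (each RNA replicate and the DNA sample), strict purity on every replicate
#' and the DNA, replicate concordance, and control exclusion. Sites passing
#' all filters are reported with per-replicate editing levels and their mean,
#' sorted by decreasing mean level. A missing DNA sample is an error, since
#' the DNA subtraction is part of the level definition.
#'
#' @param counts Count table (see [read_site_counts()] for the schema); RNA
#'   rows are grouped into replicates by their `replicate` id, `CONTROL` rows
#'   are evaluated per row.
#' @param config Thresholds from [call_config()].
#' @return An `editing_calls` data frame: `seq_id`, `pos`, `sample`, `strand`
#'   (`"-"` for antisense calls), `antisense`, `n_replicates`, `coverage`
#'   (total RNA reads over replicates), `level_mean`, `level_reps`
#'   (list-column of per-replicate levels), `label` (NA until annotated).
#' @export
call_sites <- function(counts, config = call_config()) {
  need <- c("seq_id", "pos", "sample", "replicate", "role",
            "nA", "nC", "nG", "nT")
  stopifnot(all(need %in% names(counts)))
  counts$role <- toupper(counts$role)
  key <- paste(counts$seq_id, counts$pos, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- counts[key == k, , drop = FALSE]
    dna_rows <- sub[sub$role == "DNA", , drop = FALSE]
    if (nrow(dna_rows) == 0L) {
      stop("missing DNA sample at site ", sub$seq_id[1], ":", sub$pos[1])
    }
    dna <- .as_counts(colSums(dna_rows[c("nA", "nC", "nG", "nT")]))
    ctl_rows <- sub[sub$role == "CONTROL", , drop = FALSE]
    controls <- lapply(seq_len(nrow(ctl_rows)), function(i)
      .as_counts(ctl_rows[i, , drop = FALSE]))
    rna_rows <- sub[sub$role == "RNA", , drop = FALSE]
    for (smp in unique(rna_rows$sample)) {
      rr <- rna_rows[rna_rows$sample == smp, , drop = FALSE]
      reps <- lapply(seq_len(nrow(rr)), function(i)
        .as_counts(rr[i, , drop = FALSE]))
      names(reps) <- rr$replicate
      if (length(reps) < 2L && !config$allow_single_replicate) {
        stop("site ", sub$seq_id[1], ":", sub$pos[1], " has ", length(reps),
             " RNA replicate(s); need >= 2 (see allow_single_replicate)")
      }
      for (orientation in c("sense", "antisense")) {
        alt <- if (orientation == "sense") "T" else "A"
        if (sum(dna) < config$min_coverage ||
            any(vapply(reps, sum, 0) < config$min_coverage)) next
        if (!all(vapply(reps, passes_purity, logical(1), dna = dna,
                        orientation = orientation,
                        threshold = config$purity_threshold))) next
        if (!replicate_concordant(reps, alt, config$min_alt,
                                  allow_single = TRUE)) next
        clean <- withCallingHandlers(
          control_clean(controls, alt, config$max_control_alt),
          warning = function(w) invokeRestart("muffleWarning"))
        if (length(controls) == 0L) {
          warning("no control rows at site ", sub$seq_id[1], ":", sub$pos[1],
                  "; control filter vacuously true")
        }
        if (!clean) next
        levels <- vapply(reps, function(r) editing_level(r, dna, alt),
                         numeric(1))
        row <- data.frame(seq_id = sub$seq_id[1], pos = sub$pos[1],
                          sample = smp,
                          strand = if (orientation == "sense") "+" else "-",
                          antisense = orientation == "antisense",
                          n_replicates = length(reps),
                          coverage = sum(vapply(reps, sum, 0)),
                          level_mean = mean(levels),
                          stringsAsFactors = FALSE)
        row$level_reps <- I(list(unname(levels)))
        row$label <- NA_character_
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), pos = integer(), sample = character(),
               strand = character(), antisense = logical(),
               n_replicates = integer(), coverage = numeric(),
               level_mean = numeric(), level_reps = I(list()),
               label = character(), stringsAsFactors = FALSE)
  res <- res[order(-res$level_mean, res$seq_id, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("editing_calls", "data.frame")
  res
}
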