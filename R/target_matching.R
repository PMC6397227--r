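# Juxtaposing PPR arrays with RNA target windows; match categories and scores.

.MATCH_CATEGORIES <- c("MATCH", "PYRIMIDINE_TRANSITION", "PURINE_TRANSITION",
                       "MISMATCH", "NO_EXPECTATION")

#' Default match-scoring weights
#'
#' Weights reflect the observed asymmetry between purine- and
#' pyrimidine-addressing repeats: single purine transitions at coded P/S
#' positions abolish editing while some pyrimidine changes are tolerated, so
#' purine matches score double and purine transitions are penalised. L-type
#' repeats contribute at reduced weight by default; set `promote_l = TRUE` to
#' score code-conforming L repeats like P/S repeats. The terminal P2-L2-S2
#' triplet never contributes to the score (the immediate -3..-1 context is
#' handled by scanner constraints, not by the repeat code).
#'
#' @param ps_match_purine Weight of a P/S MATCH where the expectation is a
#'   purine.
#' @param ps_match_pyrimidine Weight of a P/S MATCH where the expectation is a
#'   pyrimidine (ranked or unranked).
#' @param l_match Weight of an L-type MATCH.
#' @param pyrimidine_transition,purine_transition,mismatch,no_expectation
#'   Category weights shared by all numbered repeats.
#' @param promote_l Score L-type repeats with full P/S match weights.
#' @return Named list of weights.
#' @export
default_match_weights <- function(ps_match_purine = 2,
                                  ps_match_pyrimidine = 1,
                                  l_match = 0.5,
                                  pyrimidine_transition = 0.5,
                                  purine_transition = -1,
                                  mismatch = -1,
                                  no_expectation = 0,
                                  promote_l = FALSE) {
  list(ps_match_purine = ps_match_purine,
       ps_match_pyrimidine = ps_match_pyrimidine,
       l_match = l_match,
       pyrimidine_transition = pyrimidine_transition,
       purine_transition = purine_transition,
       mismatch = mismatch,
       no_expectation = no_expectation,
       promote_l = isTRUE(promote_l))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("Uu", "Tt", x))))
}

#' Extract an RNA window around a candidate editing site
#'
#' Cuts the region covering `W` nucleotides upstream and `D` downstream of the
#' site (position 0), the span used when cloning editing targets (at least 33
#' upstream and 5 downstream). DNA input is converted to RNA (T to U); windows
#' truncated at sequence ends are padded with N. For the minus strand the
#' sequence is reverse-complemented first and the site re-indexed, so the
#' window always reads 5' to 3' on the edited strand.
#'
#' @param sequence Nucleotide string (DNA or RNA alphabet).
#' @param site_index 0-based offset of the candidate site in `sequence`
#'   (plus-strand coordinates regardless of `strand`).
#' @param W,D Upstream / downstream extent of the window.
#' @param strand `"+"` or `"-"`.
#' @param id Optional sequence identifier recorded in the window source.
#' @param require_site_c Error unless the site nucleotide is a cytidine.
#' @return A `target_window`: list with `sequence` (RNA, length `W + 1 + D`),
#'   `W`, `D`, `site_nt`, and `source` (id, coord, strand).
#' @export
extract_window <- function(sequence, site_index, W = 33L, D = 5L,
                           strand = c("+", "-"), id = NA_character_,
                           require_site_c = FALSE) {
  strand <- match.arg(strand)
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  stopifnot(length(site_index) == 1L, site_index >= 0L, site_index < n)
  orig_index <- site_index
  if (strand == "-") {
    sequence <- .revcomp_chr(sequence)
    site_index <- n - 1L - site_index
  }
  from <- site_index - W
  to <- site_index + D
  core <- substr(sequence, max(from, 0L) + 1L, min(to, n - 1L) + 1L)
  s <- paste0(strrep("N", max(0L, -from)), core,
              strrep("N", max(0L, to - (n - 1L))))
  s <- chartr("T", "U", s)
  if (!grepl("^[ACGUN]*$", s)) stop("window contains non-nucleotide characters")
  site_nt <- substr(s, W + 1L, W + 1L)
  if (require_site_c && site_nt != "C") {
    stop("site nucleotide is ", site_nt, ", not C")
  }
  structure(list(sequence = s, W = as.integer(W), D = as.integer(D),
                 site_nt = site_nt,
                 source = list(id = id, coord = as.integer(orig_index),
                               strand = strand)),
            class = "target_window")
}

#' Wrap a pre-aligned window string as a target window
#'
#' For windows already aligned to the editing site (fixtures, consensus
#' panels): the string must have length `W + 1 + D` with the site at position
#' `W + 1`.
#'
#' @param sequence Window string (DNA or RNA alphabet, N allowed).
#' @param W,D Upstream / downstream extent.
#' @param id Optional identifier.
#' @return A `target_window`.
#' @export
as_target_window <- function(sequence, W = 33L, D = 5L, id = NA_character_) {
  s <- chartr("T", "U", toupper(as.character(sequence)))
  if (nchar(s) != W + 1L + D) {
    stop("window length ", nchar(s), " does not equal W + 1 + D = ", W + 1L + D)
  }
  if (!grepl("^[ACGUN]*$", s)) stop("window contains non-nucleotide characters")
  structure(list(sequence = s, W = as.integer(W), D = as.integer(D),
                 site_nt = substr(s, W + 1L, W + 1L),
                 source = list(id = id, coord = NA_integer_, strand = "+")),
            class = "target_window")
}

#' Nucleotide(s) of a window at site-relative positions
#'
#' @param window A `target_window`.
#' @param pos Integer vector of positions in `-W..D` (site = 0).
#' @return Character vector of nucleotides.
#' @export
window_nt <- function(window, pos) {
  stopifnot(inherits(window, "target_window"))
  if (any(pos < -window$W | pos > window$D)) {
    stop("position outside window range")
  }
  i <- pos + window$W + 1L
  substring(window$sequence, i, i)
}

#' @export
print.target_window <- function(x, ...) {
  cat("<target_window> ", x$source$id, if (!is.na(x$source$coord))
    paste0(":", x$source$coord, ":", x$source$strand), "\n",
    "  -", x$W, "..+", x$D, "  site = ", x$site_nt, "\n  ",
    x$sequence, "\n", sep = "")
  invisible(x)
}

#' Classify one repeat-nucleotide pair
#'
#' Categories follow the shading of PPR-RNA alignments: perfect matches,
#' pyrimidine transitions (the dispreferred pyrimidine of a ranked C>U / U>C
#' expectation), purine transitions (the other purine where a purine is
#' expected), and mismatches; repeats without a coded expectation, and N
#' nucleotides, are NO_EXPECTATION. For the unranked C/U expectation both
#' pyrimidines count as MATCH.
#'
#' @param expectation An `nt_expectation` (see [expected_nucleotides()]).
#' @param nt Single nucleotide in `A`, `C`, `G`, `U`/`T`, `N`.
#' @return One of `"MATCH"`, `"PYRIMIDINE_TRANSITION"`, `"PURINE_TRANSITION"`,
#'   `"MISMATCH"`, `"NO_EXPECTATION"`.
#' @examples
#' classify_pair(expected_nucleotides("T", "D"), "A")  # purine transition
#' classify_pair(expected_nucleotides("N", "D"), "U")  # match
#' @export
classify_pair <- function(expectation, nt) {
  stopifnot(inherits(expectation, "nt_expectation"), length(nt) == 1L)
  nt <- chartr("T", "U", toupper(nt))
  if (!nt %in% c("A", "C", "G", "U", "N")) stop("invalid nucleotide: ", nt)
  if (nt == "N" || is.na(expectation$primary)) return("NO_EXPECTATION")
  unranked_pair <- !expectation$ranked && !is.na(expectation$secondary)
  if (unranked_pair) {
    return(if (nt %in% c("C", "U")) "MATCH" else "MISMATCH")
  }
  if (nt == expectation$primary) return("MATCH")
  if (!is.na(expectation$secondary) && nt == expectation$secondary) {
    return("PYRIMIDINE_TRANSITION")
  }
  if (expectation$primary %in% c("A", "G") && nt %in% c("A", "G")) {
    return("PURINE_TRANSITION")
  }
  "MISMATCH"
}

.pair_weight <- function(ptype, category, primary, weights) {
  if (ptype %in% .TRIPLET) return(0)
  is_l <- ptype == "L" && !weights$promote_l
  switch(category,
         MATCH = if (is_l) weights$l_match
                 else if (primary %in% c("A", "G")) weights$ps_match_purine
                 else weights$ps_match_pyrimidine,
         PYRIMIDINE_TRANSITION = weights$pyrimidine_transition,
         PURINE_TRANSITION = weights$purine_transition,
         MISMATCH = weights$mismatch,
         NO_EXPECTATION = weights$no_expectation)
}

#' Juxtapose an array with a target window
#'
#' Pairs every repeat with the window nucleotide at its register position (see
#' [repeat_position()]), classifies each pair and sums the configured weights
#' into a match score. `shift` displaces the whole register by one nucleotide
#' (repeat at position p reads the nucleotide at p + shift), used to evaluate
#' one-nucleotide register shifts.
#'
#' @param array A `ppr_array`.
#' @param window A `target_window` wide enough to cover the most N-terminal
#'   repeat (after shifting).
#' @param weights Weight configuration, see [default_match_weights()].
#' @param shift Register displacement in `-1, 0, 1`.
#' @return A `match_profile`: data frame with one row per repeat (`repeat_label`,
#'   `ptype`, `position`, `nt`, `expectation`, `primary`, `category`,
#'   `weight`); attributes `score`, `array_name`, `source`, `shift`.
#' @export
match_profile <- function(array, window, weights = default_match_weights(),
                          shift = 0L) {
  stopifnot(inherits(array, "ppr_array"), inherits(window, "target_window"),
            shift %in% -1:1)
  ex <- array_expectations(array)
  look <- ex$position + as.integer(shift)
  bad <- look < -window$W | look > window$D
  if (any(bad)) {
    stop("window does not cover repeat ", ex$label[which(bad)[1]],
         " (position ", ex$position[which(bad)[1]], ", shift ", shift, ")")
  }
  nt <- window_nt(window, look)
  category <- character(nrow(ex))
  weight <- numeric(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    e <- .nt_expectation(ex$primary[i], ex$secondary[i], ex$ranked[i])
    category[i] <- classify_pair(e, nt[i])
    weight[i] <- .pair_weight(ex$ptype[i], category[i], ex$primary[i], weights)
  }
  out <- data.frame(repeat_label = ex$label, ptype = ex$ptype,
                    position = ex$position, nt = nt,
                    expectation = ex$expectation, primary = ex$primary,
                    category = category, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "score") <- sum(weight)
  attr(out, "array_name") <- attr(array, "name")
  attr(out, "source") <- window$source
  attr(out, "shift") <- as.integer(shift)
  attr(out, "weights") <- weights
  class(out) <- c("match_profile", "data.frame")
  out
}

#' Score of a match profile
#'
#' Recomputes the score of a profile under a (possibly different) weight
#' configuration; the score is the sum of per-pair weights.
#'
#' @param profile A `match_profile`.
#' @param weights Weight configuration.
#' @return Numeric score.
#' @export
score_profile <- function(profile, weights = NULL) {
  stopifnot(inherits(profile, "match_profile"))
  if (is.null(weights)) weights <- attr(profile, "weights")
  if (is.null(weights)) weights <- default_match_weights()
  sum(mapply(.pair_weight, profile$ptype, profile$category, profile$primary,
             MoreArgs = list(weights = weights)))
}

#' Count perfect matches among coded P/S repeats
#'
#' @param profile A `match_profile`.
#' @return List with `n_match` (numbered P- or S-type repeats whose pair is a
#'   MATCH) and `n_coded` (numbered P/S repeats carrying a coded expectation,
#'   the denominator).
#' @export
count_perfect_PS_matches <- function(profile) {
  stopifnot(inherits(profile, "match_profile"))
  ps <- !profile$ptype %in% .TRIPLET & profile$ptype %in% c("P", "S")
  coded <- ps & !is.na(profile$primary)
  list(n_match = sum(coded & profile$category == "MATCH"),
       n_coded = sum(coded))
}

#' Maximum attainable match score of an array
#'
#' Sum over repeats of the best achievable pair weight (a MATCH at every coded
#' repeat); used for the scanner's relative score threshold.
#'
#' @param array A `ppr_array`.
#' @param weights Weight configuration.
#' @return Numeric score.
#' @export
max_attainable_score <- function(array, weights = default_match_weights()) {
  ex <- array_expectations(array)
  sum(mapply(function(pt, pr) {
    if (is.na(pr)) 0 else .pair_weight(pt, "MATCH", pr, weights)
  }, ex$ptype, ex$primary))
}

#' @export
print.match_profile <- function(x, ...) {
  cat("<match_profile> ", attr(x, "array_name"), " vs ",
      attr(x, "source")$id %||% "?",
      "  score = ", format(attr(x, "score")),
      if (attr(x, "shift") != 0L) paste0("  shift = ", attr(x, "shift")),
      "\n", sep = "")
  print.data.frame(x[c("repeat_label", "position", "nt", "expectation",
                       "category", "weight")], row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
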