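# Position frequency matrices and conservation shading over off-target windows.

.windows_to_matrix <- function(windows, W = NULL, D = NULL) {
  if (inherits(windows, "target_window")) windows <- list(windows)
  if (is.list(windows) && all(vapply(windows, inherits, TRUE, "target_window"))) {
    Ws <- vapply(windows, `[[`, 0L, "W")
    Ds <- vapply(windows, `[[`, 0L, "D")
    if (length(unique(Ws)) != 1L || length(unique(Ds)) != 1L) {
      stop("inconsistent window widths")
    }
    W <- Ws[1]; D <- Ds[1]
    strs <- vapply(windows, `[[`, "", "sequence")
  } else if (is.character(windows)) {
    if (is.null(W) || is.null(D)) stop("W and D required for raw strings")
    strs <- chartr("T", "U", toupper(windows))
    if (any(nchar(strs) != W + 1L + D)) stop("inconsistent window widths")
  } else {
    stop("windows must be target_window objects or strings")
  }
  m <- do.call(rbind, strsplit(strs, ""))
  colnames(m) <- as.character(seq.int(-W, D))
  m
}

#' Per-position nucleotide frequencies over aligned windows
#'
#' Counts A/C/G/U per site-relative position over a set of windows aligned at
#' the editing site. N observations are excluded from the denominators.
#'
#' @param windows List of `target_window` objects with identical `W`/`D`, or a
#'   character vector of aligned window strings (then give `W` and `D`).
#' @param W,D Window extent for raw string input.
#' @return A `consensus_matrix`: list with `counts` and `fractions`
#'   (4 x positions matrices, rows A/C/G/U), `positions`, `n` (number of
#'   windows) and `shading` (per-position category from the maximum fraction,
#'   see [shade()]).
#' @export
frequency_matrix <- function(windows, W = NULL, D = NULL) {
  m <- .windows_to_matrix(windows, W, D)
  if (nrow(m) < 1L) stop("need at least one window")
  positions <- as.integer(colnames(m))
  counts <- vapply(seq_len(ncol(m)), function(j) {
    c(A = sum(m[, j] == "A"), C = sum(m[, j] == "C"),
      G = sum(m[, j] == "G"), U = sum(m[, j] == "U"))
  }, numeric(4))
  colnames(counts) <- colnames(m)
  denom <- colSums(counts)
  fractions <- sweep(counts, 2, pmax(denom, 1), "/")
  fractions[, denom == 0] <- NA_real_
  maxfrac <- apply(fractions, 2, function(x) if (all(is.na(x))) NA_real_ else max(x))
  structure(list(counts = counts, fractions = fractions,
                 positions = positions, n = nrow(m),
                 shading = shade(maxfrac)),
            class = "consensus_matrix")
}

#' Conservation shading category for a fraction
#'
#' Mirrors the conservation shading of off-target alignments: at least 90% of
#' sequences is shaded black, at least 60% light green, at least 30% yellow;
#' below that no shading. Thresholds are inclusive.
#'
#' @param fraction Numeric vector of fractions in `[0, 1]`.
#' @return Character vector in `"black"`, `"light_green"`, `"yellow"`,
#'   `"none"` (`NA` stays `NA`).
#' @export
shade <- function(fraction) {
  stopifnot(all(is.na(fraction) | (fraction >= 0 & fraction <= 1)))
  out <- rep(NA_character_, length(fraction))
  ok <- !is.na(fraction)
  out[ok] <- ifelse(fraction[ok] >= 0.9, "black",
                    ifelse(fraction[ok] >= 0.6, "light_green",
                           ifelse(fraction[ok] >= 0.3, "yellow", "none")))
  out
}

#' Windows identical to a reference at given positions
#'
#' @param windows Window set (see [frequency_matrix()]).
#' @param positions Integer vector of site-relative positions (empty set:
#'   every window matches vacuously).
#' @param reference A `target_window` or aligned window string.
#' @param W,D Window extent for raw string input.
#' @return Number of windows whose nucleotides equal the reference's at all
#'   given positions.
#' @export
identity_count <- function(windows, positions, reference, W = NULL, D = NULL) {
  m <- .windows_to_matrix(windows, W, D)
  if (inherits(reference, "target_window")) {
    W <- reference$W; D <- reference$D
    ref <- strsplit(reference$sequence, "")[[1]]
  } else {
    if (is.null(W)) W <- (ncol(m) - 1L - if (is.null(D)) 5L else D)
    ref <- strsplit(chartr("T", "U", toupper(reference)), "")[[1]]
  }
  if (length(ref) != ncol(m)) stop("reference width does not match windows")
  if (length(positions) == 0L) return(nrow(m))
  j <- match(as.character(as.integer(positions)), colnames(m))
  if (anyNA(j)) stop("positions outside window range")
  sum(apply(m[, j, drop = FALSE], 1, function(x) all(x == ref[j])))
}

#' Off-target consensus report
#'
#' Orders calls by decreasing mean editing level (optionally capped to the top
#' hits), tabulates genome position, edit label, editing percentage, coverage
#' and the aligned window, and appends the frequency/shading matrix over the
#' included windows. Windows should be the post-shift-annotation windows, so a
#' shifted site contributes its shifted alignment.
#'
#' @param calls An `editing_calls` data frame (needs `seq_id`, `pos`,
#'   `level_mean`, `coverage`; `label` used when present).
#' @param windows List of `target_window`s parallel to the rows of `calls`.
#' @param top_n Optional cap on the number of reported rows.
#' @return A `consensus_report`: list with `table` (ordered data frame) and
#'   `consensus` (a `consensus_matrix` over the included windows).
#' @export
consensus_report <- function(calls, windows, top_n = NULL) {
  stopifnot(nrow(calls) == length(windows))
  ord <- order(-calls$level_mean, calls$seq_id, calls$pos)
  if (!is.null(top_n)) ord <- utils::head(ord, top_n)
  tab <- data.frame(
    genome_pos = paste0(calls$seq_id[ord], ":", calls$pos[ord]),
    label = if ("label" %in% names(calls)) calls$label[ord] else NA_character_,
    ed_pct = 100 * calls$level_mean[ord],
    coverage = calls$coverage[ord],
    window = vapply(windows[ord], function(w)
      if (inherits(w, "target_window")) w$sequence else as.character(w), ""),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, consensus = frequency_matrix(windows[ord])),
            class = "consensus_report")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("<consensus_matrix> ", x$n, " windows, positions ",
      min(x$positions), "..", max(x$positions), "\n", sep = "")
  show <- rbind(round(x$fractions, 2), shading = x$shading)
  print(show[, as.integer(colnames(x$fractions)) >= -20, drop = FALSE],
        quote = FALSE)
  invisible(x)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> ", nrow(x$table), " sites\n", sep = "")
  print.data.frame(x$table, row.names = FALSE)
  print(x$consensus)
  invisible(x)
}
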