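# Editing quantification from Sanger chromatogram peak heights.

#' Editing fraction from a T/C peak pair
#'
#' Editing at a site is quantified as the thymidine peak height divided by the
#' sum of the thymidine and cytidine peak heights; the ratio is scale
#' invariant.
#'
#' @param t_height,c_height Non-negative peak heights (vectorised).
#' @return T / (T + C); `NA` with a warning where both heights are zero.
#' @examples
#' peak_editing_fraction(700, 300)  # 0.7
#' @export
peak_editing_fraction <- function(t_height, c_height) {
  stopifnot(all(t_height >= 0), all(c_height >= 0))
  total <- t_height + c_height
  out <- ifelse(total > 0, t_height / total, NA_real_)
  if (anyNA(out)) warning("zero total peak height; fraction undefined")
  out
}

#' Aggregate replicate editing fractions
#'
#' Mean and sample (n - 1) standard deviation over replicate measurements;
#' editing values are conventionally reported as mean +/- s.d. of at least
#' three biological replicates, so fewer than three triggers a warning.
#'
#' @param values Numeric vector of editing fractions (NA dropped).
#' @return List with `mean`, `sd` (`NA` with a warning for a single value) and
#'   `n`.
#' @export
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no values to aggregate")
  if (n < 3L) warning("fewer than 3 replicates (n = ", n, ")")
  s <- if (n == 1L) NA_real_ else stats::sd(values)
  list(mean = mean(values), sd = s, n = n)
}

#' Read a Sanger peak-height table
#'
#' @param path TSV with columns `site`, `replicate`, `T_height`, `C_height`.
#' @return Data frame.
#' @export
read_peaks_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "replicate", "T_height", "C_height")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("peak table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' Per-site editing summary from peak heights
#'
#' @param peaks Data frame as returned by [read_peaks_tsv()].
#' @return Data frame with one row per site: `site`, `n`, `mean`, `sd`.
#' @export
quantify_sanger <- function(peaks) {
  need <- c("site", "replicate", "T_height", "C_height")
  stopifnot(all(need %in% names(peaks)))
  frac <- peak_editing_fraction(peaks$T_height, peaks$C_height)
  rows <- lapply(split(frac, peaks$site), function(v) {
    a <- suppressWarnings(aggregate_replicates(v))
    data.frame(n = a$n, mean = a$mean, sd = a$sd)
  })
  out <- do.call(rbind, rows)
  out <- cbind(site = names(rows), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
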