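# Bundled worked-example data.

#' PPR65 worked example (synthetic reconstruction)
#'
#' A PPR65-like editing factor (15 numbered PLS repeats plus the terminal
#' P2-L2-S2 triplet) with its native ccmFC target window and seven aligned
#' off-target windows. The repeat residues and window nucleotides are a
#' synthetic reconstruction assembled from the described recognition
#' constraints of this factor (coded-repeat identities, the native purine
#' mismatch at -9, the off-target G at -9 in all seven windows, the shared
#' -3..-1 context in six of seven), not the deposited sequences; they are
#' intended for worked examples and regression tests.
#'
#' @return List with `array` (a `ppr_array`), `native` (a `target_window`,
#'   W = 33, D = 5), `offtargets` (data frame: `id`, `ed_pct`, `read_cov`,
#'   `window`) and `offtarget_windows` (list of `target_window`s).
#' @export
ppr65_example <- function() {
  array <- parse_array_spec(
    system.file("extdata", "ppr65_array_synthetic.tsv", package = "plsedit"),
    name = "PPR65")
  tab <- utils::read.delim(
    system.file("extdata", "ppr65_windows_synthetic.tsv", package = "plsedit"),
    stringsAsFactors = FALSE)
  native_row <- tab[tab$kind == "native", , drop = FALSE]
  off <- tab[tab$kind == "offtarget", , drop = FALSE]
  rownames(off) <- NULL
  list(array = array,
       native = as_target_window(native_row$window, id = native_row$id),
       offtargets = off[c("id", "ed_pct", "read_cov", "window")],
       offtarget_windows = Map(as_target_window, off$window, id = off$id,
                               USE.NAMES = FALSE))
}
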