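# Small fixtures and an independent brute-force scan oracle.

toy_array <- function() {
  parse_array_spec("P-4TN;S-3TD;P-2NS;S-1ND;P2;L2;S2", name = "toy")
}

# perfect-match window for an array: primary expectation everywhere (C for the
# unranked pair), A elsewhere, C at the site
perfect_window <- function(array, W = 33L, D = 5L) {
  ex <- array_expectations(array)
  chars <- rep("A", W + 1L + D)
  for (i in seq_len(nrow(ex))) {
    if (is.na(ex$primary[i])) next
    nt <- if (!ex$ranked[i] && !is.na(ex$secondary[i])) "C" else ex$primary[i]
    chars[ex$position[i] + W + 1L] <- nt
  }
  chars[W + 1L] <- "C"
  as_target_window(paste(chars, collapse = ""), W = W, D = D, id = "perfect")
}

mutate_window <- function(window, pos, nt) {
  s <- window$sequence
  i <- pos + window$W + 1L
  substr(s, i, i) <- nt
  as_target_window(s, W = window$W, D = window$D, id = window$source$id)
}

# brute-force scanner: re-profile every C on both strands via match_profile
scan_oracle <- function(seqs, array, weights = default_match_weights(),
                        min_score = NULL, W = 33L, D = 5L) {
  if (is.null(min_score)) min_score <- 0.6 * max_attainable_score(array, weights)
  rows <- list()
  for (sid in names(seqs)) {
    s <- toupper(chartr("U", "T", seqs[[sid]]))
    L <- nchar(s)
    for (strand in c("+", "-")) {
      str <- if (strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      for (i in 0:(L - 1L)) {
        if (substr(str, i + 1L, i + 1L) != "C") next
        w <- extract_window(str, i, W = W, D = D, strand = "+", id = sid)
        scores <- vapply(c(0L, -1L, 1L), function(sh)
          attr(match_profile(array, w, weights, shift = sh), "score"),
          numeric(1))
        k <- which.max(scores)
        if (scores[k] < min_score) next
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, coord = if (strand == "+") i else L - 1L - i,
          strand = strand, score = scores[k], shift = c(0L, -1L, 1L)[k],
          window = w$sequence, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$seq_id, out$coord, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
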