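# Transcriptome-wide scanning for candidate editable cytidines.

# Precompile per-repeat vectors so a window can be scored without building a
# full match_profile; classification semantics identical to classify_pair().
.compile_array <- function(array, weights) {
  ex <- array_expectations(array)
  n <- nrow(ex)
  match_w <- numeric(n)
  for (i in seq_len(n)) {
    match_w[i] <- if (is.na(ex$primary[i])) 0 else
      .pair_weight(ex$ptype[i], "MATCH", ex$primary[i], weights)
  }
  triplet <- ex$ptype %in% .TRIPLET
  list(position = ex$position,
       primary = ex$primary,
       secondary = ex$secondary,
       unranked_pair = !ex$ranked & !is.na(ex$secondary),
       ranked_pair = ex$ranked & !is.na(ex$secondary),
       primary_purine = !is.na(ex$primary) & ex$primary %in% c("A", "G"),
       triplet = triplet,
       match_w = match_w,
       w_pyrt = weights$pyrimidine_transition,
       w_purt = weights$purine_transition,
       w_mism = weights$mismatch,
       w_noexp = weights$no_expectation)
}

.score_fast <- function(comp, nts) {
  noexp <- is.na(comp$primary) | nts == "N"
  m <- !noexp & (nts == comp$primary |
                   (comp$unranked_pair & (nts == "C" | nts == "U")))
  pyrt <- !noexp & !m & comp$ranked_pair & nts == comp$secondary
  purt <- !noexp & !m & !pyrt & comp$primary_purine & (nts == "A" | nts == "G")
  mism <- !(noexp | m | pyrt | purt)
  w <- ifelse(m, comp$match_w,
              ifelse(pyrt, comp$w_pyrt,
                     ifelse(purt, comp$w_purt,
                            ifelse(mism, comp$w_mism, comp$w_noexp))))
  w[comp$triplet] <- 0
  sum(w)
}

.load_sequences <- function(fasta) {
  if (inherits(fasta, "DNAStringSet") || inherits(fasta, "XStringSet")) {
    s <- as.character(fasta)
  } else if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    s <- as.character(Biostrings::readDNAStringSet(fasta))
  } else if (is.character(fasta)) {
    s <- fasta
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  } else {
    stop("cannot interpret sequence input of class ", class(fasta)[1])
  }
  names(s) <- sub("\\s.*$", "", names(s))
  toupper(chartr("U", "T", s))
}

#' Scan sequences for candidate editable cytidines
#'
#' Profiles every cytidine on both strands of the input sequences against the
#' repeat array, annotates one-nucleotide register shifts, applies optional
#' nucleotide constraints on the -3..-1 context, drops sites below the score
#' threshold and returns the candidates ranked by score.
#'
#' @param fasta FASTA file path, `DNAStringSet`, or named character vector of
#'   sequences.
#' @param array A `ppr_array`.
#' @param weights Weight configuration, see [default_match_weights()].
#' @param min_score Minimum reported score; default 60% of the array's maximum
#'   attainable score.
#' @param constraints Optional named list of allowed nucleotide sets for
#'   site-relative positions, e.g. `list("-1" = "U", "-3" = c("C", "U"))`;
#'   evaluated on the unshifted window (RNA alphabet).
#' @param W,D Window extent (see [extract_window()]).
#' @param shifts Evaluate -1/+1 register shifts and report the best
#'   (`shift != 0` only when it strictly improves the score).
#' @return A `candidate_sites` data frame: `seq_id`, `coord` (0-based on the
#'   plus strand), `strand`, `score`, `shift`, `window` (RNA, 5'->3' on the
#'   edited strand), `label` (NA until annotated), sorted by decreasing score
#'   with ties broken by (seq_id, coord, strand).
#' @export
scan_transcriptome <- function(fasta, array, weights = default_match_weights(),
                               min_score = NULL, constraints = NULL,
                               W = 33L, D = 5L, shifts = TRUE) {
  seqs <- .load_sequences(fasta)
  if (length(seqs) == 0L || all(!nzchar(seqs))) stop("no sequences to scan")
  if (is.null(min_score)) {
    min_score <- 0.6 * max_attainable_score(array, weights)
  }
  comp <- .compile_array(array, weights)
  if (!is.null(constraints)) {
    cpos <- as.integer(names(constraints))
    cset <- lapply(constraints, function(x) chartr("T", "U", toupper(x)))
  }
  res <- vector("list", 2L * length(seqs))
  k <- 0L
  for (sid in names(seqs)) {
    L <- nchar(seqs[[sid]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[sid]] else .revcomp_chr(seqs[[sid]])
      chars <- strsplit(chartr("T", "U", s), "")[[1]]
      sites <- which(chars == "C") - 1L            # 0-based on this strand
      if (length(sites) == 0L) next
      padded <- c(rep("N", W), chars, rep("N", D))
      hits <- lapply(sites, function(i) {
        base <- i + W + 1L                          # padded index of position 0
        if (!is.null(constraints)) {
          ok <- all(vapply(seq_along(cpos), function(j) {
            padded[base + cpos[j]] %in% cset[[j]]
          }, logical(1)))
          if (!ok) return(NULL)
        }
        best <- .score_fast(comp, padded[base + comp$position])
        best_shift <- 0L
        if (shifts) {
          for (sh in c(-1L, 1L)) {
            sc <- .score_fast(comp, padded[base + comp$position + sh])
            if (sc > best) { best <- sc; best_shift <- sh }
          }
        }
        if (best < min_score) return(NULL)
        data.frame(seq_id = sid,
                   coord = if (strand == "+") i else L - 1L - i,
                   strand = strand, score = best, shift = best_shift,
                   window = paste(padded[base + (-W:D)], collapse = ""),
                   stringsAsFactors = FALSE)
      })
      hits <- hits[!vapply(hits, is.null, logical(1))]
      if (length(hits)) {
        k <- k + 1L
        res[[k]] <- do.call(rbind, hits)
      }
    }
  }
  out <- if (k) do.call(rbind, res[seq_len(k)]) else
    data.frame(seq_id = character(), coord = integer(), strand = character(),
               score = numeric(), shift = integer(), window = character(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$seq_id, out$coord, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$label <- NA_character_
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' Best one-nucleotide register shift for a window
#'
#' Evaluates the match score with the repeat register displaced by one
#' nucleotide in each direction and reports the argmax, preferring the
#' unshifted register on ties (then -1 over +1).
#'
#' @param array A `ppr_array`.
#' @param window A `target_window` with at least one nucleotide of slack on
#'   both sides of the repeat span.
#' @param weights Weight configuration.
#' @return List with `shift` (in -1, 0, 1) and `score`.
#' @export
annotate_shift <- function(array, window, weights = default_match_weights()) {
  shifts <- c(0L, -1L, 1L)
  scores <- vapply(shifts, function(sh) {
    attr(match_profile(array, window, weights, shift = sh), "score")
  }, numeric(1))
  k <- which.max(scores)
  list(shift = shifts[k], score = scores[k])
}

#' Editing-site nomenclature label
#'
#' Builds the standard editing-site label: gene name, "eU", the transcript
#' position (1-based within the CDS counted from the A of the start codon;
#' negative for upstream nucleotides, -1 adjacent to the start, no position 0)
#' and, for non-synonymous CDS edits, the amino acids before and after the
#' C-to-U change (e.g. `ccmFCeU103PS`). Antisense calls get the suffix `"as"`
#' and no amino-acid change; synonymous edits carry an empty change and a
#' `synonymous` flag.
#'
#' @param gene Gene name.
#' @param cds_start 0-based offset of the A of the start codon in `sequence`.
#' @param site_pos 0-based offset of the edited cytidine in `sequence`.
#' @param sequence Sense-strand nucleotide sequence of the transcript region
#'   (DNA or RNA alphabet).
#' @param antisense Editing detected on the strand opposite to the annotated
#'   gene.
#' @param code_table Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()] (default `"11"`, bacterial; identical amino
#'   acid assignments to the standard code).
#' @return An `edit_label`: list with `gene`, `position`, `aa_change`,
#'   `synonymous`, `antisense` and the formatted `label`.
#' @examples
#' seq <- paste0(strrep("GCT", 34), "CCATAA")
#' edit_label("ccmFC", 0, 102, seq)$label   # "ccmFCeU103PS"
#' @export
edit_label <- function(gene, cds_start, site_pos, sequence, antisense = FALSE,
                       code_table = "11") {
  sequence <- toupper(chartr("Uu", "Tt", as.character(sequence)))
  n <- nchar(sequence)
  if (site_pos < 0L || site_pos >= n) {
    stop("site outside the annotated transcript")
  }
  pos <- if (site_pos >= cds_start) site_pos - cds_start + 1L else
    site_pos - cds_start
  aa_change <- ""
  synonymous <- FALSE
  if (!antisense && site_pos >= cds_start) {
    if (substr(sequence, site_pos + 1L, site_pos + 1L) != "C") {
      stop("site nucleotide is not C on the sense strand")
    }
    codon_i <- (pos - 1L) %/% 3L
    off <- (pos - 1L) %% 3L
    cstart <- cds_start + 3L * codon_i
    if (cstart + 2L < n) {
      codon <- substr(sequence, cstart + 1L, cstart + 3L)
      edited <- codon
      substr(edited, off + 1L, off + 1L) <- "T"
      gc <- Biostrings::getGeneticCode(code_table)
      aa1 <- unname(gc[codon])
      aa2 <- unname(gc[edited])
      if (identical(aa1, aa2)) synonymous <- TRUE
      else aa_change <- paste0(aa1, aa2)
    }
  }
  label <- paste0(gene, "eU", pos, aa_change, if (antisense) "as" else "")
  structure(list(gene = gene, position = pos, aa_change = aa_change,
                 synonymous = synonymous, antisense = isTRUE(antisense),
                 label = label),
            class = "edit_label")
}

#' @export
print.edit_label <- function(x, ...) {
  cat(x$label, if (x$synonymous) " (synonymous)", "\n", sep = "")
  invisible(x)
}

#' Parse an editing-site label
#'
#' Inverse of [edit_label()]: recovers gene, position, amino-acid change and
#' the antisense flag from a label string.
#'
#' @param label Label string such as `"nad4eU272SL"` or `"AJH09430eU-5"`.
#' @return List with `gene`, `position`, `aa_change`, `antisense`.
#' @export
parse_edit_label <- function(label) {
  rx <- "^(.*?)eU(-?[0-9]+)([A-Z][A-Z])?(as)?$"
  if (!grepl(rx, label)) stop("cannot parse edit label: ", label)
  m <- regmatches(label, regexec(rx, label))[[1]]
  list(gene = m[2], position = as.integer(m[3]),
       aa_change = m[4], antisense = m[5] == "as")
}
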