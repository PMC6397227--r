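# PLS-type PPR arrays and the amino-acid -> nucleotide recognition code.

.PTYPES <- c("P", "L", "S", "P2", "L2", "S2")
.TRIPLET <- c("P2", "L2", "S2")
.GAP_CHARS <- c(".", "-", "*", "")

#' Nucleotide expectation of a single PPR repeat
#'
#' The PPR-RNA code for P- and S-type (and code-conforming L-type) repeats
#' reads the amino acids at repeat positions 5 and L (last) and specifies the
#' preferred target nucleotide: T/S + N selects A, T/S + D selects G, N + N
#' selects a pyrimidine with no preference between C and U, N + S prefers C
#' over U and N + D prefers U over C. Any other residue combination carries no
#' expectation and is excluded from scoring.
#'
#' @param res5 One-letter amino acid at repeat position 5 (gap marker `"."`,
#'   `"-"` or `"*"` for unresolved residues).
#' @param resL One-letter amino acid at repeat position L (last).
#' @return An object of class `nt_expectation`: a list with `primary`
#'   (nucleotide or `NA`), `secondary` (nucleotide or `NA`) and `ranked`
#'   (`TRUE` for the C>U / U>C rules, `FALSE` for the unranked C/U pair).
#' @examples
#' expected_nucleotides("T", "D")  # G
#' expected_nucleotides("N", "S")  # C preferred over U
#' expected_nucleotides("A", "E")  # no expectation
#' @export
expected_nucleotides <- function(res5, resL) {
  stopifnot(length(res5) == 1L, length(resL) == 1L)
  r5 <- toupper(as.character(res5))
  rl <- toupper(as.character(resL))
  if (is.na(r5) || is.na(rl) || r5 %in% .GAP_CHARS || rl %in% .GAP_CHARS) {
    return(.nt_expectation())
  }
  if (r5 %in% c("T", "S") && rl == "N") return(.nt_expectation("A"))
  if (r5 %in% c("T", "S") && rl == "D") return(.nt_expectation("G"))
  if (r5 == "N" && rl == "N") return(.nt_expectation("C", "U", ranked = FALSE))
  if (r5 == "N" && rl == "S") return(.nt_expectation("C", "U", ranked = TRUE))
  if (r5 == "N" && rl == "D") return(.nt_expectation("U", "C", ranked = TRUE))
  .nt_expectation()
}

.nt_expectation <- function(primary = NA_character_, secondary = NA_character_,
                            ranked = FALSE) {
  structure(list(primary = primary, secondary = secondary, ranked = ranked),
            class = "nt_expectation")
}

#' @export
format.nt_expectation <- function(x, ...) {
  if (is.na(x$primary)) return("")
  if (is.na(x$secondary)) return(x$primary)
  if (x$ranked) paste0(x$primary, ">", x$secondary) else
    paste0(x$primary, "/", x$secondary)
}

#' @export
print.nt_expectation <- function(x, ...) {
  s <- format(x)
  cat("<nt_expectation> ", if (nzchar(s)) s else "(none)", "\n", sep = "")
  invisible(x)
}

#' Parse a PPR array specification
#'
#' Reads an ordered PLS-type repeat array, N- to C-terminus, optionally ending
#' in the terminal P2-L2-S2 triplet. Two input forms are accepted:
#'
#' * a headered TSV (file path, literal TSV text, or data frame) with columns
#'   `type`, `index`, `res5`, `resL`; triplet rows use index values
#'   `P2`/`L2`/`S2`;
#' * a compact one-line string such as `"P-4TN;S-3TD;P-2NS;S-1ND;P2..;L2..;S2.."`
#'   where each token is type-index followed by the residues at positions 5 and
#'   L (gap marker `.`).
#'
#' Numbered repeats use backward numbering: repeat 1 is the repeat adjacent to
#' P2 and numbers increase towards the N-terminus. Input listed C- to
#' N-terminus is detected and flipped. Consecutive numbering, at most one of
#' each triplet repeat (in P2, L2, S2 order at the C-terminus) and valid type
#' letters are enforced.
#'
#' @param x File path, TSV text, data frame, or compact string.
#' @param name Factor identifier stored with the array (e.g. `"PPR65"`).
#' @return A `ppr_array`: a data frame with columns `label`, `ptype`, `index`
#'   (NA for the triplet), `res5`, `resL`, ordered N- to C-terminus.
#' @export
parse_array_spec <- function(x, name = NULL) {
  tab <- if (is.data.frame(x)) {
    x
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             !dir.exists(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
  } else if (is.character(x) && length(x) == 1L &&
             grepl("[\t\n]", x)) {
    utils::read.delim(textConnection(x), stringsAsFactors = FALSE,
                      colClasses = "character")
  } else if (is.character(x)) {
    .parse_compact_tokens(unlist(strsplit(x, ";", fixed = TRUE)))
  } else {
    stop("cannot interpret array specification of class ", class(x)[1])
  }
  .validate_ppr_array(tab, name = name)
}

.parse_compact_tokens <- function(tokens) {
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("no repeats in array specification")
  rx_num <- "^([PLS])-([0-9]+)([A-Z.*-])([A-Z.*-])$"
  rx_tri <- "^(P2|L2|S2)([A-Z.*-])?([A-Z.*-])?$"
  rows <- lapply(tokens, function(tk) {
    if (grepl(rx_num, tk)) {
      data.frame(type = sub(rx_num, "\\1", tk),
                 index = sub(rx_num, "\\2", tk),
                 res5 = sub(rx_num, "\\3", tk),
                 resL = sub(rx_num, "\\4", tk),
                 stringsAsFactors = FALSE)
    } else if (grepl(rx_tri, tk)) {
      r5 <- sub(rx_tri, "\\2", tk)
      rl <- sub(rx_tri, "\\3", tk)
      data.frame(type = sub(rx_tri, "\\1", tk),
                 index = sub(rx_tri, "\\1", tk),
                 res5 = if (nzchar(r5)) r5 else ".",
                 resL = if (nzchar(rl)) rl else ".",
                 stringsAsFactors = FALSE)
    } else {
      stop("malformed repeat token: ", tk)
    }
  })
  do.call(rbind, rows)
}

.validate_ppr_array <- function(tab, name = NULL) {
  need <- c("type", "index", "res5", "resL")
  if (!all(need %in% names(tab))) {
    stop("array specification needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("no repeats in array specification")
  ptype <- toupper(trimws(as.character(tab$type)))
  bad <- setdiff(unique(ptype), .PTYPES)
  if (length(bad)) stop("unknown repeat type letter: ", paste(bad, collapse = ", "))

  is_tri <- ptype %in% .TRIPLET
  idx <- rep(NA_integer_, nrow(tab))
  idx_raw <- trimws(as.character(tab$index))
  num_ok <- grepl("^[0-9]+$", idx_raw[!is_tri])
  if (!all(num_ok)) stop("numbered repeats need a positive integer index")
  idx[!is_tri] <- as.integer(idx_raw[!is_tri])
  if (any(idx[!is_tri] < 1L)) stop("numbered repeats have index >= 1")
  tri_label_ok <- idx_raw[is_tri] %in% c(.TRIPLET, "", NA)
  if (!all(tri_label_ok)) stop("triplet rows use index values P2/L2/S2")

  norm_res <- function(r) {
    r <- toupper(trimws(as.character(r)))
    r[r %in% .GAP_CHARS | is.na(r)] <- "."
    ok <- r == "." | r %in% LETTERS
    if (!all(ok)) stop("residues must be single upper-case letters or a gap marker")
    r
  }
  res5 <- norm_res(tab$res5)
  resL <- norm_res(tab$resL)

  # orient N->C: numbered indices descending, triplet as C-terminal suffix
  n_num <- sum(!is_tri)
  if (n_num == 0L) stop("no numbered repeats in array specification")
  if (n_num > 1L) {
    d <- diff(idx[!is_tri])
    if (all(d > 0)) {               # listed C->N, flip
      ord <- rev(seq_len(nrow(tab)))
      ptype <- ptype[ord]; idx <- idx[ord]
      res5 <- res5[ord]; resL <- resL[ord]
      is_tri <- is_tri[ord]
    }
  }
  if (any(is_tri) && !all(which(is_tri) > max(which(!is_tri)))) {
    stop("triplet must be C-terminal")
  }
  ii <- idx[!is_tri]
  if (anyDuplicated(ii)) stop("duplicate index in array specification")
  if (!identical(ii, seq.int(n_num, 1L))) {
    stop("backward numbering must run consecutively from ", n_num,
         " down to 1 (N- to C-terminus)")
  }
  tri <- ptype[is_tri]
  if (anyDuplicated(tri)) stop("at most one each of P2, L2, S2")
  if (!identical(tri, .TRIPLET[.TRIPLET %in% tri])) {
    stop("triplet out of order: expected P2, L2, S2")
  }

  label <- ifelse(is_tri,
                  paste0(ptype, ifelse(res5 == "." & resL == ".", "",
                                       paste0(res5, resL))),
                  paste0(ptype, "-", idx, res5, resL))
  out <- data.frame(label = label, ptype = ptype, index = idx,
                    res5 = res5, resL = resL, stringsAsFactors = FALSE)
  attr(out, "name") <- if (is.null(name)) "array" else name
  class(out) <- c("ppr_array", "data.frame")
  out
}

#' Target position addressed by a repeat
#'
#' The repeat register juxtaposes repeat S-1 with nucleotide -4 upstream of the
#' edited cytidine (position 0); a numbered repeat k therefore addresses
#' position -(k + 3), and the terminal triplet P2, L2, S2 addresses -3, -2, -1.
#'
#' @param x A `ppr_array`, or a character vector of repeat identifiers
#'   (`"S-1"`, `"P-6"`, `"P2"`, ... full labels such as `"P-6TD"` also work).
#' @return Integer vector of target positions (named by repeat label for a
#'   `ppr_array`).
#' @examples
#' repeat_position(c("S-1", "P-6", "S-13", "S2"))
#' @export
repeat_position <- function(x) {
  if (inherits(x, "ppr_array")) {
    pos <- ifelse(is.na(x$index),
                  c(P2 = -3L, L2 = -2L, S2 = -1L)[x$ptype],
                  -(x$index + 3L))
    return(stats::setNames(as.integer(pos), x$label))
  }
  x <- as.character(x)
  vapply(x, function(lab) {
    tri <- substr(lab, 1, 2)
    if (tri %in% .TRIPLET) return(c(P2 = -3L, L2 = -2L, S2 = -1L)[[tri]])
    m <- regmatches(lab, regexec("^[PLS]-([0-9]+)", lab))[[1]]
    if (length(m) < 2) stop("cannot parse repeat identifier: ", lab)
    -(as.integer(m[2]) + 3L)
  }, integer(1))
}

#' Per-repeat expectation table of an array
#'
#' @param array A `ppr_array`.
#' @return Data frame with one row per repeat: `label`, `ptype`, `position`,
#'   `primary`, `secondary`, `ranked`, and the display string `expectation`.
#' @export
array_expectations <- function(array) {
  stopifnot(inherits(array, "ppr_array"))
  exps <- Map(expected_nucleotides, array$res5, array$resL)
  data.frame(
    label = array$label,
    ptype = array$ptype,
    position = unname(repeat_position(array)),
    primary = vapply(exps, `[[`, "", "primary"),
    secondary = vapply(exps, `[[`, "", "secondary"),
    ranked = vapply(exps, `[[`, TRUE, "ranked"),
    expectation = vapply(exps, format, ""),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ppr_array <- function(x, ...) {
  cat("<ppr_array> ", attr(x, "name"), ": ", nrow(x), " repeats (",
      sum(!x$ptype %in% .TRIPLET), " numbered)\n", sep = "")
  ex <- array_expectations(x)
  print.data.frame(cbind(ex[c("label", "ptype", "position")],
                         expectation = ex$expectation), row.names = FALSE)
  invisible(x)
}
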