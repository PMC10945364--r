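# Cleavage-site consensus motifs: construction from aligned cut windows,
# IUPAC scanning of candidate RNAs, anticodon-loop localisation.
#
# A motif is a degenerate RNA pattern with an internal cut, written in the
# field's notation with a caret, e.g. CUKG^AA: the endoribonuclease cuts
# after the 4th pattern base, and the called genomic position is the first
# nucleotide of the 3' cleavage product.

#' Degenerate consensus motif with an internal cut
#'
#' @param pattern IUPAC nucleotide string (RNA or DNA alphabet; stored as RNA).
#'   A caret may be embedded to mark the cut (`"CUKG^AA"`), in which case
#'   `cut_offset` is inferred.
#' @param cut_offset Number of pattern bases 5' of the cut (the cut lies
#'   between `pattern[cut_offset]` and `pattern[cut_offset + 1]`); must be
#'   strictly inside the pattern.
#' @return An object of class `consensus_motif` with elements `pattern`
#'   (RNA, no caret) and `cut_offset`.
#' @examples
#' consensus_motif("CUKG^AA")            # the tRNA-Ser anticodon-loop site
#' consensus_motif("GAA", cut_offset = 1) # minimal G^AA form
#' @export
consensus_motif <- function(pattern, cut_offset = NULL) {
  pattern <- toupper(as.character(pattern))
  if (grepl("^", pattern, fixed = TRUE)) {
    off <- regexpr("^", pattern, fixed = TRUE)[1] - 1L
    pattern <- sub("^", "", pattern, fixed = TRUE)
    if (!is.null(cut_offset) && cut_offset != off)
      .stopf("cut_offset (%d) disagrees with the caret position (%d)",
             cut_offset, off)
    cut_offset <- off
  }
  if (is.null(cut_offset))
    .stopf("no cut position: give 'cut_offset' or embed a caret")
  pattern <- .as_rna_chr(pattern)
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, .IUPAC_OK)
  if (length(bad))
    .stopf("non-IUPAC letters in pattern: %s", paste(bad, collapse = ", "))
  .assert_scalar_number(cut_offset, "cut_offset", 1, nchar(pattern) - 1L,
                        integer = TRUE)
  structure(list(pattern = pattern, cut_offset = as.integer(cut_offset)),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  p <- x$pattern
  cat(sprintf("<consensus_motif> %s^%s  (cut after %d of %d nt)\n",
              substr(p, 1, x$cut_offset),
              substr(p, x$cut_offset + 1L, nchar(p)),
              x$cut_offset, nchar(p)))
  invisible(x)
}

#' @export
format.consensus_motif <- function(x, ...) {
  paste0(substr(x$pattern, 1, x$cut_offset), "^",
         substr(x$pattern, x$cut_offset + 1L, nchar(x$pattern)))
}

# Concrete bases (DNA) covered by one IUPAC letter.
.iupac_bases <- function(letter) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[.as_dna_chr(letter)]], "")[[1]]
}

#' Build a degenerate consensus from aligned cut windows
#'
#' Columns are generalised to the smallest IUPAC code covering the bases that
#' together account for at least `min_fraction` of the windows (most frequent
#' bases first; with the default `min_fraction = 1` every observed base is
#' covered).  Flanking fully-degenerate (`N`) columns are trimmed, shifting
#' the cut offset accordingly.
#'
#' @param windows Character vector (or XStringSet) of equal-length sequence
#'   windows, aligned on a common cut column.
#' @param cut_offset Number of window columns 5' of the cut.
#' @param min_fraction Per-column coverage fraction in (0, 1].
#' @return A [consensus_motif()].
#' @examples
#' build_consensus(c("CUUGAA", "CUGGAA"), cut_offset = 4) # CUKG^AA
#' @export
build_consensus <- function(windows, cut_offset, min_fraction = 1) {
  windows <- .as_dna_chr(as.character(windows))
  if (length(windows) < 1L) .stopf("no windows")
  w <- unique(nchar(windows))
  if (length(w) != 1L) .stopf("windows have unequal lengths: %s",
                              paste(w, collapse = ", "))
  .assert_scalar_number(cut_offset, "cut_offset", 1, w - 1L, integer = TRUE)
  .assert_scalar_number(min_fraction, "min_fraction", 1e-9, 1)
  mat <- do.call(rbind, strsplit(windows, ""))
  code <- vapply(seq_len(w), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    frac <- cumsum(tab) / sum(tab)
    keep <- seq_len(which(frac >= min_fraction - 1e-12)[1])
    Biostrings::mergeIUPACLetters(paste(names(tab)[keep], collapse = ""))
  }, character(1))
  lead <- match(FALSE, code == "N", nomatch = w + 1L) - 1L
  trail <- match(FALSE, rev(code) == "N", nomatch = w + 1L) - 1L
  if (lead + trail >= w)
    .stopf("no informative columns: consensus is fully degenerate")
  kept <- code[(lead + 1L):(w - trail)]
  new_cut <- cut_offset - lead
  if (new_cut < 1L || new_cut >= length(kept))
    .stopf("cut column trimmed away: consensus uninformative around the cut")
  consensus_motif(paste(kept, collapse = ""), cut_offset = new_cut)
}

#' Scan RNA sequences for a consensus motif
#'
#' Finds all (including overlapping) occurrences of the motif under IUPAC
#' matching semantics; `U` and `T` are interchangeable on input.  When a
#' dot-bracket structure is supplied for a sequence, each hit is classified by
#' whether its cut falls inside the anticodon loop
#' (see [locate_anticodon_loop()]).
#'
#' @param motif A [consensus_motif()].
#' @param targets Named character vector or [Biostrings::XStringSet] of
#'   target sequences.
#' @param structures Optional named character vector of dot-bracket strings
#'   (names matching `targets`).
#' @return A data.frame with one row per hit: `sequence_id`, `start`
#'   (1-based), `cut_position` (`start + cut_offset`; first base of the 3'
#'   product), `match` (the matched substring, RNA), `in_loop` (logical, `NA`
#'   when no loop is known).
#' @examples
#' m <- consensus_motif("CUKG^AA")
#' scan_motif(m, c(t1 = "GGCUUGAAUC"))
#' @export
scan_motif <- function(motif, targets, structures = NULL) {
  stopifnot(inherits(motif, "consensus_motif"))
  seqs <- stats::setNames(.as_dna_chr(as.character(targets)),
                          names(targets) %||% as.character(seq_along(targets)))
  ids <- names(seqs)
  pat <- Biostrings::DNAString(.as_dna_chr(motif$pattern))
  out <- lapply(ids, function(id) {
    mt <- Biostrings::matchPattern(pat, Biostrings::DNAString(seqs[[id]]),
                                   fixed = FALSE)
    if (!length(mt)) return(NULL)
    st <- Biostrings::start(mt)
    data.frame(sequence_id = id, start = st,
               cut_position = st + motif$cut_offset,
               match = .as_rna_chr(as.character(mt)),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, out)
  if (is.null(hits))
    hits <- data.frame(sequence_id = character(), start = integer(),
                       cut_position = integer(), match = character(),
                       stringsAsFactors = FALSE)
  hits$in_loop <- rep(NA, nrow(hits))
  if (!is.null(structures) && nrow(hits)) {
    for (id in intersect(unique(hits$sequence_id), names(structures))) {
      loop <- locate_anticodon_loop(seqs[[id]], structures[[id]])
      if (!is.null(loop)) {
        k <- hits$sequence_id == id
        hits$in_loop[k] <- hits$cut_position[k] >= loop$start &
          hits$cut_position[k] <= loop$end
      }
    }
  }
  rownames(hits) <- NULL
  hits
}

# Pair table of a dot-bracket string; NA for unpaired.  Errors on imbalance.
.pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pair <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) .stopf("unbalanced brackets in structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j; pair[j] <- i
    } else if (ch[i] != ".")
      .stopf("structure may contain only '(', ')' and '.'")
  }
  if (length(stack)) .stopf("unbalanced brackets in structure")
  pair
}

#' Locate the anticodon loop of a tRNA
#'
#' With a dot-bracket structure, hairpin loops (maximal unpaired runs closed
#' by a base pair) are collected in 5'->3' order; a cloverleaf exposes three
#' (D loop, anticodon loop, T loop) and the second is returned.  Structures
#' with a different number of hairpin loops yield `NULL` (unknown).  Without
#' a structure, a sequence of tRNA length (60--95 nt) gets the heuristic
#' interval 32--38 of standard tRNA numbering, flagged as such.
#'
#' @param sequence RNA/DNA sequence (used only for the structure-free
#'   heuristic and a length check).
#' @param structure Optional dot-bracket string of the same length.
#' @return `NULL`, or a list with `start`, `end` (1-based, inclusive) and
#'   `method` (`"structure"` or `"heuristic"`).
#' @export
locate_anticodon_loop <- function(sequence = NULL, structure = NULL) {
  if (!is.null(structure)) {
    structure <- as.character(structure)
    if (!is.null(sequence) && nchar(structure) != nchar(sequence))
      .stopf("sequence and structure lengths differ")
    pair <- .pair_table(structure)
    loops <- list()
    i <- 1L
    n <- length(pair)
    while (i <= n) {
      if (is.na(pair[i])) {
        j <- i
        while (j < n && is.na(pair[j + 1L])) j <- j + 1L
        # hairpin loop iff the flanking positions are paired to each other
        if (i > 1L && j < n && !is.na(pair[i - 1L]) && pair[i - 1L] == j + 1L)
          loops[[length(loops) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    if (length(loops) != 3L) return(NULL)
    ac <- loops[[2L]]
    return(list(start = ac[1], end = ac[2], method = "structure"))
  }
  if (is.null(sequence)) .stopf("need a sequence or a structure")
  len <- nchar(as.character(sequence))
  if (len < 60 || len > 95) return(NULL)
  list(start = 32L, end = 38L, method = "heuristic")
}

#' Drop candidate targets lacking a minimal cleavage motif
#'
#' Homolog candidates without a single occurrence of the minimal consensus
#' (default `G^AA`) cannot be physiological substrates and are excluded.
#'
#' @param targets Named character vector or XStringSet of sequences.
#' @param motif Minimal motif; default `consensus_motif("G^AA")`.
#' @return Character vector of retained sequence ids.
#' @export
minimal_motif_filter <- function(targets, motif = consensus_motif("G^AA")) {
  hits <- scan_motif(motif, targets)
  ids <- names(targets) %||% as.character(seq_along(targets))
  ids[ids %in% unique(hits$sequence_id)]
}

#' Summarise motif hits by biotype and loop residence
#'
#' @param hits Hit table from [scan_motif()].
#' @param biotypes Named character vector mapping `sequence_id` to a biotype
#'   (e.g. `tRNA`, `mRNA`).
#' @return A data.frame with one row per biotype: number of hit-bearing
#'   sequences, total hits, and hits with the cut inside a known loop.
#' @export
classify_targets <- function(hits, biotypes) {
  if (!nrow(hits))
    return(data.frame(biotype = character(), n_sequences = integer(),
                      n_hits = integer(), n_in_loop = integer(),
                      stringsAsFactors = FALSE))
  bt <- unname(biotypes[hits$sequence_id])
  bt[is.na(bt)] <- "unknown"
  out <- do.call(rbind, lapply(split(seq_len(nrow(hits)), bt), function(k) {
    data.frame(biotype = bt[k[1]],
               n_sequences = length(unique(hits$sequence_id[k])),
               n_hits = length(k),
               n_in_loop = sum(hits$in_loop[k] %in% TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$biotype), , drop = FALSE]
}
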