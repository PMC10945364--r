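# Local peak score, toxin/control cleavage ratio, and site calling.
#
# For position i the score is
#   (m_i + 0.5) / (sum of m over the 10 transcript-upstream positions + 10*0.5)
# where m is the replicate-median 5'-end count and 0.5 a pseudocount that
# forbids zeros.  "Upstream" is strand-aware: i-1..i-10 on '+', i+1..i+10 on
# '-'.  The cleavage ratio is the toxin score over the control score at the
# same position; positions whose ratio strictly exceeds the threshold
# (default 60) are called.

.WINDOW <- 10L
.PSEUDO <- 0.5

# Dense per-position median counts for one replicon/strand.
.dense_counts <- function(track, replicon, strand, len) {
  m <- numeric(len)
  sub <- track[track$replicon == replicon & track$strand == strand, ]
  if (nrow(sub)) {
    if (any(sub$pos < 1L | sub$pos > len))
      .stopf("track position outside replicon '%s' (length %d)", replicon, len)
    m[sub$pos] <- sub$count
  }
  m
}

# Vectorized score over a dense count vector; NA where the upstream window
# runs off the replicon end.  pseudo = 0 is the test mode with pseudocounts
# disabled (scores may then be NaN at empty windows).
.score_dense <- function(m, strand, pseudo = .PSEUDO) {
  L <- length(m)
  cs0 <- c(0, cumsum(m))
  s <- rep(NA_real_, L)
  if (strand == "+") {
    if (L >= .WINDOW + 1L) {
      i <- (.WINDOW + 1L):L
      win <- cs0[i] - cs0[i - .WINDOW]
      s[i] <- (m[i] + pseudo) / (win + .WINDOW * pseudo)
    }
  } else {
    if (L >= .WINDOW + 1L) {
      i <- 1L:(L - .WINDOW)
      win <- cs0[i + .WINDOW + 1L] - cs0[i + 1L]
      s[i] <- (m[i] + pseudo) / (win + .WINDOW * pseudo)
    }
  }
  s
}

#' Local peak score at given positions
#'
#' @param track A `summary_track` (replicate-median counts) from
#'   [summarize_replicates()].
#' @param replicon Replicon name.
#' @param strand `"+"` or `"-"`.
#' @param pos Vector of 1-based positions.
#' @param replicon_lengths Named lengths (or the genome `DNAStringSet`).
#' @param pseudo Pseudocount (default 0.5; 0 disables, for scale-invariance
#'   checks).
#' @return Numeric scores; `NA` where the 10-position upstream window leaves
#'   the replicon.
#' @examples
#' # a uniform track scores (c + 0.5) / (10c + 5) = 0.1 everywhere
#' @export
local_peak_score <- function(track, replicon, strand, pos, replicon_lengths,
                             pseudo = .PSEUDO) {
  sl <- .seqlengths_of(replicon_lengths)
  if (!replicon %in% names(sl)) .stopf("unknown replicon '%s'", replicon)
  m <- .dense_counts(track, replicon, strand, sl[[replicon]])
  s <- .score_dense(m, strand, pseudo)
  if (any(pos < 1L | pos > length(m)))
    .stopf("position outside replicon '%s'", replicon)
  s[pos]
}

#' Toxin/control cleavage ratio at given positions
#'
#' @param toxin,control `summary_track`s of the two conditions.
#' @inheritParams local_peak_score
#' @return Numeric ratios (`NA` where either score is undefined).
#' @export
cleavage_ratio <- function(toxin, control, replicon, strand, pos,
                           replicon_lengths, pseudo = .PSEUDO) {
  local_peak_score(toxin, replicon, strand, pos, replicon_lengths, pseudo) /
    local_peak_score(control, replicon, strand, pos, replicon_lengths, pseudo)
}

#' Score every defined position of a summary track
#'
#' @inheritParams local_peak_score
#' @return A data.frame (`replicon`, `strand`, `pos`, `score`) covering all
#'   positions with a full upstream window, both strands.
#' @export
score_track <- function(track, replicon_lengths, pseudo = .PSEUDO) {
  sl <- .seqlengths_of(replicon_lengths)
  out <- list()
  for (r in names(sl)) for (s in c("+", "-")) {
    sc <- .score_dense(.dense_counts(track, r, s, sl[[r]]), s, pseudo)
    def <- which(!is.na(sc))
    if (length(def))
      out[[paste(r, s)]] <- data.frame(replicon = r, strand = s, pos = def,
                                       score = sc[def],
                                       stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(replicon = character(), strand = character(),
               pos = integer(), score = numeric())
  rownames(res) <- NULL
  res
}

#' Call cleavage sites from toxin and control summary tracks
#'
#' Emits every position whose toxin/control cleavage ratio strictly exceeds
#' `threshold` (both scores defined), annotated with the overlapping feature
#' and the +/-10 nt sequence context in transcript orientation.  Each
#' position is its own site; ties do not merge.
#'
#' @param toxin,control `summary_track`s.
#' @param annotation Feature annotation [GenomicRanges::GRanges].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param threshold Calling threshold on the ratio (strict `>`; default 60).
#' @param min_median Optional floor on the toxin replicate-median count at
#'   the called position (default 0: no floor).
#' @return A data.frame of class `cleavage_calls` with columns `replicon`,
#'   `position`, `strand`, `ratio`, `toxin_score`, `control_score`,
#'   `feature`, `biotype`, `context`, sorted by replicon then position.
#' @export
call_sites <- function(toxin, control, annotation, genome, threshold = 60,
                       min_median = 0) {
  sl <- .seqlengths_of(genome)
  anno_reps <- unique(as.character(GenomicRanges::seqnames(annotation)))
  if (!all(anno_reps %in% names(sl)))
    .stopf("annotation references replicons absent from the genome: %s",
           paste(setdiff(anno_reps, names(sl)), collapse = ", "))
  out <- list()
  for (r in names(sl)) for (s in c("+", "-")) {
    mt <- .dense_counts(toxin, r, s, sl[[r]])
    mc <- .dense_counts(control, r, s, sl[[r]])
    st <- .score_dense(mt, s)
    sc <- .score_dense(mc, s)
    ratio <- st / sc
    hit <- which(!is.na(ratio) & ratio > threshold & mt >= min_median)
    if (length(hit))
      out[[paste(r, s)]] <- data.frame(
        replicon = r, position = hit, strand = s, ratio = ratio[hit],
        toxin_score = st[hit], control_score = sc[hit],
        stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out) %||%
    data.frame(replicon = character(), position = integer(),
               strand = character(), ratio = numeric(),
               toxin_score = numeric(), control_score = numeric(),
               stringsAsFactors = FALSE)
  sites <- sites[order(sites$replicon, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites <- annotate_sites(sites, annotation, genome)
  structure(sites, class = c("cleavage_calls", "data.frame"),
            threshold = threshold)
}

#' Annotate called sites with feature overlap and sequence context
#'
#' Fills `feature` (gene_id of a same-strand feature containing the position,
#' else `"intergenic"`), `biotype`, and `context`: the genomic sequence from
#' 10 nt upstream to 10 nt downstream of the position in transcript
#' orientation (reverse-complemented on `-` so the cut reads 5'->3'),
#' clipped at replicon ends.
#'
#' @param sites Data.frame with `replicon`, `position`, `strand`.
#' @param annotation Feature annotation.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return `sites` with `feature`, `biotype`, `context` columns filled.
#' @export
annotate_sites <- function(sites, annotation, genome) {
  sites$feature <- rep("intergenic", nrow(sites))
  sites$biotype <- rep(NA_character_, nrow(sites))
  sites$context <- rep(NA_character_, nrow(sites))
  if (!nrow(sites)) return(sites)
  sl <- .seqlengths_of(genome)
  if (any(sites$position < 1L | sites$position > sl[sites$replicon]))
    .stopf("site outside genome bounds")
  gr <- GenomicRanges::GRanges(sites$replicon,
                               IRanges::IRanges(sites$position, sites$position),
                               strand = sites$strand)
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits); f <- S4Vectors::subjectHits(hits)
  first <- !duplicated(q)
  sites$feature[q[first]] <- annotation$gene_id[f[first]]
  sites$biotype[q[first]] <- annotation$biotype[f[first]]
  for (i in seq_len(nrow(sites))) {
    L <- sl[[sites$replicon[i]]]
    a <- max(1L, sites$position[i] - 10L)
    b <- min(L, sites$position[i] + 10L)
    ctx <- as.character(Biostrings::subseq(genome[[sites$replicon[i]]], a, b))
    sites$context[i] <- if (sites$strand[i] == "-") .revcomp_chr(ctx) else ctx
  }
  sites
}

#' @export
print.cleavage_calls <- function(x, ...) {
  cat(sprintf("Cleavage sites: %d position(s) with ratio > %s\n",
              nrow(x), format(attr(x, "threshold"))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L), ...)
  if (nrow(x) > 20L) cat(sprintf("... and %d more\n", nrow(x) - 20L))
  invisible(x)
}

#' @export
summary.cleavage_calls <- function(object, ...) {
  df <- as.data.frame(object)
  by_bt <- if (nrow(df)) table(ifelse(is.na(df$biotype), "intergenic",
                                      df$biotype)) else table(character())
  out <- list(n_sites = nrow(df), threshold = attr(object, "threshold"),
              by_biotype = by_bt,
              ratio_range = if (nrow(df)) range(df$ratio) else c(NA, NA))
  class(out) <- "summary.cleavage_calls"
  out
}

#' @export
print.summary.cleavage_calls <- function(x, ...) {
  cat(sprintf("%d cleavage site(s) at ratio > %s\n", x$n_sites,
              format(x$threshold)))
  if (x$n_sites) {
    cat("by biotype:\n"); print(x$by_biotype)
    cat(sprintf("ratio range: %.1f .. %.1f\n",
                x$ratio_range[1], x$ratio_range[2]))
  }
  invisible(x)
}

#' Write called sites as BED6 and a full TSV
#'
#' BED scores are `min(1000, round(ratio))`; BED intervals are 0-based
#' half-open around the called position.
#'
#' @param calls A `cleavage_calls` object.
#' @param prefix Path prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_calls <- function(calls, prefix) {
  df <- as.data.frame(calls)
  bed <- data.frame(chrom = df$replicon, start = df$position - 1L,
                    end = df$position, name = df$feature,
                    score = pmin(1000L, as.integer(round(df$ratio))),
                    strand = df$strand)
  pb <- paste0(prefix, ".bed"); pt <- paste0(prefix, ".tsv")
  utils::write.table(bed, pb, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(df, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pb, pt))
}
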