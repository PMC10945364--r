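# From alignment records to strand-aware fractional per-position 5'-end count
# tracks and replicate summaries.
#
# Counting rules: reads with any mismatch in their first 30 nucleotides are
# removed; reads must agree in orientation with the annotated feature at
# their 5' end; each read contributes total mass 1, spread as 1/x over its x
# equally-best placements.

# 5'-end genomic position of each record (rightmost base for minus strand).
.five_prime_pos <- function(records) {
  ifelse(records$strand == "+", records$leftmost,
         records$leftmost + records$aligned_length - 1L)
}

#' Filter alignment records before 5'-end counting
#'
#' Removes records with at least one mismatch within the first
#' `max_clean_prefix` nucleotides of the read (counted from its 5' end), and
#' records whose strand disagrees with every annotated feature overlapping
#' their 5'-end position.  Records overlapping no feature are kept by default.
#'
#' @param records Alignment-record data.frame.
#' @param annotation [GenomicRanges::GRanges] feature annotation.
#' @param max_clean_prefix Mismatch-free prefix length required (default 30:
#'   a mismatch at 0-based offset 29 removes the read, offset 30 does not).
#' @param keep_unannotated Keep reads whose 5' end overlaps no feature.
#' @return The surviving records, unchanged.
#' @export
filter_reads <- function(records, annotation, max_clean_prefix = 30L,
                         keep_unannotated = TRUE) {
  if (!nrow(records)) return(records)
  known <- unique(as.character(GenomicRanges::seqnames(annotation)))
  bad <- !(records$replicon %in% known)
  if (any(bad))
    .stopf("record '%s' references unknown replicon '%s'",
           records$read_id[which(bad)[1]], records$replicon[which(bad)[1]])
  keep_mm <- .min_offset(records$mismatch_offsets) >= max_clean_prefix
  pos <- .five_prime_pos(records)
  gr <- GenomicRanges::GRanges(records$replicon, IRanges::IRanges(pos, pos),
                               strand = records$strand)
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  same <- as.character(GenomicRanges::strand(annotation))[
    S4Vectors::subjectHits(hits)] ==
    records$strand[S4Vectors::queryHits(hits)]
  overlapped <- tabulate(S4Vectors::queryHits(hits), nrow(records)) > 0L
  agreeing <- tabulate(S4Vectors::queryHits(hits)[same], nrow(records)) > 0L
  keep_or <- ifelse(overlapped, agreeing, keep_unannotated)
  out <- records[keep_mm & keep_or, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count fractional 5'-end read starts per position
#'
#' Each placement of a read increments the position of the read's 5' end
#' (leftmost base on `+`, rightmost on `-`) by `1/x`, `x` being the number of
#' equally-best placements, so every read contributes total mass 1 across its
#' placements.  With `multimap = "primary-only"` only primary placements are
#' counted, with weight 1.
#'
#' @param records Filtered alignment records.
#' @param multimap `"spread"` (default, 1/x per placement) or
#'   `"primary-only"`.
#' @param condition,replicate Optional labels stored as attributes.
#' @return A data.frame of class `end_count_track` with columns `replicon`,
#'   `strand`, `pos`, `count`, sorted by replicon, strand, position.
#' @export
count_five_prime_ends <- function(records, multimap = c("spread", "primary-only"),
                                  condition = NULL, replicate = NULL) {
  multimap <- match.arg(multimap)
  if (multimap == "primary-only") {
    prim <- if (!is.null(records$primary)) records$primary
            else !duplicated(records$read_id)
    records <- records[prim, , drop = FALSE]
    w <- rep(1, nrow(records))
  } else {
    w <- 1 / records$n_best_hits
  }
  if (!nrow(records)) {
    out <- data.frame(replicon = character(), strand = character(),
                      pos = integer(), count = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    pos <- .five_prime_pos(records)
    key <- paste(records$replicon, records$strand, pos, sep = "\r")
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    out <- data.frame(
      replicon = vapply(parts, `[`, character(1), 1L),
      strand = vapply(parts, `[`, character(1), 2L),
      pos = as.integer(vapply(parts, `[`, character(1), 3L)),
      count = as.numeric(agg[, 1L]),
      stringsAsFactors = FALSE)
    out <- out[order(out$replicon, out$strand, out$pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("end_count_track", "data.frame"),
            condition = condition, replicate = replicate)
}

#' Total counted mass of a track
#'
#' Equals the number of retained reads under 1/x counting.
#'
#' @param track An `end_count_track` or `summary_track`.
#' @return A number.
#' @export
track_mass <- function(track) sum(track$count)

#' Per-position replicate summary of 5'-end count tracks
#'
#' At every position present in any replicate, takes the median (default)
#' across replicates of that position's count, absent positions counting as
#' zero.  With two replicates the median equals the arithmetic mean.
#' `stat = "sum"` instead sums the replicates, the alternative reading of a
#' replicate-combination step.
#'
#' @param tracks List of `end_count_track`s of one condition (at least 2).
#' @param stat `"median"` or `"sum"`.
#' @param condition Optional label; defaults to the tracks' common condition
#'   attribute.
#' @return A data.frame of class `summary_track` with columns `replicon`,
#'   `strand`, `pos`, `count`.
#' @export
summarize_replicates <- function(tracks, stat = c("median", "sum"),
                                 condition = NULL) {
  stat <- match.arg(stat)
  if (length(tracks) < 2L) .stopf("need at least 2 replicate tracks")
  conds <- unique(unlist(lapply(tracks, attr, "condition")))
  if (length(conds) > 1L)
    .stopf("tracks mix conditions: %s", paste(conds, collapse = ", "))
  condition <- condition %||% (if (length(conds)) conds else NULL)
  keys <- lapply(tracks, function(t) paste(t$replicon, t$strand, t$pos,
                                           sep = "\r"))
  all_keys <- unique(unlist(keys))
  mat <- matrix(0, nrow = length(all_keys), ncol = length(tracks))
  for (j in seq_along(tracks))
    mat[match(keys[[j]], all_keys), j] <- tracks[[j]]$count
  val <- if (stat == "median") apply(mat, 1L, stats::median) else rowSums(mat)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(
    replicon = vapply(parts, `[`, character(1), 1L),
    strand = vapply(parts, `[`, character(1), 2L),
    pos = as.integer(vapply(parts, `[`, character(1), 3L)),
    count = val,
    stringsAsFactors = FALSE)
  out <- out[order(out$replicon, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("summary_track", "data.frame"),
            condition = condition, n_replicates = length(tracks), stat = stat)
}

#' Write a count track as bedGraph (one file per strand) plus a combined TSV
#'
#' bedGraph intervals are 0-based half-open, one per counted position.
#'
#' @param track An `end_count_track` or `summary_track`.
#' @param prefix Output path prefix; writes `<prefix>.plus.bedGraph`,
#'   `<prefix>.minus.bedGraph` and `<prefix>.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_track <- function(track, prefix) {
  paths <- character(0)
  for (s in c("+", "-")) {
    sub <- track[track$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(sub$replicon,
                                 IRanges::IRanges(sub$pos, sub$pos),
                                 score = sub$count)
    p <- sprintf("%s.%s.bedGraph", prefix, if (s == "+") "plus" else "minus")
    rtracklayer::export(gr, p, format = "bedGraph")
    paths <- c(paths, p)
  }
  p <- paste0(prefix, ".tsv")
  utils::write.table(as.data.frame(track), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p))
}

#' End-to-end ingest: alignment files to one summary track per condition
#'
#' Reads each file, applies the mismatch/orientation filter, counts fractional
#' 5' ends, and combines replicates.
#'
#' @param files Named list: `toxin` and `control`, each a character vector of
#'   alignment files (SAM or tabular dialect), one per replicate.
#' @param annotation Feature annotation [GenomicRanges::GRanges].
#' @param multimap Passed to [count_five_prime_ends()].
#' @param stat Passed to [summarize_replicates()].
#' @param ... Passed to [filter_reads()].
#' @return List with `toxin` and `control` `summary_track`s.
#' @export
ingest_alignments <- function(files, annotation,
                              multimap = c("spread", "primary-only"),
                              stat = c("median", "sum"), ...) {
  multimap <- match.arg(multimap)
  stat <- match.arg(stat)
  if (!all(c("toxin", "control") %in% names(files)))
    .stopf("'files' must name 'toxin' and 'control' replicate file sets")
  lapply(files[c("toxin", "control")], function(fs) {
    tracks <- lapply(seq_along(fs), function(i) {
      rec <- read_alignments(fs[[i]])
      rec <- filter_reads(rec, annotation, ...)
      count_five_prime_ends(rec, multimap = multimap, replicate = i,
                            condition = NULL)
    })
    summarize_replicates(tracks, stat = stat)
  })
}
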