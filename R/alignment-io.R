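# Alignment I/O: the plain tabular dialect and SAM.
#
# Tabular dialect (TSV): read_id, replicon, leftmost, strand, aligned_length,
# mismatch_offsets (comma-joined 0-based offsets from the read's 5' end,
# empty allowed), n_best_hits.  SAM carries the same information via FLAG,
# CIGAR, NM/MD and the NH (equally-best placements) tag.

.DIALECT_COLS <- c("read_id", "replicon", "leftmost", "strand",
                   "aligned_length", "mismatch_offsets", "n_best_hits")

#' Write alignment records as the tabular dialect
#'
#' @param records Alignment-record data.frame (see [simulate_reads()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_alignments_tsv <- function(records, path) {
  df <- records[, .DIALECT_COLS]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# MD tag for an all-match CIGAR with <=1 substitution at reference offset ro.
.md_string <- function(alen, ro) {
  if (is.na(ro)) as.character(alen)
  else paste0(ro, "A", alen - ro - 1L)
}

#' Write alignment records as SAM
#'
#' Emits a headered SAM file (`@SQ` lines from the genome) with all-match
#' CIGARs, `NM`/`MD` mismatch tags and the `NH` tag giving the number of
#' equally-best placements; the second placement of a multi-mapped read is
#' flagged secondary (0x100).
#'
#' @param records Alignment-record data.frame.
#' @param genome Named [Biostrings::DNAStringSet] or named lengths vector.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_alignments_sam <- function(records, genome, path) {
  sl <- .seqlengths_of(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl)), con)
  if (nrow(records)) {
    minus <- records$strand == "-"
    flag <- ifelse(minus, 16L, 0L)
    primary <- if (!is.null(records$primary)) records$primary else TRUE
    flag <- flag + ifelse(primary, 0L, 256L)
    off5 <- .min_offset(records$mismatch_offsets)
    has <- is.finite(off5)
    ro <- rep(NA_integer_, nrow(records))
    ro[has] <- ifelse(minus[has],
                      records$aligned_length[has] - 1L - off5[has],
                      off5[has])
    md <- mapply(.md_string, records$aligned_length, ro)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d\tMD:Z:%s\tNH:i:%d",
                       records$read_id, flag, records$replicon,
                       records$leftmost, records$aligned_length,
                       as.integer(has), md, records$n_best_hits), con)
  }
  invisible(path)
}

# Reference offsets (0-based) of substitutions from an MD tag, assuming an
# all-match CIGAR (no indels are ever emitted by the simulator).
.md_mismatch_ref_offsets <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  pos <- 0L
  out <- integer(0)
  for (t in toks) {
    if (grepl("^\\d+$", t)) pos <- pos + as.integer(t)
    else if (startsWith(t, "^")) pos <- pos + nchar(t) - 1L
    else { out <- c(out, pos); pos <- pos + 1L }
  }
  out
}

.cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]$", "", o))
    sum(n[sub("^\\d+", "", o) %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Read alignment records from SAM or the tabular dialect
#'
#' SAM files are converted with [Rsamtools::asBam()] and scanned; mismatch
#' offsets (0-based from the read's 5' end) are reconstructed from the `MD`
#' tag and the strand.  Records missing the `NH` tag get `n_best_hits` equal
#' to the number of times their `read_id` occurs in the file.
#'
#' @param path A `.sam` file or a dialect TSV.
#' @param format `"auto"` (by extension/content), `"sam"` or `"tsv"`.
#' @return An alignment-record data.frame (see [simulate_reads()]).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam"
      else if (startsWith(readLines(path, n = 1L), "@")) "sam" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = c(
      read_id = "character", replicon = "character", leftmost = "integer",
      strand = "character", aligned_length = "integer",
      mismatch_offsets = "character", n_best_hits = "integer"))
    missing <- setdiff(.DIALECT_COLS, names(df))
    if (length(missing))
      .stopf("tabular alignment file lacks columns: %s",
             paste(missing, collapse = ", "))
    df$mismatch_offsets[is.na(df$mismatch_offsets)] <- ""
    df$primary <- !duplicated(df$read_id) | df$n_best_hits == 1L
    return(df)
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("NM", "MD", "NH"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(b$qname)
  minus <- bitwAnd(b$flag, 16L) > 0L
  alen <- .cigar_ref_width(b$cigar)
  md <- b$tag$MD
  offsets <- character(n)
  if (!is.null(md)) {
    for (i in which(!is.na(md))) {
      ro <- .md_mismatch_ref_offsets(md[i])
      if (length(ro)) {
        o5 <- if (minus[i]) alen[i] - 1L - ro else ro
        offsets[i] <- paste(sort(o5), collapse = ",")
      }
    }
  }
  nh <- b$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  miss <- is.na(nh)
  if (any(miss)) {
    occ <- table(b$qname)
    nh[miss] <- as.integer(occ[b$qname[miss]])
  }
  data.frame(read_id = b$qname,
             replicon = as.character(b$rname),
             leftmost = b$pos,
             strand = ifelse(minus, "-", "+"),
             aligned_length = alen,
             mismatch_offsets = offsets,
             n_best_hits = as.integer(nh),
             primary = bitwAnd(b$flag, 256L) == 0L,
             stringsAsFactors = FALSE)
}

#' Write one simulated experiment to disk
#'
#' One file per condition x replicate, in either format.
#'
#' @param alignments A `simulated_alignments` object.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"sam"`.
#' @param genome Genome (required for SAM headers).
#' @return Named character vector of written paths.
#' @export
write_alignment_set <- function(alignments, dir, format = c("tsv", "sam"),
                                genome = NULL) {
  format <- match.arg(format)
  if (format == "sam" && is.null(genome))
    .stopf("SAM output needs the genome for @SQ header lines")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cond in names(alignments)) {
    for (rep in names(alignments[[cond]])) {
      p <- file.path(dir, sprintf("%s_%s.%s", cond, rep, format))
      if (format == "tsv") write_alignments_tsv(alignments[[cond]][[rep]], p)
      else write_alignments_sam(alignments[[cond]][[rep]], genome, p)
      paths[paste(cond, rep, sep = "_")] <- p
    }
  }
  paths
}
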