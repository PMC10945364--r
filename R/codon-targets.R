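# Serine-codon composition analysis: per-gene codon counts, threshold gene
# lists named after the tRNA-Ser isoacceptor whose loss they model, Venn
# intersections, replicon bias, and subset representativeness.
#
# Thresholds follow the asymmetric rare/frequent convention: a transcript is
# "rich" in a rare codon (UCU, UCA, AGU) at >= 4 occurrences, and in a
# frequent codon (UCC, UCG, AGC) at >= 12.

#' Count the six serine codons of an in-frame CDS
#'
#' Reading-frame counts (every third triplet from position 1); all other
#' codons are ignored.  `U`/`T` interchangeable on input.
#'
#' @param cds A single nucleotide sequence (character or XString), length a
#'   multiple of 3.
#' @return Named integer vector over UCU, UCC, UCA, UCG, AGU, AGC.
#' @examples
#' count_serine_codons("UCUUCAUCCAGC")
#' @export
count_serine_codons <- function(cds) {
  m <- serine_codon_matrix(cds)
  stats::setNames(as.integer(m[1L, ]), colnames(m))
}

#' In-frame serine-codon counts for many sequences
#'
#' @param cds Character vector (or XStringSet) of in-frame sequences.
#' @return Integer matrix, one row per sequence, columns UCU..AGC.
#' @export
serine_codon_matrix <- function(cds) {
  seqs <- .as_dna_chr(as.character(cds))
  bad <- nchar(seqs) %% 3L != 0L
  if (any(bad))
    .stopf("sequence length not a multiple of 3 (element %d, %d nt)",
           which(bad)[1], nchar(seqs)[which(bad)[1]])
  freq <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 3L, step = 3L)
  m <- freq[, .SER_DNA, drop = FALSE]
  colnames(m) <- .SER_RNA
  storage.mode(m) <- "integer"
  m
}

#' Assemble coding records
#'
#' One row per gene: replicon, fixation-zone read count, CDS, and its
#' serine-codon counts (computed here, so the counts are always consistent
#' with the sequence).
#'
#' @param gene_id,replicon Character vectors.
#' @param zone_reads Nonnegative normalized read counts.
#' @param cds In-frame sequences.
#' @param zone_specific Optional logical flag column.
#' @return A data.frame with the six codon-count columns appended.
#' @export
coding_records <- function(gene_id, replicon, zone_reads, cds,
                           zone_specific = TRUE) {
  if (any(zone_reads < 0)) .stopf("'zone_reads' must be nonnegative")
  counts <- serine_codon_matrix(cds)
  cbind(data.frame(gene_id = as.character(gene_id),
                   replicon = as.character(replicon),
                   zone_specific = rep_len(zone_specific, length(gene_id)),
                   zone_reads = as.numeric(zone_reads),
                   cds = as.character(cds), stringsAsFactors = FALSE),
        as.data.frame(counts))
}

#' Relative usage of the six serine codons
#'
#' Pooled over records on absolute counts (usage of a set of genes equals the
#' usage of their concatenation).
#'
#' @param records Coding-record data.frame (codon-count columns), or a
#'   character vector of sequences.
#' @return Named fractions over UCU..AGC, summing to 1.
#' @export
relative_codon_usage <- function(records) {
  counts <- if (is.data.frame(records)) {
    if (!all(.SER_RNA %in% names(records)))
      .stopf("records lack serine codon-count columns; use coding_records()")
    colSums(records[, .SER_RNA, drop = FALSE])
  } else colSums(serine_codon_matrix(records))
  tot <- sum(counts)
  if (tot == 0) .stopf("no serine codons in the input: usage undefined")
  counts / tot
}

#' Build the threshold-defined gene lists
#'
#' List definitions (over the supplied universe, typically the zone-specific
#' genes):
#' \describe{
#'   \item{ZIII+}{`zone_reads >= zone_threshold` (default 1500; the
#'     comparison operator is configurable).}
#'   \item{serT}{at least `rare_min` UCA codons.}
#'   \item{rare_serX}{at least `rare_min` UCU codons.}
#'   \item{serX}{`rare_serX` plus genes with at least `frequent_min` UCC
#'     (so `rare_serX` is always a subset of `serX`).}
#'   \item{serU}{at least `frequent_min` UCG codons.}
#'   \item{serV}{at least `rare_min` AGU or `frequent_min` AGC codons.}
#' }
#'
#' @param records Coding-record data.frame.
#' @param zone_threshold ZIII+ read-count threshold (default 1500).
#' @param zone_cmp `">="` (default) or `">"` for the ZIII+ comparison.
#' @param rare_min,frequent_min Codon minima (defaults 4 and 12).
#' @return A named list of gene-id character vectors, class `gene_list_set`.
#' @export
build_lists <- function(records, zone_threshold = 1500,
                        zone_cmp = c(">=", ">"),
                        rare_min = 4L, frequent_min = 12L) {
  zone_cmp <- match.arg(zone_cmp)
  if (zone_threshold < 0 || rare_min < 0 || frequent_min < 0)
    .stopf("thresholds must be nonnegative")
  g <- records$gene_id
  zr <- records$zone_reads
  in_zone <- if (zone_cmp == ">=") zr >= zone_threshold else zr > zone_threshold
  lists <- list(
    `ZIII+` = g[in_zone],
    serT = g[records$UCA >= rare_min],
    serX = g[records$UCU >= rare_min | records$UCC >= frequent_min],
    rare_serX = g[records$UCU >= rare_min],
    serU = g[records$UCG >= frequent_min],
    serV = g[records$AGU >= rare_min | records$AGC >= frequent_min])
  structure(lists, class = "gene_list_set",
            thresholds = c(zone = zone_threshold, rare = rare_min,
                           frequent = frequent_min))
}

#' @export
print.gene_list_set <- function(x, ...) {
  cat("<gene_list_set>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %d gene(s)\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Exact Venn regions of 2--4 gene lists
#'
#' Every subset signature gets its exclusive member set (genes in all named
#' lists and none of the others), so each gene of the union lies in exactly
#' one region and region counts sum to the union size.
#'
#' @param lists A `gene_list_set` or named list of character vectors.
#' @param select Optional names choosing 2--4 lists (default: all, must be
#'   2--4).
#' @return A list of class `venn_result`: `region_members` and
#'   `region_counts`, keyed by signatures like `"ZIII+&serT"`, plus `sets`.
#' @export
venn <- function(lists, select = NULL) {
  if (!is.null(select)) {
    missing <- setdiff(select, names(lists))
    if (length(missing)) .stopf("unknown list(s): %s",
                                paste(missing, collapse = ", "))
    lists <- lists[select]
  }
  lists <- lapply(lists, unique)
  k <- length(lists)
  if (k < 2L || k > 4L) .stopf("venn needs 2 to 4 lists, got %d", k)
  nms <- names(lists)
  universe <- unique(unlist(lists))
  members <- list()
  for (mask in seq_len(2L^k - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
    sig <- paste(nms[inset], collapse = "&")
    sel <- universe
    for (j in seq_len(k)) {
      sel <- if (inset[j]) intersect(sel, lists[[j]])
             else setdiff(sel, lists[[j]])
    }
    members[[sig]] <- sel
  }
  structure(list(region_members = members,
                 region_counts = vapply(members, length, integer(1)),
                 sets = lists),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> %d set(s), union %d gene(s)\n",
              length(x$sets), sum(x$region_counts)))
  for (sig in names(x$region_counts))
    cat(sprintf("  %-30s %d\n", sig, x$region_counts[[sig]]))
  invisible(x)
}

#' Replicon bias of a gene list
#'
#' Per replicon: total genes, list members, member fraction; plus a
#' two-sided Fisher exact test of equal member proportions for every
#' replicon pair, Bonferroni-corrected over the pairs.  The test choice is a
#' package decision (the bias itself, not a named test, is the scientific
#' claim).
#'
#' @param records Coding-record data.frame (a `replicon` column).
#' @param members Character vector of list-member gene ids (e.g. one element
#'   of [build_lists()]).
#' @return A list of class `replicon_bias`: `table` (per-replicon counts and
#'   fractions) and `tests` (pairwise statistics; zero rows with a single
#'   replicon).
#' @export
replicon_bias <- function(records, members) {
  reps <- unique(records$replicon)
  counts <- t(vapply(reps, function(r) {
    on_r <- records$replicon == r
    c(n_genes = sum(on_r),
      n_members = sum(on_r & records$gene_id %in% members))
  }, c(n_genes = 0, n_members = 0)))
  empty <- counts[, "n_genes"] == 0
  if (any(empty)) {
    warning(sprintf("replicon(s) with zero genes excluded: %s",
                    paste(reps[empty], collapse = ", ")), call. = FALSE)
    reps <- reps[!empty]; counts <- counts[!empty, , drop = FALSE]
  }
  tab <- data.frame(replicon = reps,
                    n_genes = as.integer(counts[, "n_genes"]),
                    n_members = as.integer(counts[, "n_members"]),
                    fraction = counts[, "n_members"] / counts[, "n_genes"],
                    stringsAsFactors = FALSE)
  tests <- data.frame(replicon_a = character(), replicon_b = character(),
                      odds_ratio = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE)
  if (nrow(tab) >= 2L) {
    prs <- utils::combn(seq_len(nrow(tab)), 2L)
    for (c0 in seq_len(ncol(prs))) {
      a <- prs[1, c0]; b <- prs[2, c0]
      m <- matrix(c(tab$n_members[a], tab$n_genes[a] - tab$n_members[a],
                    tab$n_members[b], tab$n_genes[b] - tab$n_members[b]),
                  nrow = 2L)
      ft <- stats::fisher.test(m, alternative = "two.sided")
      tests <- rbind(tests, data.frame(
        replicon_a = tab$replicon[a], replicon_b = tab$replicon[b],
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        p_adjusted = NA_real_, stringsAsFactors = FALSE))
    }
    tests$p_adjusted <- pmin(1, tests$p_value * nrow(tests))
  }
  structure(list(table = tab, tests = tests,
                 method = "two-sided Fisher exact, Bonferroni over pairs"),
            class = "replicon_bias")
}

#' @export
print.replicon_bias <- function(x, ...) {
  cat("Replicon bias of list membership\n")
  print(x$table, row.names = FALSE)
  if (nrow(x$tests)) {
    cat(sprintf("pairwise tests (%s):\n", x$method))
    print(x$tests, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Compare a gene subset's length and serine-codon-frequency distributions
#' to the full universe
#'
#' Two-sample Kolmogorov--Smirnov tests on protein length (codons) and on
#' per-gene serine-codon frequency (serine codons per codon), plus summary
#' quantiles.  A report, not a gate.
#'
#' @param records Coding-record data.frame (the universe).
#' @param subset_ids Gene ids of the subset (must be drawn from the
#'   universe, non-empty).
#' @return A list of class `representativeness_report` with `length_test`,
#'   `serine_test` (`htest` objects) and `quantiles`.
#' @export
subset_representativeness <- function(records, subset_ids) {
  if (!length(subset_ids)) .stopf("empty subset")
  if (!all(subset_ids %in% records$gene_id))
    .stopf("subset contains ids outside the universe")
  len <- nchar(records$cds) / 3
  serf <- rowSums(records[, .SER_RNA]) / len
  sel <- records$gene_id %in% subset_ids
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  res <- list(
    length_test = suppressWarnings(stats::ks.test(len[sel], len)),
    serine_test = suppressWarnings(stats::ks.test(serf[sel], serf)),
    quantiles = list(
      length = rbind(subset = stats::quantile(len[sel], qs),
                     universe = stats::quantile(len, qs)),
      serine_frequency = rbind(subset = stats::quantile(serf[sel], qs),
                               universe = stats::quantile(serf, qs))),
    n_subset = sum(sel), n_universe = nrow(records))
  class(res) <- "representativeness_report"
  res
}

#' @export
print.representativeness_report <- function(x, ...) {
  cat(sprintf("Subset representativeness: %d of %d genes\n",
              x$n_subset, x$n_universe))
  cat(sprintf("  length:     KS D = %.4f, p = %.3g\n",
              x$length_test$statistic, x$length_test$p.value))
  cat(sprintf("  serine frq: KS D = %.4f, p = %.3g\n",
              x$serine_test$statistic, x$serine_test$p.value))
  invisible(x)
}

#' Write gene lists and Venn regions to disk
#'
#' @param lists A `gene_list_set`.
#' @param vr Optional `venn_result`.
#' @param prefix Path prefix; writes `<prefix>.lists.tsv` (gene, list
#'   membership matrix) and, with `vr`, `<prefix>.venn.tsv` +
#'   `<prefix>.venn.json`.
#' @return Invisibly, the written paths.
#' @export
write_lists <- function(lists, prefix, vr = NULL) {
  genes <- sort(unique(unlist(lists)))
  mat <- vapply(lists, function(l) genes %in% l, logical(length(genes)))
  df <- data.frame(gene_id = genes, mat, check.names = FALSE)
  p1 <- paste0(prefix, ".lists.tsv")
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(vr)) {
    vt <- data.frame(region = names(vr$region_counts),
                     n = unname(vr$region_counts),
                     genes = vapply(vr$region_members, paste,
                                    character(1), collapse = ","))
    p2 <- paste0(prefix, ".venn.tsv")
    utils::write.table(vt, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- paste0(prefix, ".venn.json")
    jsonlite::write_json(vr$region_members, p3, auto_unbox = FALSE)
    paths <- c(paths, p2, p3)
  }
  invisible(paths)
}
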