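# Synthetic genome + annotation generator with planted cleavage motifs.
#
# The simulator emulates a small multi-replicon rhizobial genome (chromosome
# plus up to two megaplasmid-like replicons) carrying tRNA and CDS features,
# optionally with identical-sequence duplicated tRNA gene pairs (the serX/serW
# situation that exercises fractional multi-mapping downstream).

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specification for a synthetic genome
#'
#' Bundles and validates the parameters of [simulate_genome()].  Defaults
#' describe a compact three-replicon genome in the style of *Sinorhizobium
#' meliloti* (chromosome + two megaplasmids, GC-rich), scaled down so a full
#' simulate/align/call round trip runs in seconds.
#'
#' @param n_replicons Number of replicons (1--3).  Named `chr`, `pSymA`,
#'   `pSymB` in that order.
#' @param replicon_lengths Integer vector of replicon lengths in nucleotides
#'   (recycled to `n_replicons`).
#' @param n_trna_genes Total number of tRNA genes (each 85 nt).
#' @param n_duplicate_trna_pairs Number of identical-sequence tRNA gene pairs
#'   (members of a pair share a replicon and lie at least 1 kb apart).  Each
#'   pair uses two of the `n_trna_genes` slots.
#' @param n_cds_genes Number of protein-coding genes (lengths multiples of 3).
#' @param gc_content GC fraction of the random background sequence.
#' @param cds_length_range Two integers: min/max CDS length (rounded to
#'   multiples of 3).
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return A list of class `genome_spec`.
#' @seealso [simulate_genome()], [plant_motif_sites()]
#' @export
genome_spec <- function(n_replicons = 3,
                        replicon_lengths = c(20000L, 12000L, 12000L),
                        n_trna_genes = 8,
                        n_duplicate_trna_pairs = 1,
                        n_cds_genes = 20,
                        gc_content = 0.62,
                        cds_length_range = c(300L, 900L),
                        seed = 1L) {
  .assert_scalar_number(n_replicons, "n_replicons", 1, 3, integer = TRUE)
  if (!is.numeric(replicon_lengths) || any(replicon_lengths < 1000))
    .stopf("'replicon_lengths' must be numeric, all >= 1000")
  replicon_lengths <- as.integer(rep_len(replicon_lengths, n_replicons))
  .assert_scalar_number(n_trna_genes, "n_trna_genes", 0, Inf, integer = TRUE)
  .assert_scalar_number(n_duplicate_trna_pairs, "n_duplicate_trna_pairs",
                        0, Inf, integer = TRUE)
  if (2 * n_duplicate_trna_pairs > n_trna_genes)
    .stopf("need n_trna_genes >= 2 * n_duplicate_trna_pairs")
  .assert_scalar_number(n_cds_genes, "n_cds_genes", 0, Inf, integer = TRUE)
  .assert_scalar_number(gc_content, "gc_content", 0, 1)
  structure(list(
    n_replicons = as.integer(n_replicons),
    replicon_lengths = stats::setNames(
      replicon_lengths, c("chr", "pSymA", "pSymB")[seq_len(n_replicons)]),
    n_trna_genes = as.integer(n_trna_genes),
    n_duplicate_trna_pairs = as.integer(n_duplicate_trna_pairs),
    n_cds_genes = as.integer(n_cds_genes),
    gc_content = gc_content,
    cds_length_range = as.integer(cds_length_range),
    seed = as.integer(seed)
  ), class = "genome_spec")
}

.random_sequence <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.TRNA_LEN <- 85L
.MIN_GAP <- 30L
.DUP_MIN_SEP <- 1000L

#' Simulate a genome with annotated tRNA and CDS features
#'
#' Generates random replicon sequences at the requested GC content, places
#' non-overlapping tRNA and CDS features on random strands, and copies the
#' sequence of one member of each duplicated tRNA pair over its partner so the
#' two gene copies are identical (partners share a replicon and strand and are
#' separated by at least 1 kb).
#'
#' @param spec A [genome_spec()].
#' @return A list of class `synthetic_genome` with elements
#'   `genome` (a named [Biostrings::DNAStringSet]),
#'   `annotation` (a [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `biotype` in `{tRNA, CDS}`, and `dup_partner` naming the identical gene
#'   copy, `NA` otherwise), and `spec`.
#' @examples
#' sim <- simulate_genome(genome_spec(seed = 42))
#' sim$annotation
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  .with_seed(spec$seed, {
    seqs <- vapply(spec$replicon_lengths, .random_sequence,
                   character(1), gc = spec$gc_content)
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(spec$replicon_lengths)

    # feature inventory
    n_trna <- spec$n_trna_genes
    n_cds <- spec$n_cds_genes
    cds_len <- 3L * sample(
      seq(spec$cds_length_range[1] %/% 3L, spec$cds_length_range[2] %/% 3L),
      n_cds, replace = TRUE)
    feats <- data.frame(
      gene_id = c(sprintf("trna%02d", seq_len(n_trna)),
                  sprintf("cds%03d", seq_len(n_cds)))[seq_len(n_trna + n_cds)],
      biotype = rep(c("tRNA", "CDS"), c(n_trna, n_cds)),
      width = c(rep(.TRNA_LEN, n_trna), cds_len),
      stringsAsFactors = FALSE)
    if (nrow(feats) == 0L)
      .stopf("spec declares no features")

    # duplicated pairs occupy the first 2*k tRNA slots; keep each pair on one
    # replicon by assigning both members together
    n_pairs <- spec$n_duplicate_trna_pairs
    pair_of <- rep(NA_integer_, nrow(feats))
    if (n_pairs > 0)
      pair_of[seq_len(2L * n_pairs)] <- rep(seq_len(n_pairs), each = 2L)

    reps <- names(spec$replicon_lengths)
    feats$replicon <- sample(reps, nrow(feats), replace = TRUE,
                             prob = spec$replicon_lengths)
    if (n_pairs > 0) {
      for (p in seq_len(n_pairs)) {
        idx <- which(pair_of == p)
        feats$replicon[idx] <- feats$replicon[idx[1]]
      }
    }
    feats$strand <- sample(c("+", "-"), nrow(feats), replace = TRUE)
    if (n_pairs > 0)
      for (p in seq_len(n_pairs)) {
        idx <- which(pair_of == p)
        feats$strand[idx] <- feats$strand[idx[1]]
      }

    # sequential placement per replicon; duplicated partners pinned to the
    # front/back of the order so they end up >= 1 kb apart
    feats$start <- NA_integer_
    for (r in reps) {
      idx <- which(feats$replicon == r)
      if (!length(idx)) next
      ord <- sample(idx)
      for (p in unique(stats::na.omit(pair_of[idx]))) {
        pr <- which(pair_of == p)
        ord <- c(pr[1], setdiff(ord, pr), pr[2])
      }
      L <- spec$replicon_lengths[[r]]
      need <- sum(feats$width[ord]) + .MIN_GAP * (length(ord) + 1L)
      if (need > L)
        .stopf("replicon '%s' (%d nt) cannot hold %d features spanning %d nt",
               r, L, length(ord), need)
      slack <- L - need
      extra <- if (slack > 0) {
        u <- c(0, sort(stats::runif(length(ord), 0, slack)))
        round(diff(c(u, slack)))[seq_along(ord)]
      } else rep(0L, length(ord))
      pos <- .MIN_GAP + 1L
      for (k in seq_along(ord)) {
        pos <- pos + extra[k]
        feats$start[ord[k]] <- as.integer(pos)
        pos <- pos + feats$width[ord[k]] + .MIN_GAP
      }
    }
    feats$end <- feats$start + feats$width - 1L

    # copy sequence over duplicated partners -> bit-identical gene copies
    feats$dup_partner <- NA_character_
    if (n_pairs > 0) {
      for (p in seq_len(n_pairs)) {
        idx <- which(pair_of == p)
        a <- idx[1]; b <- idx[2]
        if (abs(feats$start[b] - feats$start[a]) < .DUP_MIN_SEP + .TRNA_LEN)
          .stopf("duplicated pair on '%s' closer than 1 kb; enlarge the replicon",
                 feats$replicon[a])
        src <- Biostrings::subseq(genome[[feats$replicon[a]]],
                                  feats$start[a], feats$end[a])
        Biostrings::subseq(genome[[feats$replicon[b]]],
                           feats$start[b], feats$end[b]) <- src
        feats$dup_partner[a] <- feats$gene_id[b]
        feats$dup_partner[b] <- feats$gene_id[a]
      }
    }

    anno <- GenomicRanges::GRanges(
      seqnames = feats$replicon,
      ranges = IRanges::IRanges(feats$start, feats$end),
      strand = feats$strand,
      gene_id = feats$gene_id,
      biotype = feats$biotype,
      dup_partner = feats$dup_partner,
      seqlengths = spec$replicon_lengths)
    anno <- GenomicRanges::sort(anno, ignore.strand = TRUE)

    structure(list(genome = genome, annotation = anno, spec = spec),
              class = "synthetic_genome")
  })
}

#' Extract the transcript-orientation sequence of an annotated feature
#'
#' @param sim A `synthetic_genome` (or a list with `genome` and `annotation`).
#' @param gene_id Gene identifier present in the annotation.
#' @return Character: feature sequence 5'->3' (reverse-complemented for
#'   minus-strand features), DNA alphabet.
#' @export
feature_sequence <- function(sim, gene_id) {
  anno <- sim$annotation
  i <- match(gene_id, anno$gene_id)
  if (is.na(i)) .stopf("unknown gene_id '%s'", gene_id)
  s <- as.character(Biostrings::subseq(
    sim$genome[[as.character(GenomicRanges::seqnames(anno)[i])]],
    GenomicRanges::start(anno)[i], GenomicRanges::end(anno)[i]))
  if (as.character(GenomicRanges::strand(anno)[i]) == "-") .revcomp_chr(s) else s
}

#' Write simulated genome and annotation to FASTA / GFF3
#'
#' @param sim A `synthetic_genome`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(sim, fasta, gff3) {
  Biostrings::writeXStringSet(sim$genome, fasta)
  gr <- sim$annotation
  S4Vectors::mcols(gr)$type <- S4Vectors::mcols(gr)$biotype
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$gene_id
  S4Vectors::mcols(gr)$phase <- ifelse(gr$biotype == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read an annotation GFF3 into the internal GRanges form
#'
#' Expects attributes `gene_id` and `biotype` (as written by [write_genome()];
#' `type` is used as a biotype fallback).
#'
#' @param path GFF3 file.
#' @param genome Optional genome ([Biostrings::DNAStringSet] or named lengths)
#'   used to set replicon lengths.
#' @return A [GenomicRanges::GRanges] with `gene_id` and `biotype` columns.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id)) mc$gene_id <- mc$ID
  if (is.null(mc$biotype)) mc$biotype <- as.character(mc$type)
  S4Vectors::mcols(gr) <- mc[, intersect(c("gene_id", "biotype", "dup_partner"),
                                         names(mc)), drop = FALSE]
  if (!is.null(genome)) {
    sl <- .seqlengths_of(genome)
    GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}
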