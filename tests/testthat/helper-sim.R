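# Shared fixture builders; everything is generated in code at test time.

# Alignment-record data.frame with defaults suitable for one-liners.
make_records <- function(n = 1, replicon = "chr", leftmost = 100L,
                         strand = "+", aligned_length = 150L,
                         mismatch_offsets = "", n_best_hits = 1L,
                         read_id = NULL) {
  data.frame(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    replicon = rep_len(replicon, n),
    leftmost = as.integer(rep_len(leftmost, n)),
    strand = rep_len(strand, n),
    aligned_length = as.integer(rep_len(aligned_length, n)),
    mismatch_offsets = rep_len(mismatch_offsets, n),
    n_best_hits = as.integer(rep_len(n_best_hits, n)),
    primary = TRUE,
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny annotation: one + gene at 1001-2000, one - gene at 3001-4000 on 'chr'.
tiny_annotation <- function(len = 6000L) {
  GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(1001L, 3001L), c(2000L, 4000L)),
    strand = c("+", "-"),
    gene_id = c("geneA", "geneB"), biotype = c("tRNA", "CDS"),
    dup_partner = NA_character_,
    seqlengths = c(chr = len))
}

# Build a summary_track by hand from parallel vectors.
manual_track <- function(replicon, strand, pos, count, condition = NULL) {
  df <- data.frame(replicon = replicon, strand = strand, pos = as.integer(pos),
                   count = as.numeric(count), stringsAsFactors = FALSE)
  structure(df, class = c("summary_track", "data.frame"),
            condition = condition)
}

# Literal per-position score oracle working from raw replicate tracks:
# median across replicate counts at each window position, then the formula,
# written without cumulative sums or vectorization.
oracle_score <- function(replicate_tracks, replicon, strand, i, len) {
  lookup <- function(pos) {
    vals <- vapply(replicate_tracks, function(t) {
      j <- which(t$replicon == replicon & t$strand == strand & t$pos == pos)
      if (length(j)) t$count[j] else 0
    }, numeric(1))
    stats::median(vals)
  }
  window <- if (strand == "+") (i - 1):(i - 10) else (i + 1):(i + 10)
  if (any(window < 1 | window > len)) return(NA_real_)
  s <- 0
  for (k in window) s <- s + lookup(k)
  (lookup(i) + 0.5) / (s + 10 * 0.5)
}

# Run the full ingest on a simulated alignment set (in-memory records).
summaries_from_sim <- function(aln, annotation, ...) {
  lapply(aln[c("toxin", "control")], function(reps) {
    tracks <- lapply(seq_along(reps), function(i) {
      rec <- filter_reads(reps[[i]], annotation)
      count_five_prime_ends(rec, replicate = i, ...)
    })
    summarize_replicates(tracks)
  })
}

# Small genome tuned for fast end-to-end recovery runs.
recovery_sim <- function(seed, n_sites = 20, enrichment = 300) {
  sim <- simulate_genome(genome_spec(
    n_replicons = 2, replicon_lengths = c(15000L, 15000L),
    n_trna_genes = 6, n_duplicate_trna_pairs = 1, n_cds_genes = 24,
    seed = seed))
  plant_motif_sites(sim, n_sites = n_sites, enrichment = enrichment,
                    seed = seed + 1000L)
}
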