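# Planting cleavage signatures: the consensus motif is written into the
# sequence of chosen features and the cut coordinate recorded as ground truth.

# Draw one concrete realisation of a degenerate pattern (DNA alphabet).
.realize_pattern <- function(pattern) {
  paste(vapply(strsplit(.as_dna_chr(pattern), "")[[1]], function(l) {
    b <- .iupac_bases(l)
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1)), collapse = "")
}

#' Plant cleavage-motif sites into annotated features
#'
#' Writes concrete realisations of a degenerate motif into the sequence of
#' randomly chosen features (strand-aware: reverse-complemented on `-` so the
#' transcript reads the motif 5'->3') and records, per site, the genomic
#' coordinate of the first nucleotide of the 3' cleavage product -- the
#' position at which 5'-end read starts pile up in the toxin condition.
#' When a chosen feature has an identical duplicated partner, the motif is
#' mirrored into the partner at the homologous offset so the two gene copies
#' stay identical; only the chosen copy is recorded as planted.
#'
#' @param sim A `synthetic_genome` from [simulate_genome()].
#' @param n_sites Number of sites (at most one per feature).
#' @param motif A [consensus_motif()]; default the anticodon-loop consensus
#'   `CUKG^AA`.
#' @param enrichment Fold-increase of 5'-end starts at each site in the toxin
#'   condition (scalar or length `n_sites`); must exceed 1.
#' @param seed Integer seed.
#' @param max_attempts Placement retries per site before failing.
#' @return The `synthetic_genome` with modified `genome` and a `sites`
#'   data.frame (`replicon`, `position`, `strand`, `enrichment`, `context`,
#'   `gene_id`), plus the `motif` used.
#' @examples
#' sim <- simulate_genome(genome_spec(seed = 3))
#' sim <- plant_motif_sites(sim, n_sites = 4, seed = 3)
#' sim$sites
#' @export
plant_motif_sites <- function(sim, n_sites,
                              motif = consensus_motif("CUKG^AA"),
                              enrichment = 300, seed = NULL,
                              max_attempts = 50L) {
  stopifnot(inherits(sim, "synthetic_genome"), inherits(motif, "consensus_motif"))
  .assert_scalar_number(n_sites, "n_sites", 0, Inf, integer = TRUE)
  if (any(enrichment <= 1)) .stopf("'enrichment' must exceed 1")
  enrichment <- rep_len(enrichment, max(n_sites, 1L))
  anno <- sim$annotation
  empty <- data.frame(replicon = character(), position = integer(),
                      strand = character(), enrichment = numeric(),
                      context = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (n_sites == 0L) {
    sim$sites <- empty; sim$motif <- motif
    return(sim)
  }
  if (n_sites > length(anno))
    .stopf("n_sites (%d) exceeds the number of annotated features (%d)",
           n_sites, length(anno))
  L <- nchar(motif$pattern)
  .with_seed(seed, {
    widths <- GenomicRanges::width(anno)
    eligible <- which(widths >= L + 24L)   # keep the motif off feature edges
    if (length(eligible) < n_sites)
      .stopf("only %d features are long enough for the motif", length(eligible))
    chosen <- sample(eligible, n_sites)
    sites <- empty
    used <- list()  # per replicon: genomic intervals already written
    genome <- sim$genome
    for (k in seq_len(n_sites)) {
      i <- chosen[k]
      rep_name <- as.character(GenomicRanges::seqnames(anno)[i])
      fs <- GenomicRanges::start(anno)[i]
      fe <- GenomicRanges::end(anno)[i]
      strand <- as.character(GenomicRanges::strand(anno)[i])
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        # transcript offset of the motif's first base; keep the full scoring
        # window and the +/-10 nt context inside the feature
        o <- sample(seq(12L, widths[i] - L - 10L), 1L)
        if (strand == "+") {
          gstart <- fs + o - 1L
        } else {
          gstart <- fe - (o + L - 1L) + 1L
        }
        gint <- c(gstart - 10L, gstart + L + 9L)
        clash <- any(vapply(used[[rep_name]] %||% list(), function(u)
          gint[1] <= u[2] && u[1] <= gint[2], logical(1)))
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed)
        .stopf("could not place site %d without collision after %d attempts",
               k, max_attempts)
      used[[rep_name]] <- c(used[[rep_name]] %||% list(), list(gint))
      realized <- .realize_pattern(motif$pattern)
      written <- if (strand == "+") realized else .revcomp_chr(realized)
      Biostrings::subseq(genome[[rep_name]], gstart, gstart + L - 1L) <-
        Biostrings::DNAString(written)
      # mirror into an identical duplicated partner at the homologous offset
      partner <- anno$dup_partner[i]
      if (!is.na(partner)) {
        j <- match(partner, anno$gene_id)
        pgstart <- if (strand == "+")
          GenomicRanges::start(anno)[j] + o - 1L
        else GenomicRanges::end(anno)[j] - (o + L - 1L) + 1L
        Biostrings::subseq(genome[[as.character(GenomicRanges::seqnames(anno)[j])]],
                           pgstart, pgstart + L - 1L) <-
          Biostrings::DNAString(written)
      }
      # cut position: first base 3' of the cut in transcript orientation
      cut_pos <- if (strand == "+") gstart + motif$cut_offset
                 else gstart + L - 1L - motif$cut_offset
      sites <- rbind(sites, data.frame(
        replicon = rep_name, position = as.integer(cut_pos), strand = strand,
        enrichment = enrichment[k], context = .as_rna_chr(realized),
        gene_id = anno$gene_id[i], stringsAsFactors = FALSE))
    }
    sim$genome <- genome
    sim$sites <- sites[order(sites$replicon, sites$position), , drop = FALSE]
    rownames(sim$sites) <- NULL
    sim$motif <- motif
    sim
  })
}
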