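# Simulated 5'-end sequencing: aligned single-end reads whose 5' starts are
# drawn per transcribed position, with planted cleavage positions enriched in
# the toxin condition only.

#' Parameters for the aligned-read simulator
#'
#' Defaults emulate a 1 x 150 bp single-end 5'-end library sequenced in two
#' replicates per condition.
#'
#' @param reads_per_replicate Reads per library; `NULL` (default) sizes each
#'   library as `round(sum of per-position start weights)`, so per-position
#'   background counts approximate Poisson(`background_start_rate`).
#' @param replicates_per_condition Replicates per condition (default 2).
#' @param read_length Read length in nucleotides (default 150, single-end);
#'   reads are truncated at replicon ends.
#' @param background_start_rate Mean 5'-end starts per transcribed position.
#' @param mismatch_rate Fraction of reads carrying one mismatch within their
#'   first 30 aligned bases (recorded in the alignment, for the downstream
#'   mismatch filter).
#' @param multimap_fraction Fraction of reads drawn from duplicated tRNA
#'   genes; those reads are reported at both homologous placements with
#'   `n_best_hits = 2`.  With 0, every record is unique (`n_best_hits = 1`).
#' @param capture_probability Per-site probability that a cleavage product's
#'   5' end is captured by the library chemistry (thins the enrichment).
#' @param replicate_scaling Optional per-replicate library-size factors
#'   (length `replicates_per_condition`), modelling replicate heterogeneity.
#' @param seed Integer seed; simulation is reproducible given the seed.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(reads_per_replicate = NULL,
                            replicates_per_condition = 2L,
                            read_length = 150L,
                            background_start_rate = 2,
                            mismatch_rate = 0.01,
                            multimap_fraction = 0,
                            capture_probability = 1,
                            replicate_scaling = NULL,
                            seed = 1L) {
  if (!is.null(reads_per_replicate))
    .assert_scalar_number(reads_per_replicate, "reads_per_replicate", 1, Inf,
                          integer = TRUE)
  .assert_scalar_number(replicates_per_condition, "replicates_per_condition",
                        1, Inf, integer = TRUE)
  .assert_scalar_number(read_length, "read_length", 1, Inf, integer = TRUE)
  .assert_scalar_number(background_start_rate, "background_start_rate", 0, Inf)
  .assert_scalar_number(mismatch_rate, "mismatch_rate", 0, 1)
  .assert_scalar_number(multimap_fraction, "multimap_fraction", 0, 1)
  .assert_scalar_number(capture_probability, "capture_probability", 0, 1)
  if (!is.null(replicate_scaling)) {
    if (length(replicate_scaling) != replicates_per_condition ||
        any(replicate_scaling <= 0))
      .stopf("'replicate_scaling' must be %d positive factors",
             replicates_per_condition)
  }
  structure(list(
    reads_per_replicate = reads_per_replicate,
    replicates_per_condition = as.integer(replicates_per_condition),
    read_length = as.integer(read_length),
    background_start_rate = background_start_rate,
    mismatch_rate = mismatch_rate,
    multimap_fraction = multimap_fraction,
    capture_probability = capture_probability,
    replicate_scaling = replicate_scaling,
    seed = as.integer(seed)
  ), class = "read_sim_params")
}

# Per-(replicon,strand) pool of transcribed positions with feature bookkeeping.
.position_pool <- function(anno) {
  n <- length(anno)
  if (!n) .stopf("annotation holds no features")
  w <- GenomicRanges::width(anno)
  data.frame(
    replicon = rep(as.character(GenomicRanges::seqnames(anno)), w),
    strand = rep(as.character(GenomicRanges::strand(anno)), w),
    pos = unlist(lapply(seq_len(n), function(i)
      GenomicRanges::start(anno)[i]:GenomicRanges::end(anno)[i])),
    feature = rep(seq_len(n), w),
    stringsAsFactors = FALSE)
}

#' Simulate aligned 5'-end reads for two conditions
#'
#' Draws each library's read 5'-start positions multinomially over transcribed
#' positions (all positions inside annotated features, on the feature strand).
#' Per-position weights equal `background_start_rate`; in the toxin condition
#' only, the weight at each planted site is multiplied by its enrichment
#' (times `capture_probability`).  Reads starting inside duplicated tRNA genes
#' are, when `multimap_fraction > 0`, reported at both homologous placements
#' with `n_best_hits = 2`; the weights of duplicated-gene positions are scaled
#' so those reads make up about `multimap_fraction` of each library.
#' A `mismatch_rate` fraction of reads carries one mismatch within the first
#' 30 aligned bases, recorded in `mismatch_offsets`.
#'
#' @param sim A `synthetic_genome`, typically after [plant_motif_sites()].
#' @param params A [read_sim_params()].
#' @param sites Planted-site table (default `sim$sites`); may be an empty
#'   data.frame for a null simulation.
#' @return A list of class `simulated_alignments`: one element per condition
#'   (`toxin`, `control`), each a named list of alignment-record data.frames
#'   (`R1`, `R2`, ...) with columns `read_id`, `replicon`, `leftmost`,
#'   `strand`, `aligned_length`, `mismatch_offsets` (comma-joined, empty
#'   allowed), `n_best_hits`, `primary`.
#' @export
simulate_reads <- function(sim, params = read_sim_params(), sites = sim$sites) {
  stopifnot(inherits(sim, "synthetic_genome"), inherits(params, "read_sim_params"))
  sl <- .seqlengths_of(sim$genome)
  if (any(sl == 0)) .stopf("zero-length replicon: %s",
                           paste(names(sl)[sl == 0], collapse = ", "))
  sites <- sites %||% data.frame()
  anno <- sim$annotation
  pool <- .position_pool(anno)
  key <- paste(pool$replicon, pool$strand, pool$pos)
  dup_pos <- !is.na(anno$dup_partner[pool$feature])

  base_w <- rep(params$background_start_rate, nrow(pool))
  if (params$multimap_fraction > 0) {
    if (!any(dup_pos))
      .stopf("multimap_fraction > 0 but the genome has no duplicated genes")
    f <- params$multimap_fraction
    s_dup <- sum(base_w[dup_pos]); s_oth <- sum(base_w[!dup_pos])
    if (s_oth > 0 && f < 1)
      base_w[dup_pos] <- base_w[dup_pos] * (f / (1 - f)) * (s_oth / s_dup)
  }

  site_idx <- integer(0)
  if (nrow(sites)) {
    site_idx <- match(paste(sites$replicon, sites$strand, sites$position), key)
    if (anyNA(site_idx))
      .stopf("planted site outside annotated transcribed positions")
  }
  tox_w <- base_w
  if (length(site_idx))
    tox_w[site_idx] <- tox_w[site_idx] *
      sites$enrichment * params$capture_probability
  if (any(!is.finite(tox_w)) || sum(tox_w) > .Machine$double.xmax / 2)
    .stopf("enrichment causes non-finite start weights")

  scaling <- params$replicate_scaling %||%
    rep(1, params$replicates_per_condition)

  .with_seed(params$seed, {
    one_library <- function(condition, replicate, w) {
      n <- params$reads_per_replicate %||% round(sum(w))
      n <- max(1L, as.integer(round(n * scaling[replicate])))
      idx <- sample.int(nrow(pool), n, replace = TRUE, prob = w)
      strand <- pool$strand[idx]
      s <- pool$pos[idx]
      L <- sl[pool$replicon[idx]]
      plus <- strand == "+"
      leftmost <- ifelse(plus, s, pmax(1L, s - params$read_length + 1L))
      alen <- ifelse(plus, pmin(params$read_length, L - s + 1L),
                     s - leftmost + 1L)
      has_mm <- stats::runif(n) < params$mismatch_rate
      off <- rep(NA_integer_, n)
      off[has_mm] <- floor(stats::runif(sum(has_mm)) *
                             pmin(30L, alen[has_mm]))
      rec <- data.frame(
        read_id = sprintf("%s_R%d_%06d", condition, replicate, seq_len(n)),
        replicon = pool$replicon[idx],
        leftmost = as.integer(leftmost),
        strand = strand,
        aligned_length = as.integer(alen),
        mismatch_offsets = ifelse(has_mm, as.character(off), ""),
        n_best_hits = 1L,
        primary = TRUE,
        stringsAsFactors = FALSE)
      if (params$multimap_fraction > 0) {
        mm <- dup_pos[idx]
        if (any(mm)) {
          rec$n_best_hits[mm] <- 2L
          fi <- pool$feature[idx[mm]]
          pj <- match(anno$dup_partner[fi], anno$gene_id)
          # homologous placement: same offset within the gene, same strand
          delta <- GenomicRanges::start(anno)[pj] - GenomicRanges::start(anno)[fi]
          sec <- rec[mm, , drop = FALSE]
          sec$leftmost <- sec$leftmost + as.integer(delta)
          sec$replicon <- as.character(GenomicRanges::seqnames(anno)[pj])
          sec$primary <- FALSE
          rec <- rbind(rec, sec)
        }
      }
      rownames(rec) <- NULL
      rec
    }
    reps <- sprintf("R%d", seq_len(params$replicates_per_condition))
    out <- list(
      toxin = stats::setNames(lapply(seq_along(reps), function(r)
        one_library("toxin", r, tox_w)), reps),
      control = stats::setNames(lapply(seq_along(reps), function(r)
        one_library("control", r, base_w)), reps))
    structure(out, class = "simulated_alignments", params = params)
  })
}
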