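# Synthetic zone-specific expression / codon-composition tables with known
# ground truth, emulating a nodule fixation-zone transcriptome: a gene
# universe with normalized per-zone read counts, realized coding sequences
# whose serine-codon content follows a configurable isoacceptor mix, and
# replicon labels with an optional rare-codon bias on one replicon.

.SER_RNA <- c("UCU", "UCC", "UCA", "UCG", "AGU", "AGC")
.SER_DNA <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")
.RARE_SER <- c("UCU", "UCA", "AGU")
.STOP_DNA <- c("TAA", "TAG", "TGA")

#' Specification for the synthetic zone-expression table
#'
#' Defaults are the study conditions scaled down by ~10: a universe of 900
#' genes of which 220 are zone-specific (the 8933 / 2209 analog), log-normal
#' normalized read counts, a GC-rich serine-codon usage (frequent UCC / UCG /
#' AGC, rare UCU / UCA / AGU), and a chromosome + two megaplasmid replicon
#' structure.
#'
#' @param n_genes_universe Genes in the universe.
#' @param n_zone_specific Zone-specific genes (a subset of the universe).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of the
#'   fixation-zone normalized read counts of zone-specific genes.
#' @param background_meanlog,background_sdlog Same, for the rest of the
#'   universe.
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length in
#'   codons (clamped to 60--2000).
#' @param serine_fraction Per-codon probability of a serine codon.
#' @param serine_codon_mix Named probabilities over the six serine codons
#'   (UCU, UCC, UCA, UCG, AGU, AGC); normalized to sum 1.
#' @param replicon_probs Named assignment probabilities per replicon.
#' @param rare_bias_replicon Optional replicon name whose genes get the rare
#'   serine codons (UCU, UCA, AGU) up-weighted by `rare_bias_factor`.
#' @param rare_bias_factor Multiplier on rare-codon mix weights for
#'   `rare_bias_replicon` (1 = no bias).
#' @param seed Integer seed.
#' @return A list of class `zone_expression_spec`.
#' @export
zone_expression_spec <- function(n_genes_universe = 900L,
                                 n_zone_specific = 220L,
                                 expression_meanlog = log(500),
                                 expression_sdlog = 1.2,
                                 background_meanlog = log(100),
                                 background_sdlog = 1,
                                 length_meanlog = log(300),
                                 length_sdlog = 0.35,
                                 serine_fraction = 0.06,
                                 serine_codon_mix = c(UCU = 0.08, UCC = 0.30,
                                                      UCA = 0.06, UCG = 0.26,
                                                      AGU = 0.05, AGC = 0.25),
                                 replicon_probs = c(chromosome = 0.5,
                                                    pSymA = 0.25,
                                                    pSymB = 0.25),
                                 rare_bias_replicon = NULL,
                                 rare_bias_factor = 1,
                                 seed = 1L) {
  .assert_scalar_number(n_genes_universe, "n_genes_universe", 1, Inf,
                        integer = TRUE)
  .assert_scalar_number(n_zone_specific, "n_zone_specific", 0, n_genes_universe,
                        integer = TRUE)
  .assert_scalar_number(serine_fraction, "serine_fraction", 0, 1)
  if (length(serine_codon_mix) != 6L ||
      !setequal(names(serine_codon_mix), .SER_RNA))
    .stopf("'serine_codon_mix' must name the six serine codons %s",
           paste(.SER_RNA, collapse = ", "))
  if (any(serine_codon_mix < 0) || sum(serine_codon_mix) <= 0)
    .stopf("'serine_codon_mix' probabilities must be nonnegative, not all zero")
  serine_codon_mix <- serine_codon_mix[.SER_RNA] / sum(serine_codon_mix)
  if (any(replicon_probs < 0) || sum(replicon_probs) <= 0 ||
      is.null(names(replicon_probs)))
    .stopf("'replicon_probs' must be named nonnegative probabilities")
  replicon_probs <- replicon_probs / sum(replicon_probs)
  if (!is.null(rare_bias_replicon) &&
      !rare_bias_replicon %in% names(replicon_probs))
    .stopf("'rare_bias_replicon' must be one of %s",
           paste(names(replicon_probs), collapse = ", "))
  .assert_scalar_number(rare_bias_factor, "rare_bias_factor", 0, Inf)
  structure(list(
    n_genes_universe = as.integer(n_genes_universe),
    n_zone_specific = as.integer(n_zone_specific),
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    length_meanlog = length_meanlog,
    length_sdlog = length_sdlog,
    serine_fraction = serine_fraction,
    serine_codon_mix = serine_codon_mix,
    replicon_probs = replicon_probs,
    rare_bias_replicon = rare_bias_replicon,
    rare_bias_factor = rare_bias_factor,
    seed = as.integer(seed)
  ), class = "zone_expression_spec")
}

# Ground-truth list labels from planted per-gene codon counts (never from the
# realized sequences -- the recount equivalence is what the tests check).
.truth_lists <- function(counts, zone_reads, gene_ids, zone_threshold = 1500,
                         rare_min = 4L, frequent_min = 12L) {
  list(
    `ZIII+` = gene_ids[zone_reads >= zone_threshold],
    serT = gene_ids[counts[, "UCA"] >= rare_min],
    serX = gene_ids[counts[, "UCU"] >= rare_min |
                      counts[, "UCC"] >= frequent_min],
    rare_serX = gene_ids[counts[, "UCU"] >= rare_min],
    serU = gene_ids[counts[, "UCG"] >= frequent_min],
    serV = gene_ids[counts[, "AGU"] >= rare_min |
                      counts[, "AGC"] >= frequent_min])
}

#' Simulate a zone-expression / codon-composition table
#'
#' Realizes, per gene: a replicon label, a length (codons), a normalized
#' fixation-zone read count, planted counts of the six serine codons
#' (binomial serine content split by the isoacceptor mix, with the optional
#' rare-codon replicon bias), and an in-frame CDS whose codons reproduce the
#' planted counts exactly (non-serine positions drawn from the 55 non-serine
#' sense codons, so no accidental serine codons arise).  Ground-truth
#' threshold-list labels over the zone-specific genes are retained.
#'
#' @param spec A [zone_expression_spec()].
#' @param forced Optional data.frame planting exact values into the first
#'   `nrow(forced)` zone-specific genes; recognized columns: `UCU`, `UCC`,
#'   `UCA`, `UCG`, `AGU`, `AGC`, `zone_reads` (boundary genes for threshold
#'   tests).
#' @return A list of class `zone_expression`: `records` (data.frame with
#'   `gene_id`, `replicon`, `zone_specific`, `zone_reads`, `cds` and the six
#'   codon-count columns), `truth` (named gene-id sets for lists ZIII+,
#'   serT, serX, rare_serX, serU, serV, computed over the zone-specific
#'   genes), and `spec`.
#' @export
simulate_zone_expression <- function(spec, forced = NULL) {
  stopifnot(inherits(spec, "zone_expression_spec"))
  n <- spec$n_genes_universe
  .with_seed(spec$seed, {
    gene_id <- sprintf("g%04d", seq_len(n))
    replicon <- sample(names(spec$replicon_probs), n, replace = TRUE,
                       prob = spec$replicon_probs)
    zone_specific <- seq_len(n) %in% sample.int(n, spec$n_zone_specific)
    n_codons <- pmin(2000L, pmax(60L, round(stats::rlnorm(
      n, spec$length_meanlog, spec$length_sdlog))))
    zone_reads <- round(ifelse(
      zone_specific,
      stats::rlnorm(n, spec$expression_meanlog, spec$expression_sdlog),
      stats::rlnorm(n, spec$background_meanlog, spec$background_sdlog)))

    n_ser <- stats::rbinom(n, n_codons, spec$serine_fraction)
    counts <- matrix(0L, n, 6L, dimnames = list(NULL, .SER_RNA))
    for (i in seq_len(n)) {
      mix <- spec$serine_codon_mix
      if (!is.null(spec$rare_bias_replicon) &&
          replicon[i] == spec$rare_bias_replicon) {
        mix[.RARE_SER] <- mix[.RARE_SER] * spec$rare_bias_factor
        mix <- mix / sum(mix)
      }
      if (n_ser[i] > 0)
        counts[i, ] <- stats::rmultinom(1L, n_ser[i], mix)[, 1L]
    }

    if (!is.null(forced)) {
      tgt <- which(zone_specific)[seq_len(nrow(forced))]
      if (anyNA(tgt)) .stopf("fewer zone-specific genes than forced rows")
      for (cc in intersect(colnames(forced), .SER_RNA))
        counts[tgt, cc] <- as.integer(forced[[cc]])
      if ("zone_reads" %in% colnames(forced))
        zone_reads[tgt] <- forced$zone_reads
      n_ser[tgt] <- rowSums(counts[tgt, , drop = FALSE])
      n_codons[tgt] <- pmax(n_codons[tgt], n_ser[tgt])
    }

    nonser <- setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1, paste, collapse = ""),
      c(.SER_DNA, .STOP_DNA))
    cds <- character(n)
    for (i in seq_len(n)) {
      codons <- c(rep(.SER_DNA, counts[i, ]),
                  sample(nonser, n_codons[i] - n_ser[i], replace = TRUE))
      cds[i] <- paste(sample(codons), collapse = "")
    }

    records <- data.frame(gene_id = gene_id, replicon = replicon,
                          zone_specific = zone_specific,
                          zone_reads = zone_reads, cds = cds,
                          stringsAsFactors = FALSE)
    records <- cbind(records, as.data.frame(counts))
    truth <- .truth_lists(counts[zone_specific, , drop = FALSE],
                          zone_reads[zone_specific], gene_id[zone_specific])
    structure(list(records = records, truth = truth, spec = spec),
              class = "zone_expression")
  })
}

#' Write / read the expression table (TSV)
#'
#' Columns: `gene_id`, `replicon`, `zone_specific`, `zone_reads`,
#' `cds_sequence`.  Reading recomputes the serine-codon count columns from
#' the sequences.
#'
#' @param ze A `zone_expression` (or its `records` data.frame).
#' @param path TSV path.
#' @return Invisibly `path` / the records data.frame.
#' @export
write_expression_table <- function(ze, path) {
  rec <- if (inherits(ze, "zone_expression")) ze$records else ze
  df <- data.frame(gene_id = rec$gene_id, replicon = rec$replicon,
                   zone_specific = rec$zone_specific %||% TRUE,
                   zone_reads = rec$zone_reads, cds_sequence = rec$cds,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  coding_records(df$gene_id, df$replicon, df$zone_reads, df$cds_sequence,
                 zone_specific = df$zone_specific %||% TRUE)
}

#' Write planted ground truth (sites and/or list labels) as JSON
#'
#' @param x A `synthetic_genome` (planted sites) or `zone_expression`
#'   (list labels), or a plain list.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(x, path) {
  payload <- if (inherits(x, "synthetic_genome")) list(sites = x$sites)
    else if (inherits(x, "zone_expression")) list(list_labels = x$truth)
    else x
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
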