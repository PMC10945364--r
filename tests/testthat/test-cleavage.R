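test_that("uniform tracks score exactly 0.1 at every interior position", {
  len <- 200L
  for (c0 in c(0, 1, 2, 7, 300)) {
    for (s in c("+", "-")) {
      track <- manual_track("chr", s, seq_len(len), rep(c0, len))
      interior <- 11:(len - 10)
      sc <- local_peak_score(track, "chr", s, interior, c(chr = len))
      expect_identical(sc, rep(0.1, length(interior)))
    }
  }
  # the empty track is the pseudocount-only case: 0.5 / 5 = 0.1
  empty <- manual_track(character(), character(), integer(), numeric())
  expect_identical(local_peak_score(empty, "chr", "+", 50L, c(chr = 200L)), 0.1)
})

test_that("score and ratio reproduce direct formula evaluations", {
  len <- 100L
  # m_i = 300 over a window of constant 2: (300 + .5) / (20 + 5) = 12.02
  track <- manual_track("chr", "+", seq_len(len),
                        ifelse(seq_len(len) == 50L, 300, 2))
  expect_equal(local_peak_score(track, "chr", "+", 50L, c(chr = len)), 12.02)
  # against a uniform control scoring 0.1 -> ratio 120.2
  ctrl <- manual_track("chr", "+", seq_len(len), rep(7, len))
  expect_equal(cleavage_ratio(track, ctrl, "chr", "+", 50L, c(chr = len)),
               120.2)
  # identical tracks give ratio 1 everywhere defined
  r <- cleavage_ratio(track, track, "chr", "+", 11:90, c(chr = len))
  expect_equal(r, rep(1, 80))
  # uniform tracks at different depths: both score 0.1, ratio 1 (scale-free)
  u1 <- manual_track("chr", "-", seq_len(len), rep(3, len))
  u2 <- manual_track("chr", "-", seq_len(len), rep(50, len))
  expect_equal(cleavage_ratio(u1, u2, "chr", "-", 20L, c(chr = len)), 1)
})

test_that("positions without a full upstream window are undefined", {
  len <- 40L
  track <- manual_track("chr", "+", seq_len(len), rep(1, len))
  expect_true(all(is.na(local_peak_score(track, "chr", "+", 1:10,
                                         c(chr = len)))))
  expect_false(anyNA(local_peak_score(track, "chr", "+", 11:40, c(chr = len))))
  minus <- local_peak_score(track, "chr", "-", c(30L, 31L), c(chr = len))
  expect_false(is.na(minus[1]))
  expect_true(is.na(minus[2]))
  expect_error(local_peak_score(track, "chr", "+", 41L, c(chr = len)),
               "outside replicon")
})

test_that("vectorized scores match a literal per-position oracle", {
  sim <- recovery_sim(seed = 51, n_sites = 6)
  aln <- simulate_reads(sim, read_sim_params(background_start_rate = 0.5,
                                             seed = 12L))
  reps <- lapply(seq_along(aln$toxin), function(i)
    count_five_prime_ends(filter_reads(aln$toxin[[i]], sim$annotation),
                          replicate = i))
  summary <- summarize_replicates(reps)
  sl <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  # sample positions across both strands, including score-carrying ones
  set.seed(1)
  check <- rbind(
    data.frame(replicon = summary$replicon, strand = summary$strand,
               pos = summary$pos)[sample(nrow(summary), 50), ],
    expand.grid(replicon = "chr", strand = c("+", "-"),
                pos = seq(11L, 11000L, by = 397L), stringsAsFactors = FALSE))
  for (k in seq_len(nrow(check))) {
    r <- check$replicon[k]; s <- check$strand[k]; p <- check$pos[k]
    expect_equal(local_peak_score(summary, r, s, p, sl),
                 oracle_score(reps, r, s, p, sl[[r]]),
                 tolerance = 1e-12)
  }
})

test_that("ratios are exactly scale invariant without pseudocounts", {
  len <- 120L
  set.seed(7)
  m1 <- rpois(len, 3) + 1
  m2 <- rpois(len, 3) + 1
  t1 <- manual_track("chr", "+", seq_len(len), m1)
  t2 <- manual_track("chr", "+", seq_len(len), m2)
  t1s <- manual_track("chr", "+", seq_len(len), m1 * 17)
  t2s <- manual_track("chr", "+", seq_len(len), m2 * 17)
  pos <- 11:110
  r0 <- cleavage_ratio(t1, t2, "chr", "+", pos, c(chr = len), pseudo = 0)
  rs <- cleavage_ratio(t1s, t2s, "chr", "+", pos, c(chr = len), pseudo = 0)
  expect_equal(r0, rs, tolerance = 1e-12)
})

test_that("raising a toxin count raises its ratio and weakly lowers downstream", {
  len <- 100L
  set.seed(3)
  base <- rpois(len, 2)
  ctrl <- manual_track("chr", "+", seq_len(len), rep(2, len))
  sl <- c(chr = len)
  i <- 50L
  bumped <- base; bumped[i] <- bumped[i] + 25
  t0 <- manual_track("chr", "+", seq_len(len), base)
  t1 <- manual_track("chr", "+", seq_len(len), bumped)
  expect_gt(cleavage_ratio(t1, ctrl, "chr", "+", i, sl),
            cleavage_ratio(t0, ctrl, "chr", "+", i, sl))
  down <- (i + 1L):(i + 10L)   # '+' strand: i is upstream of i+1..i+10
  expect_true(all(cleavage_ratio(t1, ctrl, "chr", "+", down, sl) <=
                    cleavage_ratio(t0, ctrl, "chr", "+", down, sl)))
})

test_that("planted sites are recovered exactly at threshold 60", {
  sim <- recovery_sim(seed = 61, n_sites = 20, enrichment = 300)
  aln <- simulate_reads(sim, read_sim_params(background_start_rate = 2,
                                             seed = 62L))
  tracks <- summaries_from_sim(aln, sim$annotation)
  calls <- call_sites(tracks$toxin, tracks$control, sim$annotation,
                      sim$genome, threshold = 60)
  truth <- paste(sim$sites$replicon, sim$sites$strand, sim$sites$position)
  found <- paste(calls$replicon, calls$strand, calls$position)
  expect_setequal(found, truth)
  expect_true(all(calls$ratio > 60))
  expect_equal(calls$ratio, calls$toxin_score / calls$control_score,
               tolerance = 1e-9)
  # an infinite threshold calls nothing
  none <- call_sites(tracks$toxin, tracks$control, sim$annotation,
                     sim$genome, threshold = Inf)
  expect_identical(nrow(none), 0L)
})

test_that("a site in one duplicated gene surfaces in both copies via 1/x", {
  # plant until a site lands in a duplicated tRNA, then simulate multimapped
  # reads: both copies must be called at homologous positions
  found <- FALSE
  for (seed in 1:20) {
    sim <- recovery_sim(seed = seed, n_sites = 8)
    anno <- sim$annotation
    dup_genes <- anno$gene_id[!is.na(anno$dup_partner)]
    hit <- sim$sites$gene_id %in% dup_genes
    if (!any(hit)) next
    found <- TRUE
    st <- sim$sites[hit, ][1, ]
    aln <- simulate_reads(sim, read_sim_params(multimap_fraction = 0.2,
                                               seed = 77L))
    tracks <- summaries_from_sim(aln, anno)
    calls <- call_sites(tracks$toxin, tracks$control, anno, sim$genome)
    i <- match(st$gene_id, anno$gene_id)
    j <- match(anno$dup_partner[i], anno$gene_id)
    homolog <- st$position +
      (GenomicRanges::start(anno)[j] - GenomicRanges::start(anno)[i])
    key <- paste(calls$replicon, calls$strand, calls$position)
    expect_true(paste(st$replicon, st$strand, st$position) %in% key)
    expect_true(paste(as.character(GenomicRanges::seqnames(anno)[j]),
                      st$strand, homolog) %in% key)
    break
  }
  expect_true(found)
})

test_that("site annotation reports features, intergenic gaps and context", {
  anno <- tiny_annotation()
  set.seed(10)
  genome <- Biostrings::DNAStringSet(c(chr = paste(
    sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")))
  sites <- data.frame(replicon = "chr", position = c(1500L, 2500L, 3500L),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  out <- annotate_sites(sites, anno, genome)
  expect_identical(out$feature, c("geneA", "intergenic", "geneB"))
  expect_identical(out$biotype, c("tRNA", NA, "CDS"))
  fwd <- as.character(Biostrings::subseq(genome[["chr"]], 3490, 3510))
  expect_identical(out$context[3], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
  expect_identical(nchar(out$context[1]), 21L)
  # a plus-strand site inside a minus-strand gene is intergenic for calling
  wrong <- annotate_sites(data.frame(replicon = "chr", position = 3500L,
                                     strand = "+", stringsAsFactors = FALSE),
                          anno, genome)
  expect_identical(wrong$feature, "intergenic")
})

test_that("calls serialize as BED6 and TSV", {
  sim <- recovery_sim(seed = 71, n_sites = 3)
  aln <- simulate_reads(sim, read_sim_params(seed = 72L))
  tracks <- summaries_from_sim(aln, sim$annotation)
  calls <- call_sites(tracks$toxin, tracks$control, sim$annotation, sim$genome)
  prefix <- tempfile()
  write_calls(calls, prefix)
  bed <- utils::read.table(paste0(prefix, ".bed"))
  expect_identical(nrow(bed), nrow(calls))
  expect_true(all(bed$V5 <= 1000L))
  expect_equal(bed$V2, calls$position - 1L)
  tsv <- utils::read.delim(paste0(prefix, ".tsv"))
  expect_identical(tsv$feature, calls$feature)
})
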