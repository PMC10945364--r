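test_that("serine codons are counted in frame", {
  expect_identical(count_serine_codons("UCUUCAUCCAGC"),
                   c(UCU = 1L, UCC = 1L, UCA = 1L, UCG = 0L,
                     AGU = 0L, AGC = 1L))
  # AUC UCA: no overlapping-frame counting, AUC is Ile
  expect_identical(count_serine_codons("AUCUCA"),
                   c(UCU = 0L, UCC = 0L, UCA = 1L, UCG = 0L,
                     AGU = 0L, AGC = 0L))
  expect_error(count_serine_codons("AUCU"), "multiple of 3")
  # random 3 kb CDS against a literal every-third-triplet oracle
  set.seed(11)
  cds <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  oracle <- table(factor(substring(cds, seq(1, 2998, 3), seq(3, 3000, 3)),
                         levels = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")))
  expect_identical(unname(count_serine_codons(cds)),
                   as.integer(unname(oracle)))
})

test_that("relative codon usage pools absolute counts", {
  rec <- coding_records(c("a", "b"), c("chr", "chr"), c(10, 10),
                        c("UCUUCCUCAUCGAGUAGC", "UCCUCCUCC"))
  u1 <- relative_codon_usage(rec[1, ])
  expect_equal(unname(u1), rep(1 / 6, 6))
  expect_equal(unname(relative_codon_usage(rec[2, ])["UCC"]), 1)
  # pooled usage equals usage of the concatenation
  pooled <- relative_codon_usage(rec)
  concat <- relative_codon_usage(paste0(rec$cds[1], rec$cds[2]))
  expect_equal(pooled, concat)
  expect_equal(sum(pooled), 1, tolerance = 1e-12)
  expect_error(relative_codon_usage("AAAGGG"), "usage undefined")
})

test_that("list thresholds implement the rare/frequent asymmetry exactly", {
  mk <- function(ucu = 0, ucc = 0, uca = 0, ucg = 0, agu = 0, agc = 0)
    paste(c(rep("UCU", ucu), rep("UCC", ucc), rep("UCA", uca),
            rep("UCG", ucg), rep("AGU", agu), rep("AGC", agc), "GCG"),
          collapse = "")
  rec <- coding_records(
    gene_id = c("ucu4", "ucu3ucc12", "ucu3ucc11", "uca4", "uca3",
                "ucg12", "agu4", "agc12", "low"),
    replicon = "chr", zone_reads = c(1500, 1499, 2000, 9, 9, 9, 9, 9, 9),
    cds = c(mk(ucu = 4), mk(ucu = 3, ucc = 12), mk(ucu = 3, ucc = 11),
            mk(uca = 4), mk(uca = 3), mk(ucg = 12), mk(agu = 4),
            mk(agc = 12), mk()))
  gl <- build_lists(rec)
  expect_setequal(gl$`ZIII+`, c("ucu4", "ucu3ucc11"))   # >= 1500 semantics
  expect_setequal(gl$rare_serX, "ucu4")
  expect_setequal(gl$serX, c("ucu4", "ucu3ucc12"))      # UCC >= 12 joins serX
  expect_setequal(gl$serT, "uca4")
  expect_setequal(gl$serU, "ucg12")
  expect_setequal(gl$serV, c("agu4", "agc12"))
  expect_true(all(gl$rare_serX %in% gl$serX))
  # strict zone comparison drops the boundary gene
  expect_false("ucu4" %in% build_lists(rec, zone_cmp = ">")$`ZIII+`)
  # raising a threshold never adds members
  for (nm in names(gl))
    expect_true(all(build_lists(rec, zone_threshold = 2000, rare_min = 6L,
                                frequent_min = 14L)[[nm]] %in% gl[[nm]]))
  expect_error(build_lists(rec, rare_min = -1), "nonnegative")
})

test_that("venn regions partition the union", {
  v <- venn(list(A = c("1", "2"), B = c("2", "3")))
  expect_identical(v$region_members$A, "1")
  expect_identical(v$region_members$B, "3")
  expect_identical(v$region_members$`A&B`, "2")
  # disjoint lists: all intersection regions empty
  v2 <- venn(list(A = c("a", "b"), B = c("c"), C = c("d")))
  expect_identical(sum(v2$region_counts[grepl("&", names(v2$region_counts))]),
                   0L)
  expect_error(venn(list(A = "x")), "2 to 4")
  # inclusion-exclusion on random lists: regions partition the union
  set.seed(9)
  pool <- sprintf("g%03d", 1:60)
  ls <- list(A = sample(pool, 25), B = sample(pool, 30), C = sample(pool, 15))
  v3 <- venn(ls)
  expect_identical(sum(v3$region_counts),
                   length(unique(unlist(ls))))
  all_members <- unlist(v3$region_members)
  expect_identical(anyDuplicated(all_members), 0L)
  for (g in unique(unlist(ls))) {
    sig <- paste(names(ls)[vapply(ls, function(l) g %in% l, logical(1))],
                 collapse = "&")
    expect_true(g %in% v3$region_members[[sig]])
  }
})

test_that("planted triple-overlap genes are recovered from the Venn", {
  # seven genes satisfy ZIII+ and (serT or serX); the relevant overlap
  # regions must recover exactly those seven
  forced <- data.frame(
    UCA = c(4L, 4L, 0L, 0L, 5L, 0L, 4L, 0L, 9L),
    UCU = c(0L, 4L, 4L, 0L, 4L, 6L, 0L, 0L, 0L),
    UCC = c(0L, 0L, 0L, 12L, 0L, 6L, 12L, 0L, 0L),
    zone_reads = c(rep(2000L, 7), 2000L, 100L))
  # genes 1-7: ZIII+ and codon-listed; gene 8: ZIII+ only; gene 9: serT only
  ze <- simulate_zone_expression(
    zone_expression_spec(n_genes_universe = 120L, n_zone_specific = 40L,
                         expression_meanlog = log(20),
                         serine_fraction = 0, seed = 13L),
    forced)
  rec <- ze$records[ze$records$zone_specific, ]
  planted <- rec$gene_id[1:7]
  gl <- build_lists(rec)
  v <- venn(gl, select = c("ZIII+", "serT", "serX"))
  hit_regions <- names(v$region_counts)[
    grepl("ZIII\\+&", names(v$region_counts))]
  recovered <- unlist(v$region_members[hit_regions])
  expect_setequal(recovered, planted)
  # and the computed lists equal the generator's ground truth exactly
  for (nm in names(ze$truth))
    expect_setequal(gl[[nm]], ze$truth[[nm]])
})

test_that("replicon bias reports counts, fractions and pairwise tests", {
  ze <- simulate_zone_expression(zone_expression_spec(seed = 17L))
  rb <- replicon_bias(ze$records, build_lists(ze$records)$rare_serX)
  expect_setequal(rb$table$replicon, c("chromosome", "pSymA", "pSymB"))
  expect_identical(nrow(rb$tests), 3L)
  expect_true(all(rb$tests$p_adjusted >= rb$tests$p_value - 1e-12))
  # single replicon: counts only, no tests
  one <- ze$records; one$replicon <- "chromosome"
  rb1 <- replicon_bias(one, build_lists(one)$rare_serX)
  expect_identical(nrow(rb1$tests), 0L)
  expect_identical(nrow(rb1$table), 1L)
})

test_that("a 5x rare-codon replicon is flagged as the biased one", {
  spec <- zone_expression_spec(rare_bias_replicon = "pSymA",
                               rare_bias_factor = 5, seed = 19L)
  ze <- simulate_zone_expression(spec)
  rb <- replicon_bias(ze$records, build_lists(ze$records)$rare_serX)
  tab <- rb$table
  expect_identical(tab$replicon[which.max(tab$fraction)], "pSymA")
  with_a <- rb$tests$replicon_a == "pSymA" | rb$tests$replicon_b == "pSymA"
  expect_true(all(rb$tests$p_adjusted[with_a] < 0.01))
})

test_that("subset representativeness flags constructed biases only", {
  ze <- simulate_zone_expression(zone_expression_spec(seed = 23L))
  rec <- ze$records
  # subset = universe: KS statistic at its null minimum
  all_ids <- rec$gene_id
  r0 <- subset_representativeness(rec, all_ids)
  expect_equal(unname(r0$length_test$statistic), 0)
  expect_equal(unname(r0$serine_test$statistic), 0)
  # shortest 10%: length comparison rejects
  short <- rec$gene_id[order(nchar(rec$cds))][1:90]
  r1 <- subset_representativeness(rec, short)
  expect_lt(r1$length_test$p.value, 0.01)
  # a random quarter: no rejection expected at this seed
  set.seed(1)
  r2 <- subset_representativeness(rec, sample(all_ids, 225))
  expect_gt(r2$length_test$p.value, 0.05)
  expect_gt(r2$serine_test$p.value, 0.05)
  expect_error(subset_representativeness(rec, character(0)), "empty subset")
  expect_error(subset_representativeness(rec, "nope"), "outside the universe")
})

test_that("lists and Venn regions serialize", {
  gl <- build_lists(coding_records(c("a", "b", "c"), "chr",
                                   c(2000, 100, 1600),
                                   c("UCAUCAUCAUCA", "GCGGCG", "UCUUCUUCUUCU")))
  v <- venn(gl, select = c("ZIII+", "serT"))
  prefix <- tempfile()
  paths <- write_lists(gl, prefix, v)
  tab <- utils::read.delim(paths[1], check.names = FALSE)
  expect_true(all(c("gene_id", "ZIII+", "serT") %in% names(tab)))
  vt <- utils::read.delim(paths[2])
  expect_identical(sum(vt$n), 2L)   # union of ZIII+ = {a, c} and serT = {a}
})
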