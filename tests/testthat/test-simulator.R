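test_that("uniform-coverage weights are proportional to spliced length", {
  ann <- make_ann(a = list(c(0, 1000)), b = list(c(2000, 4000)))
  p <- assign_expression(ann, uniform_coverage(40))
  w <- setNames(p$weight, p$transcript_id)
  expect_equal(unname(w["b"] / w["a"]), 2)
  ## fragments needed for 40x over 3000 bases of transcript at 2x100 per
  ## fragment
  expect_equal(solve_n_fragments(ann, 40, 100), ceiling(40 * 3000 / 200))
})

test_that("exponential model expresses the configured fraction", {
  ann <- make_ann(a = list(c(0, 500)), b = list(c(1000, 1500)))
  p_all <- assign_expression(ann, exponential_expression(0.01, 1), seed = 2)
  expect_true(all(p_all$weight > 0))

  ## 30,000 transcripts: observed fraction within 2/3 +- 0.01
  big <- tx_annotation(data.table(
    transcript_id = sprintf("t%05d", 1:30000),
    gene_id = sprintf("g%05d", 1:30000),
    chrom = "chr1", strand = "+",
    start = seq(0L, by = 200L, length.out = 30000),
    end = seq(100L, by = 200L, length.out = 30000)))
  p <- assign_expression(big, exponential_expression(0.01, 2 / 3), seed = 4)
  expect_lt(abs(mean(p$weight > 0) - 2 / 3), 0.01)
})

test_that("zero-rate polymorphism is a no-op with an identity map", {
  g <- generate_genome(fixture_config(chromosome_length = 5000, seed = 3))
  res <- apply_polymorphisms(g, 0, 0, seed = 1)
  expect_identical(as.character(res$genome), as.character(g))
  expect_equal(nrow(res$variants), 0L)
  expect_equal(poly_to_ref(res$map, "chr1", c(0L, 100L, 4999L)),
               c(0L, 100L, 4999L))
})

test_that("indel maps lift coordinates across insertions and deletions", {
  g <- generate_genome(fixture_config(chromosome_length = 3000, seed = 5))
  res <- apply_polymorphisms(g, 0, 0.01, seed = 9)
  v <- res$variants
  expect_gt(nrow(v), 0)
  ## every deletion shifts downstream haplotype coordinates right by len:
  ## check against the first deletion
  del <- v[type == "del"][1]
  if (nrow(del)) {
    p <- ref_to_poly(res$map, "chr1", del$ref_pos)   # snaps past deletion
    expect_equal(poly_to_ref(res$map, "chr1", p), del$ref_pos + del$len)
  }
  ## strong oracle: every aligned (M) run of the map carries identical
  ## sequence in reference and haplotype (no substitutions requested)
  ref <- as.character(g[["chr1"]])
  hap <- as.character(res$genome[["chr1"]])
  runs <- res$map$runs[type == "M"]
  for (i in seq_len(nrow(runs)))
    expect_identical(substr(hap, runs$poly_start[i] + 1,
                            runs$poly_start[i] + runs$len[i]),
                     substr(ref, runs$ref_start[i] + 1,
                            runs$ref_start[i] + runs$len[i]))
  ## haplotype length = ref + insertions - deletions
  expect_equal(nchar(hap),
               nchar(ref) + sum(v[type == "ins", len]) -
                 sum(v[type == "del", len]))
})

test_that("substitution counts fall in their binomial interval", {
  g <- generate_genome(fixture_config(chromosome_length = 1e6, seed = 7))
  res <- apply_polymorphisms(g, 0.001, 0, seed = 11)
  n_sub <- nrow(res$variants[type == "sub"])
  bounds <- qbinom(c(0.005, 0.995), 1e6, 0.001)
  expect_gte(n_sub, bounds[1])
  expect_lte(n_sub, bounds[2])
  ## substituted base always differs from the reference base
  expect_true(all(res$variants$ref_allele != res$variants$alt_allele))
})

test_that("fragment lengths obey the truncated normal law", {
  cfg <- simulation_config(seed = 1)
  set.seed(2)
  x <- draw_fragment_length(cfg, 1e5)
  expect_true(all(x >= 200 & x <= 500))

  cfg0 <- simulation_config(frag_min = 300, frag_max = 300,
                            frag_median = 300, seed = 1)
  set.seed(3)
  expect_true(all(draw_fragment_length(cfg0, 50) == 300))

  ## chi-square GOF against the closed-form truncated normal (alpha 0.01)
  br <- seq(199.5, 500.5, by = 20)
  br[length(br)] <- 500.5
  obs <- table(cut(x, br))
  pr <- diff(pnorm(br, 300, 1000 / 3)) /
    (pnorm(500.5, 300, 1000 / 3) - pnorm(199.5, 300, 1000 / 3))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("a junction-spanning mate gets an N of the intron length", {
  set.seed(1)
  g <- generate_genome(fixture_config(chromosome_length = 1000, seed = 2))
  ann <- make_ann(t1 = list(c(0, 80), c(380, 620)))   # intron 300
  p <- data.table(transcript_id = "t1", weight = 1)
  cfg <- simulation_config(frag_min = 320, frag_max = 320,
                           frag_median = 320, n_fragments = 5, seed = 3)
  sim <- simulate_dataset(g, ann, p, cfg)
  ## transcript length 320 = fragment length: every fragment covers it all;
  ## mate1 spans the junction (80 exon1 + 20 exon2), mate2 sits in exon2
  rec <- strsplit(sim$sam[!startsWith(sim$sam, "@")], "\t")
  cigars <- vapply(rec, `[`, "", 6)
  poss <- as.integer(vapply(rec, `[`, "", 4))
  expect_setequal(cigars, c("80M300N20M", "100M"))
  expect_equal(sort(unique(poss)), c(1L, 521L))
  expect_true(all(sim$truth_table$fragment_length == 320))
})

test_that("noise-free simulation reproduces the reference at every base", {
  fix <- small_fixture(n_genes = 8, seed = 33)
  tr <- small_truth(fix, n_single = 1, counts = c(`2` = 1L), seed = 35)
  sim <- simulate_dataset(fix$genome, tr, uniform_profile(tr),
                          simulation_config(seed = 37))
  expect_equal(sam_vs_genome_identity(sim$sam, fix$genome), 1.0)
  ## conservation: FASTQ pairs = truth rows = SAM pairs = n_fragments
  expect_equal(nrow(sim$reads), sim$n_fragments)
  expect_equal(nrow(sim$truth_table), sim$n_fragments)
  expect_equal(sum(!startsWith(sim$sam, "@")), 2L * sim$n_fragments)
})

test_that("sequencing errors appear at the configured base rate", {
  fix <- small_fixture(n_genes = 5, seed = 41)
  tr <- small_truth(fix, n_single = 1, counts = c(`2` = 1L), seed = 43)
  sim <- simulate_dataset(fix$genome, tr, uniform_profile(tr),
                          simulation_config(basewise_error = 0.005,
                                            seed = 47))
  acc <- sam_vs_genome_identity_bases(sim$sam, fix$genome)
  n <- acc$total
  bounds <- qbinom(c(0.005, 0.995), n, 0.005)
  expect_gte(acc$mismatch, bounds[1])
  expect_lte(acc$mismatch, bounds[2])
})

test_that("polymorphic simulation still aligns perfectly through the map", {
  ## reads carry substitutions/indels relative to the reference, but the
  ## truth CIGAR must place every non-variant base on its reference
  ## coordinate; M-block mismatch rate equals the substitution rate
  fix <- small_fixture(n_genes = 6, seed = 51)
  tr <- small_truth(fix, n_single = 1, counts = c(`2` = 1L), seed = 53)
  sim <- simulate_dataset(fix$genome, tr, uniform_profile(tr),
                          simulation_config(substitution_frequency = 0.002,
                                            indel_frequency = 0.001,
                                            seed = 59))
  acc <- sam_vs_genome_identity_bases(sim$sam, fix$genome)
  expect_lt(acc$mismatch / acc$total, 0.004)  # ~2x the substitution rate
  expect_gt(acc$mismatch, 0)
  ## some reads must carry indel operations
  cigars <- vapply(strsplit(sim$sam[!startsWith(sim$sam, "@")], "\t"),
                   `[`, "", 6)
  expect_true(any(grepl("[ID]", cigars)))
})

test_that("intron signal is pervasive but low-coverage", {
  ## introns ~10x exon length
  fix <- small_fixture(n_genes = 6, seed = 61,
                       exon_length_law = discrete_law(c(100L, 150L)),
                       intron_length_law = discrete_law(c(1000L, 1500L)),
                       chromosome_length = 4e5)
  tr <- small_truth(fix, n_single = 2, counts = c(`2` = 1L), seed = 63)
  sim <- simulate_dataset(fix$genome, tr, uniform_profile(tr),
                          simulation_config(intron_frequency = 0.3,
                                            seed = 67))
  tbl <- sim$truth_table
  expect_gt(sum(tbl$intron_signal), 0)
  tt <- transcripts_tbl(tr$annotation)
  gene_len <- tt[, .(glen = max(tx_end) - min(tx_start),
                     elen = sum(length)), by = gene_id]
  intr <- tbl[intron_signal == TRUE, .N, by = gene_id]
  intr <- merge(intr, gene_len, by = "gene_id")
  cov_intron <- mean(intr$N * 200 / intr$glen)
  cov_exon <- mean(sim$true_quant$coverage[sim$true_quant$fragments > 0])
  expect_lt(cov_intron, cov_exon)
})

test_that("true FPKM follows the exonic-fragment formula", {
  tbl <- data.table(read_id = paste0("seq.", 1:100),
                    transcript_id = "t1", gene_id = "g1",
                    intron_signal = FALSE)
  ann <- make_ann(t1 = list(c(0, 1000)))
  q <- true_fpkm(tbl, ann, read_length = 100)
  expect_equal(q$fragments, 100L)
  expect_equal(q$fpkm, 100 / ((1000 / 1e3) * (100 / 1e6)))  # 1e6
  expect_equal(q$coverage, 100 * 200 / 1000)

  ## zero-count transcripts get FPKM 0 and counts are conserved
  ann2 <- make_ann(t1 = list(c(0, 1000)), t2 = list(c(2000, 3000)))
  q2 <- true_fpkm(tbl, ann2, read_length = 100)
  expect_equal(q2[transcript_id == "t2", fpkm], 0)
  expect_equal(sum(q2$fragments), nrow(tbl))
})

test_that("simulated files land on disk and are seed-reproducible", {
  fix <- small_fixture(n_genes = 5, seed = 71)
  tr <- small_truth(fix, n_single = 1, counts = c(`2` = 1L), seed = 73)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- simulation_config(n_fragments = 200, seed = 77)
  simulate_dataset(fix$genome, tr, uniform_profile(tr), cfg, out_dir = d1)
  simulate_dataset(fix$genome, tr, uniform_profile(tr), cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  fq <- readLines(file.path(d1, "sim_1.fastq"))
  expect_equal(length(fq), 4L * 200L)
  expect_match(fq[1], "^@seq\\.1/1$")
})
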