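two_exon <- function(s, gap = 200, w = 100) {
  list(c(s, s + w), c(s + w + gap, s + 2 * w + gap))
}

test_that("terminal extensions stay TP; junction shifts become FP", {
  truth <- make_ann(t1 = list(c(100, 200), c(300, 400), c(500, 600)))
  ## both terminal exons extended by 50: same junction chain
  pred_ext <- make_ann(p1 = list(c(50, 200), c(300, 400), c(500, 650)))
  cls <- classify_predictions(pred_ext, truth)
  expect_equal(cls$predictions$class_, "TP")
  expect_equal(cls$predictions$matched_truth, "t1")

  ## one junction moved by 3: false positive
  pred_shift <- make_ann(p1 = list(c(100, 203), c(300, 400), c(500, 600)))
  cls2 <- classify_predictions(pred_shift, truth)
  expect_equal(cls2$predictions$class_, "FP")
  pr <- precision_recall(cls2)
  expect_equal(pr$FP, 1)
  expect_equal(pr$FN, 1)
})

test_that("matching is strand-aware, '.' matching either strand", {
  truth <- make_ann(t1 = list(c(100, 200), c(300, 400)), strand = "+")
  wrong <- make_ann(p1 = list(c(100, 200), c(300, 400)), strand = "-")
  expect_equal(classify_predictions(wrong, truth)$predictions$class_, "FP")
  dot <- make_ann(p1 = list(c(100, 200), c(300, 400)), strand = ".")
  expect_equal(classify_predictions(dot, truth)$predictions$class_, "TP")
})

test_that("single-exon forms match by >= 50% reciprocal overlap", {
  truth <- make_ann(t1 = list(c(1000, 2000)))
  hit <- make_ann(p1 = list(c(1400, 2400)))     # 600/1000 both ways
  miss <- make_ann(p1 = list(c(1600, 2600)))    # 400/1000
  expect_equal(classify_predictions(hit, truth)$predictions$class_, "TP")
  expect_equal(classify_predictions(miss, truth)$predictions$class_, "FP")
  ## a single-exon prediction never matches a multi-exon truth
  truth2 <- make_ann(t1 = list(c(1000, 1400), c(1600, 2000)))
  one <- make_ann(p1 = list(c(1000, 2000)))
  expect_equal(classify_predictions(one, truth2)$predictions$class_, "FP")
})

test_that("duplicate predictions of one truth form are deduplicated", {
  truth <- make_ann(t1 = list(c(100, 200), c(300, 400)))
  preds <- make_ann(p1 = list(c(100, 200), c(300, 400)),
                    p2 = list(c(90, 200), c(300, 410)))
  cls <- classify_predictions(preds, truth)
  expect_setequal(cls$predictions$class_, c("TP", "DUP"))
  pr <- precision_recall(cls)
  expect_equal(pr$TP, 1)
  expect_equal(pr$FP, 0)
  expect_equal(pr$precision, 1)     # invariant under duplication
  expect_equal(cls$n_duplicates, 1L)
})

test_that("fast classification agrees with the exhaustive matcher", {
  for (seed in 1:40) {
    truth <- random_instance(sample(3:20, 1), seed)
    preds <- perturb_instance(truth, seed + 1000)
    if (is.null(preds)) next
    cls <- precision_recall(classify_predictions(preds, truth))
    ref <- brute_match(preds, truth)
    expect_equal(cls$TP, ref$TP, info = paste("seed", seed))
    expect_equal(cls$FP, ref$FP, info = paste("seed", seed))
    expect_equal(cls$FN, ref$FN, info = paste("seed", seed))
  }
})

test_that("precision/recall arithmetic and degenerate strata", {
  ## TP=2 FP=1 FN=2 -> precision 2/3, recall 1/2
  truth <- make_ann(t1 = two_exon(0), t2 = two_exon(1000),
                    t3 = two_exon(2000), t4 = two_exon(3000))
  preds <- make_ann(p1 = two_exon(0), p2 = two_exon(1000),
                    p3 = two_exon(5000))
  pr <- precision_recall(classify_predictions(preds, truth))
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 1 / 2)

  ## no predictions at all: precision undefined, recall 0
  empty <- tx_annotation(data.table(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer()))
  pr0 <- precision_recall(classify_predictions(empty, truth))
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)
})

test_that("comfort-zone flag flips exactly at its floors", {
  mk <- function(n_truth, n_hit, n_fp) {
    truth <- do.call(make_ann, setNames(
      lapply(seq_len(n_truth) - 1L, function(i) two_exon(i * 1000)),
      paste0("t", seq_len(n_truth))))
    ex <- c(lapply(seq_len(n_hit) - 1L, function(i) two_exon(i * 1000)),
            lapply(seq_len(n_fp), function(i) two_exon(50000 + i * 1000)))
    preds <- do.call(make_ann, setNames(ex, paste0("p", seq_along(ex))))
    precision_recall(classify_predictions(preds, truth))
  }
  ## recall exactly 0.25 (1 of 4), precision 1: inside the zone
  expect_true(mk(4, 1, 0)$comfort_zone)
  ## recall 0.2 (1 of 5): outside
  expect_false(mk(5, 1, 0)$comfort_zone)
  ## precision exactly 2/3 (2 TP, 1 FP), recall 1: inside
  expect_true(mk(2, 2, 1)$comfort_zone)
  ## precision 0.6 (3 TP, 2 FP), recall 1: outside
  expect_false(mk(3, 3, 2)$comfort_zone)
})

test_that("coverage strata follow the half-open bin convention", {
  q <- data.table(transcript_id = paste0("t", 1:5),
                  coverage = c(0.5, 1, 10, 99.9, 1e6))
  b <- stratify_by_coverage(q)
  expect_equal(b$cov_bin, c(NA, "low", "medium", "medium", "high"))
})

test_that("quantification agreement counts on/off errors and outliers", {
  tq <- data.table(transcript_id = paste0("t", 1:3), fpkm = c(0, 5, 5))
  iq <- data.table(transcript_id = paste0("t", 1:3), fpkm = c(2, 0, 5))
  q <- quantification_agreement(tq, iq)
  expect_equal(q$n_false_on, 1L)
  expect_equal(q$n_false_off, 1L)
  expect_equal(q$n_both_positive, 1L)
  expect_true(is.na(q$pearson_r))               # < 3 surviving pairs

  ## identity and affine scaling both give r = 1, no on/off errors
  tq2 <- data.table(transcript_id = paste0("t", 1:6),
                    fpkm = c(1, 2, 4, 8, 16, 32))
  q_id <- quantification_agreement(tq2, tq2)
  expect_equal(q_id$pearson_r, 1)
  expect_equal(q_id$n_false_on + q_id$n_false_off, 0L)
  iq2 <- copy(tq2)[, fpkm := 2 * fpkm]
  expect_equal(quantification_agreement(tq2, iq2)$pearson_r, 1)

  ## classification identity: on + off + both_pos + both_zero = union size
  tq3 <- data.table(transcript_id = paste0("t", 1:4), fpkm = c(0, 0, 3, 9))
  iq3 <- data.table(transcript_id = paste0("t", c(1, 3, 5)),
                    fpkm = c(4, 6, 0))
  q3 <- quantification_agreement(tq3, iq3)
  expect_equal(q3$n_false_on + q3$n_false_off + q3$n_both_positive +
                 q3$n_both_zero, 5L)

  ## extreme outliers are removed and counted
  tq4 <- data.table(transcript_id = paste0("t", 1:4),
                    fpkm = c(1, 2, 3, 4))
  iq4 <- data.table(transcript_id = paste0("t", 1:4),
                    fpkm = c(1, 2, 3, 4000))    # ratio 1000 > 10^2
  q4 <- quantification_agreement(tq4, iq4)
  expect_equal(q4$n_outliers_removed, 1L)
  expect_equal(q4$pearson_r, 1)
})

test_that("evaluation reports are deterministic and stratified", {
  fix <- small_fixture(n_genes = 10, seed = 101)
  tr <- small_truth(fix, n_single = 2, counts = c(`2` = 1L), seed = 103)
  sim <- simulate_dataset(fix$genome, tr, uniform_profile(tr),
                          simulation_config(seed = 107))
  cls <- classify_predictions(tr$annotation, tr, sim$true_quant)
  rep <- evaluation_report(cls, quantification_agreement(sim$true_quant,
                                                         sim$true_quant))
  expect_true("overall" %in% rep$strata$stratum)
  expect_true(all(rep$strata$precision == 1))
  expect_true(all(rep$strata$recall == 1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, f1)
  write_report(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".summary.txt")))
  expect_gt(length(readLines(f1)), 1)
})
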