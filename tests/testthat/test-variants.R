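base5 <- function() {
  ann <- make_ann(b = list(c(100, 200), c(300, 400), c(500, 600),
                           c(700, 800), c(900, 1000)))
  select_base_transcripts(ann)[["b"]]
}

chain_of <- function(v) paste(v$exons[-nrow(v$exons), 2],
                              v$exons[-1, 1], collapse = ";")

test_that("base-transcript selection filters by exon count and length", {
  ann <- make_ann(short = list(c(0, 150)),                    # 150 b
                  few = list(c(300, 400), c(500, 600), c(700, 800),
                             c(900, 1000)),                   # 4 exons
                  ok = list(c(2000, 2100), c(2200, 2300), c(2400, 2500),
                            c(2600, 2700), c(2800, 2900)))
  expect_equal(names(select_base_transcripts(ann, 5, 200)), "ok")
  expect_false("short" %in% names(select_base_transcripts(ann, 1, 200)))
  ## no-op filter keeps everything (container order: chrom, transcript id)
  expect_setequal(names(select_base_transcripts(ann, 1, 1)),
                  c("short", "few", "ok"))
})

test_that("exon skipping removes 1-2 internal exons, keeps terminals", {
  b <- base5()
  ## enumerate all admissible outcomes: internal exons {2,3,4}, k in {1,2}
  drop_sets <- c(lapply(2:4, identity),
                 combn(2:4, 2, simplify = FALSE))
  admissible <- lapply(drop_sets, function(d) b$exons[-d, , drop = FALSE])
  set.seed(42)
  for (i in 1:50) {
    v <- exon_skipping_variant(b)
    expect_true(any(vapply(admissible, identical, TRUE, y = v$exons)))
    expect_identical(v$exons[1, ], b$exons[1, ])
    expect_identical(v$exons[nrow(v$exons), ], b$exons[5, ])
    expect_false(identical(chain_of(v), chain_of(b)))
  }
  two <- make_ann(t = list(c(0, 10), c(20, 30)))
  expect_error(exon_skipping_variant(select_base_transcripts(two)[["t"]]),
               "3 exons")
})

test_that("truncation yields contiguous subsequences, down to one exon", {
  b <- base5()
  set.seed(7)
  seen_single <- FALSE
  for (i in 1:200) {
    v <- truncation_variant(b)
    n <- nrow(v$exons)
    expect_true(n >= 1 && n <= 4)
    ## contiguous subsequence of the base
    first <- which(b$exons[, 1] == v$exons[1, 1])
    expect_identical(v$exons,
                     b$exons[first:(first + n - 1), , drop = FALSE])
    if (n == 1) seen_single <- TRUE
  }
  expect_true(seen_single)   # a+b = n-1 leaves a single exon, empty chain
  one <- make_ann(t = list(c(0, 100)))
  expect_error(truncation_variant(select_base_transcripts(one)[["t"]]),
               "2 exons")
})

test_that("splice shifts move exactly one internal boundary by a legal delta", {
  ## roomy base: offsets up to 9 can never violate positivity
  ann <- make_ann(b = list(c(0, 1000), c(2000, 3000), c(4000, 5000)))
  b <- select_base_transcripts(ann)[["b"]]
  set.seed(11)
  deltas <- integer(10000)
  one_boundary <- legal_delta <- terminals_kept <- logical(10000)
  for (i in 1:10000) {
    v <- splice_shift_variant(b)
    diff <- v$exons - b$exons
    changed <- which(diff != 0)
    one_boundary[i] <- length(changed) == 1L
    d <- if (length(changed) == 1L) diff[changed] else NA_integer_
    legal_delta[i] <- isTRUE(abs(d) %in% c(1, 2, 3, 6, 9))
    terminals_kept[i] <- v$exons[1, 1] == b$exons[1, 1] &&
      v$exons[3, 2] == b$exons[3, 2]
    deltas[i] <- d
  }
  expect_true(all(one_boundary))
  expect_true(all(legal_delta))
  expect_true(all(terminals_kept))
  ## "mostly multiples of three": 0.9 +- 0.01 over 10,000 seeded draws
  expect_lt(abs(mean(deltas %% 3 == 0) - 0.9), 0.01)
})

test_that("shifts violating intron or exon positivity are redrawn", {
  ## tight base: intron of length 1 and short exons force rejections, but
  ## admissible shifts exist, so the call must always succeed legally
  ann <- make_ann(b = list(c(0, 100), c(101, 130), c(200, 300)))
  b <- select_base_transcripts(ann)[["b"]]
  set.seed(3)
  for (i in 1:200) {
    v <- splice_shift_variant(b)
    e <- v$exons
    expect_true(all(e[, 2] > e[, 1]))
    expect_true(all(e[-1, 1] > e[-nrow(e), 2]))
  }
})

test_that("t1 truth build delivers the designed gene and form counts", {
  fix <- small_fixture(n_genes = 30, seed = 13, chromosome_length = 8e5)
  des <- t1_design(n_single_form_genes = 3,
                   per_category_counts = c(`2` = 2L, `3` = 2L),
                   seed = 17)
  tr <- build_t1_truth(fix$ann, des)
  expect_equal(nrow(tr$gene_info), 3 + 3 * 4)
  tt <- transcripts_tbl(tr$annotation)
  expect_equal(nrow(tt), 3 + 3 * (2 * 2 + 2 * 3))
  ## per-gene form counts match the labels
  got <- tt[, .N, by = gene_id]
  m <- merge(got, tr$gene_info, by = "gene_id")
  expect_equal(m$N, m$n_forms)
  ## determinism
  tr2 <- build_t1_truth(fix$ann, des)
  expect_identical(as.data.frame(tr$annotation),
                   as.data.frame(tr2$annotation))
})

test_that("variants in a gene are category-pure and pairwise distinct", {
  fix <- small_fixture(n_genes = 40, seed = 23, chromosome_length = 1e6)
  tr <- build_t1_truth(fix$ann, t1_design(
    n_single_form_genes = 2,
    per_category_counts = c(`3` = 3L, `5` = 2L), seed = 29))
  tt <- transcripts_tbl(tr$annotation)
  base_of <- tt[, .SD[1], by = gene_id]        # first form is the base
  for (g in tr$gene_info$gene_id) {
    cat_g <- tr$gene_info[gene_id == g, category]
    forms <- tt[gene_id == g]
    ## pairwise distinct on chain + terminals
    expect_equal(anyDuplicated(
      paste(forms$chain, forms$tx_start, forms$tx_end)), 0)
    if (cat_g == "SINGLE_FORM") next
    base_ex <- as.data.table(tr$annotation)[
      transcript_id == base_of[gene_id == g, transcript_id]][order(start)]
    for (tid in forms$transcript_id[-1]) {
      ex <- as.data.table(tr$annotation)[transcript_id == tid][order(start)]
      key_b <- paste(base_ex$start, base_ex$end)
      key_v <- paste(ex$start, ex$end)
      if (cat_g == "EXON_SKIPPING") {
        ## exon subset with both terminals kept
        expect_true(all(key_v %in% key_b))
        expect_equal(key_v[1], key_b[1])
        expect_equal(key_v[length(key_v)], key_b[length(key_b)])
      } else if (cat_g == "TRUNCATION") {
        ## contiguous subsequence
        first <- match(key_v[1], key_b)
        expect_false(is.na(first))
        expect_equal(key_v, key_b[first:(first + length(key_v) - 1)])
      } else {
        ## same exon count, only internal boundary deltas
        expect_equal(nrow(ex), nrow(base_ex))
        expect_equal(ex$start[1], base_ex$start[1])
        expect_equal(ex$end[nrow(ex)], base_ex$end[nrow(base_ex)])
      }
    }
  }
})

test_that("a no-op design returns the first qualifying genes unchanged", {
  fix <- small_fixture(n_genes = 12, seed = 19)
  des <- t1_design(n_single_form_genes = 10,
                   per_category_counts = c(`2` = 0L),
                   min_exons_single = 5, seed = 1)
  tr <- build_t1_truth(fix$ann, des)
  tt0 <- transcripts_tbl(fix$ann)
  keep <- tt0[n_exons >= 5 & length >= 200][1:10, transcript_id]
  got <- as.data.frame(as.data.table(tr$annotation)[order(transcript_id, start)])
  want <- as.data.frame(as.data.table(fix$ann)[transcript_id %in% keep][
    order(transcript_id, start)])
  expect_equal(got, want)
})
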