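## Shared fixture builders: everything is generated in code at test time.

suppressMessages(library(data.table))
options(txbench.verbose = FALSE)

## a transcript table built directly from exon coordinate pairs
make_ann <- function(..., chrom = "chr1", strand = "+", gene = NULL) {
  txs <- list(...)
  parts <- lapply(seq_along(txs), function(i) {
    ex <- txs[[i]]
    data.table(transcript_id = names(txs)[i] %||% paste0("t", i),
               gene_id = if (is.null(gene)) paste0("g", i) else gene,
               chrom = chrom, strand = strand,
               start = vapply(ex, `[`, 0, 1),
               end = vapply(ex, `[`, 0, 2))
  })
  tx_annotation(rbindlist(parts))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## small genome + single-isoform annotation
small_fixture <- function(n_genes = 12, seed = 3,
                          chromosome_length = 3e5, ...) {
  cfg <- fixture_config(n_genes = n_genes,
                        chromosome_length = chromosome_length,
                        seed = seed, ...)
  g <- generate_genome(cfg)
  list(genome = g, ann = generate_annotation(g, cfg), cfg = cfg)
}

## small multi-form truth set
small_truth <- function(fix = small_fixture(), n_single = 2,
                        counts = c(`2` = 2L, `3` = 1L), seed = 5) {
  build_t1_truth(fix$ann,
                 t1_design(n_single_form_genes = n_single,
                           per_category_counts = counts, seed = seed))
}

uniform_profile <- function(truth, target = 40) {
  p <- assign_expression(truth, uniform_coverage(target))
  attr(p, "model") <- uniform_coverage(target)
  p
}

## oracle: fraction of truth-SAM M-operation bases whose SEQ letter equals
## the reference base at the stated coordinate (independent of the
## simulator's own coordinate bookkeeping)
sam_vs_genome_identity <- function(sam_lines, genome) {
  refs <- lapply(setNames(seq_along(genome), names(genome)),
                 function(i) as.character(genome[[i]]))
  recs <- sam_lines[!startsWith(sam_lines, "@")]
  good <- 0; total <- 0
  for (r in strsplit(recs, "\t", fixed = TRUE)) {
    refstr <- refs[[r[3]]]
    pos <- as.integer(r[4]); sq <- r[10]
    ops <- regmatches(r[6], gregexpr("[0-9]+[A-Z]", r[6]))[[1]]
    qcur <- 0L; rcur <- pos - 1L
    for (o in ops) {
      L <- as.integer(substr(o, 1, nchar(o) - 1))
      ty <- substr(o, nchar(o), nchar(o))
      if (ty == "M") {
        total <- total + L
        if (substr(sq, qcur + 1L, qcur + L) ==
            substr(refstr, rcur + 1L, rcur + L)) good <- good + L
        qcur <- qcur + L; rcur <- rcur + L
      } else if (ty %in% c("I", "S")) qcur <- qcur + L
      else rcur <- rcur + L
    }
  }
  good / total
}

## as above, but returning counts of mismatching M bases (for error-rate
## and polymorphism checks)
sam_vs_genome_identity_bases <- function(sam_lines, genome) {
  refs <- lapply(setNames(seq_along(genome), names(genome)),
                 function(i) as.character(genome[[i]]))
  recs <- sam_lines[!startsWith(sam_lines, "@")]
  mism <- 0; total <- 0
  for (r in strsplit(recs, "\t", fixed = TRUE)) {
    refstr <- refs[[r[3]]]
    pos <- as.integer(r[4]); sq <- r[10]
    ops <- regmatches(r[6], gregexpr("[0-9]+[A-Z]", r[6]))[[1]]
    qcur <- 0L; rcur <- pos - 1L
    for (o in ops) {
      L <- as.integer(substr(o, 1, nchar(o) - 1))
      ty <- substr(o, nchar(o), nchar(o))
      if (ty == "M") {
        a <- strsplit(substr(sq, qcur + 1L, qcur + L), "")[[1]]
        b <- strsplit(substr(refstr, rcur + 1L, rcur + L), "")[[1]]
        mism <- mism + sum(a != b)
        total <- total + L
        qcur <- qcur + L; rcur <- rcur + L
      } else if (ty %in% c("I", "S")) qcur <- qcur + L
      else rcur <- rcur + L
    }
  }
  list(mismatch = mism, total = total)
}

## brute-force transcript matcher: compares every predicted/truth pair
## exhaustively; the reference implementation the fast path must agree with
brute_match <- function(predicted, truth_ann, min_ov = 0.5) {
  pt <- transcripts_tbl(predicted)
  tt <- transcripts_tbl(truth_ann)
  pair_match <- function(p, t) {
    if (p$chrom != t$chrom) return(FALSE)
    if (p$strand != "." && t$strand != "." && p$strand != t$strand)
      return(FALSE)
    if (p$n_exons > 1L || t$n_exons > 1L)
      return(p$n_exons > 1L && t$n_exons > 1L && p$chain == t$chain)
    ov <- min(p$tx_end, t$tx_end) - max(p$tx_start, t$tx_start)
    lp <- p$tx_end - p$tx_start; lt <- t$tx_end - t$tx_start
    ov >= min_ov * lp && ov >= min_ov * lt
  }
  matched_truth <- rep(FALSE, nrow(tt))
  pred_tp <- rep(FALSE, nrow(pt))
  for (i in seq_len(nrow(pt))) {
    for (j in seq_len(nrow(tt))) {
      if (pair_match(pt[i], tt[j])) {
        pred_tp[i] <- TRUE
        matched_truth[j] <- TRUE
      }
    }
  }
  list(TP = sum(matched_truth), FP = sum(!pred_tp),
       FN = sum(!matched_truth))
}

## random annotation with pairwise-distinct junction chains on disjoint loci
random_instance <- function(n_tx, seed) {
  set.seed(seed)
  parts <- list()
  cursor <- 0L
  for (i in seq_len(n_tx)) {
    n_ex <- sample(1:5, 1)
    ex_len <- sample(50:200, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(30:300, n_ex - 1, replace = TRUE) else integer()
    starts <- cursor + cumsum(c(sample(10:50, 1), head(ex_len, -1) + in_len))
    parts[[i]] <- data.table(
      transcript_id = sprintf("T%03d", i), gene_id = sprintf("G%03d", i),
      chrom = sample(c("chr1", "chr2"), 1),
      strand = sample(c("+", "-"), 1),
      start = starts, end = starts + ex_len)
    cursor <- max(starts + ex_len) + 500L
  }
  tx_annotation(rbindlist(parts))
}

## predictions derived from a truth instance: copies, terminal extensions,
## internal junction shifts, drops
perturb_instance <- function(truth_ann, seed) {
  set.seed(seed)
  tt <- transcripts_tbl(truth_ann)
  parts <- list()
  k <- 0L
  for (tid in tt$transcript_id) {
    ex <- as.data.table(truth_ann)[transcript_id == tid][order(start)]
    action <- sample(c("copy", "extend", "shift", "drop"), 1,
                     prob = c(.35, .25, .25, .15))
    if (action == "drop") next
    k <- k + 1L
    if (action == "extend") {
      ex$start[1] <- max(0L, ex$start[1] - sample(1:60, 1))
      ex$end[nrow(ex)] <- ex$end[nrow(ex)] + sample(1:60, 1)
    } else if (action == "shift" && nrow(ex) > 1L) {
      j <- sample(nrow(ex) - 1L, 1)     # junction j: end of exon j
      d <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1)
      new_end <- ex$end[j] + d
      if (new_end > ex$start[j] && new_end < ex$start[j + 1L])
        ex$end[j] <- new_end
    }
    ex$transcript_id <- sprintf("P%03d", k)
    ex$gene_id <- sprintf("PG%03d", k)
    parts[[k]] <- ex
  }
  if (!length(parts)) return(NULL)
  tx_annotation(rbindlist(parts))
}
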