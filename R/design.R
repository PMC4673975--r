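## Ground-truth design: controlled alternative-processing variants.
##
## A truth set in the T1 style is built from a base annotation of
## single-isoform genes: a block of single-form genes (with a minimum exon
## count), then, for each of three alternative-processing categories —
## exon skipping, truncation (alternate transcription start/end) and
## splice-site shift — blocks of genes carrying 2..5 forms each. Categories
## are never mixed within a gene, so downstream accuracy can be isolated
## per event type.

CATEGORIES <- c("EXON_SKIPPING", "TRUNCATION", "SPLICE_SHIFT")

#' T1-style truth design
#'
#' Defaults reproduce the canonical layout: 1000 single-form genes with at
#' least 5 exons, plus — for each of the three categories — 1000 genes each
#' with 2, 3, 4 and 5 forms: 13,000 genes, 43,000 transcripts in total.
#'
#' @param n_single_form_genes genes kept with exactly one form.
#' @param per_category_counts named integer vector mapping forms-per-gene
#'   (as names, "2".."5") to number of genes *per category*.
#' @param categories event categories to include (default all three).
#' @param min_exons_single minimum exon count for single-form genes.
#' @param min_exons_variant minimum exon count for genes receiving variants
#'   (3 keeps every event type applicable).
#' @param min_gene_length genes shorter than this (spliced bases) are
#'   filtered out before design.
#' @param events_mean number of events per variant is `1 + Poisson(events_mean)`
#'   (capped by admissibility); most variants carry a single event.
#' @param shift_triplet_prob probability that a splice-shift offset is a
#'   multiple of three (see [splice_shift_variant()]).
#' @param seed RNG seed.
#' @export
t1_design <- function(n_single_form_genes = 1000L,
                      per_category_counts = c(`2` = 1000L, `3` = 1000L,
                                              `4` = 1000L, `5` = 1000L),
                      categories = CATEGORIES,
                      min_exons_single = 5L,
                      min_exons_variant = 3L,
                      min_gene_length = 200L,
                      events_mean = 0.5,
                      shift_triplet_prob = 0.9,
                      seed = 1L) {
  stopifnot(all(categories %in% CATEGORIES),
            all(as.integer(names(per_category_counts)) >= 2L),
            n_single_form_genes >= 0L, all(per_category_counts >= 0L))
  structure(list(n_single_form_genes = as.integer(n_single_form_genes),
                 per_category_counts = per_category_counts,
                 categories = categories,
                 min_exons_single = as.integer(min_exons_single),
                 min_exons_variant = as.integer(min_exons_variant),
                 min_gene_length = as.integer(min_gene_length),
                 events_mean = events_mean,
                 shift_triplet_prob = shift_triplet_prob,
                 seed = as.integer(seed)),
            class = "t1_design")
}

design_n_genes <- function(design) {
  design$n_single_form_genes +
    length(design$categories) * sum(design$per_category_counts)
}

design_n_transcripts <- function(design) {
  f <- as.integer(names(design$per_category_counts))
  design$n_single_form_genes +
    length(design$categories) * sum(design$per_category_counts * f)
}

#' Filter base transcripts eligible for truth design
#'
#' Returns, in input order, the transcripts of a single-isoform annotation
#' with at least `min_exons` exons and spliced length at least
#' `min_length` (short genes are under-represented by any realistic
#' fragment-length law, so they are removed up front).
#'
#' @param annotation a [tx_annotation()] of single-transcript genes.
#' @param min_exons,min_length inclusive floors.
#' @return list of transcript views (fields `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exons` matrix), named by transcript id.
#' @export
select_base_transcripts <- function(annotation, min_exons = 1L,
                                    min_length = 1L) {
  tt <- transcripts_tbl(annotation)
  keep <- tt[n_exons >= min_exons & tt$length >= min_length]
  views <- tx_view(keep, annotation[annotation$transcript_id %in%
                                      keep$transcript_id])
  views[keep$transcript_id]
}

## ---- single-event variant operations -------------------------------------

#' Exon-skipping variant
#'
#' Removes k internal exons, k uniform on {1, ..., min(2, n_internal)}.
#' Terminal exons are always retained, so the result's junction chain
#' always differs from the base's.
#'
#' @param base transcript view (see [select_base_transcripts()]).
#' @return a transcript view with fewer exons.
#' @export
exon_skipping_variant <- function(base) {
  m <- base$exons
  n <- nrow(m)
  if (n < 3L)
    stop_txbench("exon skipping needs >= 3 exons (no internal exon in ",
                 base$transcript_id, ")", class = "txbench_not_applicable")
  internal <- 2:(n - 1L)
  k <- sample.int(min(2L, length(internal)), 1L)
  drop <- internal[sample.int(length(internal), k)]
  base$exons <- m[-drop, , drop = FALSE]
  base
}

#' Truncation variant (alternate transcription start/end)
#'
#' Removes a prefix of `a` exons and a suffix of `b` exons, with
#' `(a, b)` uniform over all admissible pairs (`a + b >= 1`, at least one
#' exon remains). The result is always a contiguous exon subsequence of the
#' base; it may be a single exon.
#'
#' @inheritParams exon_skipping_variant
#' @export
truncation_variant <- function(base) {
  m <- base$exons
  n <- nrow(m)
  if (n < 2L)
    stop_txbench("truncation needs >= 2 exons (", base$transcript_id, ")",
                 class = "txbench_not_applicable")
  pairs <- truncation_pairs(n)
  p <- pairs[sample.int(nrow(pairs), 1L), ]
  base$exons <- m[(p[1L] + 1L):(n - p[2L]), , drop = FALSE]
  base
}

truncation_pairs <- function(n) {
  g <- expand.grid(a = 0:(n - 1L), b = 0:(n - 1L))
  as.matrix(g[g$a + g$b >= 1L & g$a + g$b <= n - 1L, , drop = FALSE])
}

#' Splice-shift variant (alternate splice site)
#'
#' Moves one junction-adjacent exon boundary — the start of an exon other
#' than the first, or the end of an exon other than the last — by an offset
#' delta. With probability `triplet_prob` delta is drawn uniformly from
#' {±3, ±6, ±9} (in-frame shifts dominate real alternate splice sites),
#' otherwise uniformly from {±1, ±2}. Draws violating exon or intron
#' positivity are rejected and redrawn. The result differs from the base by
#' exactly one junction coordinate.
#'
#' @inheritParams exon_skipping_variant
#' @param triplet_prob probability of a multiple-of-three offset.
#' @param max_tries bounded rejection budget before declaring the event
#'   inapplicable.
#' @export
splice_shift_variant <- function(base, triplet_prob = 0.9, max_tries = 100L) {
  m <- base$exons
  n <- nrow(m)
  if (n < 2L)
    stop_txbench("splice shift needs >= 2 exons (", base$transcript_id, ")",
                 class = "txbench_not_applicable")
  ## boundaries: (exon index, side); side 1 = start (exons 2..n),
  ## side 2 = end (exons 1..n-1)
  bnd <- rbind(cbind(2:n, 1L), cbind(1:(n - 1L), 2L))
  for (try in seq_len(max_tries)) {
    b <- bnd[sample.int(nrow(bnd), 1L), ]
    delta <- draw_shift_delta(triplet_prob)
    i <- b[1L]; side <- b[2L]
    m2 <- m
    if (side == 1L) m2[i, 1L] <- m2[i, 1L] + delta
    else m2[i, 2L] <- m2[i, 2L] + delta
    ok <- m2[i, 1L] < m2[i, 2L] &&                       # exon positivity
      (i == 1L || m2[i, 1L] > m2[i - 1L, 2L]) &&         # intron left
      (i == n  || m2[i, 2L] < m2[i + 1L, 1L]) &&         # intron right
      m2[i, 1L] >= 0L
    if (ok) {
      base$exons <- m2
      return(base)
    }
  }
  stop_txbench("no admissible splice shift for ", base$transcript_id,
               class = "txbench_not_applicable")
}

draw_shift_delta <- function(triplet_prob = 0.9) {
  if (runif(1) < triplet_prob) sample(c(-9L, -6L, -3L, 3L, 6L, 9L), 1L)
  else sample(c(-2L, -1L, 1L, 2L), 1L)
}

## one *variant* = one or more events of the same category applied in
## sequence; inapplicable events simply stop the sequence early.
make_variant <- function(base, category, design) {
  n_events <- 1L + rpois(1L, design$events_mean)
  v <- base
  applied <- 0L
  for (e in seq_len(n_events)) {
    v2 <- tryCatch(switch(category,
      EXON_SKIPPING = exon_skipping_variant(v),
      TRUNCATION = truncation_variant(v),
      SPLICE_SHIFT = splice_shift_variant(v, design$shift_triplet_prob)),
      txbench_not_applicable = function(e) NULL)
    if (is.null(v2)) break
    v <- v2
    applied <- applied + 1L
  }
  if (applied == 0L) NULL else v
}

## ---- truth assembly -------------------------------------------------------

#' Build a T1-style truth annotation
#'
#' Assigns base genes to design slots in input order — the single-form
#' block first (requiring `min_exons_single` exons), then one block per
#' category and forms-per-gene count — and generates pairwise-distinct
#' variants for each multi-form gene. Distinctness is judged on the
#' junction chain together with the terminal coordinates, since two forms
#' may legitimately share all junctions and differ only in their
#' transcription start/end. A gene for which enough distinct forms cannot
#' be generated within the retry budget is replaced by the next eligible
#' candidate (counted and reported).
#'
#' @param annotation a single-isoform base annotation ([tx_annotation()]).
#' @param design a [t1_design()].
#' @return an object of class `truth_annotation`: list with `annotation`
#'   (the multi-form [tx_annotation()]), `gene_info` (data.table `gene_id`,
#'   `category`, `n_forms`) and `design`.
#' @export
build_t1_truth <- function(annotation, design = t1_design()) {
  stopifnot(inherits(design, "t1_design"))
  with_seed(seed_stream(design$seed, "t1-design"), {
    tt <- transcripts_tbl(annotation)
    ok_len <- tt$length >= design$min_gene_length
    single_ok <- ok_len & tt$n_exons >= design$min_exons_single
    variant_ok <- ok_len & tt$n_exons >= design$min_exons_variant

    n_single <- design$n_single_form_genes
    single_idx <- which(single_ok)
    if (length(single_idx) < n_single)
      stop_txbench(sprintf(
        "only %d candidate genes with >= %d exons and length >= %d; %d needed for the single-form block",
        length(single_idx), design$min_exons_single, design$min_gene_length,
        n_single))
    single_idx <- single_idx[seq_len(n_single)]

    pool <- setdiff(which(variant_ok), single_idx)  # input order preserved
    n_variant_genes <- length(design$categories) * sum(design$per_category_counts)
    if (length(pool) < n_variant_genes)
      stop_txbench(sprintf(
        "only %d candidate genes left for %d variant-gene slots",
        length(pool), n_variant_genes))

    views <- tx_view(tt, annotation)

    out <- vector("list", design_n_genes(design))
    info <- vector("list", design_n_genes(design))
    oi <- 0L
    for (i in single_idx) {
      oi <- oi + 1L
      out[[oi]] <- list(views[[tt$transcript_id[i]]])
      info[[oi]] <- data.table(gene_id = tt$gene_id[i],
                               category = "SINGLE_FORM", n_forms = 1L)
    }

    pool_pos <- 1L
    n_substituted <- 0L
    form_counts <- as.integer(names(design$per_category_counts))
    for (category in design$categories) {
      for (fi in order(form_counts)) {
        f <- form_counts[fi]
        for (g in seq_len(design$per_category_counts[fi])) {
          repeat {
            if (pool_pos > length(pool))
              stop_txbench("ran out of candidate genes while substituting; ",
                           "enlarge the base annotation")
            i <- pool[pool_pos]; pool_pos <- pool_pos + 1L
            forms <- grow_gene_forms(views[[tt$transcript_id[i]]], category,
                                     f, design)
            if (!is.null(forms)) break
            n_substituted <- n_substituted + 1L
          }
          oi <- oi + 1L
          out[[oi]] <- forms
          info[[oi]] <- data.table(gene_id = tt$gene_id[i],
                                   category = category, n_forms = f)
        }
      }
    }
    if (n_substituted > 0L)
      tb_log(n_substituted, " gene(s) substituted after failing to yield ",
             "enough distinct forms")
    ann_out <- tx_views_to_annotation(unlist(out, recursive = FALSE),
                                      validate = FALSE)
    structure(list(annotation = ann_out,
                   gene_info = rbindlist(info),
                   design = design),
              class = "truth_annotation")
  })
}

## generate f pairwise-distinct forms for one gene, or NULL on failure
grow_gene_forms <- function(base, category, f, design, max_tries = 60L) {
  forms <- list(base)
  keys <- structure_key(base$exons[, 1L], base$exons[, 2L])
  tries <- 0L
  while (length(forms) < f && tries < max_tries) {
    tries <- tries + 1L
    v <- make_variant(base, category, design)
    if (is.null(v)) next
    k <- structure_key(v$exons[, 1L], v$exons[, 2L])
    if (k %in% keys) next
    v$transcript_id <- sprintf("%s.T%d", base$gene_id, length(forms) + 1L)
    forms <- c(forms, list(v))
    keys <- c(keys, k)
  }
  if (length(forms) < f) NULL else forms
}

#' @export
print.truth_annotation <- function(x, ...) {
  cat(sprintf("<truth_annotation> %d genes, %d transcripts\n",
              nrow(x$gene_info), uniqueN(x$annotation$transcript_id)))
  print(x$gene_info[, .N, by = category])
  invisible(x)
}

#' Write/read the truth sidecar table
#'
#' TSV with one row per transcript: `transcript_id`, `gene_id`,
#' `category`, `forms_in_gene`. Together with the truth GTF this fully
#' describes a `truth_annotation`.
#'
#' @param truth a `truth_annotation`.
#' @param path TSV file.
#' @export
write_truth_sidecar <- function(truth, path) {
  tt <- transcripts_tbl(truth$annotation)[, .(transcript_id, gene_id)]
  side <- merge(tt, truth$gene_info, by = "gene_id", sort = FALSE)
  setcolorder(side, c("transcript_id", "gene_id", "category", "n_forms"))
  setnames(side, "n_forms", "forms_in_gene")
  setorder(side, transcript_id)
  fwrite(side, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @param gtf_path truth annotation GTF written by [write_gtf()].
#' @export
read_truth_sidecar <- function(gtf_path, path) {
  ann <- read_gtf(gtf_path)
  side <- fread(path, sep = "\t", colClasses = list(
    character = c("transcript_id", "gene_id", "category")))
  gene_info <- unique(side[, .(gene_id, category, n_forms = forms_in_gene)])
  structure(list(annotation = ann, gene_info = gene_info, design = NULL),
            class = "truth_annotation")
}
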