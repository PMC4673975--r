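## Annotation corruption: the deliberately imperfect "provided" gene models
## used to run assemblers in annotation-guided mode. Real annotation is
## missing expressed transcripts and contains unexpressed ones; both
## defects are reproduced here under a ledger that records exactly what
## was done, so the evaluator can stratify accuracy by annotation status.

#' Corrupt a truth annotation
#'
#' Hides `round(hide_fraction * n_expressed)` expressed transcripts
#' (uniformly at random; rounding is half-up) and, when `replace = TRUE`,
#' plants for each hidden transcript a newly generated *unexpressed* decoy
#' variant of the same gene, so the provided annotation keeps its size.
#' Decoys are generated with the gene's own event category when known
#' (exon skipping otherwise) and are required to be structurally distinct
#' from every form of the gene — distinct junction chain, or for
#' single-exon forms less than 50% reciprocal overlap — so that a decoy
#' called expressed is unambiguously a false positive. With
#' `replace = FALSE` transcripts are only removed (the natural mode when
#' the expression spectrum already leaves a third of the annotation
#' unexpressed).
#'
#' @param truth a `truth_annotation` or [tx_annotation()].
#' @param profile expression profile ([assign_expression()]); transcripts
#'   with weight > 0 are the expressed ones.
#' @param hide_fraction fraction of expressed transcripts to hide.
#' @param replace plant one decoy per hidden transcript.
#' @param seed RNG seed.
#' @return list with `annotation` (the provided [tx_annotation()]) and
#'   `ledger` (data.table `transcript_id`, `gene_id`, `status` in
#'   retained / hidden_expressed / planted_decoy).
#' @export
corrupt_annotation <- function(truth, profile, hide_fraction,
                               replace = TRUE, seed = 1L) {
  stopifnot(hide_fraction >= 0, hide_fraction <= 1)
  ann <- if (inherits(truth, "truth_annotation")) truth$annotation else truth
  gene_cat <- if (inherits(truth, "truth_annotation"))
    setNames(truth$gene_info$category, truth$gene_info$gene_id) else c()
  tt <- transcripts_tbl(ann)
  w <- merge(tt[, .(transcript_id)], profile, by = "transcript_id",
             all.x = TRUE, sort = TRUE)
  w[is.na(weight), weight := 0]
  expressed <- w$transcript_id[w$weight > 0]
  n_hide <- as.integer(round_half_up(hide_fraction * length(expressed)))

  with_seed(seed_stream(seed, "corruption"), {
    hidden <- if (n_hide > 0L)
      sort(sample(expressed, n_hide)) else character()
    keep <- setdiff(tt$transcript_id, hidden)
    ledger <- data.table(
      transcript_id = c(keep, hidden),
      gene_id = c(tt[match(keep, transcript_id), gene_id],
                  tt[match(hidden, transcript_id), gene_id]),
      status = rep(c("retained", "hidden_expressed"),
                   c(length(keep), length(hidden))))

    provided_exons <- ann[ann$transcript_id %in% keep]
    decoys <- list()
    if (replace && length(hidden)) {
      views <- tx_view(tt, ann)
      ## existing structures per gene, for the distinctness check
      gene_forms <- split(tt, tt$gene_id)
      n_failed <- 0L
      design <- t1_design()           # event-law defaults for decoy drawing
      for (h in hidden) {
        gid <- tt[transcript_id == h, gene_id]
        cat_h <- gene_cat[gid]
        if (is.na(cat_h) || is.null(cat_h) || cat_h == "SINGLE_FORM")
          cat_h <- "EXON_SKIPPING"
        ## the gene's most exon-rich form gives the most room for a
        ## distinct variant (the hidden form itself may be a single exon)
        gtt <- gene_forms[[gid]]
        base_id <- gtt$transcript_id[which.max(gtt$n_exons)]
        d <- make_decoy(views[[base_id]], views, gtt, cat_h, design,
                        already = decoys)
        if (is.null(d)) {
          n_failed <- n_failed + 1L
          next
        }
        d$transcript_id <- sprintf("%s.decoy%d", gid, length(decoys) + 1L)
        decoys <- c(decoys, list(d))
        ledger <- rbind(ledger, data.table(
          transcript_id = d$transcript_id, gene_id = gid,
          status = "planted_decoy"))
      }
      if (n_failed > 0L)
        tb_log(n_failed, " hidden transcript(s) could not be replaced ",
               "with a decoy (no constructible distinct variant)")
      if (length(decoys))
        provided_exons <- rbind(provided_exons,
                                tx_views_to_annotation(decoys,
                                                       validate = FALSE))
    }
    provided <- tx_annotation(provided_exons, validate = FALSE)
    setorder(ledger, transcript_id)
    list(annotation = provided, ledger = ledger[])
  })
}

## one decoy for gene `gid`: try the gene's category first, then the
## others; structural distinctness from all truth forms of the gene and
## all decoys already planted there
make_decoy <- function(base, views, gene_tt, category, design, already,
                       max_tries = 40L) {
  others <- setdiff(CATEGORIES, category)
  gene_views <- lapply(gene_tt$transcript_id, function(t) views[[t]])
  planted <- Filter(function(d) d$gene_id == base$gene_id, already)
  for (cat_try in c(category, others)) {
    for (k in seq_len(max_tries)) {
      v <- tryCatch(make_variant(base, cat_try, design),
                    txbench_not_applicable = function(e) NULL)
      if (is.null(v)) break               # category inapplicable to base
      if (decoy_distinct(v, c(gene_views, planted))) return(v)
    }
  }
  NULL
}

decoy_distinct <- function(v, forms) {
  vch <- chain_string(v$exons[, 1L], v$exons[, 2L])
  for (f in forms) {
    fch <- chain_string(f$exons[, 1L], f$exons[, 2L])
    if (nrow(v$exons) > 1L || nrow(f$exons) > 1L) {
      if (identical(vch, fch) && nrow(v$exons) > 1L && nrow(f$exons) > 1L)
        return(FALSE)
    } else {
      ## both single-exon: require < 50% reciprocal overlap
      ov <- min(v$exons[1L, 2L], f$exons[1L, 2L]) -
        max(v$exons[1L, 1L], f$exons[1L, 1L])
      if (ov >= 0.5 * (v$exons[1L, 2L] - v$exons[1L, 1L]) ||
          ov >= 0.5 * (f$exons[1L, 2L] - f$exons[1L, 1L]))
        return(FALSE)
    }
  }
  TRUE
}

#' Write/read a corruption ledger
#' @param ledger data.table from [corrupt_annotation()].
#' @param path TSV file.
#' @export
write_ledger <- function(ledger, path) {
  fwrite(ledger, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  fread(path, sep = "\t", colClasses = list(
    character = c("transcript_id", "gene_id", "status")))
}
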