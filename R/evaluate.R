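## Scoring predicted transcript sets against truth.
##
## A predicted multi-exon transcript is a true positive iff some truth
## transcript on the same chromosome and strand has an identical junction
## chain; transcription start/end are notoriously hard to call and are
## deliberately ignored. A single wrong junction makes a false positive.
## Single-exon predictions (no junctions to match) are matched by >= 50%
## reciprocal exon overlap against single-exon truth forms. An expressed
## truth transcript never matched is a false negative. Redundant
## predictions of one truth form are deduplicated: one TP, the surplus
## counted neither as TP nor FP.

#' Evaluation configuration
#'
#' @param recall_floor,precision_floor comfort-zone floors: results with
#'   recall below 25% or precision below 66.6% are flagged as outside the
#'   zone where error rates are usable in practice.
#' @param coverage_breaks lower edges of the coverage strata; the default
#'   `c(1, 10, 100)` gives low \[1,10), medium \[10,100), high \[100,Inf).
#'   Transcripts below the first edge are left unbinned.
#' @param fn_expression_threshold minimum true exonic fragment count for a
#'   truth transcript to count as expressed (and hence as a potential
#'   false negative).
#' @param outlier_log10 quantification pairs with
#'   `|log10(inferred/true)| > outlier_log10` are removed (and counted)
#'   before the Pearson correlation.
#' @param single_exon_min_overlap reciprocal-overlap floor for single-exon
#'   matching.
#' @export
evaluation_config <- function(recall_floor = 0.25,
                              precision_floor = 2 / 3,
                              coverage_breaks = c(1, 10, 100),
                              fn_expression_threshold = 1L,
                              outlier_log10 = 2,
                              single_exon_min_overlap = 0.5) {
  stopifnot(recall_floor > 0, recall_floor < 1,
            precision_floor > 0, precision_floor < 1,
            !is.unsorted(coverage_breaks), length(coverage_breaks) >= 1)
  structure(list(recall_floor = recall_floor,
                 precision_floor = precision_floor,
                 coverage_breaks = coverage_breaks,
                 fn_expression_threshold = as.integer(fn_expression_threshold),
                 outlier_log10 = outlier_log10,
                 single_exon_min_overlap = single_exon_min_overlap),
            class = "evaluation_config")
}

coverage_bin_labels <- function(breaks) {
  k <- length(breaks)
  labs <- if (k == 3L) c("low", "medium", "high")
          else paste0("bin", seq_len(k))
  labs
}

#' Assign expressed transcripts to coverage strata
#'
#' Half-open bins on mean exonic coverage, unbounded on top; transcripts
#' with coverage below the first edge are unbinned (`NA`) and excluded
#' from binned strata.
#'
#' @param true_counts data.table from [true_fpkm()].
#' @param config an [evaluation_config()].
#' @return data.table `transcript_id`, `cov_bin`.
#' @export
stratify_by_coverage <- function(true_counts, config = evaluation_config()) {
  br <- config$coverage_breaks
  labs <- coverage_bin_labels(br)
  i <- findInterval(true_counts$coverage, br)
  data.table(transcript_id = true_counts$transcript_id,
             cov_bin = ifelse(i == 0L, NA_character_, labs[pmax(i, 1L)]))
}

#' Classify predictions against truth
#'
#' @param predicted predicted annotation ([tx_annotation()], e.g. from
#'   [read_gtf()] on an assembler's output).
#' @param truth a `truth_annotation` or plain [tx_annotation()].
#' @param true_counts per-transcript truth quantification ([true_fpkm()]);
#'   `NULL` treats every truth transcript as expressed.
#' @param ledger corruption ledger ([corrupt_annotation()]) or `NULL`;
#'   provides the annotated-vs-hidden stratification and lets false
#'   positives matching a planted decoy inherit its gene's strata.
#' @param config an [evaluation_config()].
#' @return `tx_classification`: list with `predictions` (per predicted
#'   transcript: `class_` in TP/FP/DUP, matched truth id, strata),
#'   `truth` (per truth transcript: expressed, detected, strata) and
#'   `n_duplicates`.
#' @export
classify_predictions <- function(predicted, truth, true_counts = NULL,
                                 ledger = NULL,
                                 config = evaluation_config()) {
  tru <- if (inherits(truth, "truth_annotation")) truth else
    structure(list(annotation = truth, gene_info = NULL), class = "truth_annotation")
  tt <- transcripts_tbl(tru$annotation)
  pt <- transcripts_tbl(predicted)

  ## truth-side labels
  if (!is.null(true_counts)) {
    tt <- merge(tt, true_counts[, .(transcript_id, fragments, coverage)],
                by = "transcript_id", all.x = TRUE, sort = FALSE)
    tt[is.na(fragments), `:=`(fragments = 0L, coverage = 0)]
  } else tt[, `:=`(fragments = NA_integer_, coverage = NA_real_)]
  tt[, expressed := if (is.null(true_counts)) TRUE
     else fragments >= config$fn_expression_threshold]
  if (!is.null(true_counts)) {
    cb <- stratify_by_coverage(tt[, .(transcript_id, coverage)], config)
    tt <- merge(tt, cb, by = "transcript_id", sort = FALSE)
  } else tt[, cov_bin := NA_character_]
  if (!is.null(tru$gene_info))
    tt <- merge(tt, tru$gene_info, by = "gene_id", all.x = TRUE,
                sort = FALSE)
  else tt[, `:=`(category = NA_character_, n_forms = NA_integer_)]
  tt[, status := "annotated"]
  if (!is.null(ledger))
    tt[transcript_id %in%
         ledger[status == "hidden_expressed", transcript_id],
       status := "hidden"]

  ## --- multi-exon matching by junction chain ------------------------------
  tmulti <- tt[n_exons > 1L]
  key_of <- function(chrom, strand, chain) paste(chrom, strand, chain,
                                                 sep = "|")
  truth_keys <- setNames(tmulti$transcript_id,
                         key_of(tmulti$chrom, tmulti$strand, tmulti$chain))
  setorder(pt, transcript_id)
  pm <- pt[n_exons > 1L]
  match_multi <- unname(truth_keys[key_of(pm$chrom, pm$strand, pm$chain)])
  ## unstranded predictions match either strand
  dot <- which(pm$strand == "." & is.na(match_multi))
  if (length(dot)) {
    for (s in c("+", "-")) {
      still <- dot[is.na(match_multi[dot])]
      match_multi[still] <-
        unname(truth_keys[key_of(pm$chrom[still], s, pm$chain[still])])
    }
    tb_log(length(dot), " unstranded multi-exon prediction(s) matched ",
           "against both strands")
  }

  ## --- single-exon matching by reciprocal overlap -------------------------
  ps <- pt[n_exons == 1L]
  tsingle <- tt[n_exons == 1L]
  match_single <- rep(NA_character_, nrow(ps))
  if (nrow(ps) && nrow(tsingle)) {
    for (i in seq_len(nrow(ps))) {
      cand <- tsingle[chrom == ps$chrom[i] &
                        (strand == ps$strand[i] | ps$strand[i] == "." |
                           strand == ".")]
      if (!nrow(cand)) next
      ov <- pmin(cand$tx_end, ps$tx_end[i]) - pmax(cand$tx_start, ps$tx_start[i])
      lenp <- ps$tx_end[i] - ps$tx_start[i]
      lent <- cand$tx_end - cand$tx_start
      ok <- ov >= config$single_exon_min_overlap * lenp &
        ov >= config$single_exon_min_overlap * lent
      if (any(ok)) {
        best <- which.max(ifelse(ok, ov / pmax(lenp, lent), -Inf))
        match_single[i] <- cand$transcript_id[best]
      }
    }
  }

  preds <- rbind(
    data.table(transcript_id = pm$transcript_id, matched_truth = match_multi),
    data.table(transcript_id = ps$transcript_id, matched_truth = match_single))
  setorder(preds, transcript_id)
  preds[, class_ := ifelse(is.na(matched_truth), "FP", "TP")]
  ## deduplicate: one TP per truth form, surplus neither TP nor FP
  dup <- preds[class_ == "TP"][duplicated(matched_truth)]
  preds[transcript_id %in% dup$transcript_id, class_ := "DUP"]
  n_dup <- nrow(dup)
  if (n_dup > 0L)
    tb_log(n_dup, " duplicate prediction(s) of already-matched truth ",
           "forms (not counted)")

  ## strata for predictions: TP/DUP inherit the matched truth transcript;
  ## FPs matching a planted decoy's structure inherit the decoy's gene
  preds <- merge(preds,
                 tt[, .(matched_truth = transcript_id, status, category,
                        n_forms, cov_bin)],
                 by = "matched_truth", all.x = TRUE, sort = FALSE)
  if (!is.null(ledger)) {
    ## a false positive that *is* a planted decoy (an annotated,
    ## unexpressed model called expressed) belongs to the annotated
    ## stratum; recognisable by id when predictions come straight from
    ## the provided annotation
    decoy_ids <- ledger[status == "planted_decoy", transcript_id]
    preds[class_ == "FP" & transcript_id %in% decoy_ids,
          status := "annotated"]
  }
  preds[class_ == "FP" & is.na(status), status := "novel"]

  truth_out <- copy(tt)
  matched_set <- unique(preds[class_ == "TP", matched_truth])
  truth_out[, detected := transcript_id %in% matched_set]
  setorder(preds, transcript_id)

  structure(list(predictions = preds[], truth = truth_out[],
                 n_duplicates = n_dup, config = config),
            class = "tx_classification")
}

#' @export
print.tx_classification <- function(x, ...) {
  pr <- precision_recall(x)
  cat(sprintf(
    "<tx_classification> TP %d, FP %d, FN %d | precision %.3f, recall %.3f%s\n",
    pr$TP, pr$FP, pr$FN, pr$precision, pr$recall,
    if (isTRUE(pr$comfort_zone)) " [comfort zone]" else ""))
  invisible(x)
}

#' Precision and recall for one stratum
#'
#' @param classification a `tx_classification`.
#' @param stratum `"overall"` or a named list over `status`
#'   (annotated/hidden), `category`, `n_forms`, `cov_bin`; truth-side
#'   counts (TP, FN) are filtered on the truth transcript's labels,
#'   false-positive counts on the labels the FP inherited (FPs with no
#'   label only enter `overall` and `status = "novel"`).
#' @return list `TP`, `FP`, `FN`, `precision`, `recall`, `comfort_zone`
#'   (precision/recall are `NA` when undefined; `comfort_zone` is `NA`
#'   for an empty stratum).
#' @export
precision_recall <- function(classification, stratum = "overall") {
  stopifnot(inherits(classification, "tx_classification"))
  cfg <- classification$config
  tr <- classification$truth
  pr <- classification$predictions
  if (!identical(stratum, "overall")) {
    for (f in names(stratum)) {
      tr <- tr[tr[[f]] %in% stratum[[f]]]
      pr <- pr[pr[[f]] %in% stratum[[f]]]
    }
  }
  TP <- sum(tr$detected & tr$expressed)
  ## a detected-but-unexpressed truth form was still correctly
  ## reconstructed; it enters neither TP (no fragments to recall) nor FP.
  FP <- sum(pr$class_ == "FP")
  FN <- sum(tr$expressed & !tr$detected)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  comfort <- if (is.na(precision) || is.na(recall)) NA
             else recall >= cfg$recall_floor & precision >= cfg$precision_floor
  list(TP = TP, FP = FP, FN = FN, precision = precision, recall = recall,
       comfort_zone = comfort)
}

#' Full stratified evaluation report
#'
#' One row per stratum: overall, by annotation status, by event category,
#' by forms-per-gene and by coverage bin.
#'
#' @param classification a `tx_classification`.
#' @param quant optional quantification block from
#'   [quantification_agreement()].
#' @return `evaluation_report`: list with `strata` (data.table) and
#'   `quantification`.
#' @export
evaluation_report <- function(classification, quant = NULL) {
  rows <- list(data.table(stratum = "overall",
                          as.data.table(precision_recall(classification))))
  add <- function(field, values, prefix) {
    for (v in values) {
      s <- setNames(list(v), field)
      rows[[length(rows) + 1L]] <<- data.table(
        stratum = paste0(prefix, v),
        as.data.table(precision_recall(classification, s)))
    }
  }
  tr <- classification$truth
  add("status", sort(unique(tr$status)), "status:")
  add("category", sort(unique(tr$category[!is.na(tr$category)])), "category:")
  add("n_forms", sort(unique(tr$n_forms[!is.na(tr$n_forms)])), "forms:")
  add("cov_bin", intersect(c("low", "medium", "high"), tr$cov_bin),
      "coverage:")
  structure(list(strata = rbindlist(rows), quantification = quant,
                 n_duplicates = classification$n_duplicates),
            class = "evaluation_report")
}

#' Quantification agreement between true and inferred FPKM
#'
#' Splits transcripts into on/off errors (true zero but inferred positive,
#' or true positive but inferred zero), removes extreme outliers among the
#' both-positive pairs, and reports the Pearson correlation of the
#' survivors.
#'
#' @param true_quant data.table `transcript_id`, `fpkm` (or [true_fpkm()]
#'   output).
#' @param inferred_quant data.table `transcript_id`, `fpkm`; transcripts
#'   absent from it are treated as inferred zero.
#' @param config an [evaluation_config()].
#' @return list `pearson_r`, `n_both_positive`, `n_false_on`,
#'   `n_false_off`, `n_both_zero`, `n_outliers_removed`.
#' @export
quantification_agreement <- function(true_quant, inferred_quant,
                                     config = evaluation_config()) {
  tq <- as.data.table(true_quant)[, .(transcript_id, true = fpkm)]
  iq <- as.data.table(inferred_quant)[, .(transcript_id, inferred = fpkm)]
  m <- merge(tq, iq, by = "transcript_id", all = TRUE)
  m[is.na(m$true), true := 0]
  m[is.na(m$inferred), inferred := 0]
  n_false_on <- nrow(m[m$true == 0 & m$inferred > 0])
  n_false_off <- nrow(m[m$true > 0 & m$inferred == 0])
  n_both_zero <- nrow(m[m$true == 0 & m$inferred == 0])
  bp <- m[m$true > 0 & m$inferred > 0]
  out <- abs(log10(bp$inferred / bp$true)) > config$outlier_log10
  surv <- bp[!out]
  r <- if (nrow(surv) >= 3L && stats::sd(surv$true) > 0 &&
           stats::sd(surv$inferred) > 0)
    cor(surv$true, surv$inferred) else NA_real_
  list(pearson_r = r, n_both_positive = nrow(bp),
       n_false_on = n_false_on, n_false_off = n_false_off,
       n_both_zero = n_both_zero, n_outliers_removed = sum(out))
}

#' Write an evaluation report
#'
#' `<path>` gets the per-stratum TSV; `<path>.summary.txt` a short
#' human-readable summary. Output is deterministic for a fixed report.
#'
#' @param report an `evaluation_report`.
#' @param path output TSV path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  st <- copy(report$strata)
  num <- c("precision", "recall")
  st[, (num) := lapply(.SD, function(x) round(x, 6)), .SDcols = num]
  tryCatch(fwrite(st, path, sep = "\t", na = "NA"),
           error = function(e) stop_txbench("cannot write: ", path))
  s <- report$strata[stratum == "overall"]
  lines <- c(
    sprintf("overall: TP=%d FP=%d FN=%d precision=%s recall=%s comfort_zone=%s",
            s$TP, s$FP, s$FN, format(round(s$precision, 4)),
            format(round(s$recall, 4)), as.character(s$comfort_zone)),
    sprintf("duplicate predictions (uncounted): %d",
            report$n_duplicates %||% 0L))
  if (!is.null(report$quantification)) {
    q <- report$quantification
    lines <- c(lines, sprintf(
      "quantification: r=%s both_positive=%d false_on=%d false_off=%d outliers_removed=%d",
      format(round(q$pearson_r, 4)), q$n_both_positive, q$n_false_on,
      q$n_false_off, q$n_outliers_removed))
  }
  writeLines(lines, paste0(path, ".summary.txt"))
  invisible(path)
}
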