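## Core containers: exon tables, transcripts, genes, junction chains.
##
## Internal coordinates are 0-based half-open throughout; GTF/GFF I/O
## converts at the boundary. Junction coordinates are stored in genomic
## (ascending) order regardless of strand: the matching criterion used by
## the evaluator is purely coordinate-based, so donor/acceptor naming is
## positional, not biological.

#' Construct an annotation from an exon table
#'
#' The central container of txbench. An annotation is a flat exon table
#' (one row per exon) with columns `transcript_id`, `gene_id`, `chrom`,
#' `strand`, `start`, `end`, where `start`/`end` are 0-based half-open
#' genomic coordinates. Exons are validated per transcript: sorted,
#' non-overlapping, separated by at least one base (introns have positive
#' length), and all exons of a gene share chromosome and strand.
#'
#' @param exons data.frame/data.table with the six columns above.
#' @param validate logical; skip validation only for internally-built tables.
#' @return An object of class `tx_annotation` (a keyed data.table).
#' @export
tx_annotation <- function(exons, validate = TRUE) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop_txbench("exon table lacks column(s): ", paste(miss, collapse = ", "))
  ex <- as.data.table(exons)[, .(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = as.integer(start),
    end = as.integer(end))]
  setorder(ex, chrom, transcript_id, start)
  if (validate) validate_annotation(ex)
  setattr(ex, "class", c("tx_annotation", class(data.table())))
  ex[]
}

validate_annotation <- function(ex) {
  if (!all(ex$strand %in% c("+", "-", ".")))
    stop_txbench("strand must be one of '+', '-', '.'")
  if (any(ex$start >= ex$end))
    stop_txbench("exon with start >= end (coordinates are 0-based half-open)")
  bad <- ex[, {
    ok_chain <- all(start[-1] > end[-.N]) # sorted, disjoint, intron >= 1
    ok_one <- uniqueN(chrom) == 1L && uniqueN(strand) == 1L &&
      uniqueN(gene_id) == 1L
    .(ok = ok_chain && ok_one)
  }, by = transcript_id][!(ok)]
  if (nrow(bad))
    stop_txbench("invalid exon structure in transcript(s): ",
                 paste(head(bad$transcript_id, 5), collapse = ", "))
  gb <- unique(ex[, .(transcript_id, gene_id, chrom, strand)])
  gbad <- gb[, .(ok = uniqueN(chrom) == 1L && uniqueN(strand) == 1L),
             by = gene_id][!(ok)]
  if (nrow(gbad))
    stop_txbench("transcripts of gene(s) ", paste(head(gbad$gene_id, 5),
                 collapse = ", "), " disagree on chrom/strand")
  invisible(ex)
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("<tx_annotation> %d exons, %d transcripts, %d genes, %d chromosome(s)\n",
              nrow(x), uniqueN(x$transcript_id), uniqueN(x$gene_id),
              uniqueN(x$chrom)))
  invisible(x)
}

#' Per-transcript summary table
#'
#' One row per transcript: exon count, spliced length, genomic span and the
#' junction-chain key used for matching.
#'
#' @param ann a `tx_annotation`.
#' @return data.table with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `n_exons`, `length`, `tx_start`, `tx_end`, `chain`,
#'   `chain_key`.
#' @export
transcripts_tbl <- function(ann) {
  tt <- ann[, .(
    gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
    n_exons = .N, length = sum(end - start),
    ## .N guard: data.table probes j on a 0-row group for typing
    tx_start = if (.N) min(start) else NA_integer_,
    tx_end = if (.N) max(end) else NA_integer_,
    chain = chain_string(start, end)
  ), by = transcript_id]
  tt[, chain_key := paste(chrom, strand, chain, sep = "|")]
  setattr(tt, "class", class(data.table()))  # plain table out
  tt[]
}

## junction chain of one transcript given its sorted exon starts/ends:
## "(end of exon i)-(start of exon i+1)" pairs, comma separated; "" if
## single exon.
chain_string <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return("")
  paste(ends[-n], starts[-1L], sep = "-", collapse = ",")
}

#' Junction chain of a transcript
#'
#' The ordered internal exon/exon boundary pairs of a transcript — the
#' identity under which predictions are matched to truth. A transcript with
#' n exons yields n-1 junctions; a single-exon transcript yields the empty
#' chain. Junctions are genomic-coordinate pairs in ascending order on
#' either strand; the first exon's start and the last exon's end do not
#' enter the chain, so transcripts differing only in their transcription
#' start/end have equal chains.
#'
#' @param ann a `tx_annotation`.
#' @param transcript_id id of the transcript.
#' @return list of class `junction_chain` with fields `chrom`, `strand` and
#'   `junctions` (integer matrix, columns `donor`, `acceptor`; 0 rows for a
#'   single-exon transcript).
#' @export
junction_chain <- function(ann, transcript_id) {
  tid <- transcript_id
  ex <- ann[ann$transcript_id == tid]
  if (!nrow(ex)) stop_txbench("unknown transcript: ", tid)
  setorder(ex, start)
  n <- nrow(ex)
  j <- if (n < 2L)
    matrix(integer(), 0L, 2L, dimnames = list(NULL, c("donor", "acceptor")))
  else
    cbind(donor = ex$end[-n], acceptor = ex$start[-1L])
  structure(list(chrom = ex$chrom[1L], strand = ex$strand[1L], junctions = j),
            class = "junction_chain")
}

#' @export
print.junction_chain <- function(x, ...) {
  cat(sprintf("<junction_chain> %s(%s): %d junction(s)\n",
              x$chrom, x$strand, nrow(x$junctions)))
  if (nrow(x$junctions))
    cat(" ", paste(x$junctions[, 1], x$junctions[, 2], sep = "-",
                   collapse = ", "), "\n")
  invisible(x)
}

## structural identity of a transcript: chain plus terminal coordinates.
## Two forms of one gene must differ on this key (forms may share all
## junctions as long as the transcription start/end differ).
structure_key <- function(starts, ends) {
  paste(chain_string(starts, ends), starts[1L], ends[length(ends)],
        sep = "@")
}

## lightweight transcript view used by the variant designer: exon matrix
## plus identity; avoids data.table overhead in per-gene loops.
tx_view <- function(ann_tt, ann) {
  split_ex <- split(ann[, .(start, end)], ann$transcript_id)
  lapply(setNames(ann_tt$transcript_id, ann_tt$transcript_id), function(tid) {
    ex <- as.matrix(split_ex[[tid]])
    i <- ann_tt[transcript_id == tid]
    list(transcript_id = tid, gene_id = i$gene_id, chrom = i$chrom,
         strand = i$strand, exons = ex[order(ex[, 1L]), , drop = FALSE])
  })
}

## rebuild an exon data.table from a list of tx views
tx_views_to_annotation <- function(views, validate = TRUE) {
  parts <- lapply(views, function(v)
    data.table(transcript_id = v$transcript_id, gene_id = v$gene_id,
               chrom = v$chrom, strand = v$strand,
               start = v$exons[, 1L], end = v$exons[, 2L]))
  tx_annotation(rbindlist(parts), validate = validate)
}
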