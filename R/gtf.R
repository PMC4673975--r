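## GTF/GFF3 annotation I/O.
##
## GTF is 1-based inclusive; internal coordinates are 0-based half-open.
## The conversion happens here and only here.

#' Read a GTF annotation
#'
#' Exon features are grouped into transcripts by `transcript_id` and into
#' genes by `gene_id`. Transcript/gene feature lines without any exon line
#' are dropped with a warning. Non-exon features (CDS, UTR, ...) are
#' ignored.
#'
#' @param path GTF file (GTF2.2 dialect; exon features must carry
#'   `gene_id` and `transcript_id` attributes).
#' @return a [tx_annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_txbench("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop_txbench("malformed GTF '", path, "': ",
                                conditionMessage(e)))
  df <- as.data.table(as.data.frame(gr))
  if (!nrow(df)) stop_txbench("GTF '", path, "' contains no features")
  ex <- df[type == "exon"]
  if (!nrow(ex)) stop_txbench("GTF '", path, "' contains no exon features")
  if (!"transcript_id" %in% names(ex) || anyNA(ex$transcript_id))
    stop_txbench("GTF '", path, "': exon feature lacks transcript_id")
  if (!"gene_id" %in% names(ex) || anyNA(ex$gene_id))
    stop_txbench("GTF '", path, "': exon feature lacks gene_id")
  declared <- if ("transcript" %in% df$type)
    unique(df[type == "transcript", as.character(transcript_id)]) else character()
  orphan <- setdiff(declared, unique(ex$transcript_id))
  if (length(orphan)) {
    warning(sprintf("dropping %d transcript(s) without exon features (e.g. %s)",
                    length(orphan), orphan[1L]), call. = FALSE)
  }
  tx_annotation(ex[, .(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(seqnames),
    strand = as.character(strand),
    start = as.integer(start) - 1L,    # GTF 1-based inclusive -> 0-based half-open
    end = as.integer(end))])
}

#' Read a GFF3 annotation (thin shim)
#'
#' Maps GFF3 `Parent`/`ID` attributes onto `transcript_id`/`gene_id`: each
#' exon's `Parent` is its transcript, and the transcript feature's own
#' `Parent` (when present) is its gene. Output is always written as GTF.
#'
#' @param path GFF3 file.
#' @return a [tx_annotation()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_txbench("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop_txbench("malformed GFF3 '", path, "': ",
                                conditionMessage(e)))
  df <- as.data.table(as.data.frame(gr))
  ex <- df[type == "exon"]
  if (!nrow(ex)) stop_txbench("GFF3 '", path, "' contains no exon features")
  tid <- vapply(ex$Parent, function(p) as.character(p)[1L], character(1))
  if (anyNA(tid) || any(tid == ""))
    stop_txbench("GFF3 '", path, "': exon feature lacks Parent")
  ## transcript -> gene map from mRNA/transcript features
  txf <- df[type %in% c("mRNA", "transcript") & !is.na(ID)]
  t2g <- if (nrow(txf)) {
    g <- vapply(txf$Parent, function(p) {
      p <- as.character(p); if (length(p)) p[1L] else NA_character_
    }, character(1))
    setNames(g, as.character(txf$ID))
  } else c()
  gid <- unname(t2g[tid])
  gid[is.na(gid)] <- tid[is.na(gid)]
  tx_annotation(data.table(
    transcript_id = tid, gene_id = gid,
    chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
    start = as.integer(ex$start) - 1L, end = as.integer(ex$end)))
}

#' Write an annotation as GTF
#'
#' Emits exon features only, 1-based inclusive coordinates, transcripts
#' sorted by chromosome, genomic start and id. Output bytes are a
#' deterministic function of the annotation.
#'
#' @param ann a [tx_annotation()].
#' @param path output file.
#' @param source value of the GTF source column.
#' @export
write_gtf <- function(ann, path, source = "txbench") {
  stopifnot(inherits(ann, "tx_annotation"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop_txbench("cannot write: ", path))
  on.exit(close(con))
  writeLines("#gtf-version 2.2", con, sep = "\n")
  if (!nrow(ann)) return(invisible(path))
  ex <- copy(ann)
  tt <- ex[, .(tx_start = min(start)), by = .(transcript_id, chrom)]
  setorder(tt, chrom, tx_start, transcript_id)
  ex[, exon_rank := seq_len(.N), by = transcript_id]
  setkey(ex, transcript_id)
  ex <- ex[tt$transcript_id]    # transcript blocks in canonical order
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\";",
    ex$chrom, source, ex$start + 1L, ex$end, ex$strand,
    ex$gene_id, ex$transcript_id, ex$exon_rank)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
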