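## Minimal SAM handling for base-level alignment accuracy.
##
## Only the fields the accuracy metric needs are parsed: read id, flag,
## chromosome, 1-based position, CIGAR. A sequenced base is "accurate"
## iff the test alignment places it at the same reference coordinate as
## the truth alignment; the denominator is the number of truth-aligned
## bases, so unaligned or missing reads count against accuracy.

#' Read the alignment records of a SAM file
#'
#' @param path SAM text file.
#' @return data.table `qname`, `flag`, `rname`, `pos` (1-based), `cigar`,
#'   plus derived `mate` (1/2), `reversed`, `unmapped`, `read_len`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop_txbench("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), mate = integer(),
                      reversed = logical(), unmapped = logical(),
                      read_len = integer()))
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  d <- data.table(qname = f[[1]], flag = as.integer(f[[2]]),
                  rname = f[[3]], pos = as.integer(f[[4]]),
                  cigar = f[[6]], seq = f[[10]])
  d[, mate := fifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)]
  d[, reversed := bitwAnd(flag, 16L) > 0L]
  d[, unmapped := bitwAnd(flag, 4L) > 0L | cigar == "*"]
  d[, read_len := nchar(seq)]
  d[, seq := NULL]
  d[]
}

## split a CIGAR string into ops and lengths
parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) stop_txbench("unparsable CIGAR: ", cigar)
  list(op = substring(ops, nchar(ops)),
       len = as.integer(substring(ops, 1L, nchar(ops) - 1L)))
}

## per-base placement of one record: data.table(qidx, ref) where qidx is
## the base index in the *original read orientation* (1-based) and ref
## the 0-based reference coordinate; only aligned (M/=/X) bases appear.
sam_base_map <- function(qname, mate, rname, pos, cigar, reversed,
                         read_len) {
  cg <- parse_cigar(cigar)
  q <- 0L                       # query cursor in SEQ orientation
  r <- pos - 1L                 # 0-based reference cursor
  qidx <- integer(0); ref <- integer(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      qidx <- c(qidx, (q + 1L):(q + len))
      ref <- c(ref, r:(r + len - 1L))
      q <- q + len; r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }                            # H/P consume nothing we track
  }
  if (reversed) qidx <- read_len + 1L - qidx
  data.table(rid = paste0(qname, "/", mate), qidx = qidx,
             chrom = rname, ref = ref)
}

sam_base_table <- function(d) {
  d <- d[unmapped == FALSE]
  if (!nrow(d)) return(data.table(rid = character(), qidx = integer(),
                                  chrom = character(), ref = integer()))
  rbindlist(lapply(seq_len(nrow(d)), function(i)
    sam_base_map(d$qname[i], d$mate[i], d$rname[i], d$pos[i], d$cigar[i],
                 d$reversed[i], d$read_len[i])))
}

#' Base-level alignment accuracy against a truth alignment
#'
#' @param test_sam path to the alignment under evaluation.
#' @param truth_sam path to the truth alignment.
#' @return proportion of truth-aligned bases that the test alignment
#'   places at the correct reference coordinate (unaligned or missing
#'   reads contribute inaccurate bases).
#' @export
alignment_base_accuracy <- function(test_sam, truth_sam) {
  truth <- read_sam(truth_sam)
  test <- read_sam(test_sam)
  mate_key <- function(d)
    if (!nrow(d)) character(0) else unique(paste0(d$qname, "/", d$mate))
  truth_keys <- mate_key(truth)
  test_keys <- mate_key(test)
  extra <- setdiff(test_keys, truth_keys)
  if (length(extra))
    stop_txbench("read(s) present in test but absent from truth: ",
                 paste(head(extra, 3), collapse = ", "))
  tb <- sam_base_table(truth)
  if (!nrow(tb)) stop_txbench("truth SAM has no aligned bases")
  eb <- sam_base_table(test)
  j <- merge(tb, eb, by = c("rid", "qidx", "chrom"),
             suffixes = c("_t", ""), all.x = TRUE)
  sum(!is.na(j$ref) & j$ref == j$ref_t) / nrow(tb)
}
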