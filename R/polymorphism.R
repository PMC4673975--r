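## Polymorphic-haplotype construction and reference<->haplotype coordinate
## mapping.
##
## Reads are sequenced from a polymorphic copy of the genome (one
## haplotype), while truth alignments and the truth annotation are
## expressed against the reference, so the evaluator can compare aligner
## output directly. The bridge is a per-chromosome alignment of the two
## genomes stored as ordered runs: M (both advance), I (insertion — the
## haplotype advances), D (deletion — the reference advances). All
## coordinates are 0-based half-open.

#' Apply substitutions and indels to a genome
#'
#' Each reference base is independently substituted with probability
#' `substitution_frequency` (to a uniformly chosen different base). Indel
#' events are seeded per base with probability `indel_frequency`; each is
#' an insertion or a deletion with equal odds, of length uniform on
#' {1, 2, 3} (small indels dominate real polymorphism). Overlapping indel
#' seeds are dropped left-to-right.
#'
#' @param genome named `DNAStringSet` (reference).
#' @param substitution_frequency,indel_frequency per-base event
#'   probabilities.
#' @param seed RNG seed.
#' @return list with `genome` (polymorphic haplotype), `map` (a
#'   `coordinate_map`) and `variants` (data.table: `chrom`, `type`
#'   in sub/ins/del, `ref_pos`, `len`, `ref_allele`, `alt_allele`).
#' @export
apply_polymorphisms <- function(genome, substitution_frequency = 0,
                                indel_frequency = 0, seed = 1L) {
  validate_genome(genome)
  stopifnot(substitution_frequency >= 0, substitution_frequency <= 1,
            indel_frequency >= 0, indel_frequency <= 1)
  if (substitution_frequency == 0 && indel_frequency == 0) {
    return(list(genome = genome, map = identity_map(genome),
                variants = empty_variants()))
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed_stream(seed, "polymorphism"), {
    out_seq <- character(length(genome))
    runs <- vector("list", length(genome))
    vars <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      chrom <- names(genome)[ci]
      s <- as.character(genome[[ci]])
      L <- nchar(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]

      vtab <- list()
      if (substitution_frequency > 0) {
        pos <- which(runif(L) < substitution_frequency)       # 1-based
        pos <- pos[ch[pos] != "N"]
        if (length(pos)) {
          old <- ch[pos]
          new <- vapply(old, function(b) sample(setdiff(bases, b), 1L),
                        character(1))
          ch[pos] <- new
          vtab <- c(vtab, list(data.table(
            chrom = chrom, type = "sub", ref_pos = pos - 1L, len = 1L,
            ref_allele = old, alt_allele = new)))
        }
      }

      ins_at <- integer(); ins_seq <- character()
      del_at <- integer(); del_len <- integer()
      if (indel_frequency > 0) {
        sites <- which(runif(L) < indel_frequency)            # 1-based
        if (length(sites)) {
          is_ins <- runif(length(sites)) < 0.5
          lens <- sample.int(3L, length(sites), replace = TRUE)
          ## drop overlapping deletions left-to-right
          last_end <- -1L
          keep <- logical(length(sites))
          for (k in seq_along(sites)) {
            s0 <- sites[k] - 1L                               # 0-based
            if (s0 <= last_end) next
            keep[k] <- TRUE
            if (!is_ins[k]) last_end <- s0 + lens[k] - 1L
            else last_end <- s0 - 1L
          }
          sites <- sites[keep]; is_ins <- is_ins[keep]; lens <- lens[keep]
          del <- !is_ins & (sites - 1L + lens) <= L
          ins_at <- sites[is_ins] - 1L                        # insert before
          ins_seq <- vapply(lens[is_ins], function(l)
            paste(sample(bases, l, replace = TRUE), collapse = ""),
            character(1))
          del_at <- sites[del] - 1L
          del_len <- lens[del]
          if (length(ins_at))
            vtab <- c(vtab, list(data.table(
              chrom = chrom, type = "ins", ref_pos = ins_at,
              len = lens[is_ins], ref_allele = "", alt_allele = ins_seq)))
          if (length(del_at))
            vtab <- c(vtab, list(data.table(
              chrom = chrom, type = "del", ref_pos = del_at, len = del_len,
              ref_allele = substring(s, del_at + 1L, del_at + del_len),
              alt_allele = "")))
        }
      }

      built <- build_haplotype(ch, L, ins_at, ins_seq, del_at, del_len)
      built$runs[, chrom := chrom]
      out_seq[ci] <- built$seq
      runs[[ci]] <- built$runs
      vars[[ci]] <- if (length(vtab)) rbindlist(vtab) else empty_variants()
    }
    map <- structure(list(runs = rbindlist(runs)), class = "coordinate_map")
    variants <- rbindlist(vars)
    setorder(variants, chrom, ref_pos)
    list(genome = setNames(Biostrings::DNAStringSet(out_seq), names(genome)),
         map = map, variants = variants)
  })
}

empty_variants <- function() {
  data.table(chrom = character(), type = character(), ref_pos = integer(),
             len = integer(), ref_allele = character(),
             alt_allele = character())
}

## assemble the haplotype string and the run table from indel events
build_haplotype <- function(ch, L, ins_at, ins_seq, del_at, del_len) {
  ev <- data.table(pos = c(ins_at, del_at),
                   is_ins = rep(c(TRUE, FALSE), c(length(ins_at),
                                                  length(del_at))),
                   len = c(nchar(ins_seq), del_len),
                   seq = c(ins_seq, rep("", length(del_at))))
  setorder(ev, pos)
  pieces <- character(0)
  runs <- list()
  ref_cur <- 0L; poly_cur <- 0L
  for (k in seq_len(nrow(ev))) {
    p <- ev$pos[k]
    if (p > ref_cur) {                       # M run up to the event
      mlen <- p - ref_cur
      pieces <- c(pieces, paste(ch[(ref_cur + 1L):p], collapse = ""))
      runs <- c(runs, list(data.table(type = "M", len = mlen,
                                      ref_start = ref_cur,
                                      poly_start = poly_cur)))
      ref_cur <- p; poly_cur <- poly_cur + mlen
    }
    if (ev$is_ins[k]) {
      pieces <- c(pieces, ev$seq[k])
      runs <- c(runs, list(data.table(type = "I", len = ev$len[k],
                                      ref_start = ref_cur,
                                      poly_start = poly_cur)))
      poly_cur <- poly_cur + ev$len[k]
    } else {
      runs <- c(runs, list(data.table(type = "D", len = ev$len[k],
                                      ref_start = ref_cur,
                                      poly_start = poly_cur)))
      ref_cur <- ref_cur + ev$len[k]
    }
  }
  if (ref_cur < L) {
    pieces <- c(pieces, paste(ch[(ref_cur + 1L):L], collapse = ""))
    runs <- c(runs, list(data.table(type = "M", len = L - ref_cur,
                                    ref_start = ref_cur,
                                    poly_start = poly_cur)))
  }
  list(seq = paste(pieces, collapse = ""), runs = rbindlist(runs))
}

#' Identity coordinate map for a genome
#' @param genome named `DNAStringSet`.
#' @export
identity_map <- function(genome) {
  runs <- data.table(type = "M", len = as.integer(Biostrings::width(genome)),
                     ref_start = 0L, poly_start = 0L,
                     chrom = names(genome))
  structure(list(runs = runs), class = "coordinate_map")
}

map_is_identity <- function(map, chrom) {
  r <- map$runs[map$runs$chrom == chrom]
  nrow(r) == 1L && r$type == "M"
}

## M runs of one chromosome, ordered
map_m_runs <- function(map, chrom) {
  r <- map$runs[map$runs$chrom == chrom & map$runs$type == "M"]
  setorder(r, poly_start)
  r
}

#' Map haplotype coordinates to reference coordinates
#'
#' Positions falling inside an insertion (no reference base) snap to the
#' next reference coordinate, which makes the map usable for half-open
#' interval endpoints on either side.
#'
#' @param map a `coordinate_map`.
#' @param chrom chromosome.
#' @param pos 0-based haplotype positions.
#' @return 0-based reference positions.
#' @export
poly_to_ref <- function(map, chrom, pos) {
  m <- map_m_runs(map, chrom)
  i <- findInterval(pos, m$poly_start)
  out <- integer(length(pos))
  inside <- i >= 1L & pos < (m$poly_start[pmax(i, 1L)] + m$len[pmax(i, 1L)])
  out[inside] <- m$ref_start[i[inside]] + (pos[inside] - m$poly_start[i[inside]])
  snap <- which(!inside)                    # in an insertion (or before run 1)
  for (k in snap) {
    j <- i[k] + 1L
    out[k] <- if (j <= nrow(m)) m$ref_start[j]
              else m$ref_start[nrow(m)] + m$len[nrow(m)]
  }
  out
}

#' Map reference coordinates to haplotype coordinates
#'
#' Positions inside a deletion snap right to the next haplotype base.
#' @inheritParams poly_to_ref
#' @param pos 0-based reference positions.
#' @export
ref_to_poly <- function(map, chrom, pos) {
  m <- map_m_runs(map, chrom)
  setorder(m, ref_start)
  i <- findInterval(pos, m$ref_start)
  out <- integer(length(pos))
  inside <- i >= 1L & pos < (m$ref_start[pmax(i, 1L)] + m$len[pmax(i, 1L)])
  out[inside] <- m$poly_start[i[inside]] + (pos[inside] - m$ref_start[i[inside]])
  snap <- which(!inside)
  for (k in snap) {
    j <- i[k] + 1L
    out[k] <- if (j <= nrow(m)) m$poly_start[j]
              else m$poly_start[nrow(m)] + m$len[nrow(m)]
  }
  out
}

## CIGAR-style ops for one haplotype interval [ps, pe) against the
## reference: list(ops, lens, ref_start, ref_end). Leading/trailing
## insertions are reported as I here; the SAM writer soft-clips them.
map_poly_interval <- function(map, chrom, ps, pe) {
  stopifnot(pe > ps)
  if (map_is_identity(map, chrom))
    return(list(ops = "M", lens = pe - ps, ref_start = ps, ref_end = pe))
  r <- map$runs[map$runs$chrom == chrom]
  setorder(r, poly_start, ref_start)
  ops <- character(0); lens <- integer(0)
  ref_start <- NA_integer_; ref_end <- NA_integer_
  started <- FALSE
  for (k in seq_len(nrow(r))) {
    ty <- r$type[k]
    if (ty == "D") {
      ## zero haplotype extent: include only strictly inside the interval
      if (started && r$poly_start[k] > ps && r$poly_start[k] < pe) {
        ops <- c(ops, "D"); lens <- c(lens, r$len[k])
        ref_end <- r$ref_start[k] + r$len[k]
      }
      next
    }
    p0 <- r$poly_start[k]; p1 <- p0 + r$len[k]
    o0 <- max(p0, ps); o1 <- min(p1, pe)
    if (o0 >= o1) next
    if (ty == "M") {
      ops <- c(ops, "M"); lens <- c(lens, o1 - o0)
      rs <- r$ref_start[k] + (o0 - p0)
      if (is.na(ref_start)) ref_start <- rs
      ref_end <- rs + (o1 - o0)
      started <- TRUE
    } else {                                 # I
      ops <- c(ops, "I"); lens <- c(lens, o1 - o0)
      started <- TRUE
    }
  }
  ## merge adjacent identical ops (D dropped between clipped edges etc.)
  if (length(ops) > 1L) {
    keep_ops <- character(0); keep_lens <- integer(0)
    for (k in seq_along(ops)) {
      if (length(keep_ops) && keep_ops[length(keep_ops)] == ops[k])
        keep_lens[length(keep_lens)] <- keep_lens[length(keep_lens)] + lens[k]
      else {
        keep_ops <- c(keep_ops, ops[k]); keep_lens <- c(keep_lens, lens[k])
      }
    }
    ops <- keep_ops; lens <- keep_lens
  }
  ## a deletion is only meaningful between aligned bases: trim at edges
  while (length(ops) && ops[1L] == "D") {
    ref_start <- ref_start + lens[1L]
    ops <- ops[-1L]; lens <- lens[-1L]
  }
  while (length(ops) && ops[length(ops)] == "D") {
    ref_end <- ref_end - lens[length(ops)]
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  list(ops = ops, lens = lens, ref_start = ref_start, ref_end = ref_end)
}
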