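## Synthetic genome + base annotation fixtures.
##
## These stand in for a real reference genome and single-isoform gene set so
## that every downstream stage (truth design, simulation, corruption,
## evaluation) runs without any download. Sequence is i.i.d. with a chosen
## GC fraction; no splice-site motifs are written, because every stage of
## the toolkit scores coordinates, and only alignment — which txbench does
## not perform — could ever look at motifs.

#' Discrete length/count law
#'
#' A tiny container for the discrete distributions a fixture draws from
#' (exon counts, exon lengths, intron lengths). A point mass is
#' `discrete_law(k)`.
#'
#' @param values integer support.
#' @param weights sampling weights (default uniform).
#' @export
discrete_law <- function(values, weights = NULL) {
  values <- as.integer(values)
  if (!length(values) || any(values <= 0L))
    stop_txbench("law support must be positive")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0) ||
      sum(weights) <= 0)
    stop_txbench("invalid law weights")
  structure(list(values = values, weights = weights / sum(weights)),
            class = "discrete_law")
}

draw_law <- function(law, n) {
  if (length(law$values) == 1L) rep(law$values, n)
  else sample(law$values, n, replace = TRUE, prob = law$weights)
}

law_max <- function(law) max(law$values)

#' Fixture configuration
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome (bases).
#' @param n_genes number of (single-transcript, non-overlapping) genes.
#' @param exon_count_law,exon_length_law,intron_length_law discrete laws
#'   ([discrete_law()]) for exons per transcript and exon/intron lengths.
#' @param intergenic_gap_min minimum gap between consecutive genes; actual
#'   gaps are drawn uniformly in `[gap_min, 2*gap_min]`.
#' @param gc_fraction genome GC content in `[0,1]`.
#' @param seed RNG seed; the fixture is a deterministic function of the
#'   config.
#' @export
fixture_config <- function(n_chromosomes = 1L,
                           chromosome_length = 1e6L,
                           n_genes = 100L,
                           exon_count_law = discrete_law(5:9),
                           exon_length_law = discrete_law(c(100L, 150L, 200L, 300L)),
                           intron_length_law = discrete_law(c(200L, 500L, 1000L)),
                           intergenic_gap_min = 200L,
                           gc_fraction = 0.45,
                           seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1, n_genes >= 0,
            intergenic_gap_min >= 1,
            gc_fraction >= 0, gc_fraction <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 n_genes = as.integer(n_genes),
                 exon_count_law = exon_count_law,
                 exon_length_law = exon_length_law,
                 intron_length_law = intron_length_law,
                 intergenic_gap_min = as.integer(intergenic_gap_min),
                 gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Worst-case footprint of one fixture gene (bases, including its gap)
#'
#' Sizing a genome as `n_genes * fixture_gene_footprint(cfg)` guarantees by
#' construction that all genes fit.
#' @param config a [fixture_config()].
#' @export
fixture_gene_footprint <- function(config) {
  k <- law_max(config$exon_count_law)
  k * law_max(config$exon_length_law) +
    (k - 1L) * law_max(config$intron_length_law) +
    2L * config$intergenic_gap_min
}

#' Generate a synthetic genome
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc_fraction`, split evenly within
#' each pair. Chromosomes are named `chr1`, `chr2`, ...
#'
#' @param config a [fixture_config()].
#' @return named `DNAStringSet`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  gc <- config$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed_stream(config$seed, "genome"), {
    code <- as.raw(utf8ToInt("ACGT"))   # byte construction: fast at Mb scale
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      idx <- sample.int(4L, config$chromosome_length, replace = TRUE,
                        prob = p)
      rawToChar(code[idx])
    }, character(1))
    setNames(Biostrings::DNAStringSet(seqs),
             paste0("chr", seq_len(config$n_chromosomes)))
  })
}

#' Generate a single-isoform base annotation on a genome
#'
#' Genes are placed left-to-right greedily, never overlapping, separated by
#' gaps drawn uniformly in `[gap_min, 2*gap_min]`, spilling onto the next
#' chromosome when the current one is full. Strands are assigned uniformly.
#' Each gene has one transcript whose exon count and exon/intron lengths
#' come from the configured laws.
#'
#' @param genome named `DNAStringSet` (only lengths are used).
#' @param config a [fixture_config()].
#' @return a [tx_annotation()] of `n_genes` single-transcript genes.
#' @export
generate_annotation <- function(genome, config) {
  stopifnot(inherits(config, "fixture_config"))
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  n <- config$n_genes
  gap_min <- config$intergenic_gap_min
  with_seed(seed_stream(config$seed, "annotation"), {
    n_ex <- draw_law(config$exon_count_law, n)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    gaps <- floor(runif(n, gap_min, 2 * gap_min + 1))
    parts <- vector("list", n)
    ci <- 1L
    cursor <- 0L
    for (g in seq_len(n)) {
      k <- n_ex[g]
      ex_len <- draw_law(config$exon_length_law, k)
      in_len <- if (k > 1L) draw_law(config$intron_length_law, k - 1L) else integer()
      span <- sum(ex_len) + sum(in_len)
      placed <- FALSE
      while (!placed) {
        s0 <- cursor + gaps[g]
        if (ci > length(chrom_len))
          stop_txbench(sprintf(
            "genome too small for %d genes: need about %.0f more bases (worst-case footprint %d/gene)",
            n, (n - g + 1) * (span + gaps[g]), fixture_gene_footprint(config)))
        if (s0 + span <= chrom_len[ci]) {
          starts <- s0 + cumsum(c(0L, head(ex_len, -1L) + in_len))
          gid <- sprintf("G%05d", g)
          parts[[g]] <- data.table(
            transcript_id = paste0(gid, ".T1"), gene_id = gid,
            chrom = names(chrom_len)[ci], strand = strands[g],
            start = as.integer(starts),
            end = as.integer(starts + ex_len))
          cursor <- s0 + span
          placed <- TRUE
        } else {            # next chromosome
          ci <- ci + 1L
          cursor <- 0L
        }
      }
    }
    tx_annotation(rbindlist(parts))
  })
}

#' Write/read a fixture config as YAML
#' @param config a [fixture_config()]; laws are stored as value/weight lists.
#' @param path YAML file.
#' @export
write_fixture_config <- function(config, path) {
  x <- config
  for (f in c("exon_count_law", "exon_length_law", "intron_length_law"))
    x[[f]] <- list(values = x[[f]]$values, weights = x[[f]]$weights)
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_fixture_config
#' @export
read_fixture_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("exon_count_law", "exon_length_law", "intron_length_law"))
    x[[f]] <- discrete_law(x[[f]]$values, x[[f]]$weights)
  do.call(fixture_config, x)
}
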