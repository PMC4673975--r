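## Expression models: per-transcript molecule weights.

#' Uniform-coverage expression model
#'
#' Every transcript is expressed at the same high per-base depth. Molecule
#' weights are proportional to spliced length, so expected fragment counts
#' scale with length and expected coverage is flat; the fragment count that
#' realises `target_coverage` is solved by [solve_n_fragments()].
#'
#' @param target_coverage expected per-base fold coverage (default 40).
#' @export
uniform_coverage <- function(target_coverage = 40) {
  stopifnot(target_coverage > 0)
  structure(list(target_coverage = target_coverage),
            class = c("uniform_coverage", "expression_model"))
}

#' Exponential expression model
#'
#' Each transcript is independently expressed with probability
#' `expressed_fraction`; expressed transcripts draw a molecule weight from
#' Exponential(rate), unexpressed transcripts get weight zero. The default
#' rate 0.01 gives a realistic long-tailed intensity spectrum (mean weight
#' 100); two-thirds expressed matches quality bulk data.
#'
#' @param rate exponential rate of expressed-transcript weights.
#' @param expressed_fraction probability a transcript is expressed.
#' @export
exponential_expression <- function(rate = 0.01, expressed_fraction = 2 / 3) {
  stopifnot(rate > 0, expressed_fraction >= 0, expressed_fraction <= 1)
  structure(list(rate = rate, expressed_fraction = expressed_fraction),
            class = c("exponential_expression", "expression_model"))
}

#' Assign per-transcript expression weights
#'
#' @param truth a `truth_annotation` or [tx_annotation()].
#' @param model an expression model ([uniform_coverage()] or
#'   [exponential_expression()]).
#' @param seed RNG seed (only the exponential model is random).
#' @return data.table `transcript_id`, `weight` (relative molecule
#'   abundance, >= 0).
#' @export
assign_expression <- function(truth, model, seed = 1L) {
  ann <- if (inherits(truth, "truth_annotation")) truth$annotation else truth
  tt <- transcripts_tbl(ann)
  if (!nrow(tt)) stop_txbench("empty truth annotation")
  if (inherits(model, "uniform_coverage")) {
    prof <- tt[, .(transcript_id, weight = as.numeric(length))]
  } else if (inherits(model, "exponential_expression")) {
    prof <- with_seed(seed_stream(seed, "expression"), {
      on <- runif(nrow(tt)) < model$expressed_fraction
      w <- numeric(nrow(tt))
      w[on] <- rexp(sum(on), rate = model$rate)
      tt[, .(transcript_id, weight = w)]
    })
  } else stop_txbench("unknown expression model")
  if (!any(prof$weight > 0))
    stop_txbench("expression profile has no expressed transcript")
  prof[]
}

#' Fragment count realising a target uniform coverage
#'
#' `ceiling(target_coverage * total spliced length / (2 * read_length))`:
#' each fragment contributes two mates of `read_length` sequenced bases.
#'
#' @param truth truth annotation (any form accepted by
#'   [assign_expression()]).
#' @param target_coverage fold coverage.
#' @param read_length bases per mate.
#' @export
solve_n_fragments <- function(truth, target_coverage = 40,
                              read_length = 100L) {
  ann <- if (inherits(truth, "truth_annotation")) truth$annotation else truth
  total <- sum(as.numeric(ann$end - ann$start))
  as.integer(ceiling(target_coverage * total / (2 * read_length)))
}
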