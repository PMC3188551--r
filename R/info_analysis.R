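# Quantised single-cell stimulus-specific information.
#
# The two 40-transform spaces are near-continuous, so for information
# analysis one space is quantised into five contiguous blocks of eight
# transforms; the central transform of each block, combined with all 40
# transforms of the other space, defines 5 stimuli x 40 transforms = 200
# test faces.  For each output cell the discretised responses r give
#   I(s, R) = sum_r P(r|s) log2( P(r|s) / P(r) )
# (stimulus-specific information), and the single-cell information is the
# maximum of I(s, R) over the five stimuli, bounded by log2(5) = 2.32 bits.
# A cell that fires for all transforms of exactly one stimulus and never
# otherwise attains the bound.

#' Quantise a transform space into contiguous stimulus blocks
#'
#' @param n_transforms number of transforms (default 40).
#' @param n_blocks number of stimulus blocks (default 5); must divide
#'   `n_transforms`.
#' @return list with `n_transforms`, `n_blocks`, `block_size`, `blocks`
#'   (list of index vectors) and `central` (the central transform of each
#'   block, the `ceiling(block_size / 2)`-th element; the 4th of each block
#'   of 8 at the defaults, i.e. 4, 12, 20, 28, 36).
#' @export
quantise_space <- function(n_transforms = 40L, n_blocks = 5L) {
  if (n_transforms %% n_blocks != 0L)
    stop("n_blocks must divide n_transforms", call. = FALSE)
  bs <- n_transforms %/% n_blocks
  blocks <- lapply(seq_len(n_blocks), function(b) ((b - 1L) * bs + 1L):(b * bs))
  list(n_transforms = as.integer(n_transforms),
       n_blocks = as.integer(n_blocks), block_size = as.integer(bs),
       blocks = blocks,
       central = vapply(blocks, function(b) b[ceiling(bs / 2)], integer(1)))
}

#' Discretise recorded responses into a response table
#'
#' @param responses numeric matrix of firing rates in `[0, 1]`, one row per
#'   cell and one column per presentation, columns ordered stimulus-major
#'   (all transforms of stimulus 1, then stimulus 2, ...).
#' @param scheme a [quantise_space()] scheme (its `n_blocks` and the
#'   transform count per stimulus must match `ncol(responses)`).
#' @param n_bins number of equal-width response bins; the default 2
#'   binarises firing at 0.5, matching the near-binary firing regime.
#' @return integer array `n_cells x n_blocks x n_transforms` of bin codes
#'   (1..n_bins), class `"response_table"`.
#' @export
build_response_table <- function(responses, scheme, n_bins = 2L) {
  ns <- scheme$n_blocks
  nt <- ncol(responses) / ns
  if (nt != round(nt))
    stop("response columns must be a multiple of the number of stimuli",
         call. = FALSE)
  if (any(responses < 0 | responses > 1))
    stop("responses must lie in [0, 1]", call. = FALSE)
  bins <- pmin(pmax(ceiling(responses * n_bins), 1L), n_bins)
  # columns run transform-fastest within stimulus; make dims (cell, s, t)
  tab <- aperm(array(as.integer(bins), dim = c(nrow(responses), nt, ns)),
               c(1L, 3L, 2L))
  structure(tab, n_bins = as.integer(n_bins),
            class = c("response_table", "array"))
}

#' Stimulus-specific information of one cell about one stimulus
#'
#' Computes `I(s, R) = sum_r P(r|s) log2(P(r|s) / P(r))` from the
#' discretised response table; `P(r|s)` is estimated over the transforms of
#' stimulus `s` and `P(r)` by pooling all presentations (stimuli are
#' equiprobable by design).  Terms with `P(r|s) = 0` contribute zero.
#'
#' @param table a `"response_table"`.
#' @param cell cell index (row of the table).
#' @param s stimulus index in `1..n_blocks`.
#' @return information in bits (non-negative).
#' @export
stimulus_specific_information <- function(table, cell, s) {
  d <- dim(table)
  if (d[3L] < 1L) stop("empty response set", call. = FALSE)
  rs <- table[cell, s, ]
  rall <- table[cell, , ]
  n_bins <- attr(table, "n_bins")
  p_rs <- tabulate(rs, n_bins) / length(rs)
  p_r <- tabulate(rall, n_bins) / length(rall)
  keep <- p_rs > 0
  sum(p_rs[keep] * log2(p_rs[keep] / p_r[keep]))
}

#' Single-cell information
#'
#' The maximum stimulus-specific information the cell conveys about any one
#' stimulus over all transforms; bounded by `log2(n_blocks)`.
#'
#' @param table a `"response_table"`.
#' @param cell cell index.
#' @return information in bits.
#' @export
single_cell_information <- function(table, cell) {
  max(vapply(seq_len(dim(table)[2L]), function(s)
    stimulus_specific_information(table, cell, s), numeric(1)))
}

#' Record the quantised-space test responses of the output layer
#'
#' Presents the 5 central transforms of the analysed space combined with
#' every transform of the other space (complete faces) and records output
#' firing, ordered stimulus-major.
#'
#' @param model a `"som_network"`.
#' @param space `"identity"` or `"expression"`: the space being quantised
#'   and analysed; the other space provides the transforms.
#' @param scheme optional [quantise_space()] scheme (defaults to the
#'   configured block count over the configured transform count).
#' @return numeric response matrix `n_cells x (n_blocks * n_transforms)`.
#' @export
quantised_responses <- function(model, space = c("identity", "expression"),
                                scheme = NULL) {
  space <- match.arg(space)
  st <- model$config$stimuli
  n_analysed <- if (space == "identity") st$n_identity else st$n_expression
  n_other <- if (space == "identity") st$n_expression else st$n_identity
  if (is.null(scheme))
    scheme <- quantise_space(n_analysed, model$config$analysis$n_blocks)
  imgs <- list()
  for (s in scheme$central) for (t in seq_len(n_other)) {
    imgs[[length(imgs) + 1L]] <- if (space == "identity")
      render_face(s, t, "complete", st$size, st$n_identity, st$n_expression)
    else
      render_face(t, s, "complete", st$size, st$n_identity, st$n_expression)
  }
  .output_responses(model, imgs)
}

#' Ranked single-cell information profile of the output layer
#'
#' Runs the quantised-space test, discretises responses, computes each
#' output cell's single-cell information and sorts it in descending order;
#' also counts the cells at the information ceiling `log2(n_blocks)`.
#'
#' @param model a `"som_network"` (trained or untrained).
#' @param space `"identity"` or `"expression"`.
#' @param n_bins response bins (default 2: binarised firing).
#' @param responses optional precomputed [quantised_responses()] matrix.
#' @return list with `information` (descending per-cell bits), `order`
#'   (cell indices in rank order), `ceiling` (`log2(n_blocks)`),
#'   `n_at_ceiling` (cells within 1e-6 of the ceiling), `space`.
#' @export
ranked_information_profile <- function(model,
                                       space = c("identity", "expression"),
                                       n_bins = 2L, responses = NULL) {
  space <- match.arg(space)
  st <- model$config$stimuli
  n_analysed <- if (space == "identity") st$n_identity else st$n_expression
  scheme <- quantise_space(n_analysed, model$config$analysis$n_blocks)
  if (is.null(responses)) responses <- quantised_responses(model, space, scheme)
  tab <- build_response_table(responses, scheme, n_bins)
  info <- vapply(seq_len(dim(tab)[1L]), function(i)
    single_cell_information(tab, i), numeric(1))
  ord <- order(info, decreasing = TRUE)
  ceiling_bits <- log2(scheme$n_blocks)
  list(information = info[ord], order = ord, ceiling = ceiling_bits,
       n_at_ceiling = sum(abs(info - ceiling_bits) < 1e-6), space = space)
}
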