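# Firing-rate response analyses of the output layer.
#
# After training, output cells are probed with (i) the complete faces used
# in training, giving a 2-D response matrix over the identity x expression
# grid per cell (identity-selective cells appear as vertical bars, i.e.
# near-constant over expression; expression-selective cells as horizontal
# bars), and (ii) the isolated identity-only / expression-only feature
# images, giving two tuning curves per cell from which cells are classified
# into identity-selective, expression-selective, dual, multi-region or
# unresponsive.  A join-count permutation statistic quantifies the spatial
# clustering of cell preferences across the output sheet.

# output-layer firing for a list of stimulus images (one column per image)
.output_responses <- function(model, images, up_to_layer = 4L) {
  cfg <- model$config
  lc <- cfg$layers[[up_to_layer]]
  out <- matrix(0, prod(lc$dims), length(images))
  for (k in seq_along(images)) {
    rc <- apply_filterbank(images[[k]], normalise = cfg$retina$normalise)
    out[, k] <- as.vector(forward_pass(rc, model, up_to_layer)[[up_to_layer]])
  }
  out
}

#' Response matrices to the complete faces
#'
#' Presents every complete face of the configured grid and records output
#' firing; no weights are modified.
#'
#' @param model a `"som_network"` (trained or untrained).
#' @param stimuli optional stimulus list (identity-major); generated from
#'   the model's configuration if `NULL`.
#' @return an array `n_cells x n_identity x n_expression` of firing rates in
#'   `[0, 1]`, class `"response_matrix"`.
#' @export
test_complete_faces <- function(model, stimuli = NULL) {
  st <- model$config$stimuli
  if (is.null(stimuli))
    stimuli <- generate_stimulus_set(st$n_identity, st$n_expression,
                                     "complete", st$size)
  if (length(stimuli) != st$n_identity * st$n_expression)
    stop("stimulus set incomplete", call. = FALSE)
  resp <- .output_responses(model, stimuli)
  out <- array(0, dim = c(nrow(resp), st$n_identity, st$n_expression))
  for (i in seq_len(st$n_identity)) for (e in seq_len(st$n_expression))
    out[, i, e] <- resp[, (i - 1L) * st$n_expression + e]
  structure(out, class = c("response_matrix", "array"))
}

#' Tuning curves to the isolated feature spaces
#'
#' Presents the identity-only images (all identity transforms) and the
#' expression-only images (all expression transforms) separately and records
#' output firing.
#'
#' @param model a `"som_network"`.
#' @return list with matrices `identity` (`n_cells x n_identity`) and
#'   `expression` (`n_cells x n_expression`), class `"tuning_curves"`.
#' @export
test_isolated_spaces <- function(model) {
  st <- model$config$stimuli
  id_imgs <- lapply(seq_len(st$n_identity), function(i)
    render_face(i, 1L, "identity_only", st$size, st$n_identity,
                st$n_expression))
  ex_imgs <- lapply(seq_len(st$n_expression), function(e)
    render_face(1L, e, "expression_only", st$size, st$n_identity,
                st$n_expression))
  structure(list(identity = .output_responses(model, id_imgs),
                 expression = .output_responses(model, ex_imgs)),
            class = "tuning_curves")
}

# maximal runs of consecutive supra-threshold transforms, minimum length
.count_regions <- function(curve, threshold, min_len) {
  r <- rle(curve > threshold)
  sum(r$values & r$lengths >= min_len)
}

#' Classify one output cell from its isolated-space tuning curves
#'
#' A cell "responds to a portion of a space" when its tuning curve has at
#' least one contiguous run of at least `min_len` transforms above
#' `threshold`.  One region in exactly one space gives identity- or
#' expression-selective; one region in each gives `dual`; more than one
#' region in either space gives `multi_region`; no region gives
#' `unresponsive`.
#'
#' @param identity_curve,expression_curve numeric vectors of firing in
#'   `[0, 1]`.
#' @param threshold response threshold (default 0.5, matching the
#'   near-binary firing regime).
#' @param min_len minimum contiguous run length (default 2).
#' @return one of `"identity_selective"`, `"expression_selective"`,
#'   `"dual"`, `"multi_region"`, `"unresponsive"`.
#' @export
classify_cell <- function(identity_curve, expression_curve, threshold = 0.5,
                          min_len = 2L) {
  stopifnot(all(identity_curve >= 0 & identity_curve <= 1),
            all(expression_curve >= 0 & expression_curve <= 1))
  ni <- .count_regions(identity_curve, threshold, min_len)
  ne <- .count_regions(expression_curve, threshold, min_len)
  if (ni > 1L || ne > 1L) return("multi_region")
  if (ni == 1L && ne == 1L) return("dual")
  if (ni == 1L) return("identity_selective")
  if (ne == 1L) return("expression_selective")
  "unresponsive"
}

#' Classify every output cell
#'
#' @param curves a `"tuning_curves"` object from [test_isolated_spaces()].
#' @param threshold,min_len see [classify_cell()].
#' @return character vector of cell types, one per output cell.
#' @export
classify_cells <- function(curves, threshold = 0.5, min_len = 2L) {
  vapply(seq_len(nrow(curves$identity)), function(i)
    classify_cell(curves$identity[i, ], curves$expression[i, ],
                  threshold, min_len), character(1))
}

#' Preference label map for spatial clustering
#'
#' Labels each output cell by the space it responds to more strongly:
#' `"identity"` or `"expression"` by the larger of the two maximal isolated
#' responses, `"dual"` on exact ties, `"unresponsive"` when neither maximum
#' exceeds the threshold.
#'
#' @param curves a `"tuning_curves"` object.
#' @param dims output sheet dimensions.
#' @param threshold response threshold.
#' @return character matrix of labels with shape `dims`.
#' @export
preference_map <- function(curves, dims, threshold = 0.5) {
  mi <- apply(curves$identity, 1L, max)
  me <- apply(curves$expression, 1L, max)
  lab <- ifelse(pmax(mi, me) <= threshold, "unresponsive",
                ifelse(mi > me, "identity",
                       ifelse(me > mi, "expression", "dual")))
  matrix(lab, dims[1L], dims[2L])
}

#' Join-count spatial clustering statistic
#'
#' The fraction of 4-neighbour (rook adjacency) cell pairs on the output
#' sheet sharing a label, compared against random relabellings of the same
#' sheet.  The p-value is `(1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param labels character (or factor) matrix of cell labels.
#' @param n_perm number of label permutations (default 999).
#' @return list with `statistic` (observed same-label fraction), `p_value`,
#'   `n_perm`, and `perm` (the permuted statistics).
#' @export
clustering_statistic <- function(labels, n_perm = 999L) {
  if (length(unique(as.vector(labels))) < 2L) {
    warning("single-class label map: clustering is degenerate",
            call. = FALSE)
    return(list(statistic = 1, p_value = 1, n_perm = n_perm,
                perm = rep(1, n_perm)))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  same_frac <- function(m)
    (sum(m[-nr, ] == m[-1L, ]) + sum(m[, -nc] == m[, -1L])) /
    (nr * (nc - 1L) + nc * (nr - 1L))
  obs <- same_frac(labels)
  perm <- vapply(seq_len(n_perm), function(i)
    same_frac(matrix(sample(as.vector(labels)), nr, nc)), numeric(1))
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm, perm = perm)
}
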