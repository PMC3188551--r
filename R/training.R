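# Layer-wise training.
#
# The hierarchy is purely feedforward, so layers are trained one at a time,
# 1 through 4; a layer only starts once all layers below it are trained and
# frozen.  One epoch presents every face in the stimulus set once (1600
# presentations at full scale).  Because frozen layers are deterministic,
# each layer's responses to the whole stimulus set are computed once and
# cached as the input to the next layer; for layer 1 the cache is restricted
# to the retina positions actually sampled by layer-1 afferents, which keeps
# memory bounded.

# restrict a synaptic map to the sorted unique set of its afferent indices
.compress_synapses <- function(syn) {
  uidx <- sort(unique(as.vector(syn$idx)))
  csyn <- syn
  csyn$idx <- matrix(match(syn$idx, uidx), nrow(syn$idx))
  list(syn = csyn, uidx = uidx)
}

.present <- function(y_pre, syn, lc) {
  h <- compute_activations(y_pre, syn)
  r <- lateral_filter(matrix(h, lc$dims[1L], lc$dims[2L]), lc$lateral)
  apply_sigmoid(r, lc$sigmoid$percentile, lc$sigmoid$beta)
}

#' Train one layer on cached presynaptic firing
#'
#' Runs the layer's scheduled epochs of Hebbian learning over the stimulus
#' set, presenting the cached responses of the frozen preceding stage in a
#' (seeded) shuffled order each epoch.  Weights of every other layer are
#' untouched.
#'
#' @param model a `"som_network"`.
#' @param layer_idx layer to train (1..4); all lower layers must already be
#'   trained.
#' @param pre_firing numeric matrix of presynaptic firing, one column per
#'   stimulus (for layer 1: the compressed retina cache, see
#'   [train_network()]).
#' @param epochs number of epochs; defaults to the layer's scheduled count.
#' @param compressed if `TRUE`, `pre_firing` rows correspond to the
#'   compressed afferent index set of this layer.
#' @return the model with the layer trained and a per-epoch log entry
#'   (mean absolute weight change, mean firing sparseness, worst deviation
#'   of weight norms from 1) appended.
#' @export
train_layer <- function(model, layer_idx, pre_firing,
                        epochs = model$config$training$epochs[layer_idx],
                        compressed = FALSE) {
  if (layer_idx > 1L && !all(model$trained[seq_len(layer_idx - 1L)]))
    stop("layers below ", layer_idx, " must be trained first", call. = FALSE)
  lc <- model$config$layers[[layer_idx]]
  tr <- model$config$training
  syn <- model$synapses[[layer_idx]]
  if (compressed) {
    cs <- .compress_synapses(syn)
    work <- cs$syn
  } else work <- syn
  n_stim <- ncol(pre_firing)
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- if (isTRUE(tr$shuffle)) sample.int(n_stim) else seq_len(n_stim)
    w_before <- work$w
    spars <- 0
    for (k in ord) {
      y_pre <- pre_firing[, k]
      y <- .present(y_pre, work, lc)
      spars <- spars + mean(y > 0.5)
      work <- hebbian_update(y_pre, as.vector(y), work, tr$learning_rate)
    }
    norms <- sqrt(.rowSums(work$w^2, nrow(work$w), ncol(work$w)))
    log[[ep]] <- list(layer = layer_idx, epoch = ep,
                      mean_dw = mean(abs(work$w - w_before)),
                      sparseness = spars / n_stim,
                      max_norm_err = max(abs(norms - 1)),
                      presentations = n_stim)
  }
  syn$w <- work$w          # afferent order unchanged by compression
  model$synapses[[layer_idx]] <- syn
  model$trained[layer_idx] <- TRUE
  model$log <- c(model$log, log)
  model
}

# firing of one layer for every stimulus column of its (possibly
# compressed) presynaptic cache
.layer_responses_from_cache <- function(syn, lc, pre_firing) {
  out <- matrix(0, prod(lc$dims), ncol(pre_firing))
  for (k in seq_len(ncol(pre_firing)))
    out[, k] <- as.vector(.present(pre_firing[, k], syn, lc))
  out
}

#' Train the full hierarchy on the face set
#'
#' Generates (or accepts) the complete-face stimulus set, filters it through
#' the V1 bank, and trains layers 1 to 4 in sequence with the configured
#' epoch schedule, caching each frozen layer's responses to the whole set as
#' the next layer's input.  Fully deterministic given `(config, seed)`.
#'
#' @param config a [default_config()] list.
#' @param seed integer seed controlling connectivity, initial weights and
#'   presentation order.
#' @param stimuli optional pre-generated stimulus list (identity-major, as
#'   from [generate_stimulus_set()]); generated from `config` if `NULL`.
#' @param verbose print per-layer progress.
#' @return a trained `"som_network"` with a training `log` (one entry per
#'   epoch) recording mean weight change, firing sparseness, weight-norm
#'   error and presentation counts.
#' @export
train_network <- function(config, seed = 1L, stimuli = NULL, verbose = FALSE) {
  if (is.null(stimuli))
    stimuli <- generate_stimulus_set(config$stimuli$n_identity,
                                     config$stimuli$n_expression,
                                     "complete", config$stimuli$size)
  n_stim <- config$stimuli$n_identity * config$stimuli$n_expression
  if (length(stimuli) != n_stim)
    stop("stimulus set incomplete: expected ", n_stim, " images",
         call. = FALSE)
  model <- init_network(config, seed)
  set.seed(seed + 1L)                 # presentation-order stream
  cs <- .compress_synapses(model$synapses[[1L]])
  if (verbose) message("filtering ", n_stim, " stimuli ...")
  cache <- matrix(0, length(cs$uidx), n_stim)
  for (k in seq_len(n_stim)) {
    rc <- apply_filterbank(stimuli[[k]], normalise = config$retina$normalise)
    cache[, k] <- rc[cs$uidx]
  }
  for (l in 1:4) {
    if (verbose) message("training layer ", l, " (",
                         config$training$epochs[l], " epochs) ...")
    model <- train_layer(model, l, cache, compressed = (l == 1L))
    if (l < 4L) {
      syn <- if (l == 1L) {
        cs <- .compress_synapses(model$synapses[[1L]])
        cs$syn
      } else model$synapses[[l]]
      cache <- .layer_responses_from_cache(syn, config$layers[[l]], cache)
    }
  }
  model$log_summary <- list(
    total_presentations = n_stim * sum(config$training$epochs))
  model
}

#' Per-epoch training log as a data.frame
#'
#' @param model a trained `"som_network"`.
#' @return data.frame with columns `layer`, `epoch`, `mean_dw`,
#'   `sparseness`, `max_norm_err`, `presentations`.
#' @export
training_log <- function(model) {
  do.call(rbind, lapply(model$log, as.data.frame))
}
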