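# The four-layer SOM hierarchy.
#
# Each layer is a sheet of rate-coded neurons.  A presentation runs, per
# layer: a linear activation through sparse topological afferents
# (h_i = sum_j w_ij y_j), a Mexican-hat lateral difference-of-Gaussians
# convolution across the sheet (short-range excitation, long-range
# inhibition -- the SOM interaction), and a steep sigmoid
# y = 1 / (1 + exp(-2 beta (r - alpha))) whose threshold alpha is set to a
# percentile of the current lateral-filtered activations, fixing the firing
# sparseness.  Learning is Hebbian (dw_ij = rate * y_i * y_j) on existing
# connections only, with each neuron's weight vector renormalised to unit
# Euclidean length after every update.

# --- connectivity ----------------------------------------------------------

# Fraction of sampled afferents expected within `radius` of the centre for
# a Gaussian of scale sigma over a discrete candidate offset grid with
# squared distances d2.  When n_draw is given, the fraction is computed
# under the distinct-draw inclusion probabilities pi_i = 1 - exp(-c w_i)
# (with c solved so that sum(pi) = n_draw): drawing n distinct afferents
# flattens the realised distribution relative to the raw Gaussian, and the
# calibration must account for that to keep the stated 67% convergence.
.gauss_fraction <- function(sigma, d2, radius, n_draw = NULL) {
  w <- exp(-d2 / (2 * sigma^2))
  inside <- d2 <= radius^2
  if (is.null(n_draw)) return(sum(w[inside]) / sum(w))
  w <- w / sum(w)
  support <- sum(w > 0)
  if (support <= n_draw)   # degenerate: every reachable candidate is drawn
    return(sum(inside & w > 0) / n_draw)
  g <- function(logc) sum(1 - exp(-exp(logc) * w)) - n_draw
  logc <- uniroot(g, c(log(n_draw), log(n_draw) + 20), extendInt = "yes",
                  tol = 1e-10)$root
  sum(1 - exp(-exp(logc) * w[inside])) / n_draw
}

# Solve for the Gaussian scale at which `radius` contains 67% of the drawn
# connections, the stated convergence of the topological connectivity.
.calibrate_sigma <- function(radius, d2, n_draw = NULL) {
  f <- function(s) .gauss_fraction(s, d2, radius, n_draw) - 0.67
  if (f(radius / 10) < 0 || f(radius * 10) > 0)
    stop("connection radius ", radius,
         " infeasible for the layer geometry", call. = FALSE)
  uniroot(f, c(radius / 10, radius * 10), tol = 1e-8)$root
}

# squared torus distances of all offsets on an n x n sheet
.torus_d2 <- function(n) {
  off <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  outer(off^2, off^2, `+`)
}

# draw n distinct values from `candidates` with probabilities `prob`
# (repeated weighted draws, duplicates discarded)
.sample_distinct <- function(candidates, prob, n) {
  if (length(candidates) < n)
    stop("cannot draw ", n, " distinct afferents from ",
         length(candidates), " candidates", call. = FALSE)
  acc <- integer(0)
  while (length(acc) < n) {
    k <- 2L * (n - length(acc)) + 8L
    acc <- unique(c(acc, sample(candidates, k, replace = TRUE, prob = prob)))
  }
  acc[seq_len(n)]
}

# map post-sheet coordinates to the topologically corresponding position in
# a pre-sheet of different linear size
.map_centre <- function(pos, n_post, n_pre) (pos - 0.5) * (n_pre / n_post) + 0.5

.sample_layer1 <- function(config) {
  lc <- config$layers[[1L]]
  size <- config$stimuli$size
  n <- lc$dims[1L]
  specs <- filter_specs()
  groups <- lapply(names(lc$freq_connections), function(f)
    specs$channel[specs$frequency == as.numeric(f)])
  ng <- unname(lc$freq_connections)
  radius <- lc$radius
  win <- ceiling(2.5 * radius)
  # calibrate on the central (untruncated) candidate grid
  d2c <- outer((-win:win)^2, (-win:win)^2, `+`)
  sigma <- .calibrate_sigma(radius, d2c)
  idx <- matrix(0L, n * n, lc$n_connections)
  for (pc in seq_len(n)) {
    cx <- .map_centre(pc, n, size)
    cols <- max(1L, floor(cx - win)):min(size, ceiling(cx + win))
    for (pr in seq_len(n)) {
      cy <- .map_centre(pr, n, size)
      rows <- max(1L, floor(cy - win)):min(size, ceiling(cy + win))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      w <- exp(-d2 / (2 * sigma^2))
      pix <- as.vector(outer(rows, (cols - 1L) * size, `+`))
      neuron <- pr + (pc - 1L) * n
      taken <- integer(0)
      for (gi in seq_along(groups)) {
        ch <- groups[[gi]]
        want <- ng[gi]
        acc <- integer(0)
        while (length(acc) < want) {
          k <- 2L * (want - length(acc)) + 8L
          p <- sample(pix, k, replace = TRUE, prob = w)
          c_ <- sample(ch, k, replace = TRUE)
          acc <- setdiff(unique(c(acc, p + (c_ - 1L) * size * size)), taken)
        }
        sel <- acc[seq_len(want)]
        taken <- c(taken, sel)
        idx[neuron, (sum(ng[seq_len(gi - 1L)]) + 1L):sum(ng[seq_len(gi)])] <- sel
      }
    }
  }
  list(idx = idx, n_pre = size * size * 32L, sigma = sigma)
}

.sample_higher <- function(config, layer_idx) {
  lc <- config$layers[[layer_idx]]
  n <- lc$dims[1L]
  n_pre <- config$layers[[layer_idx - 1L]]$dims[1L]
  if (n != n_pre)
    stop("layers must share sheet dimensions", call. = FALSE)
  d2 <- .torus_d2(n)
  sigma <- .calibrate_sigma(lc$radius, d2, lc$n_connections)
  w0 <- exp(-d2 / (2 * sigma^2))
  idx <- matrix(0L, n * n, lc$n_connections)
  all_pre <- seq_len(n * n)
  for (pc in seq_len(n)) {
    for (pr in seq_len(n)) {
      # weight of pre neuron (r, c) = w0 at torus offset (r - pr, c - pc)
      wmat <- w0[((seq_len(n) - pr) %% n) + 1L, ((seq_len(n) - pc) %% n) + 1L]
      neuron <- pr + (pc - 1L) * n
      idx[neuron, ] <- .sample_distinct(all_pre, as.vector(wmat),
                                        lc$n_connections)
    }
  }
  list(idx = idx, n_pre = n * n, sigma = sigma)
}

#' Sample the afferent connectivity of one layer
#'
#' Draws, for every postsynaptic neuron, a sparse set of distinct afferents
#' from the preceding stage using a Gaussian distribution of connection
#' probabilities centred on the neuron's topologically corresponding
#' position.  The Gaussian scale is calibrated so the layer's stated radius
#' contains approximately 67% of the drawn connections.  Layer 1 draws from
#' the retina with the per-spatial-frequency connection counts of the
#' default configuration; higher layers draw on the (toroidal) sheet of the
#' preceding layer.  Initial weights are positive uniform random,
#' unit-normalised per neuron.  Fully determined by the RNG state.
#'
#' @param config a [default_config()] list.
#' @param layer_idx layer number, 1..4.
#' @return a synaptic map: list with `idx` (neurons x connections matrix of
#'   afferent indices), `w` (matching weights, unit row norm), `n_pre`,
#'   `dims`, `layer`, `sigma`.
#' @export
sample_connectivity <- function(config, layer_idx) {
  lc <- config$layers[[layer_idx]]
  if (lc$radius <= 0) stop("radius must be positive", call. = FALSE)
  s <- if (layer_idx == 1L) .sample_layer1(config)
       else .sample_higher(config, layer_idx)
  w <- matrix(runif(length(s$idx)), nrow(s$idx), ncol(s$idx))
  w <- w / sqrt(.rowSums(w^2, nrow(w), ncol(w)))
  list(idx = s$idx, w = w, n_pre = s$n_pre, dims = lc$dims,
       layer = layer_idx, sigma = s$sigma)
}

# --- forward dynamics ------------------------------------------------------

#' Linear afferent activation
#'
#' Computes `h_i = sum_j w_ij y_j` over each neuron's afferents.
#'
#' @param y_pre numeric vector of presynaptic firing (a flattened retina
#'   code or preceding-layer firing field).
#' @param syn a synaptic map from [sample_connectivity()].
#' @return numeric vector of activations, one per neuron.
#' @export
compute_activations <- function(y_pre, syn) {
  if (max(syn$idx) > length(y_pre))
    stop("presynaptic vector shorter than afferent indices", call. = FALSE)
  .cpp_activations(syn$idx, syn$w, as.numeric(y_pre))
}

.lateral_kernel <- function(params) {
  if (params$sigma_E <= 0 || params$sigma_I <= 0)
    stop("lateral radii must be positive", call. = FALSE)
  h <- ceiling(3 * params$sigma_I)
  d2 <- outer((-h:h)^2, (-h:h)^2, `+`)
  params$delta_E * exp(-d2 / (2 * params$sigma_E^2)) -
    params$delta_I * exp(-d2 / (2 * params$sigma_I^2))
}

.lateral_fft <- function(dims, params, wrap) {
  key <- paste("lat", paste(dims, collapse = "x"),
               paste(unlist(params), collapse = ","), wrap, sep = "|")
  .cache_get(key, function() {
    k <- .lateral_kernel(params)
    h <- (nrow(k) - 1L) %/% 2L
    n <- dims[1L]
    if (wrap) {
      km <- matrix(0, n, n)
      for (a in -h:h) for (b in -h:h)
        km[(a %% n) + 1L, (b %% n) + 1L] <-
          km[(a %% n) + 1L, (b %% n) + 1L] + k[a + h + 1L, b + h + 1L]
      list(fft = fft(km), pad = NULL, half = h)
    } else {
      pad <- nextn(n + nrow(k) - 1L, c(2, 3))
      kp <- matrix(0, pad, pad)
      kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
      list(fft = fft(kp), pad = pad, half = h)
    }
  })
}

#' Mexican-hat lateral filtering of a layer's activations
#'
#' Convolves the activation sheet with the SOM interaction kernel
#' `L(a, b) = delta_E exp(-(a^2+b^2) / (2 sigma_E^2)) -
#'  delta_I exp(-(a^2+b^2) / (2 sigma_I^2))`,
#' truncated at 3 `sigma_I`.  By default the sheet is treated as a torus
#' (wrap-around), which keeps the competition homogeneous across the sheet;
#' `wrap = FALSE` zero-pads instead.
#'
#' @param h numeric matrix of activations (the neuron sheet).
#' @param params list with `sigma_E`, `delta_E`, `sigma_I`, `delta_I`.
#' @param wrap toroidal boundary (default `TRUE`).
#' @return filtered activation matrix of the same shape.
#' @export
lateral_filter <- function(h, params, wrap = TRUE) {
  n <- nrow(h)
  if (ncol(h) != n) stop("activation sheet must be square", call. = FALSE)
  kf <- .lateral_fft(c(n, n), params, wrap)
  if (wrap) {
    Re(fft(fft(h) * kf$fft, inverse = TRUE)) / (n * n)
  } else {
    pad <- kf$pad
    hp <- matrix(0, pad, pad)
    hp[seq_len(n), seq_len(n)] <- h
    full <- Re(fft(fft(hp) * kf$fft, inverse = TRUE)) / (pad * pad)
    full[kf$half + seq_len(n), kf$half + seq_len(n)]
  }
}

#' Percentile-threshold sigmoid firing
#'
#' Applies `y = 1 / (1 + exp(-2 beta (r - alpha)))` with the threshold
#' `alpha` at the configured percentile of the current activations, so a
#' fixed fraction of neurons (5% at the default 95th percentile) fires above
#' 0.5 regardless of the overall activation scale.
#'
#' The sigmoid operates on the layer's normalised activation scale: `r` is
#' rank-transformed to `[0, 1]` (empirical CDF, average ranks on ties) and
#' the threshold sits exactly at `percentile/100`.  This makes the per-layer
#' slope table meaningful independently of the raw activation scale, which
#' the lateral contrast parameters stretch by orders of magnitude between
#' layers, and yields graded (not step) firing around the threshold --
#' without it the steep slopes reduce competition to a hard winner set and
#' the map cannot differentiate.  The raw activation at the percentile is
#' returned as attribute `"alpha"`.
#'
#' @param r numeric matrix or vector of lateral-filtered activations.
#' @param percentile percentile (0..100) defining the threshold.
#' @param beta sigmoid slope (on the rank scale).
#' @return firing rates in `[0, 1]`, same shape as `r`, with the threshold
#'   attached as attribute `"alpha"`.
#' @export
apply_sigmoid <- function(r, percentile = 95, beta = 1) {
  if (any(!is.finite(r))) stop("activations must be finite", call. = FALSE)
  alpha <- quantile(r, percentile / 100, names = FALSE, type = 7)
  if (max(r) == min(r))
    warning("degenerate activation field: all values equal", call. = FALSE)
  rk <- rank(r, ties.method = "average") / length(r)
  y <- 1 / (1 + exp(-2 * beta * (rk - percentile / 100)))
  dim(y) <- dim(r)
  attr(y, "alpha") <- alpha
  y
}

#' Hebbian weight update with weight normalisation
#'
#' Applies `dw_ij = rate * y_i * y_j` to existing connections, then rescales
#' each postsynaptic neuron's weight vector to unit Euclidean length.
#'
#' @param y_pre presynaptic firing vector.
#' @param y_post postsynaptic firing vector (one value per neuron).
#' @param syn synaptic map.
#' @param rate learning rate (>= 0).
#' @return the synaptic map with updated weights.
#' @export
hebbian_update <- function(y_pre, y_post, syn, rate = 0.1) {
  if (rate < 0) stop("learning rate must be non-negative", call. = FALSE)
  if (rate == 0) return(syn)
  syn$w <- .cpp_hebbian(syn$idx, syn$w, as.numeric(y_pre),
                        as.numeric(y_post), rate)
  syn
}

# --- model -----------------------------------------------------------------

#' Initialise an untrained model
#'
#' Samples the connectivity and random initial weights of all four layers.
#'
#' @param config a [default_config()] list.
#' @param seed integer RNG seed; the resulting model is fully determined by
#'   `(config, seed)`.
#' @return an object of class `"som_network"`.
#' @export
init_network <- function(config, seed = 1L) {
  set.seed(seed)
  synapses <- lapply(1:4, function(l) sample_connectivity(config, l))
  structure(list(config = config, synapses = synapses,
                 trained = rep(FALSE, 4L), seed = seed, log = list()),
            class = "som_network")
}

.as_retina_vector <- function(retina, model) {
  size <- model$config$stimuli$size
  need <- size * size * 32L
  v <- as.numeric(retina)
  if (length(v) != need)
    stop("retina input must have ", need, " elements", call. = FALSE)
  v
}

#' Propagate one stimulus through the hierarchy
#'
#' Runs activation, lateral filtering and the percentile sigmoid layer by
#' layer with no weight change (the same dynamics used during training).
#'
#' @param retina a `retina_output` array from [apply_filterbank()] (or the
#'   flattened vector).
#' @param model a `"som_network"`.
#' @param up_to_layer propagate through layers `1..up_to_layer` (default 4).
#' @return a list of firing-rate matrices, one per computed layer.
#' @export
forward_pass <- function(retina, model, up_to_layer = 4L) {
  stopifnot(up_to_layer >= 1L, up_to_layer <= 4L)
  y_pre <- .as_retina_vector(retina, model)
  out <- vector("list", up_to_layer)
  for (l in seq_len(up_to_layer)) {
    lc <- model$config$layers[[l]]
    syn <- model$synapses[[l]]
    if (is.null(syn)) stop("layer ", l, " has no weights", call. = FALSE)
    h <- compute_activations(y_pre, syn)
    r <- lateral_filter(matrix(h, lc$dims[1L], lc$dims[2L]), lc$lateral)
    y <- apply_sigmoid(r, lc$sigmoid$percentile, lc$sigmoid$beta)
    out[[l]] <- y
    y_pre <- as.vector(y)
  }
  names(out) <- paste0("layer", seq_len(up_to_layer))
  out
}

#' Save / load a model
#'
#' Persists the model as an R binary container (`model.rds`) plus a JSON
#' metadata sidecar echoing the configuration, seed, training state and
#' per-layer weight checksums.  `load_model(save_model(m, dir))` returns an
#' identical model.
#'
#' @param model a `"som_network"`.
#' @param dir output directory (created if missing).
#' @return `save_model`: `dir`, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(
    package = "facesom",
    config = unclass(model$config),
    seed = model$seed,
    trained = model$trained,
    weight_sums = vapply(model$synapses, function(s) sum(s$w), numeric(1)))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "model.rds") else dir
  model <- readRDS(path)
  if (!inherits(model, "som_network"))
    stop("not a saved som_network: ", path, call. = FALSE)
  model
}

#' @export
print.som_network <- function(x, ...) {
  cat(sprintf("<som_network preset=%s  seed=%d  trained: %s>\n",
              x$config$preset, x$seed,
              paste(ifelse(x$trained, "yes", "no"), collapse = "/")))
  invisible(x)
}
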