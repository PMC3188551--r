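# Experiment configuration.
#
# The default ("full" preset) configuration holds the published operating
# point of the model verbatim: four 32x32 layers; 272/100/100/100 afferents
# per neuron with topological radii 6/6/9/12 capturing ~67% of connections;
# layer-1 afferents split 201/50/13/8 across the 0.5/0.25/0.125/0.0625
# cycles/pixel filter groups; Mexican-hat lateral parameters per layer;
# 95th-percentile sigmoid thresholds with slopes 190/40/75/26; training
# epochs 50/100/100/75 at learning rate 0.1 and sparseness 0.05.

.full_layers <- function() {
  lat <- list(
    sigma_E = c(0.7, 0.55, 0.4, 0.6),
    delta_E = c(5.35, 33.15, 117.57, 120.12),
    sigma_I = c(1.38, 2.7, 4.0, 6.0),
    delta_I = c(1.5, 1.5, 1.6, 1.4))
  beta <- c(190, 40, 75, 26)
  n_conn <- c(272L, 100L, 100L, 100L)
  radius <- c(6, 6, 9, 12)
  lapply(1:4, function(l) c(
    list(dims = c(32L, 32L),
         n_connections = n_conn[l],
         radius = radius[l]),
    if (l == 1L) list(freq_connections =
      c("0.5" = 201L, "0.25" = 50L, "0.125" = 13L, "0.0625" = 8L)),
    list(lateral = list(sigma_E = lat$sigma_E[l], delta_E = lat$delta_E[l],
                        sigma_I = lat$sigma_I[l], delta_I = lat$delta_I[l]),
         sigmoid = list(percentile = 95, beta = beta[l]))))
}

#' Default experiment configuration
#'
#' @param preset `"full"` for the full-scale published operating point, or
#'   `"desk"` for a scaled-down variant (16x16 layers, 10x10 stimulus grid,
#'   epochs 10/20/20/15) that exercises the identical dynamics at a size
#'   suitable for continuous testing.
#' @return a nested list of class `"facesom_config"`.
#' @export
default_config <- function(preset = c("full", "desk")) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    stimuli = list(size = 128L, n_identity = 40L, n_expression = 40L),
    retina = list(normalise = TRUE),
    layers = .full_layers(),
    training = list(epochs = c(50L, 100L, 100L, 75L), learning_rate = 0.1,
                    sparseness = 0.05, shuffle = TRUE),
    analysis = list(response_threshold = 0.5, min_region_length = 2L,
                    n_blocks = 5L, n_permutations = 999L)
  )
  if (preset == "desk") {
    cfg$stimuli$n_identity <- 10L
    cfg$stimuli$n_expression <- 10L
    cfg$training$epochs <- c(10L, 20L, 20L, 15L)
    # fewer afferents and adjusted radii: on a 16x16 sheet the 67%
    # convergence is only feasible when the radius encloses comfortably
    # more grid positions than the number of distinct afferents drawn
    radius <- c(6, 4, 5, 6)
    for (l in 1:4) {
      cfg$layers[[l]]$dims <- c(16L, 16L)
      cfg$layers[[l]]$radius <- radius[l]
      if (l > 1L) cfg$layers[[l]]$n_connections <- 50L
    }
  }
  structure(cfg, class = "facesom_config")
}

.merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".", key)),
           call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", sub("^\\.", "", paste0(path, ".", key)),
             " must be a mapping", call. = FALSE)
      base[[key]] <- .merge_config(base[[key]], user[[key]],
                                   paste0(path, ".", key))
    } else {
      val <- user[[key]]
      if (is.list(val)) val <- unlist(val)
      base[[key]] <- val
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a JSON configuration, fills every missing key with the default
#' value from the chosen preset, and rejects unknown keys by name.  An empty
#' file (or `{}`) therefore yields the full default configuration.
#'
#' @param path path to a JSON file; keys mirror [default_config()].
#' @param preset base preset to merge into.
#' @return a `"facesom_config"` list.
#' @export
load_config <- function(path, preset = "full") {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nzchar(trimws(txt))) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else list()
  base <- default_config(preset)
  if (!is.null(user$preset)) {
    base <- default_config(user$preset)
    user$preset <- NULL
  }
  if (!is.null(user$layers)) {
    if (length(user$layers) != 4L)
      stop("configuration key layers must list all 4 layers", call. = FALSE)
    for (l in 1:4)
      base$layers[[l]] <- .merge_config(base$layers[[l]], user$layers[[l]],
                                        paste0("layers[", l, "]"))
    user$layers <- NULL
  }
  out <- .merge_config(unclass(base), user)
  fc <- out$layers[[1L]]$freq_connections
  if (is.null(names(fc)))   # JSON arrays drop the frequency labels
    names(fc) <- c("0.5", "0.25", "0.125", "0.0625")
  out$layers[[1L]]$freq_connections <- fc
  structure(out, class = "facesom_config")
}

#' Save a configuration as JSON
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config a `"facesom_config"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.facesom_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<facesom_config preset=%s  layers %s  stimuli %dx%d  epochs %s  ",
    "rate %g  sparseness %g>\n"),
    x$preset, paste(vapply(x$layers, function(l) l$dims[1], 1), collapse = "/"),
    x$stimuli$n_identity, x$stimuli$n_expression,
    paste(x$training$epochs, collapse = "/"),
    x$training$learning_rate, x$training$sparseness))
  invisible(x)
}
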