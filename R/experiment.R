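# End-to-end experiment driver.
#
# Runs the full procedure -- stimulus generation, V1 filtering, layer-wise
# training, firing-rate response analysis, spatial clustering, and the
# quantised information analysis for both spaces -- and writes all
# artefacts (CSVs, PGM figures, JSON manifest) under one output directory.

.write_manifest <- function(out_dir, config, seed, stages) {
  manifest <- list(
    package = "facesom",
    version = as.character(utils::packageVersion("facesom")),
    r_version = R.version.string,
    seed = seed,
    config = unclass(config),
    stages = stages,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# grey-scale mosaic of per-cell response matrices (output sheet sample),
# dark = high firing
.response_mosaic <- function(rmat, cells, nrow_mosaic = 8L) {
  ni <- dim(rmat)[2L]; ne <- dim(rmat)[3L]
  ncol_mosaic <- ceiling(length(cells) / nrow_mosaic)
  mos <- matrix(255L, nrow_mosaic * (ne + 1L) + 1L,
                ncol_mosaic * (ni + 1L) + 1L)
  for (ci in seq_along(cells)) {
    rblk <- (ci - 1L) %% nrow_mosaic
    cblk <- (ci - 1L) %/% nrow_mosaic
    block <- t(matrix(rmat[cells[ci], , ], ni, ne))   # rows = expression
    mos[rblk * (ne + 1L) + 1L + seq_len(ne),
        cblk * (ni + 1L) + 1L + seq_len(ni)] <-
      as.integer(round(255 * (1 - block)))
  }
  mos
}

#' Run the complete experiment
#'
#' @param config a [default_config()] list (or preset name).
#' @param seed integer master seed; all randomness (connectivity, initial
#'   weights, presentation order, permutation tests) derives from it.
#' @param out_dir output directory (created if missing); pass `NULL` to
#'   skip writing artefacts.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the trained `model`, `tuning` curves,
#'   `types` table, `preference` map, `clustering` result, and
#'   `information` profiles for both spaces.
#' @export
run_experiment <- function(config = default_config("full"), seed = 1L,
                           out_dir = "facesom-results", verbose = TRUE) {
  if (is.character(config)) config <- default_config(config)
  stages <- list()
  say <- function(...) if (verbose) message(...)

  say("stage 1/4: stimuli + filtering + training")
  model <- train_network(config, seed = seed, verbose = verbose)
  stages$training <- model$log_summary

  say("stage 2/4: firing-rate response analysis")
  rmat <- test_complete_faces(model)
  curves <- test_isolated_spaces(model)
  thr <- config$analysis$response_threshold
  types <- classify_cells(curves, thr, config$analysis$min_region_length)
  pref <- preference_map(curves, config$layers[[4L]]$dims, thr)
  stages$cell_types <- as.list(table(types))

  say("stage 3/4: spatial clustering")
  set.seed(seed + 2L)
  clus <- clustering_statistic(pref, config$analysis$n_permutations)
  stages$clustering <- clus[c("statistic", "p_value")]

  say("stage 4/4: information analysis")
  info <- lapply(c(identity = "identity", expression = "expression"),
                 function(sp) ranked_information_profile(model, sp))
  stages$information <- lapply(info, function(x)
    list(n_at_ceiling = x$n_at_ceiling, ceiling = x$ceiling,
         max = max(x$information)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lg <- training_log(model)
    write.csv(lg, file.path(out_dir, "training_log.csv"), row.names = FALSE)
    cells <- data.frame(
      cell = seq_along(types), type = types,
      preference = as.vector(pref),
      peak_identity = apply(curves$identity, 1L, which.max),
      peak_expression = apply(curves$expression, 1L, which.max),
      max_identity = apply(curves$identity, 1L, max),
      max_expression = apply(curves$expression, 1L, max))
    write.csv(cells, file.path(out_dir, "cell_types.csv"), row.names = FALSE)
    for (sp in names(info)) {
      write.csv(data.frame(rank = seq_along(info[[sp]]$information),
                           cell = info[[sp]]$order,
                           information_bits = info[[sp]]$information),
                file.path(out_dir, paste0("information_", sp, ".csv")),
                row.names = FALSE)
    }
    n_cells <- prod(config$layers[[4L]]$dims)
    show <- round(seq(1L, n_cells, length.out = min(64L, n_cells)))
    write_pgm(.response_mosaic(rmat, show),
              file.path(out_dir, "response_mosaic.pgm"))
    .write_manifest(out_dir, config, seed, stages)
    say("artefacts written to ", normalizePath(out_dir))
  }
  invisible(list(model = model, response_matrix = rmat, tuning = curves,
                 types = types, preference = pref, clustering = clus,
                 information = info, stages = stages))
}
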