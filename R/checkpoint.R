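# Model checkpointing: parameters plus an architecture-config JSON sidecar,
# so any checkpoint can be rebuilt without code changes.

# Batch-norm running statistics, keyed by layer path.
collect_bn_stats <- function(layer, path = "root") {
  out <- list()
  if (identical(layer$kind, "bn")) {
    out[[path]] <- list(run_mean = layer$run_mean, run_var = layer$run_var)
  }
  chn <- names(layer$children)
  for (i in seq_along(layer$children)) {
    tag <- if (!is.null(chn) && nzchar(chn[i])) chn[i] else as.character(i)
    out <- c(out, collect_bn_stats(layer$children[[i]],
                                   paste(path, tag, sep = "/")))
  }
  out
}

assign_bn_stats <- function(layer, stats, path = "root") {
  if (identical(layer$kind, "bn") && !is.null(stats[[path]])) {
    layer$run_mean <- stats[[path]]$run_mean
    layer$run_var <- stats[[path]]$run_var
  }
  chn <- names(layer$children)
  for (i in seq_along(layer$children)) {
    tag <- if (!is.null(chn) && nzchar(chn[i])) chn[i] else as.character(i)
    assign_bn_stats(layer$children[[i]], stats,
                    paste(path, tag, sep = "/"))
  }
  invisible(NULL)
}

model_arch <- function(model) {
  if (inherits(model, "leaf_unet")) {
    list(type = "leaf_unet", config = unclass(model$config))
  } else if (inherits(model, "leaf_multimodel")) {
    list(type = "leaf_multimodel",
         head1 = unclass(model$head1$config),
         head2 = unclass(model$head2$config))
  } else if (inherits(model, "leaf_classifier")) {
    list(type = "leaf_classifier", config = unclass(model$config))
  } else {
    stop("unknown model type", call. = FALSE)
  }
}

config_from_list <- function(x) {
  cfg <- backbone_config(x$family,
                         input_resolution = unlist(x$input_resolution),
                         width_multiplier = x$width_multiplier,
                         base_filters = x$base_filters,
                         n_classes = x$n_classes)
  if (!is.null(x$stages)) cfg$stages <- as.data.frame(x$stages)
  cfg
}

#' Save a model checkpoint
#'
#' Writes `arch.json` (the architecture configuration) and `params.rds`
#' (parameters and batch-norm running statistics) into `dir`; the
#' checkpoint is rebuilt by [load_model()] from the sidecar alone.
#'
#' @param model A `leaf_unet`, `leaf_classifier` or `leaf_multimodel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(model_arch(model), file.path(dir, "arch.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  slots <- nn_param_slots(model)
  params <- stats::setNames(
    lapply(slots, function(s) s$env$params[[s$name]]),
    vapply(slots, `[[`, character(1), "path"))
  saveRDS(list(params = params, bn = collect_bn_stats(model)),
          file.path(dir, "params.rds"))
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_model()].
#' @return The rebuilt model with restored parameters and batch-norm
#'   statistics.
#' @export
load_model <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "arch.json"),
                              simplifyVector = TRUE)
  model <- switch(arch$type,
    leaf_unet = build_unet(do.call(unet_config, arch$config[
      c("input_height", "input_width", "input_channels", "base_filters",
        "dropout_rate")]), seed = 1L),
    leaf_classifier = build_backbone(config_from_list(arch$config),
                                     seed = 1L),
    leaf_multimodel = build_multimodel(config_from_list(arch$head1),
                                       config_from_list(arch$head2),
                                       seed = 1L),
    stop("unknown checkpoint type: ", arch$type, call. = FALSE))
  blob <- readRDS(file.path(dir, "params.rds"))
  slots <- nn_param_slots(model)
  for (s in slots) {
    p <- blob$params[[s$path]]
    if (is.null(p)) stop("checkpoint missing parameter ", s$path,
                         call. = FALSE)
    if (!is.null(dim(s$env$params[[s$name]]))) {
      dim(p) <- dim(s$env$params[[s$name]])
    }
    s$env$params[[s$name]] <- p
  }
  assign_bn_stats(model, blob$bn)
  model
}
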