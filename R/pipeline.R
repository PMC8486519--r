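# End-to-end orchestration: stratified splitting, class-registry merging,
# the two-branch multimodel, joint multiloss training with Adam + cyclic
# learning rate, evaluation and the full synthetic pipeline.

#' Stratified train/validation/test split
#'
#' Assigns each item to train/val/test independently within each class, so
#' per-class counts deviate from `fraction * class_size` by less than one
#' (largest-remainder apportionment). Classes with fewer than 3 items go
#' entirely to train, with a warning.
#'
#' @param ds A `leaf_dataset`.
#' @param fractions Positive train/val/test fractions summing to 1.
#' @param seed Shuffling seed; identical seeds give identical assignments.
#' @return The dataset with a `split` factor (`train`, `val`, `test`).
#' @export
split_dataset <- function(ds, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(inherits(ds, "leaf_dataset"), length(fractions) == 3,
            all(fractions >= 0), abs(sum(fractions) - 1) < 1e-8)
  n <- length(ds$labels)
  split <- character(n)
  with_seed(seed, {
    for (k in unique(ds$labels)) {
      idx <- which(ds$labels == k)
      nk <- length(idx)
      if (nk < 3) {
        warning(sprintf("class %s has %d < 3 items; assigning all to train",
                        k, nk))
        split[idx] <- "train"
        next
      }
      target <- fractions * nk
      counts <- floor(target)
      rem <- target - counts
      short <- nk - sum(counts)
      if (short > 0) {
        counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
          counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
      }
      shuffled <- sample(idx)
      split[shuffled] <- rep(c("train", "val", "test"), times = counts)
    }
  })
  ds$split <- factor(split, levels = c("train", "val", "test"))
  ds
}

#' Merge class registries, dropping duplicate names
#'
#' Union of the class-name lists preserving first-seen order; used when
#' combining datasets whose species overlap.
#'
#' @param registries List of character vectors of class names.
#' @return A `registry_merge`: list with the merged `registry` and the
#'   counts `total_before`, `duplicates_removed`, `total_after`.
#' @examples
#' merge_class_registries(list(c("a", "b"), c("b", "c")))
#' @export
merge_class_registries <- function(registries) {
  stopifnot(length(registries) >= 1,
            all(vapply(registries, is.character, logical(1))))
  all_names <- unlist(registries)
  merged <- unique(all_names)
  structure(list(registry = merged,
                 total_before = length(all_names),
                 duplicates_removed = length(all_names) - length(merged),
                 total_after = length(merged)),
            class = "registry_merge")
}

#' @export
print.registry_merge <- function(x, ...) {
  cat(sprintf("<registry_merge> %d names, %d duplicates removed -> %d classes\n",
              x$total_before, x$duplicates_removed, x$total_after))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs Training epochs (>= 0).
#' @param batch_size Minibatch size.
#' @param lr_min,lr_max Bounds of the triangular cyclic learning rate.
#' @param cycle_epochs Length of one learning-rate cycle in epochs.
#' @param seed Seed controlling shuffling, augmentation sampling and
#'   dropout.
#' @param lambda Multiloss coupling weight.
#' @param sign_mode `"literal"` or `"diversity"` (see [multiloss()]).
#' @param use_unet_crop Run segmentation-and-crop preprocessing in
#'   [run_full_pipeline()].
#' @param augmentation An [augmentation_spec()] applied to training items
#'   only, or `NULL` for none.
#' @param history_csv Optional path; per-epoch loss components are
#'   appended there as CSV.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 16L, lr_min = 1e-5,
                         lr_max = 1e-3, cycle_epochs = 4L, seed = 1L,
                         lambda = 3, sign_mode = "literal",
                         use_unet_crop = FALSE, augmentation = NULL,
                         history_csv = NULL) {
  stopifnot(epochs >= 0, lr_min <= lr_max, lambda >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_min = lr_min, lr_max = lr_max,
                 cycle_epochs = as.integer(cycle_epochs),
                 seed = as.integer(seed), lambda = lambda,
                 sign_mode = sign_mode, use_unet_crop = use_unet_crop,
                 augmentation = augmentation, history_csv = history_csv),
            class = "train_config")
}

#' Build the two-branch multimodel
#'
#' Two jointly trainable classification heads over a shared input
#' resolution; by default head 1 is the MobileNet V1 family and head 2 the
#' EfficientNet B0 family. Prediction applies softmax to each head and
#' fuses by probability averaging.
#'
#' @param head1_config,head2_config [backbone_config()]s with equal
#'   `n_classes` and input resolutions.
#' @param seed Weight-initialization seed (head 2 uses `seed + 1`).
#' @return A `leaf_multimodel`.
#' @export
build_multimodel <- function(head1_config = backbone_config("mobilenet_v1"),
                             head2_config = backbone_config("efficientnet_b0"),
                             seed = 42L) {
  if (head1_config$n_classes != head2_config$n_classes) {
    stop("heads must share the same number of classes", call. = FALSE)
  }
  if (!identical(head1_config$input_resolution,
                 head2_config$input_resolution)) {
    stop("heads must share the same input resolution", call. = FALSE)
  }
  e <- new_layer("multimodel")
  e$head1 <- build_backbone(head1_config, seed = seed)
  e$head2 <- build_backbone(head2_config, seed = seed + 1L)
  e$children <- list(head1 = e$head1, head2 = e$head2)
  e$n_classes <- head1_config$n_classes
  e$input_resolution <- head1_config$input_resolution
  e$frozen <- character(0)
  e$fw <- function(x, training = FALSE) {
    list(s1 = e$head1$fw(x, training), s2 = e$head2$fw(x, training))
  }
  class(e) <- c("leaf_multimodel", "nn_layer")
  e
}

#' Freeze one head of a multimodel
#'
#' A frozen head's parameters are excluded from optimizer updates.
#' @param model A `leaf_multimodel`.
#' @param head `"head1"` or `"head2"` (or both).
#' @export
freeze_head <- function(model, head) {
  stopifnot(all(head %in% c("head1", "head2")))
  model$frozen <- union(model$frozen, head)
  invisible(model)
}

# Resize a raw 0-255 image to a model's input resolution (bilinear),
# keeping 3 channels and the 0-255 scale.
classifier_prepare_raw <- function(image, resolution) {
  img <- image
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3L))
  resize_image(img, resolution[1], resolution[2])
}

# One-hot C x N matrix from 0-based labels.
onehot_matrix <- function(labels, n_classes) {
  t <- matrix(0, n_classes, length(labels))
  t[cbind(labels + 1, seq_along(labels))] <- 1
  t
}

#' Jointly train a multimodel under the multiloss
#'
#' Minimizes the batch-mean multiloss with Adam and a triangular cyclic
#' learning rate. Augmentation (when configured) is applied to training
#' items only, re-sampled each epoch. Per-epoch loss components L1-L4,
#' kappa, and train/validation accuracy are recorded.
#'
#' @param model A `leaf_multimodel`.
#' @param ds A split `leaf_dataset` (see [split_dataset()]); images may be
#'   any size and are resized to the model's input resolution.
#' @param config A [train_config()].
#' @return The trained model with a `history` data frame attached
#'   (columns epoch, L1..L4, kappa, train_acc, val_acc).
#' @export
train_multimodel <- function(model, ds, config = train_config()) {
  stopifnot(inherits(model, "leaf_multimodel"),
            inherits(ds, "leaf_dataset"), inherits(config, "train_config"))
  history <- data.frame(epoch = integer(), L1 = numeric(), L2 = numeric(),
                        L3 = numeric(), L4 = numeric(), kappa = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  if (config$epochs == 0) {
    model$history <- history
    return(invisible(model))
  }
  if (is.null(ds$split)) stop("dataset has no split; run split_dataset()",
                              call. = FALSE)
  tr <- which(ds$split == "train")
  if (length(tr) == 0) stop("empty train split", call. = FALSE)
  va <- which(ds$split == "val")
  res <- model$input_resolution
  C <- model$n_classes
  raw_tr <- lapply(ds$images[tr], classifier_prepare_raw, resolution = res)
  lab_tr <- ds$labels[tr]
  xs_va <- if (length(va)) {
    stack_images(lapply(ds$images[va], function(im)
      classifier_prepare_raw(im, res) / 255))
  }
  lab_va <- ds$labels[va]
  n <- length(tr)
  steps_per_epoch <- ceiling(n / config$batch_size)
  cycle_steps <- max(2L, config$cycle_epochs * steps_per_epoch)
  slots_trainable <- function() {
    keep <- setdiff(c("head1", "head2"), model$frozen)
    do.call(c, lapply(keep, function(h) nn_param_slots(model[[h]], h)))
  }
  with_seed(config$seed, {
    slots <- slots_trainable()
    state <- list(slots = slots,
                  m = lapply(slots, function(s) 0 * s$env$params[[s$name]]),
                  v = lapply(slots, function(s) 0 * s$env$params[[s$name]]),
                  t = 0L)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      sums <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 0, kappa = 0)
      correct <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        imgs <- raw_tr[idx]
        if (!is.null(config$augmentation)) {
          aug_seeds <- sample.int(.Machine$integer.max - 1, length(idx))
          imgs <- Map(function(im, sd) augment(im, config$augmentation, sd),
                      imgs, aug_seeds)
        }
        xb <- stack_images(lapply(imgs, function(im) im / 255))
        tb <- onehot_matrix(lab_tr[idx], C)
        nn_zero_grads(model)
        out <- model$fw(xb, training = TRUE)
        g <- multiloss_logit_grads(tb, out$s1, out$s2,
                                   lambda = config$lambda,
                                   sign_mode = config$sign_mode)
        model$head1$bw(g$gs1)
        model$head2$bw(g$gs2)
        step <- step + 1L
        lr <- cyclic_lr(step, config$lr_min, config$lr_max, cycle_steps)
        state <- nn_adam_step(state, lr)
        v <- g$value
        wgt <- length(idx)
        sums <- sums + wgt * c(v$L1, v$L2, v$L3, v$L4, v$kappa)
        pf <- fuse_probs(softmax(out$s1), softmax(out$s2))
        correct <- correct + sum(max.col(t(pf), ties.method = "first") - 1 ==
                                   lab_tr[idx])
      }
      val_acc <- NA_real_
      if (length(va)) {
        outv <- model$fw(xs_va, training = FALSE)
        pfv <- fuse_probs(softmax(outv$s1), softmax(outv$s2))
        val_acc <- mean(max.col(t(pfv), ties.method = "first") - 1 == lab_va)
      }
      history[nrow(history) + 1, ] <- c(list(ep), as.list(sums / n),
                                        list(correct / n, val_acc))
      if (!is.null(config$history_csv)) {
        utils::write.csv(history, config$history_csv, row.names = FALSE)
      }
    }
  })
  model$history <- history
  invisible(model)
}

#' Train a single classification head with plain cross-entropy
#'
#' Baseline trainer for one backbone: softmax cross-entropy, Adam with the
#' same triangular cyclic learning rate and augmentation handling as
#' [train_multimodel()]. Used for single-network comparisons against the
#' jointly trained ensemble.
#'
#' @param model A `leaf_classifier`.
#' @param ds A split `leaf_dataset`.
#' @param config A [train_config()] (`lambda`/`sign_mode` are ignored).
#' @return The trained model with a `history` data frame (epoch, loss,
#'   train_acc, val_acc).
#' @export
train_classifier <- function(model, ds, config = train_config()) {
  stopifnot(inherits(model, "leaf_classifier"),
            inherits(ds, "leaf_dataset"), inherits(config, "train_config"))
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  if (config$epochs == 0) {
    model$history <- history
    return(invisible(model))
  }
  if (is.null(ds$split)) stop("dataset has no split; run split_dataset()",
                              call. = FALSE)
  tr <- which(ds$split == "train")
  if (length(tr) == 0) stop("empty train split", call. = FALSE)
  va <- which(ds$split == "val")
  res <- model$config$input_resolution
  C <- model$config$n_classes
  raw_tr <- lapply(ds$images[tr], classifier_prepare_raw, resolution = res)
  lab_tr <- ds$labels[tr]
  xs_va <- if (length(va)) {
    stack_images(lapply(ds$images[va], function(im)
      classifier_prepare_raw(im, res) / 255))
  }
  lab_va <- ds$labels[va]
  n <- length(tr)
  steps_per_epoch <- ceiling(n / config$batch_size)
  cycle_steps <- max(2L, config$cycle_epochs * steps_per_epoch)
  with_seed(config$seed, {
    state <- nn_adam_init(model)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; correct <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        imgs <- raw_tr[idx]
        if (!is.null(config$augmentation)) {
          aug_seeds <- sample.int(.Machine$integer.max - 1, length(idx))
          imgs <- Map(function(im, sd) augment(im, config$augmentation, sd),
                      imgs, aug_seeds)
        }
        xb <- stack_images(lapply(imgs, function(im) im / 255))
        tb <- onehot_matrix(lab_tr[idx], C)
        nn_zero_grads(model)
        s <- model$fw(xb, training = TRUE)
        p <- softmax(s)
        loss <- -mean(colSums(tb * log(pmax(p, 1e-12))))
        model$bw((p - tb) / ncol(tb))
        step <- step + 1L
        state <- nn_adam_step(state, cyclic_lr(step, config$lr_min,
                                               config$lr_max, cycle_steps))
        ep_loss <- ep_loss + loss * length(idx)
        correct <- correct + sum(max.col(t(p), ties.method = "first") - 1 ==
                                   lab_tr[idx])
      }
      val_acc <- NA_real_
      if (length(va)) {
        pv <- softmax(model$fw(xs_va, training = FALSE))
        val_acc <- mean(max.col(t(pv), ties.method = "first") - 1 == lab_va)
      }
      history[nrow(history) + 1, ] <- list(ep, ep_loss / n, correct / n,
                                           val_acc)
    }
  })
  model$history <- history
  invisible(model)
}

#' Predict the species of a single leaf image
#'
#' Applies softmax to each head and averages the probabilities (early
#' fusion); the predicted class is the fused argmax, ties broken toward
#' the lowest class index.
#'
#' @param object A `leaf_multimodel`.
#' @param image H x W x 3 array on the 0-255 scale.
#' @param ... Unused.
#' @return List with `class_id` (0-based), `fused`, `p_head1`, `p_head2`.
#' @export
predict.leaf_multimodel <- function(object, image, ...) {
  x <- classifier_prepare_raw(image, object$input_resolution) / 255
  dim(x) <- c(dim(x), 1L)
  out <- object$fw(x, training = FALSE)
  p1 <- softmax(as.numeric(out$s1))
  p2 <- softmax(as.numeric(out$s2))
  pf <- fuse_probs(p1, p2)
  list(class_id = which.max(pf) - 1L, fused = pf, p_head1 = p1,
       p_head2 = p2)
}

# Fused class predictions (0-based) for a batch of dataset indices.
predict_batch <- function(model, ds, idx) {
  res <- if (inherits(model, "leaf_multimodel")) model$input_resolution else
    model$config$input_resolution
  xb <- stack_images(lapply(ds$images[idx], function(im)
    classifier_prepare_raw(im, res) / 255))
  if (inherits(model, "leaf_multimodel")) {
    out <- model$fw(xb, training = FALSE)
    pf <- fuse_probs(softmax(out$s1), softmax(out$s2))
  } else {
    pf <- softmax(model$fw(xb, training = FALSE))
  }
  max.col(t(pf), ties.method = "first") - 1L
}

#' Evaluate a model on one split of a dataset
#'
#' @param model A `leaf_multimodel` or single `leaf_classifier`.
#' @param ds A split `leaf_dataset`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return A `leaf_evaluation`: list with `accuracy`, `confusion` (C x C
#'   matrix, rows = truth), `n`, and `mean_seconds` per image (reported,
#'   never a test criterion).
#' @export
evaluate_model <- function(model, ds, split = "test") {
  stopifnot(inherits(ds, "leaf_dataset"))
  idx <- if (is.null(ds$split)) seq_along(ds$labels) else
    which(ds$split == split)
  if (length(idx) == 0) stop("empty split: ", split, call. = FALSE)
  C <- length(ds$class_registry)
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_batch(model, ds, idx)
  secs <- (proc.time()[["elapsed"]] - t0) / length(idx)
  truth <- ds$labels[idx]
  confusion <- matrix(0L, C, C,
                      dimnames = list(truth = ds$class_registry,
                                      predicted = ds$class_registry))
  for (i in seq_along(idx)) {
    confusion[truth[i] + 1, pred[i] + 1] <-
      confusion[truth[i] + 1, pred[i] + 1] + 1L
  }
  structure(list(accuracy = mean(pred == truth), confusion = confusion,
                 n = length(idx), mean_seconds = secs, split = split),
            class = "leaf_evaluation")
}

#' @export
print.leaf_evaluation <- function(x, ...) {
  cat(sprintf("<leaf_evaluation> %s: accuracy %.4f on %d images (%.4f s/image)\n",
              x$split, x$accuracy, x$n, x$mean_seconds))
  invisible(x)
}

#' Run the full recognition pipeline on a synthetic dataset
#'
#' Generates data, Gaussian-smooths every image, optionally trains a U-Net
#' and replaces images by their segmented crops, splits, trains the
#' two-branch multimodel under the multiloss and evaluates on the test
#' split. Intended at desk scale with tiny heads; every random stage is
#' controlled by `seed`.
#'
#' @param n_classes,n_per_class,height,width,background_kind Synthetic
#'   dataset parameters (see [generate_dataset()]).
#' @param config A [train_config()].
#' @param head1_config,head2_config Backbone configurations; default tiny
#'   heads.
#' @param unet_base_filters,unet_epochs U-Net size/training budget when
#'   `config$use_unet_crop` is `TRUE`.
#' @param smooth_sigma Gaussian preprocessing sigma (pixels).
#' @param seed Master seed for data generation and splitting.
#' @param report_path Optional path for a JSON report.
#' @return A `leaf_pipeline_report` list: config hash, seeds, split sizes,
#'   final metrics and the loss history.
#' @export
run_full_pipeline <- function(n_classes = 5L, n_per_class = 20L,
                              height = 64L, width = 64L,
                              background_kind = "white",
                              config = train_config(),
                              head1_config = backbone_config("tiny"),
                              head2_config = backbone_config("tiny"),
                              unet_base_filters = 8L, unet_epochs = 10L,
                              smooth_sigma = 1.0, seed = 1L,
                              report_path = NULL) {
  stage <- "synthesize"
  report <- tryCatch({
    ds <- generate_dataset(n_classes, n_per_class, height, width,
                           master_seed = seed,
                           background_kind = background_kind)
    stage <- "smooth"
    ds$images <- lapply(ds$images, gaussian_smooth, sigma = smooth_sigma)
    unet_acc <- NA_real_
    if (isTRUE(config$use_unet_crop)) {
      stage <- "segment"
      side <- 16L * max(2L, min(height, width) %/% 16L)
      um <- build_unet(unet_config(side, side, 1L,
                                   base_filters = unet_base_filters),
                       seed = seed)
      train_unet(um, ds$images, ds$masks, epochs = unet_epochs,
                 seed = seed)
      unet_acc <- utils::tail(um$history$pixel_accuracy, 1)
      stage <- "crop"
      size1 <- head1_config$input_resolution
      ds$images <- lapply(ds$images, function(im) {
        resize_image(unet_crop(um, im), size1[1], size1[2])
      })
    }
    stage <- "split"
    ds <- split_dataset(ds, seed = seed)
    stage <- "train"
    model <- build_multimodel(head1_config, head2_config, seed = seed)
    train_multimodel(model, ds, config)
    stage <- "evaluate"
    ev <- evaluate_model(model, ds, "test")
    list(
      config_hash = substr(paste(
        sum(utils::head(as.integer(charToRaw(paste(
          deparse(config), collapse = ""))), 1000)), collapse = ""), 1, 16),
      seed = seed,
      split_sizes = as.list(table(ds$split)),
      n_classes = n_classes,
      use_unet_crop = isTRUE(config$use_unet_crop),
      unet_train_pixel_accuracy = unet_acc,
      test_accuracy = ev$accuracy,
      mean_seconds_per_image = ev$mean_seconds,
      history = model$history
    )
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "leaf_pipeline_report"
  if (!is.null(report_path)) {
    jsonlite::write_json(report[setdiff(names(report), "history")],
                         report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

#' @export
print.leaf_pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline report> seed %d, %d classes, unet_crop=%s, test accuracy %.4f\n",
    x$seed, x$n_classes, x$use_unet_crop, x$test_accuracy))
  invisible(x)
}
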