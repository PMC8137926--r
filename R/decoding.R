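#' Assemble a position-decoding dataset
#'
#' Converts time-series activity to position-based samples: the track is
#' divided into 100 fine bins (3 cm) and each cell's mean significant
#' \eqn{\Delta}F/F is computed per (lap, fine bin), restricted to running
#' periods. Decoding targets are the 50 coarse position classes obtained by
#' pairing fine bins.
#'
#' @param traces n_cells x n_frames matrix of significant-transient-only
#'   activity.
#' @param behavior a `"pf_behavior"` object.
#' @param config a [pf_config()] (`n_fine_bins`, `n_bins`).
#' @return An object of class `"pf_decoder_dataset"`: `X` (samples x cells),
#'   `lap`, `fine_bin` (1-based), `class` (coarse, 1..50), `position_cm`
#'   (fine-bin center), `n_classes`, `track_length_cm`.
#' @export
build_decoder_dataset <- function(traces, behavior, config = pf_config()) {
  nf <- config$n_fine_bins
  per_cell <- lapply(seq_len(nrow(traces)), function(i) {
    lap_bin_matrix(traces[i, ], behavior, n_bins = nf,
                   config$velocity_threshold_cm_s)
  })
  occ <- attr(per_cell[[1]], "occupancy") > 0
  sel <- which(occ, arr.ind = TRUE)  # (lap, fine_bin) pairs with samples
  X <- vapply(per_cell, function(m) m[sel], numeric(nrow(sel)))
  fine <- sel[, 2]
  cls <- (fine - 1L) %/% (nf %/% config$n_bins) + 1L
  structure(list(X = X, lap = sel[, 1], fine_bin = fine, class = cls,
                 position_cm = (fine - 0.5) * config$fine_bin_width_cm,
                 n_classes = config$n_bins,
                 track_length_cm = behavior$track_length_cm),
            class = "pf_decoder_dataset")
}

#' Combine decoder datasets across sessions by bin alignment
#'
#' Concatenates the cell columns of several sessions' datasets on the shared
#' (lap, fine bin) grid, so cells recorded in different sessions (or mice)
#' can feed one decoder. Only grid points present in every dataset are kept.
#'
#' @param datasets list of `"pf_decoder_dataset"` objects.
#' @return A combined `"pf_decoder_dataset"`.
#' @export
combine_decoder_datasets <- function(datasets) {
  if (length(datasets) == 1) return(datasets[[1]])
  keys <- lapply(datasets, function(d) paste(d$lap, d$fine_bin))
  common <- Reduce(intersect, keys)
  base <- datasets[[1]]
  sel1 <- match(common, keys[[1]])
  X <- do.call(cbind, lapply(seq_along(datasets), function(j) {
    datasets[[j]]$X[match(common, keys[[j]]), , drop = FALSE]
  }))
  structure(list(X = X, lap = base$lap[sel1], fine_bin = base$fine_bin[sel1],
                 class = base$class[sel1],
                 position_cm = base$position_cm[sel1],
                 n_classes = base$n_classes,
                 track_length_cm = base$track_length_cm),
            class = "pf_decoder_dataset")
}

#' Train a Gaussian naive Bayes position decoder
#'
#' Per (position class, cell) Gaussian likelihoods with a floored variance
#' and a uniform class prior, estimated from the training laps (6--35 by
#' default). Validation error on laps 36--40 is reported with the model.
#'
#' @param dataset a `"pf_decoder_dataset"`.
#' @param cells column indices of the cells to use (default all).
#' @param train_laps,val_laps lap ranges for training and validation.
#' @param var_floor variance floor (\eqn{\Delta}F/F squared).
#' @param shuffle_labels permute the training class labels (chance control).
#' @param seed RNG seed (used only when shuffling labels).
#' @return An object of class `"pf_nb_decoder"`: `mu`, `var` (class x cell),
#'   `cells`, `classes`, `val_error_cm`.
#' @export
train_nb_decoder <- function(dataset, cells = seq_len(ncol(dataset$X)),
                             train_laps = 6:35, val_laps = 36:40,
                             var_floor = 1e-4, shuffle_labels = FALSE,
                             seed = 1L) {
  sel <- dataset$lap %in% train_laps
  if (!any(sel)) stop("empty training split")
  X <- dataset$X[sel, cells, drop = FALSE]
  y <- dataset$class[sel]
  if (shuffle_labels) {
    set.seed(seed)
    y <- sample(y)
  }
  classes <- seq_len(dataset$n_classes)
  if (!all(classes %in% y)) {
    stop("classes with no training samples: ",
         paste(setdiff(classes, y), collapse = ", "))
  }
  mu <- rowsum(X, y) / as.numeric(table(factor(y, levels = classes)))
  vr <- rowsum(X^2, y) / as.numeric(table(factor(y, levels = classes))) - mu^2
  vr <- pmax(vr, var_floor)
  model <- structure(list(mu = mu, var = vr, cells = cells,
                          classes = classes, var_floor = var_floor,
                          n_classes = dataset$n_classes,
                          track_length_cm = dataset$track_length_cm),
                     class = "pf_nb_decoder")
  if (length(val_laps) > 0 && any(dataset$lap %in% val_laps)) {
    model$val_error_cm <- decode_and_score(model, dataset, val_laps)$error_cm
  }
  model
}

#' @export
print.pf_nb_decoder <- function(x, ...) {
  cat(sprintf("pf_nb_decoder: %d cells, %d classes%s\n", length(x$cells),
              x$n_classes,
              if (!is.null(x$val_error_cm)) {
                sprintf(", validation error %.1f cm", x$val_error_cm)
              } else ""))
  invisible(x)
}

## log-likelihood matrix (samples x classes) under the Gaussian NB model
nb_loglik <- function(model, X) {
  m <- nrow(X)
  ll <- matrix(0, m, length(model$classes))
  for (c in model$classes) {
    mu <- model$mu[c, ]
    vr <- model$var[c, ]
    ll[, c] <- -0.5 * colSums((t(X) - mu)^2 / vr + log(2 * pi * vr))
  }
  ll
}

#' Decode position and score the error
#'
#' Maximum-a-posteriori class per sample (uniform prior), decoding error as
#' the mean absolute difference between the predicted class center and the
#' true position, and the true x predicted confusion matrix.
#'
#' @param model a trained `"pf_nb_decoder"`.
#' @param dataset a `"pf_decoder_dataset"`.
#' @param laps laps to decode (default the first lap).
#' @return A list: `predicted_class`, `predicted_cm`, `true_cm`, `error_cm`,
#'   `confusion` (n_classes x n_classes, rows = true class).
#' @export
decode_and_score <- function(model, dataset, laps = 1) {
  sel <- dataset$lap %in% laps
  if (!any(sel)) stop("no samples in the requested laps")
  X <- dataset$X[sel, model$cells, drop = FALSE]
  ll <- nb_loglik(model, X)
  pred <- max.col(ll, ties.method = "first")
  class_w <- model$track_length_cm / model$n_classes
  pred_cm <- (pred - 0.5) * class_w
  true_cm <- dataset$position_cm[sel]
  true_cls <- dataset$class[sel]
  conf <- matrix(0L, model$n_classes, model$n_classes)
  for (k in seq_along(pred)) {
    conf[true_cls[k], pred[k]] <- conf[true_cls[k], pred[k]] + 1L
  }
  list(predicted_class = pred, predicted_cm = pred_cm, true_cm = true_cm,
       error_cm = mean(abs(pred_cm - true_cm)), confusion = conf)
}

#' Repeated-subsampling decoding experiment
#'
#' Repeats the decoder construction `n_repeats` times, each with a fresh
#' random draw of `n_cells` cells (without replacement), training on the
#' mid-session laps and decoding the first lap.
#'
#' @param dataset a `"pf_decoder_dataset"`.
#' @param n_repeats decoder trials.
#' @param n_cells cells per trial; an error names the shortfall when the
#'   population is smaller.
#' @param seed RNG seed.
#' @param test_laps laps scored per trial.
#' @param train_laps,val_laps passed to [train_nb_decoder()].
#' @param shuffle_labels train on permuted labels (chance control).
#' @return A list: `errors_cm` (length `n_repeats`), `val_errors_cm`.
#' @export
decoding_experiment <- function(dataset, n_repeats = 20, n_cells = 200,
                                seed = 1L, test_laps = 1,
                                train_laps = 6:35, val_laps = 36:40,
                                shuffle_labels = FALSE) {
  pop <- ncol(dataset$X)
  if (pop < n_cells) {
    stop(sprintf("population has %d cells; %d requested", pop, n_cells))
  }
  set.seed(seed)
  errors <- numeric(n_repeats)
  val <- rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    cells <- sample.int(pop, n_cells)
    model <- train_nb_decoder(dataset, cells, train_laps, val_laps,
                              shuffle_labels = shuffle_labels,
                              seed = derive_seed(seed, r))
    if (!is.null(model$val_error_cm)) val[r] <- model$val_error_cm
    errors[r] <- decode_and_score(model, dataset, test_laps)$error_cm
  }
  list(errors_cm = errors, val_errors_cm = val)
}
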