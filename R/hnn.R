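#' Architecture of the seven-subnet hierarchical dose network
#'
#' Returns the subnet specifications of the hierarchical network. Five leaf
#' subnets each consume one input group — O1 the red-channel net optical
#' density (1-20-10-7-1), O2 the red irradiated/background pixel values
#' (2-10-7-2-1), O3 and O4 the green and blue pairs (2-10-7-1), O5 the three
#' inverse transmittances (3-15-7-1) — and two combining subnets merge them:
#' O6 = f(O2, O3, O4) (3-10-7-1) and O7 = f(O1, O5, O6) (3-20-6-1), whose
#' single output is the dose estimate H in cGy.
#'
#' Hidden-layer activations default to selu (O1, O6, O7), elu (O2), relu
#' (O3, O4) and softplus (O5); every subnet output layer is linear. The
#' assignment of activations to subnets is configurable through
#' `activations`, a named list of per-subnet character vectors (one entry per
#' non-input layer).
#'
#' @param activations optional named list overriding the per-subnet
#'   activation vectors; names must be drawn from
#'   `c("selu","elu","relu","softplus","linear")` and each subnet's final
#'   entry must be `"linear"`.
#' @return an object of class `hnn_spec`: a named list of subnets, each with
#'   `layer_sizes` and `activations`.
#' @examples
#' spec <- hnn_spec()
#' count_params(spec) # 1209
#' @export
hnn_spec <- function(activations = NULL) {
  sizes <- list(
    O1 = c(1, 20, 10, 7, 1),
    O2 = c(2, 10, 7, 2, 1),
    O3 = c(2, 10, 7, 1),
    O4 = c(2, 10, 7, 1),
    O5 = c(3, 15, 7, 1),
    O6 = c(3, 10, 7, 1),
    O7 = c(3, 20, 6, 1)
  )
  hidden <- list(O1 = "selu", O2 = "elu", O3 = "relu", O4 = "relu",
                 O5 = "softplus", O6 = "selu", O7 = "selu")
  spec <- lapply(names(sizes), function(nm) {
    nh <- length(sizes[[nm]]) - 2L
    acts <- c(rep(hidden[[nm]], nh), "linear")
    if (!is.null(activations) && nm %in% names(activations)) acts <- activations[[nm]]
    list(name = nm, layer_sizes = sizes[[nm]], activations = acts)
  })
  names(spec) <- names(sizes)
  validate_hnn_spec(spec)
  structure(spec, class = "hnn_spec")
}

validate_hnn_spec <- function(spec) {
  sizes <- list(
    O1 = c(1, 20, 10, 7, 1), O2 = c(2, 10, 7, 2, 1), O3 = c(2, 10, 7, 1),
    O4 = c(2, 10, 7, 1), O5 = c(3, 15, 7, 1), O6 = c(3, 10, 7, 1),
    O7 = c(3, 20, 6, 1)
  )
  for (nm in names(sizes)) {
    s <- spec[[nm]]
    if (is.null(s) || !identical(as.integer(s$layer_sizes), as.integer(sizes[[nm]]))) {
      stop_input("subnet ", nm, " must have layer sizes ",
                 paste(sizes[[nm]], collapse = "-"))
    }
    if (length(s$activations) != length(s$layer_sizes) - 1L) {
      stop_input("subnet ", nm, " needs one activation per non-input layer")
    }
    bad <- setdiff(s$activations, hnn_activations())
    if (length(bad)) stop_input("unknown activation(s): ", paste(bad, collapse = ", "))
    if (utils::tail(s$activations, 1L) != "linear") {
      stop_input("subnet ", nm, " must have a linear output layer")
    }
    if (utils::tail(s$layer_sizes, 1L) != 1L) {
      stop_input("subnet ", nm, " must have a single output")
    }
  }
  invisible(spec)
}

#' Analytic trainable-parameter count of a network specification
#'
#' Sums `fan_in * fan_out + fan_out` (weights plus biases) over every layer of
#' every subnet. The default architecture has 1209 trainable parameters.
#'
#' @param spec an [hnn_spec()] (default architecture if omitted), or a list of
#'   subnets each carrying `layer_sizes`.
#' @return integer parameter count.
#' @export
count_params <- function(spec = hnn_spec()) {
  tot <- 0L
  for (s in spec) {
    sz <- s$layer_sizes
    for (l in seq_len(length(sz) - 1L)) tot <- tot + sz[l] * sz[l + 1L] + sz[l + 1L]
  }
  as.integer(tot)
}

#' Training configuration for the hierarchical network
#'
#' Defaults mirror the calibration protocol: Adam optimiser on a mean-squared
#' error objective, batch size 20, 500 epochs, 45 % of the samples held back
#' for validation, uniform initial weights from seed 435.
#'
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training fraction.
#' @param validation_split fraction of samples held back for validation,
#'   in (0, 1); realised as a seeded shuffle followed by a tail split.
#' @param seed integer seed governing weight initialisation, the
#'   validation split and minibatch shuffling.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param init_range range of the uniform weight initialiser.
#' @param standardize if `TRUE` (default), z-score the ten input features
#'   using the training-set mean and standard deviation; the scaling is
#'   stored with the model and re-applied on prediction, so the interface
#'   still consumes features on their natural scales. Set `FALSE` to feed
#'   the raw features to the network; with the uniform weight initialiser
#'   this converges far more slowly because the pixel-value features are
#'   four orders of magnitude larger than the optical densities.
#' @param verbose print a progress line every `verbose` epochs (0 = silent).
#' @return a list of class `hnn_control`.
#' @export
hnn_control <- function(batch_size = 20, epochs = 500, validation_split = 0.45,
                        seed = 435, learning_rate = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, epsilon = 1e-7,
                        init_range = c(-0.05, 0.05),
                        standardize = TRUE, verbose = 0) {
  if (validation_split <= 0 || validation_split >= 1) {
    stop_input("validation_split must be strictly between 0 and 1")
  }
  if (batch_size < 1 || epochs < 1) stop_input("batch_size and epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 validation_split = validation_split, seed = as.integer(seed),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, init_range = init_range,
                 standardize = isTRUE(standardize), verbose = verbose),
            class = "hnn_control")
}

# Seeded uniform initialisation of all subnets of a spec.
hnn_init_weights <- function(spec, seed, init_range = c(-0.05, 0.05)) {
  with_seed(seed, {
    subnets <- lapply(spec, function(s) {
      subnet_init(s$layer_sizes, s$activations, init_range)
    })
    names(subnets) <- names(spec)
    subnets
  })
}

#' Fit the hierarchical dose network to calibration samples
#'
#' Trains the seven-subnet network end to end against delivered dose with a
#' mean-squared-error objective (single loss at the O7 output; intermediate
#' subnet outputs carry no auxiliary losses). Weights start from a seeded
#' uniform initialisation; a seeded shuffle holds back the last
#' `validation_split` fraction of the samples for validation, and the
#' training fraction is reshuffled into minibatches every epoch. Per-epoch
#' mean squared error (cGy^2), mean absolute error (cGy) and an exact-match
#' "accuracy" (recorded for protocol completeness only — it is not a
#' meaningful regression metric) are logged for both partitions.
#'
#' @param samples a `data.frame` of calibration samples: either the ten
#'   feature columns (`r_nod`, `r_ipv`, `r_bpv`, `g_ipv`, `g_bpv`, `b_ipv`,
#'   `b_bpv`, `r_it`, `g_it`, `b_it`) or raw pixel-value columns
#'   (`R_bpv`, `G_bpv`, `B_bpv`, `R_ipv`, `G_ipv`, `B_ipv`), plus the
#'   delivered dose column named by `dose_col` (cGy).
#' @param spec the network architecture, from [hnn_spec()].
#' @param control training configuration, from [hnn_control()].
#' @param dose_col name of the delivered-dose column.
#' @return an object of class `hnn` with elements `subnets` (trained
#'   weights), `spec`, `control`, `history` (per-epoch data.frame), `scaling`
#'   (feature centring/scale if standardisation was requested), `n_train`,
#'   `n_val` and `dose_range` (range of training doses, used to flag
#'   extrapolation downstream).
#' @seealso [predict.hnn()], [plot.hnn()], [write_hnn()]
#' @export
hnn_fit <- function(samples, spec = hnn_spec(), control = hnn_control(),
                    dose_col = "dose_cGy") {
  validate_hnn_spec(spec)
  if (!dose_col %in% names(samples)) stop_input("samples has no '", dose_col, "' column")
  X <- sample_features(samples)
  y <- as.numeric(samples[[dose_col]])
  n <- nrow(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop_input("features and doses must be finite")
  if (n < control$batch_size) stop_input("need at least one full batch of samples")

  scaling <- NULL
  if (control$standardize) {
    mu <- colMeans(X)
    sd <- apply(X, 2L, stats::sd)
    sd[sd == 0] <- 1
    X <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
    scaling <- list(center = mu, scale = sd)
  }

  subnets <- hnn_init_weights(spec, control$seed, control$init_range)

  nval <- floor(control$validation_split * n)
  res <- with_seed(derive_seed(control$seed, "split-and-batches"), {
    perm <- sample.int(n)
    val_idx <- if (nval > 0) utils::tail(perm, nval) else integer(0)
    tr_idx <- utils::head(perm, n - nval)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    ntr <- length(ytr)

    state <- adam_init(subnets)
    t <- 0L
    hist <- matrix(NA_real_, nrow = control$epochs, ncol = 7L)
    colnames(hist) <- c("epoch", "mse", "mae", "accuracy", "val_mse", "val_mae", "val_accuracy")
    nan_epoch <- NA_integer_

    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq.int(1L, ntr, by = control$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + control$batch_size - 1L, ntr)]
        xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        fw <- hnn_forward(subnets, xb, cache = TRUE)
        dH <- 2 * (fw$out - yb) / length(yb)
        grads <- hnn_backward(subnets, fw, dH)
        t <- t + 1L
        upd <- adam_step(subnets, grads, state, t,
                         lr = control$learning_rate, beta1 = control$beta1,
                         beta2 = control$beta2, eps = control$epsilon)
        subnets <- upd$subnets
        state <- upd$state
      }
      ptr <- hnn_forward(subnets, Xtr)
      if (any(!is.finite(ptr))) { nan_epoch <- ep; break }
      hist[ep, 1L] <- ep
      hist[ep, 2L] <- mean((ptr - ytr)^2)
      hist[ep, 3L] <- mean(abs(ptr - ytr))
      hist[ep, 4L] <- mean(ptr == ytr)
      if (nval > 0) {
        pv <- hnn_forward(subnets, Xval)
        hist[ep, 5L] <- mean((pv - yval)^2)
        hist[ep, 6L] <- mean(abs(pv - yval))
        hist[ep, 7L] <- mean(pv == yval)
      }
      if (control$verbose > 0 && ep %% control$verbose == 0) {
        message(sprintf("epoch %4d  mse %10.3f  mae %7.3f  val_mse %10.3f",
                        ep, hist[ep, 2L], hist[ep, 3L], hist[ep, 5L]))
      }
    }
    if (!is.na(nan_epoch)) {
      stop("training diverged: non-finite loss at epoch ", nan_epoch)
    }
    list(subnets = subnets, history = as.data.frame(hist), n_train = ntr, n_val = nval)
  })

  structure(list(
    subnets = res$subnets,
    spec = spec,
    control = control,
    scaling = scaling,
    history = res$history,
    n_train = res$n_train,
    n_val = res$n_val,
    dose_range = range(y),
    trained = TRUE
  ), class = "hnn")
}

# Apply stored feature scaling (if any) and run the forward pass.
hnn_eval <- function(object, X) {
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2L, object$scaling$center), 2L, object$scaling$scale, "/")
  }
  hnn_forward(object$subnets, X)
}

#' Predict dose with a trained hierarchical network
#'
#' @param object a fitted [hnn_fit()] model.
#' @param newdata a `data.frame` of samples with either the ten feature
#'   columns or raw pixel-value columns (same conventions as [hnn_fit()]).
#' @param ... unused.
#' @return numeric vector of dose estimates H in cGy, one per row.
#' @export
predict.hnn <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop_input("model has not been trained")
  X <- sample_features(newdata)
  if (!all(is.finite(X))) stop_input("features must be finite")
  as.numeric(hnn_eval(object, X))
}

#' @export
print.hnn <- function(x, ...) {
  cat("Hierarchical dose-calibration network (7 subnets,",
      count_params(x$spec), "parameters)\n")
  for (s in x$spec) {
    cat(sprintf("  %s: %s  [%s]\n", s$name,
                paste(s$layer_sizes, collapse = "-"),
                paste(s$activations, collapse = ", ")))
  }
  cat(sprintf("  trained on %d samples (+%d validation), %d epochs, batch %d, seed %d\n",
              x$n_train, x$n_val, x$control$epochs, x$control$batch_size, x$control$seed))
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("  final mse %.3f cGy^2, mae %.3f cGy (validation mse %.3f, mae %.3f)\n",
              last$mse, last$mae, last$val_mse, last$val_mae))
  invisible(x)
}

#' @export
summary.hnn <- function(object, ...) {
  h <- object$history
  structure(list(model = object, final = h[nrow(h), ]), class = "summary.hnn")
}

#' @export
print.summary.hnn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training dose range %.1f - %.1f cGy\n",
              x$model$dose_range[1L], x$model$dose_range[2L]))
  invisible(x)
}

#' @export
coef.hnn <- function(object, ...) {
  object$subnets
}

#' Residuals of a trained network on its feature/dose samples
#'
#' @param object a fitted [hnn_fit()] model.
#' @param samples sample table with features and delivered dose.
#' @param dose_col delivered-dose column name.
#' @param ... unused.
#' @return vector of `H - dose` residuals in cGy.
#' @export
residuals.hnn <- function(object, samples, dose_col = "dose_cGy", ...) {
  predict(object, samples) - as.numeric(samples[[dose_col]])
}

#' Plot the training history of a fitted network
#'
#' Draws training and validation mean-squared error against epoch on a log
#' scale.
#'
#' @param x a fitted [hnn_fit()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$mse, h$val_mse), type = "l", lty = 1,
                    col = c("black", "red3"), log = "y",
                    xlab = "epoch", ylab = expression(MSE ~ (cGy^2)), ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(x)
}

#' Serialize a fitted network to a portable JSON container
#'
#' The file holds a header (architecture, training control, feature scaling,
#' training summary) and flat weight arrays per layer, so a model outlives
#' any particular in-memory representation.
#'
#' @param object a fitted [hnn_fit()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hnn <- function(object, path) {
  if (!inherits(object, "hnn")) stop_input("object must be an 'hnn' model")
  ser <- list(
    format = "filmhnn-model",
    version = 1L,
    spec = lapply(unclass(object$spec), function(s) {
      list(name = s$name, layer_sizes = as.integer(s$layer_sizes),
           activations = s$activations)
    }),
    control = unclass(object$control),
    scaling = object$scaling,
    n_train = object$n_train, n_val = object$n_val,
    dose_range = object$dose_range,
    history = as.list(object$history),
    weights = lapply(object$subnets, function(layers) lapply(layers, function(ly) {
      list(dim = dim(ly$W), W = as.numeric(ly$W), b = as.numeric(ly$b), act = ly$act)
    }))
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Read a serialized network model
#'
#' @param path a file written by [write_hnn()].
#' @return an object of class `hnn`.
#' @export
read_hnn <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(ser$format, "filmhnn-model")) stop_input("not a filmhnn model file")
  spec <- lapply(ser$spec, function(s) {
    list(name = s$name, layer_sizes = as.integer(s$layer_sizes),
         activations = as.character(s$activations))
  })
  names(spec) <- vapply(spec, `[[`, "", "name")
  class(spec) <- "hnn_spec"
  subnets <- lapply(ser$weights, function(layers) lapply(layers, function(ly) {
    list(W = matrix(ly$W, ly$dim[1L], ly$dim[2L]), b = as.numeric(ly$b), act = ly$act)
  }))
  scaling <- ser$scaling
  if (!is.null(scaling)) {
    scaling <- list(center = unlist(scaling$center), scale = unlist(scaling$scale))
  }
  ctl <- ser$control
  control <- hnn_control(batch_size = ctl$batch_size, epochs = ctl$epochs,
                         validation_split = ctl$validation_split, seed = ctl$seed,
                         learning_rate = ctl$learning_rate, beta1 = ctl$beta1,
                         beta2 = ctl$beta2, epsilon = ctl$epsilon,
                         init_range = unlist(ctl$init_range),
                         standardize = isTRUE(ctl$standardize), verbose = 0)
  structure(list(subnets = subnets, spec = spec, control = control,
                 scaling = scaling, history = as.data.frame(ser$history),
                 n_train = ser$n_train, n_val = ser$n_val,
                 dose_range = as.numeric(ser$dose_range), trained = TRUE),
            class = "hnn")
}
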