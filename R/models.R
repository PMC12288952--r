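#' Architecture specification for the classifier family
#'
#' Three variants share a convolutional trunk over the one-hot encoded
#' window and differ in how (and whether) handcrafted k-mer features join
#' the decision layer:
#'
#' * **SM** (simple): convolutional features only.
#' * **HM** (hybrid): raw 4^k k-mer counts concatenated with the
#'   convolutional features.
#' * **DHM** (deep hybrid): k-mer counts first pass through a ReLU dense
#'   layer (`dhm_units` neurons) before concatenation.
#'
#' The trunk is `Conv1D(conv1_filters, conv1_kernel, stride 1, same
#' padding) -> ReLU -> MaxPool(pool_size) -> Dropout -> Conv1D(conv2_filters,
#' conv2_kernel) -> ReLU -> MaxPool(pool_size) -> Dropout -> Flatten`.
#' After concatenation a final Dropout, one batch-normalization layer
#' (disable with `batch_norm = FALSE`), and a sigmoid dense unit produce the
#' site probability. With the defaults (`L = 2001`, pools of 15, conv
#' kernels 23 and 33) the trunk lengths run 2001 -> 133 -> 8 and the flatten
#' width is `8 * 128 = 1024`, giving decision-layer widths 1024 (SM),
#' 2048 (HM) and 1088 (DHM).
#'
#' Max-pooling is non-overlapping with floor truncation (stride equals the
#' pool size), which is what the pooled lengths above imply. Convolutions
#' use length-preserving padding, so conv layers never change the length
#' axis. Kernel sizes must be odd for symmetric padding.
#'
#' @param variant `"SM"`, `"HM"`, or `"DHM"`.
#' @param L Input window length (default 2001).
#' @param conv1_filters,conv1_kernel First convolution: filters and kernel.
#' @param conv2_filters,conv2_kernel Second convolution: filters and kernel.
#' @param pool_size Max-pool window (= stride) for both pooling stages.
#' @param dropout Drop probability of the two trunk dropout layers (after
#'   each pooling stage).
#' @param head_dropout Drop probability of the dropout layer before the
#'   final dense unit; defaults to `dropout`.
#' @param kmer_k k of the k-mer branch; the branch width is `4^k`.
#' @param dhm_units Width of the DHM dense transform of the k-mer vector.
#' @param batch_norm Apply batch normalization before the final dense layer.
#' @return An object of class `m6a_model_spec`.
#' @export
model_spec <- function(variant = c("SM", "HM", "DHM"), L = 2001,
                       conv1_filters = 64, conv1_kernel = 23,
                       conv2_filters = 128, conv2_kernel = 33,
                       pool_size = 15, dropout = 0.5, head_dropout = dropout,
                       kmer_k = 5, dhm_units = 64, batch_norm = TRUE) {
  variant <- match.arg(variant)
  if (L < conv1_kernel) stop("L must be at least conv1_kernel", call. = FALSE)
  if (conv1_kernel %% 2 == 0 || conv2_kernel %% 2 == 0) {
    stop("conv kernels must be odd for symmetric length-preserving padding",
         call. = FALSE)
  }
  if (!(dropout >= 0 && dropout < 1) || !(head_dropout >= 0 && head_dropout < 1)) {
    stop("dropout rates must be in [0, 1)", call. = FALSE)
  }
  pooled1 <- L %/% pool_size
  pooled2 <- pooled1 %/% pool_size
  if (pooled2 < 1) {
    stop("architecture error: length chain ", L, " -> ", pooled1, " -> ",
         pooled2, " collapses to zero under two max-pool(", pool_size,
         ") stages; increase L or reduce pool_size", call. = FALSE)
  }
  kmer_dim <- 4L^kmer_k
  flatten_dim <- pooled2 * conv2_filters
  concat_dim <- switch(variant,
    SM = flatten_dim,
    HM = flatten_dim + kmer_dim,
    DHM = flatten_dim + dhm_units)
  structure(list(
    variant = variant, L = as.integer(L),
    conv1_filters = as.integer(conv1_filters), conv1_kernel = as.integer(conv1_kernel),
    conv2_filters = as.integer(conv2_filters), conv2_kernel = as.integer(conv2_kernel),
    pool_size = as.integer(pool_size), dropout = dropout,
    head_dropout = head_dropout,
    kmer_k = as.integer(kmer_k), kmer_dim = as.integer(kmer_dim),
    dhm_units = as.integer(dhm_units), batch_norm = isTRUE(batch_norm),
    pooled1 = as.integer(pooled1), pooled2 = as.integer(pooled2),
    flatten_dim = as.integer(flatten_dim), concat_dim = as.integer(concat_dim)
  ), class = "m6a_model_spec")
}

#' Desk-scale ("fast") architecture profile
#'
#' A reduced profile for short synthetic windows and quick experiments:
#' `L = 201`, conv layers of 16 filters (kernel 9) and 32 filters (kernel
#' 5), pools of 5 (lengths 201 -> 40 -> 8, flatten 256), dropout 0.1 (the
#' small nets underfit within a 10-epoch budget at the full-scale rate of
#' 0.5), and a 3-mer branch (64 dimensions) so the handcrafted-feature
#' capacity shrinks in proportion to everything else — at desk-scale sample
#' sizes a 1024-dimensional branch memorizes a few hundred training windows
#' outright instead of learning. Pair with [train_config_fast()] and encode
#' with `k = 3`. The faithful full-scale defaults of [model_spec()] remain
#' untouched; this profile simply makes the same architecture family train
#' in seconds on hundreds of records.
#'
#' @inheritParams model_spec
#' @param ... Overrides forwarded to [model_spec()].
#' @export
model_spec_fast <- function(variant = c("SM", "HM", "DHM"), L = 201, ...) {
  args <- list(variant = match.arg(variant), L = L,
               conv1_filters = 16, conv1_kernel = 9,
               conv2_filters = 32, conv2_kernel = 5,
               pool_size = 5, dropout = 0.1, kmer_k = 3)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(model_spec, args)
}

#' Training configuration
#'
#' Defaults follow the standard regimen for this model family: Adam with
#' learning rate 0.001, batch size 64, 70 epochs, binary cross-entropy
#' loss. Desk-scale runs usually lower `epochs` (and may raise
#' `learning_rate`); the loss is fixed because the task is binary.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training data (>= 1).
#' @param seed Integer seed controlling weight initialization, shuffling,
#'   and dropout; identical seeds give identical training runs.
#' @param verbose Print per-epoch loss.
#' @return An object of class `m6a_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64, epochs = 70,
                         seed = 1, verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be at least 1", call. = FALSE)
  if (epochs < 1) stop("epochs must be at least 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "m6a_train_config")
}

#' Desk-scale training regimen
#'
#' Companion to [model_spec_fast()]: 10 epochs, batch size 16, learning
#' rate 0.01 — enough optimizer steps for the reduced architectures to find
#' a centered motif in a few hundred short windows within seconds.
#'
#' @inheritParams train_config
#' @param ... Overrides forwarded to [train_config()].
#' @export
train_config_fast <- function(seed = 1, ...) {
  args <- list(learning_rate = 0.01, batch_size = 16, epochs = 10, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(train_config, args)
}

#' Build an (untrained) model from a specification
#'
#' Validates the spec, derives the full layer shape chain, and returns a
#' model handle carrying the introspection table ([model_shapes()]) and the
#' exact parameter count. Weights are initialized at training time from the
#' training seed, so building is cheap and purely structural.
#'
#' @param spec An [model_spec()] object.
#' @return An object of class `m6a_model` with elements `spec`, `shapes`,
#'   `n_params`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "m6a_model_spec"))
  shapes <- model_shapes(spec)
  structure(list(spec = spec, shapes = shapes,
                 n_params = count_params(spec)),
            class = "m6a_model")
}

count_params <- function(spec) {
  n <- spec$conv1_kernel * 4L * spec$conv1_filters + spec$conv1_filters +
    spec$conv2_kernel * spec$conv1_filters * spec$conv2_filters + spec$conv2_filters +
    spec$concat_dim + 1L
  if (spec$variant == "DHM") {
    n <- n + spec$kmer_dim * spec$dhm_units + spec$dhm_units
  }
  if (spec$batch_norm) n <- n + 2L * spec$concat_dim
  n
}

#' Layer-by-layer output shapes of a model
#'
#' The introspection table used to verify architecture conformance: one row
#' per layer with its output shape (batch dimension omitted). For the
#' default spec at `L = 2001` the chain is
#' `(2001, 4) -> (2001, 64) -> (133, 64) -> (133, 128) -> (8, 128) -> 1024`,
#' then decision widths 1024/2048/1088 for SM/HM/DHM.
#'
#' @param x An `m6a_model_spec` or `m6a_model`.
#' @return Tibble with columns `layer`, `output_shape` (integer list
#'   column), `shape` (printable string).
#' @export
model_shapes <- function(x) {
  spec <- if (inherits(x, "m6a_model")) x$spec else x
  stopifnot(inherits(spec, "m6a_model_spec"))
  rows <- list(
    list("input_onehot", c(spec$L, 4L)),
    list("conv1", c(spec$L, spec$conv1_filters)),
    list("maxpool1", c(spec$pooled1, spec$conv1_filters)),
    list("dropout1", c(spec$pooled1, spec$conv1_filters)),
    list("conv2", c(spec$pooled1, spec$conv2_filters)),
    list("maxpool2", c(spec$pooled2, spec$conv2_filters)),
    list("dropout2", c(spec$pooled2, spec$conv2_filters)),
    list("flatten_cnn", spec$flatten_dim)
  )
  if (spec$variant == "HM") {
    rows <- c(rows, list(
      list("input_kmer", spec$kmer_dim),
      list("flatten_kmer", spec$kmer_dim),
      list("concatenate", spec$concat_dim)))
  } else if (spec$variant == "DHM") {
    rows <- c(rows, list(
      list("input_kmer", spec$kmer_dim),
      list("dense_kmer", spec$dhm_units),
      list("flatten_kmer", spec$dhm_units),
      list("concatenate", spec$concat_dim)))
  }
  rows <- c(rows, list(
    list("dropout_head", spec$concat_dim),
    if (spec$batch_norm) list("batch_norm", spec$concat_dim),
    list("dense_sigmoid", 1L)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tibble::tibble(
    layer = vapply(rows, function(r) r[[1]], character(1)),
    output_shape = lapply(rows, function(r) as.integer(r[[2]])),
    shape = vapply(rows, function(r) {
      paste0("(", paste(r[[2]], collapse = ", "), ")")
    }, character(1))
  )
}

#' @export
print.m6a_model <- function(x, ...) {
  cat(sprintf("# m6a_model: variant %s, L = %d, %d parameters\n",
              x$spec$variant, x$spec$L, x$n_params))
  print(x$shapes[, c("layer", "shape")], n = Inf)
  invisible(x)
}

check_features <- function(spec, features, need_labels = TRUE) {
  stopifnot(inherits(features, "m6a_features"))
  if (is.null(features$onehot)) {
    stop("feature bundle lacks one-hot encodings (all variants need them); ",
         "encode with scheme = \"both\" or \"onehot\"", call. = FALSE)
  }
  d <- dim(features$onehot)
  if (d[2] != spec$L || d[3] != 4) {
    stop("one-hot shape mismatch: expected (*, ", spec$L, ", 4), received (*, ",
         d[2], ", ", d[3], ")", call. = FALSE)
  }
  if (spec$variant %in% c("HM", "DHM")) {
    if (is.null(features$kmer)) {
      stop("variant ", spec$variant, " needs k-mer features; encode with ",
           "scheme = \"both\" or \"kmer\"", call. = FALSE)
    }
    if (ncol(features$kmer) != spec$kmer_dim) {
      stop("k-mer width mismatch: expected ", spec$kmer_dim, ", received ",
           ncol(features$kmer), call. = FALSE)
    }
  }
  if (need_labels && !all(features$label %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a model on an encoded feature bundle
#'
#' Minimizes binary cross-entropy with Adam over shuffled mini-batches.
#' All randomness (weight initialization, epoch shuffles, dropout masks)
#' derives from `config$seed`, so two runs on identical inputs produce
#' identical histories. Training aborts with an error if the loss becomes
#' non-finite.
#'
#' @param model An [build_model()] handle (or an `m6a_model_spec`).
#' @param features An [encode_dataset()] bundle with binary labels.
#' @param config An [train_config()].
#' @return An object of class `m6a_fit`: the spec, learned weights,
#'   batch-norm running statistics, the per-epoch loss history (a tibble),
#'   and the training configuration.
#' @export
train_model <- function(model, features, config = train_config()) {
  if (inherits(model, "m6a_model_spec")) model <- build_model(model)
  stopifnot(inherits(model, "m6a_model"), inherits(config, "m6a_train_config"))
  spec <- model$spec
  check_features(spec, features)
  y <- as.numeric(features$label)
  n <- length(y)
  K <- if (spec$variant == "SM") NULL else features$kmer

  with_seed(config$seed, {
    params <- init_params(spec)
    bn_state <- list(mean = rep(0, spec$concat_dim),
                    var = rep(1, spec$concat_dim))
    opt <- adam_init(params)
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- features$onehot[idx, , , drop = FALSE]
        Kb <- if (is.null(K)) NULL else K[idx, , drop = FALSE]
        fwd <- net_forward(params, spec, Xb, Kb, bn_state, training = TRUE)
        bn_state <- fwd$bn_state
        loss <- bce_loss(fwd$p, y[idx])
        if (!is.finite(loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- net_backward(params, spec, fwd, y[idx])
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      history[epoch] <- ep_loss / n
      if (config$verbose) {
        message(sprintf("epoch %d/%d  loss %.4f", epoch, config$epochs,
                        history[epoch]))
      }
    }
    structure(list(
      spec = spec, params = params, bn_state = bn_state,
      history = tibble::tibble(epoch = seq_len(config$epochs), loss = history),
      config = config, n_train = n, n_params = model$n_params
    ), class = "m6a_fit")
  })
}

#' @export
print.m6a_fit <- function(x, ...) {
  cat(sprintf("# m6a_fit: variant %s, L = %d, %d epochs, final loss %.4f\n",
              x$spec$variant, x$spec$L, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Predict site probabilities
#'
#' Applies the trained network in inference mode (no dropout; batch
#' normalization uses running statistics). Output probabilities are strictly
#' inside (0, 1) and aligned with the bundle's record order.
#'
#' @param object An `m6a_fit`.
#' @param features An [encode_dataset()] bundle.
#' @param batch_size Records per forward batch.
#' @param ... Unused.
#' @return Numeric vector of probabilities named by record id.
#' @export
predict.m6a_fit <- function(object, features, batch_size = 256, ...) {
  check_features(object$spec, features, need_labels = FALSE)
  n <- length(features$id)
  out <- numeric(n)
  K <- if (object$spec$variant == "SM") NULL else features$kmer
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    fwd <- net_forward(object$params, object$spec,
                       features$onehot[idx, , , drop = FALSE],
                       if (is.null(K)) NULL else K[idx, , drop = FALSE],
                       object$bn_state, training = FALSE)
    out[idx] <- fwd$p
  }
  stats::setNames(out, features$id)
}

#' Extract internal embeddings from a trained model
#'
#' Taps the named internal layer for each record, typically for t-SNE
#' visualization of what the model has learned:
#' `"kmer_raw"` (the handcrafted 4^k vector, HM/DHM), `"kmer_deep"` (the
#' ReLU dense transform, DHM only), `"cnn"` (the flattened convolutional
#' features, all variants), `"fused"` (the concatenated decision-layer
#' input, HM/DHM).
#'
#' @param fit An `m6a_fit`.
#' @param features An [encode_dataset()] bundle.
#' @param tap Which layer to tap.
#' @param batch_size Records per forward batch.
#' @return Numeric matrix, one row per record.
#' @export
extract_features <- function(fit, features,
                             tap = c("cnn", "kmer_raw", "kmer_deep", "fused"),
                             batch_size = 256) {
  tap <- match.arg(tap)
  variant <- fit$spec$variant
  if (tap == "kmer_deep" && variant != "DHM") {
    stop("tap \"kmer_deep\" requires the DHM variant", call. = FALSE)
  }
  if (tap %in% c("fused", "kmer_raw") && variant == "SM") {
    stop("tap \"", tap, "\" requires a hybrid variant (HM or DHM)", call. = FALSE)
  }
  check_features(fit$spec, features, need_labels = FALSE)
  n <- length(features$id)
  K <- if (variant == "SM") NULL else features$kmer
  chunks <- vector("list", length(seq(1, n, by = batch_size)))
  ci <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    fwd <- net_forward(fit$params, fit$spec,
                       features$onehot[idx, , , drop = FALSE],
                       if (is.null(K)) NULL else K[idx, , drop = FALSE],
                       fit$bn_state, training = FALSE, want_taps = tap)
    ci <- ci + 1
    chunks[[ci]] <- fwd$taps[[tap]]
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- features$id
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.m6a_fit <- function(x, ...) x$history

#' @export
glance.m6a_fit <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant, L = x$spec$L,
                 n_params = x$n_params, n_train = x$n_train,
                 epochs = nrow(x$history),
                 initial_loss = x$history$loss[1],
                 final_loss = x$history$loss[nrow(x$history)])
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the spec, weights, batch-norm
#' state, history and config — everything [predict.m6a_fit()] needs.
#'
#' @param fit An `m6a_fit`.
#' @param path Checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the fit.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "m6a_fit"))
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "m6a_fit")
}
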