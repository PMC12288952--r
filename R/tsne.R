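# Exact t-SNE (no Barnes-Hut approximation), written for the desk-scale
# embedding views this package produces (hundreds to a few thousand
# points). Standard recipe: per-point bandwidths found by binary search to
# match the target perplexity, symmetrized affinities, early exaggeration,
# and momentum gradient descent with per-coordinate gains.

tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D[D < 0] <- 0
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2-D t-SNE embedding of feature vectors
#'
#' Exact (dense) t-distributed stochastic neighbor embedding, seeded and
#' deterministic. Requires at least `3 * perplexity` points.
#'
#' @param X Numeric matrix, one row per point (e.g. from
#'   [extract_features()]).
#' @param perplexity Effective neighborhood size.
#' @param max_iter Gradient-descent iterations.
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y` (and `id` when `X` has rownames).
#' @export
tsne_embed <- function(X, perplexity = 30, max_iter = 400, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3 * perplexity) {
    stop("too few points (", n, ") for perplexity ", perplexity,
         "; need at least 3 * perplexity", call. = FALSE)
  }
  P <- tsne_affinities(scale(X, scale = FALSE), perplexity)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    momentum <- 0.5
    eta <- 100
    exaggeration <- 4
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= 100) P * exaggeration else P
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- scale(Y, scale = FALSE)
      if (iter == 250) momentum <- 0.8
    }
    out <- tibble::tibble(x = Y[, 1], y = Y[, 2])
    if (!is.null(rownames(X))) out <- dplyr::bind_cols(tibble::tibble(id = rownames(X)), out)
    out
  })
}

#' t-SNE view of labeled embeddings
#'
#' Embeds, attaches labels, optionally writes the coordinates as CSV and
#' the scatter plot to file. With a single class present the plot is still
#' produced with a warning.
#'
#' @param embeddings Numeric matrix of per-record embeddings.
#' @param labels Binary labels aligned with the rows.
#' @param seed,perplexity,max_iter Passed to [tsne_embed()].
#' @param csv,plot_file Optional output paths (plot format from the file
#'   extension, e.g. `.png` or `.svg`).
#' @return List with `coords` (tibble `x`, `y`, `label`) and `plot`
#'   (a ggplot object).
#' @export
tsne_view <- function(embeddings, labels, seed = 1, perplexity = 30,
                      max_iter = 400, csv = NULL, plot_file = NULL) {
  coords <- tsne_embed(embeddings, perplexity = perplexity,
                       max_iter = max_iter, seed = seed)
  coords$label <- as.integer(labels)
  if (length(unique(coords$label)) < 2) {
    warning("single-class labels: the view will show one color only",
            call. = FALSE)
  }
  if (!is.null(csv)) readr::write_csv(coords, csv, progress = FALSE)
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(`0` = "#4477AA", `1` = "#EE6677"),
                                 name = "label") +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (!is.null(plot_file)) ggplot2::ggsave(plot_file, p, width = 5, height = 4)
  list(coords = coords, plot = p)
}
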