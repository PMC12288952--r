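#' All k-mers over (A, C, G, T) in lexicographic order
#'
#' The fixed index mapping used by [encode_kmer()]: position 1 is
#' `AAA...A`, position 4^k is `TTT...T`, with the first character most
#' significant. The mapping is deterministic so feature columns are
#' comparable across datasets and runs.
#'
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @examples
#' kmer_names(1) # "A" "C" "G" "T"
#' @export
kmer_names <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  letters4 <- c("A", "C", "G", "T")
  out <- letters4
  if (k > 1) {
    for (i in 2:k) out <- as.vector(t(outer(out, letters4, paste0)))
  }
  out
}

# A=0, C=1, G=2, T=3, anything else NA
.base_codes <- {
  codes <- rep(NA_integer_, 256)
  codes[utf8ToInt("A")] <- 0L
  codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L
  codes[utf8ToInt("T")] <- 3L
  codes
}

seq_to_codes <- function(seq) {
  .base_codes[utf8ToInt(seq)]
}

#' k-mer composition vector of a sequence
#'
#' Counts every length-`k` subsequence with a step-1 sliding window, giving a
#' `4^k`-dimensional vector (1024 dimensions for the default `k = 5`) indexed
#' lexicographically over (A, C, G, T) as in [kmer_names()]. Windows that
#' contain `N` contribute to no entry, so ambiguity never fabricates counts.
#' For an N-free sequence of length `L` the counts sum to `L - k + 1`.
#'
#' @param seq A nucleotide string over `A,C,G,T,N` (pass sequences through
#'   [as_m6a_dataset()] normalization first if they may contain `U` or
#'   lowercase).
#' @param k k-mer length (default 5).
#' @param normalized If `TRUE`, divide by the number of valid windows so
#'   entries sum to 1 (when any valid window exists).
#' @return Named numeric vector of length `4^k`; attributes `k` and
#'   `normalized`.
#' @examples
#' v <- encode_kmer("CAAATGTACG", 5)
#' sum(v) # 6 overlapping 5-mers
#' names(v)[v > 0]
#' @export
encode_kmer <- function(seq, k = 5, normalized = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (!is.character(seq) || length(seq) != 1) {
    stop("seq must be a single string", call. = FALSE)
  }
  n <- nchar(seq)
  if (n < k) {
    stop("sequence length (", n, ") is shorter than k (", k, ")", call. = FALSE)
  }
  v <- seq_to_codes(seq)
  nw <- n - k + 1L
  code <- v[seq_len(nw)]
  if (k > 1) {
    for (j in 1:(k - 1)) {
      code <- code * 4L + v[(1L + j):(nw + j)]
    }
  }
  counts <- tabulate(code[!is.na(code)] + 1L, nbins = 4L^k)
  counts <- as.numeric(counts)
  if (normalized) {
    tot <- sum(counts)
    if (tot > 0) counts <- counts / tot
  }
  names(counts) <- kmer_names(k)
  attr(counts, "k") <- k
  attr(counts, "normalized") <- normalized
  counts
}

#' One-hot encoding of a sequence
#'
#' Each position becomes a 4-bit indicator row: `A = (1,0,0,0)`,
#' `C = (0,1,0,0)`, `G = (0,0,1,0)`, `T = (0,0,0,1)`; `N` rows are all zero.
#' The matrix is positions x channels (`L` rows, 4 columns, column order
#' A, C, G, T) — the channels-by-positions description of the same encoding
#' is simply its transpose; the convolutional models here consume
#' (length, channels).
#'
#' @inheritParams encode_kmer
#' @return An `L x 4` integer matrix with columns `A,C,G,T`.
#' @examples
#' encode_onehot("ACGT") # 4 x 4 identity
#' @export
encode_onehot <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("seq must be a single non-empty string", call. = FALSE)
  }
  v <- seq_to_codes(seq)
  L <- length(v)
  m <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(v)
  m[cbind(which(ok), v[ok] + 1L)] <- 1L
  m
}

#' Encode a whole dataset into model-ready feature arrays
#'
#' Produces the feature bundle consumed by [build_model()] and
#' [train_model()]: a `B x L x 4` one-hot array and/or a `B x 4^k` k-mer
#' count matrix, row-aligned with the dataset's record order, plus the label
#' and id vectors.
#'
#' @param data An [as_m6a_dataset()] tibble.
#' @param scheme Which encodings to compute: `"both"` (default), `"kmer"`,
#'   or `"onehot"`.
#' @param k k-mer length for the k-mer branch.
#' @param normalized Passed to [encode_kmer()].
#' @return An object of class `m6a_features`: a list with elements `onehot`
#'   (array or `NULL`), `kmer` (matrix or `NULL`), `label`, `id`, `L`, `k`.
#' @export
encode_dataset <- function(data, scheme = c("both", "kmer", "onehot"), k = 5,
                           normalized = FALSE) {
  scheme <- match.arg(scheme)
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  L <- attr(data, "L")
  B <- nrow(data)
  onehot <- NULL
  kmer <- NULL
  if (scheme %in% c("both", "onehot")) {
    onehot <- array(0, dim = c(B, L, 4))
    for (i in seq_len(B)) onehot[i, , ] <- encode_onehot(data$sequence[i])
  }
  if (scheme %in% c("both", "kmer")) {
    kmer <- matrix(0, nrow = B, ncol = 4^k,
                   dimnames = list(data$id, kmer_names(k)))
    for (i in seq_len(B)) {
      kmer[i, ] <- encode_kmer(data$sequence[i], k = k, normalized = normalized)
    }
  }
  structure(
    list(onehot = onehot, kmer = kmer,
         label = data$label, id = data$id, L = L, k = as.integer(k)),
    class = "m6a_features")
}

#' @export
print.m6a_features <- function(x, ...) {
  cat(sprintf("# m6a_features: %d records, L = %d%s%s\n",
              length(x$label), x$L,
              if (!is.null(x$onehot)) sprintf(", one-hot %dx%dx4", dim(x$onehot)[1], x$L) else "",
              if (!is.null(x$kmer)) sprintf(", %d-mer %dx%d", x$k, nrow(x$kmer), ncol(x$kmer)) else ""))
  invisible(x)
}

#' Subset a feature bundle by record index
#'
#' Row-aligned subsetting of all arrays in an `m6a_features` bundle; used by
#' the split machinery to carve train/validation/test features out of one
#' encoded dataset.
#'
#' @param features An [encode_dataset()] bundle.
#' @param idx Integer indices or record ids.
#' @return An `m6a_features` bundle restricted to `idx`, order preserved.
#' @export
subset_features <- function(features, idx) {
  stopifnot(inherits(features, "m6a_features"))
  if (is.character(idx)) idx <- match(idx, features$id)
  if (anyNA(idx)) stop("unknown record id(s) in subset", call. = FALSE)
  structure(
    list(onehot = if (!is.null(features$onehot)) features$onehot[idx, , , drop = FALSE],
         kmer = if (!is.null(features$kmer)) features$kmer[idx, , drop = FALSE],
         label = features$label[idx], id = features$id[idx],
         L = features$L, k = features$k),
    class = "m6a_features")
}

#' Export a k-mer feature matrix as delimited text
#'
#' Writes one row per record with a header naming every k-mer column, for
#' inspection outside R.
#'
#' @param features An [encode_dataset()] bundle with a k-mer matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_kmer_table <- function(features, path) {
  stopifnot(inherits(features, "m6a_features"))
  if (is.null(features$kmer)) stop("bundle has no k-mer matrix", call. = FALSE)
  out <- tibble::as_tibble(features$kmer)
  out <- dplyr::bind_cols(tibble::tibble(id = features$id, label = features$label), out)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
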