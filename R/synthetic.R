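# IUPAC degeneracy codes over DNA letters
.iupac <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_regex <- function(consensus) {
  paste0(vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- .iupac[[ch]]
    if (is.null(opts)) stop("unknown IUPAC code: ", ch, call. = FALSE)
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

sample_motif_instance <- function(consensus) {
  paste0(vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- .iupac[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# anchor: index of the methylated adenosine within the consensus (the first
# literal A; for DRACH that is position 3)
motif_anchor <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  a <- which(chars == "A")[1]
  if (is.na(a)) (nchar(consensus) + 1L) %/% 2L else a
}

#' Configuration for the synthetic window generator
#'
#' Describes a labeled benchmark-like dataset: `n_pos` positive and `n_neg`
#' negative windows of length `L` spread over `chromosomes`, with positives
#' (and, at a lower rate, negatives) carrying one instance of a degenerate
#' consensus motif whose methylated adenosine sits at the window center
#' (plus an optional jitter). Each chromosome has its own background base
#' composition, perturbed away from uniform GC by the confounder strength
#' `confound` in `[0, 1]`: at `confound = 0` every chromosome is uniform; at
#' 1 the per-chromosome GC content spans 0.35-0.65. The motif itself is
#' never touched by the confounder, so compositional "cheating" signal and
#' true motif signal stay cleanly separable.
#'
#' Desk-scale defaults (hundreds of records, `L = 201`, six chromosomes,
#' motif insertion 0.9 for positives vs 0.1 for negatives, roughly 1:5
#' class imbalance) keep every downstream experiment fast;
#' [synth_config_benchmark()] gives the full-scale preset (10,424 positives,
#' 54,949 negatives, `L = 2001`, chr1-chr23).
#'
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param L Window length (odd so a center base exists).
#' @param chromosomes Chromosome labels.
#' @param chrom_weights Sampling weights per chromosome (default equal);
#'   normalized to sum to 1.
#' @param motif Degenerate consensus (IUPAC letters); default `"DRACH"`,
#'   i.e. `[AGT][AG]AC[ACT]`.
#' @param motif_prob_pos,motif_prob_neg Probability that a positive /
#'   negative window receives one motif instance at the (jittered) center.
#' @param center_jitter Maximum offset of the motif's adenosine from the
#'   window center (default 0: exactly centered).
#' @param confound Chromosome-composition confounder strength in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `m6a_synth_config`.
#' @export
synth_config <- function(n_pos = 300, n_neg = 1500, L = 201,
                         chromosomes = paste0("chr", 1:6),
                         chrom_weights = NULL, motif = "DRACH",
                         motif_prob_pos = 0.9, motif_prob_neg = 0.1,
                         center_jitter = 0, confound = 0, seed = 1) {
  if (n_pos < 1 || n_neg < 1) stop("need at least one record per class", call. = FALSE)
  if (L < nchar(motif)) {
    stop("infeasible config: L (", L, ") shorter than motif (", nchar(motif), ")",
         call. = FALSE)
  }
  if (!(motif_prob_pos >= 0 && motif_prob_pos <= 1) ||
      !(motif_prob_neg >= 0 && motif_prob_neg <= 1)) {
    stop("motif insertion probabilities must be in [0, 1]", call. = FALSE)
  }
  if (!(confound >= 0 && confound <= 1)) stop("confound must be in [0, 1]", call. = FALSE)
  if (is.null(chrom_weights)) chrom_weights <- rep(1, length(chromosomes))
  if (length(chrom_weights) != length(chromosomes) || any(chrom_weights < 0) ||
      sum(chrom_weights) == 0) {
    stop("chrom_weights must be non-negative, one per chromosome", call. = FALSE)
  }
  iupac_regex(motif) # validates letters
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg), L = as.integer(L),
    chromosomes = as.character(chromosomes),
    chrom_weights = chrom_weights / sum(chrom_weights),
    motif = motif, motif_prob_pos = motif_prob_pos,
    motif_prob_neg = motif_prob_neg,
    center_jitter = as.integer(center_jitter),
    confound = confound, seed = as.integer(seed)
  ), class = "m6a_synth_config")
}

#' Full-scale benchmark preset
#'
#' The class sizes, window length, and chromosome labels of the published
#' human m6A benchmark: 10,424 positives, 54,949 negatives, `L = 2001`,
#' chromosomes chr1-chr23. Generating at this scale takes minutes and is
#' meant for users who want full-scale runs; all tests use desk scale.
#'
#' @param ... Overrides forwarded to [synth_config()].
#' @export
synth_config_benchmark <- function(...) {
  args <- list(n_pos = 10424, n_neg = 54949, L = 2001,
               chromosomes = paste0("chr", 1:23))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

# per-chromosome composition offsets, evenly spaced in [-1, 1] over the
# natural-sorted chromosome order
chrom_offsets <- function(chromosomes) {
  chroms <- natural_sort(chromosomes)
  n <- length(chroms)
  s <- if (n == 1) 0 else seq(-1, 1, length.out = n)
  stats::setNames(s, chroms)
}

chrom_base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# shared generator core: class-specific chromosome weights allow the
# label-vs-chromosome coupling used by make_confounded_pair()
generate_core <- function(config, pos_weights, neg_weights, provenance) {
  L <- config$L
  offsets <- chrom_offsets(config$chromosomes)
  gc_by_chrom <- 0.5 + config$confound * 0.15 * offsets
  bases <- c("A", "C", "G", "T")
  anchor <- motif_anchor(config$motif)
  mlen <- nchar(config$motif)
  center <- (L + 1L) %/% 2L

  n <- config$n_pos + config$n_neg
  label <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  chrom <- character(n)
  chrom[label == 1L] <- sample(names(offsets), config$n_pos, replace = TRUE,
                               prob = pos_weights)
  chrom[label == 0L] <- sample(names(offsets), config$n_neg, replace = TRUE,
                               prob = neg_weights)

  seqs <- character(n)
  for (i in seq_len(n)) {
    probs <- chrom_base_probs(gc_by_chrom[[chrom[i]]])
    s <- sample(bases, L, replace = TRUE, prob = probs)
    p_ins <- if (label[i] == 1L) config$motif_prob_pos else config$motif_prob_neg
    if (stats::runif(1) < p_ins) {
      jit <- if (config$center_jitter > 0) {
        sample(seq(-config$center_jitter, config$center_jitter), 1)
      } else 0L
      at <- center + jit # position of the methylated A
      start <- at - anchor + 1L
      start <- max(1L, min(start, L - mlen + 1L))
      inst <- strsplit(sample_motif_instance(config$motif), "")[[1]]
      s[start:(start + mlen - 1L)] <- inst
    }
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("%s_%s_%06d", ifelse(label == 1L, "pos", "neg"), chrom,
                 seq_len(n))
  as_m6a_dataset(
    tibble::tibble(id = ids, chromosome = chrom, sequence = seqs, label = label),
    L = L, provenance = provenance)
}

#' Generate a synthetic labeled window dataset
#'
#' Draws every window from its chromosome's background composition and
#' inserts a concrete instance of the degenerate motif (letters sampled
#' uniformly over each position's compatible set, mimicking biological motif
#' variability) at the configured rate for each class. Both classes use the
#' same chromosome sampling weights, so label and chromosome are
#' independent — see [make_confounded_pair()] for the coupled variant.
#' Fully reproducible: the same config (including seed) yields a
#' byte-identical dataset.
#'
#' @param config An [synth_config()].
#' @return An [as_m6a_dataset()] tibble of `n_pos + n_neg` records.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "m6a_synth_config"))
  with_seed(config$seed, {
    w <- stats::setNames(config$chrom_weights, config$chromosomes)
    w <- w[natural_sort(config$chromosomes)]
    generate_core(config, w, w,
                  provenance = sprintf("generate_dataset(seed = %d)", config$seed))
  })
}

#' Generate a chromosome-confounded dataset
#'
#' Builds a dataset in which the label is partially predictable from
#' chromosome-specific background composition: positives are
#' preferentially placed on high-GC chromosomes (weight factor
#' `1 + 0.8 * confound * s_c` for chromosome offset `s_c`), negatives on
#' low-GC ones, while each chromosome's composition shifts with the same
#' offsets. A model evaluated under a random split can exploit this
#' shortcut — the same chromosomes (hence the same composition-label
#' association) appear in train and test — whereas under LOCO the held-out
#' chromosome's composition is constant within the fold and carries no
#' discriminative signal, so performance falls back to the true motif
#' signal. The default configuration deliberately carries only modest motif
#' signal (insertion 0.6 vs 0.2) so the compositional shortcut is worth
#' exploiting and the inflation is visible.
#'
#' With `confound = 0` the same construction degenerates to the
#' unconfounded control: uniform composition everywhere and label
#' independent of chromosome.
#'
#' @param config An [synth_config()]; the default is the balanced
#'   desk-scale confounded pair (250 + 250 records, six chromosomes,
#'   `confound = 0.8`).
#' @return An [as_m6a_dataset()] tibble.
#' @export
make_confounded_pair <- function(config = synth_config(
                                   n_pos = 250, n_neg = 250,
                                   motif_prob_pos = 0.6, motif_prob_neg = 0.2,
                                   confound = 0.8)) {
  stopifnot(inherits(config, "m6a_synth_config"))
  if (length(config$chromosomes) < 3) {
    stop("need at least 3 chromosomes for a meaningful confounded dataset",
         call. = FALSE)
  }
  with_seed(config$seed, {
    offsets <- chrom_offsets(config$chromosomes)
    w <- stats::setNames(config$chrom_weights, config$chromosomes)[names(offsets)]
    tilt <- 0.8 * config$confound * offsets
    pos_w <- pmax(w * (1 + tilt), 0.02 * w)
    neg_w <- pmax(w * (1 - tilt), 0.02 * w)
    generate_core(config, pos_w, neg_w,
                  provenance = sprintf("make_confounded_pair(confound = %g, seed = %d)",
                                       config$confound, config$seed))
  })
}

#' Simple baseline scores for generated data
#'
#' Deliberately crude classifiers used to characterize a dataset:
#' `"gc"` scores each window by its GC fraction (a pure composition
#' feature — exactly what the chromosome confounder leaks);
#' `"motif_count"` counts (overlapping) occurrences of the consensus
#' anywhere in the window; `"motif_center"` is 1 when a consensus instance
#' sits with its adenosine at the window center.
#'
#' @param data An [as_m6a_dataset()] tibble.
#' @param type Baseline type.
#' @param motif Degenerate consensus (default `"DRACH"`).
#' @return Numeric score vector aligned with `data`'s rows.
#' @export
baseline_scores <- function(data, type = c("gc", "motif_count", "motif_center"),
                            motif = "DRACH") {
  type <- match.arg(type)
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  seqs <- data$sequence
  if (type == "gc") {
    gc <- vapply(seqs, function(s) {
      sum(seq_to_codes(s) %in% c(1L, 2L)) / nchar(s)
    }, numeric(1), USE.NAMES = FALSE)
    return(gc)
  }
  rx <- iupac_regex(motif)
  if (type == "motif_count") {
    vapply(seqs, function(s) {
      m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
      if (m[1] == -1) 0 else length(m)
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    L <- attr(data, "L")
    center <- (L + 1L) %/% 2L
    anchor <- motif_anchor(motif)
    start <- center - anchor + 1L
    window <- substr(seqs, start, start + nchar(motif) - 1L)
    as.numeric(grepl(paste0("^", rx, "$"), window))
  }
}
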