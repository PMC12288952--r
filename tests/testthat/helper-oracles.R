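# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package: naive
# dictionary counting, direct formula evaluation, exhaustive pair counting.

# dictionary-based k-mer counter: walk every window, skip windows with N
oracle_kmer_counts <- function(seq, k) {
  counts <- stats::setNames(numeric(4^k), kmer_names(k))
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1
  }
  counts
}

# direct evaluation of the standard confusion-matrix formulas
oracle_metrics <- function(TP, TN, FP, FN) {
  list(
    accuracy = (TP + TN) / (TP + TN + FP + FN),
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    mcc = {
      d <- (TN + FP) * (TN + FN) * (TP + FP) * (TP + FN)
      if (d > 0) (TP * TN - FP * FN) / sqrt(d) else NA_real_
    }
  )
}

# exhaustive pairwise AUC: P(pos > neg) + 0.5 P(tie)
oracle_auc <- function(truth, prob) {
  pos <- prob[truth == 1]
  neg <- prob[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

random_sequence <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# small labeled dataset with random chromosome assignments, for split tests
tiny_dataset <- function(n = 40, L = 21, n_chrom = 4, seed = 1,
                         p_pos = 0.5) {
  withr::with_seed(seed, {
    as_m6a_dataset(tibble::tibble(
      id = sprintf("r%03d", seq_len(n)),
      chromosome = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
      sequence = replicate(n, random_sequence(L)),
      label = rbinom(n, 1, p_pos)
    ), L = L)
  })
}
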