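test_that("generation is seed-deterministic and honors requested counts", {
  cfg <- synth_config(n_pos = 60, n_neg = 60, L = 101, confound = 0, seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$chromosome, b$chromosome)
  expect_equal(sum(a$label == 1), 60)
  expect_equal(sum(a$label == 0), 60)
  expect_true(all(nchar(a$sequence) == 101))
  expect_true(all(grepl("^[ACGTN]+$", a$sequence)))
  c <- generate_dataset(synth_config(n_pos = 60, n_neg = 60, L = 101, seed = 8))
  expect_false(identical(a$sequence, c$sequence))
})

test_that("infeasible configs are rejected", {
  expect_error(synth_config(L = 3), "shorter than motif")
  expect_error(synth_config(motif_prob_pos = 1.2), "probabilities")
  expect_error(synth_config(confound = 2), "confound")
  expect_error(synth_config(chrom_weights = c(1, 2)), "one per chromosome")
})

test_that("positive motif-at-center rate sits in its exact binomial band", {
  n <- 400
  ds <- generate_dataset(synth_config(n_pos = n, n_neg = 50, L = 201,
                                      motif_prob_pos = 0.9, seed = 13))
  hits <- baseline_scores(ds[ds$label == 1, ], type = "motif_center")
  band <- stats::qbinom(c(0.005, 0.995), n, 0.9)
  # background can only add hits, never remove them, so test the lower
  # bound strictly and allow chance central DRACHs above
  expect_gte(sum(hits), band[1])
  # negatives at rate 0.1 stay far below the positives
  neg_hits <- baseline_scores(ds[ds$label == 0, ], type = "motif_center")
  expect_lt(mean(neg_hits), 0.5)
})

test_that("confounding shifts per-chromosome GC while the control does not", {
  n <- 600
  confounded <- generate_dataset(synth_config(n_pos = n / 2, n_neg = n / 2,
                                              L = 151, confound = 1, seed = 3))
  control <- generate_dataset(synth_config(n_pos = n / 2, n_neg = n / 2,
                                           L = 151, confound = 0, seed = 3))
  gc_spread <- function(ds) {
    gc <- baseline_scores(ds, "gc")
    diff(range(tapply(gc, ds$chromosome, mean)))
  }
  expect_gt(gc_spread(confounded), 0.15) # design: gc spans 0.35..0.65
  expect_lt(gc_spread(control), 0.05)
  av <- stats::anova(stats::lm(baseline_scores(confounded, "gc") ~ confounded$chromosome))
  expect_lt(av$`Pr(>F)`[1], 1e-10)
})

test_that("the confounded pair couples label with chromosome; the control does not", {
  cfg <- synth_config(n_pos = 300, n_neg = 300, motif_prob_pos = 0.6,
                      motif_prob_neg = 0.2, confound = 0.8, seed = 5)
  ds <- make_confounded_pair(cfg)
  tab <- table(ds$chromosome, ds$label)
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_lt(chi$p.value, 1e-6)
  # label rate should rise along the chromosome composition gradient
  rates <- prop.table(tab, 1)[paste0("chr", 1:6), 2]
  expect_gt(stats::cor(seq_along(rates), rates, method = "spearman"), 0.8)
  cfg0 <- synth_config(n_pos = 300, n_neg = 300, motif_prob_pos = 0.6,
                       motif_prob_neg = 0.2, confound = 0, seed = 5)
  chi0 <- suppressWarnings(stats::chisq.test(table(make_confounded_pair(cfg0)$chromosome,
                                                   make_confounded_pair(cfg0)$label)))
  expect_gt(chi0$p.value, 0.001)
})

test_that("a GC-content classifier exploits the confounder only under RS", {
  cfg <- synth_config(n_pos = 250, n_neg = 250, motif_prob_pos = 0.6,
                      motif_prob_neg = 0.2, confound = 0.8, seed = 9)
  ds <- make_confounded_pair(cfg)
  gc <- baseline_scores(ds, "gc")
  # RS-style evaluation: GC separates the classes
  expect_gt(as.numeric(auc_roc(ds$label, gc)), 0.6)
  # LOCO-style evaluation: within each chromosome GC carries no label signal
  per_chrom <- vapply(split(seq_len(nrow(ds)), ds$chromosome), function(i) {
    if (length(unique(ds$label[i])) < 2) return(NA_real_)
    as.numeric(auc_roc(ds$label[i], gc[i]))
  }, numeric(1))
  expect_lt(abs(mean(per_chrom, na.rm = TRUE) - 0.5), 0.1)
  # no-confound control: GC is uninformative under both views
  ds0 <- make_confounded_pair(synth_config(n_pos = 250, n_neg = 250,
                                           motif_prob_pos = 0.6,
                                           motif_prob_neg = 0.2,
                                           confound = 0, seed = 9))
  expect_lt(abs(as.numeric(auc_roc(ds0$label, baseline_scores(ds0, "gc"))) - 0.5),
            0.1)
})

test_that("motif-count AUC rises monotonically with the insertion-rate gap", {
  aucs <- vapply(c(0.2, 0.55, 0.9), function(p_pos) {
    ds <- generate_dataset(synth_config(n_pos = 250, n_neg = 250, L = 101,
                                        motif_prob_pos = p_pos,
                                        motif_prob_neg = 0.1, seed = 31))
    as.numeric(auc_roc(ds$label, baseline_scores(ds, "motif_count")))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("the benchmark-scale preset mirrors the published dataset geometry", {
  cfg <- synth_config_benchmark(seed = 1)
  expect_equal(cfg$n_pos, 10424L)
  expect_equal(cfg$n_neg, 54949L)
  expect_equal(cfg$L, 2001L)
  expect_equal(cfg$chromosomes, paste0("chr", 1:23))
  expect_equal(round(cfg$n_neg / cfg$n_pos), 5)
})
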