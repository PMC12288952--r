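make_imbalanced <- function(n_pos, n_neg, n_chrom = 4, L = 11, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    as_m6a_dataset(tibble::tibble(
      id = sprintf("r%04d", seq_len(n)),
      chromosome = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
      sequence = replicate(n, random_sequence(L)),
      label = c(rep(1L, n_pos), rep(0L, n_neg))
    ), L = L)
  })
}

test_that("balancing pairs all positives with disjoint equal negative subsets", {
  ds <- make_imbalanced(10, 50)
  reps <- balance_negatives(ds, n_subsets = 5, seed = 3)
  expect_length(reps, 5)
  neg_sets <- lapply(reps, function(r) r$id[r$label == 0])
  for (r in reps) {
    expect_equal(nrow(r), 20)
    expect_equal(sum(r$label == 1), 10)
    expect_setequal(r$id[r$label == 1], ds$id[ds$label == 1])
  }
  expect_equal(anyDuplicated(unlist(neg_sets)), 0L)
  expect_setequal(unlist(neg_sets), ds$id[ds$label == 0])
})

test_that("non-divisible negative counts spread the remainder (sizes differ <= 1)", {
  ds <- make_imbalanced(5, 52)
  reps <- balance_negatives(ds, n_subsets = 5, seed = 1)
  sizes <- sort(vapply(reps, function(r) sum(r$label == 0), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(11L, 11L, 10L, 10L, 10L))
  expect_equal(anyDuplicated(unlist(lapply(reps, function(r) r$id[r$label == 0]))), 0L)
})

test_that("balancing is reproducible under a seed and errors on degenerate input", {
  ds <- make_imbalanced(6, 30)
  a <- balance_negatives(ds, 5, seed = 11)
  b <- balance_negatives(ds, 5, seed = 11)
  expect_identical(lapply(a, function(x) x$id), lapply(b, function(x) x$id))
  c <- balance_negatives(ds, 5, seed = 12)
  expect_false(identical(lapply(a, function(x) x$id),
                         lapply(c, function(x) x$id)))
  only_pos <- ds[ds$label == 1, ]
  expect_error(balance_negatives(only_pos, 5), "both classes")
  expect_error(balance_negatives(make_imbalanced(5, 3), 5), "cannot split")
})

test_that("RS plans have the declared test size and partitioned CV folds", {
  ds <- make_imbalanced(50, 50, seed = 8)
  plan <- random_split(ds, test_fraction = 0.2, cv_folds = 5, seed = 2)
  expect_equal(plan$mode, "RS")
  expect_length(plan$folds$test[[1]], 20)
  expect_true(all(lengths(plan$folds$validation) == 16))
  expect_true(all(lengths(plan$folds$train) == 64))
  pool <- setdiff(ds$id, plan$folds$test[[1]])
  vals <- unlist(plan$folds$validation)
  expect_equal(anyDuplicated(vals), 0L)
  expect_setequal(vals, pool)
  audit_split(plan, ds)
  # stratified folds are 50/50 within one record
  lab <- stats::setNames(ds$label, ds$id)
  for (v in plan$folds$validation) {
    expect_lte(abs(sum(lab[v] == 1) - sum(lab[v] == 0)), 1)
  }
})

test_that("RS stratification errors when a class cannot fill the folds", {
  ds <- make_imbalanced(3, 60)
  expect_error(random_split(ds, cv_folds = 5, seed = 1, test_fraction = 0.2),
               "stratification error")
})

test_that("LOCO builds one complement fold per chromosome in natural order", {
  ds <- withr::with_seed(2, as_m6a_dataset(tibble::tibble(
    id = sprintf("r%03d", 1:60),
    chromosome = rep(c("chrA", "chrB", "chrC"), each = 20),
    sequence = replicate(60, random_sequence(11)),
    label = rep(c(0L, 1L), 30)
  ), L = 11))
  plan <- loco_split(ds)
  expect_equal(plan$mode, "LOCO")
  expect_equal(plan$folds$fold, c("chrA", "chrB", "chrC"))
  i <- which(plan$folds$fold == "chrA")
  expect_setequal(plan$folds$test[[i]], ds$id[ds$chromosome == "chrA"])
  expect_setequal(plan$folds$train[[i]], ds$id[ds$chromosome != "chrA"])
  all_test <- unlist(plan$folds$test)
  expect_equal(anyDuplicated(all_test), 0L)
  expect_setequal(all_test, ds$id)
  audit_split(plan, ds)
})

test_that("LOCO orders chr2 before chr10 and covers 23 chromosome labels", {
  ds <- withr::with_seed(3, {
    chroms <- paste0("chr", 1:23)
    n <- 23 * 6
    as_m6a_dataset(tibble::tibble(
      id = sprintf("r%03d", seq_len(n)),
      chromosome = rep(chroms, each = 6),
      sequence = replicate(n, random_sequence(11)),
      label = rep(c(1L, 0L), n / 2)
    ), L = 11)
  })
  plan <- loco_split(ds)
  expect_equal(nrow(plan$folds), 23)
  expect_equal(plan$folds$fold, paste0("chr", 1:23))
  audit_split(plan, ds)
})

test_that("LOCO rejects single-chromosome data and flags one-class chromosomes", {
  ds <- tiny_dataset(n = 20, n_chrom = 1, seed = 5)
  expect_error(loco_split(ds), "only one chromosome")
  ds2 <- withr::with_seed(4, as_m6a_dataset(tibble::tibble(
    id = sprintf("r%02d", 1:20),
    chromosome = rep(c("chr1", "chr2"), each = 10),
    sequence = replicate(20, random_sequence(11)),
    label = c(rep(1L, 10), rep(c(0L, 1L), 5))
  ), L = 11))
  expect_warning(loco_split(ds2), "only one class")
})

test_that("the leakage auditor rejects deliberately corrupted plans", {
  ds <- tiny_dataset(n = 40, n_chrom = 4, seed = 6)
  plan <- loco_split(ds)
  # negative control 1: move a test record into training
  bad <- plan
  bad$folds$train[[1]] <- c(bad$folds$train[[1]], bad$folds$test[[1]][1])
  expect_error(audit_split(bad, ds), "overlap")
  # negative control 2: swap a training id of the same fold's held-out
  # chromosome into the test set
  bad2 <- plan
  bad2$folds$test[[2]] <- c(bad2$folds$test[[2]], bad2$folds$train[[2]][1])
  expect_error(audit_split(bad2, ds), "overlap|leakage|spans")
  # negative control 3: unknown id
  bad3 <- plan
  bad3$folds$test[[1]][1] <- "ghost"
  expect_error(audit_split(bad3, ds), "unknown record id")
})

test_that("split plans survive a JSON round-trip", {
  ds <- tiny_dataset(n = 30, n_chrom = 3, seed = 7)
  for (plan in list(random_split(ds, seed = 4),
                    suppressWarnings(loco_split(ds, seed = 4)))) {
    path <- withr::local_tempfile(fileext = ".json")
    split_to_json(plan, path)
    back <- split_from_json(path)
    expect_equal(back$mode, plan$mode)
    expect_equal(back$seed, plan$seed)
    expect_equal(back$folds$fold, plan$folds$fold)
    expect_identical(back$folds$train, plan$folds$train)
    expect_identical(back$folds$test, plan$folds$test)
  }
})

test_that("random_split is deterministic under a seed", {
  ds <- tiny_dataset(n = 50, seed = 10)
  p1 <- random_split(ds, seed = 99)
  p2 <- random_split(ds, seed = 99)
  expect_identical(p1$folds, p2$folds)
  p3 <- random_split(ds, seed = 100)
  expect_false(identical(p1$folds$test[[1]], p3$folds$test[[1]]))
})
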