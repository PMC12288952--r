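#' Balance negatives into disjoint 1:1 replicates
#'
#' Class-imbalanced m6A benchmarks carry roughly five negatives per positive.
#' This routine randomly partitions the negative set into `n_subsets`
#' near-equal disjoint subsets and pairs each with the full positive set,
#' yielding `n_subsets` balanced replicate datasets. When the negative count
#' is not divisible by `n_subsets` the shuffled negatives are dealt
#' round-robin, so subset sizes differ by at most one and no record is
#' discarded.
#'
#' @param data An [as_m6a_dataset()] tibble containing both classes.
#' @param n_subsets Number of disjoint negative subsets (default 5).
#' @param seed Integer seed; the partition is reproducible bit-for-bit.
#' @return A list of `n_subsets` `m6a_dataset` tibbles. Each carries a
#'   `"replicate"` attribute (1-based index).
#' @export
balance_negatives <- function(data, n_subsets = 5, seed = 1) {
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  pos <- data$id[data$label == 1]
  neg <- data$id[data$label == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("dataset must contain both classes to balance", call. = FALSE)
  }
  if (length(neg) < n_subsets) {
    stop("cannot split ", length(neg), " negatives into ", n_subsets,
         " subsets", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(neg))
  lapply(seq_len(n_subsets), function(i) {
    ni <- shuffled[seq(i, length(shuffled), by = n_subsets)]
    rep_ds <- data[data$id %in% c(pos, ni), , drop = FALSE]
    attr(rep_ds, "L") <- attr(data, "L")
    attr(rep_ds, "provenance") <-
      paste0(attr(data, "provenance"), " | balanced replicate ", i, "/", n_subsets)
    attr(rep_ds, "replicate") <- i
    class(rep_ds) <- class(data)
    rep_ds
  })
}

new_split_plan <- function(mode, folds, seed) {
  structure(list(mode = mode, folds = folds, seed = as.integer(seed)),
            class = "m6a_split_plan")
}

#' @export
print.m6a_split_plan <- function(x, ...) {
  cat(sprintf("# m6a_split_plan: mode = %s, %d fold(s), seed = %d\n",
              x$mode, nrow(x$folds), x$seed))
  print(dplyr::mutate(x$folds, dplyr::across(dplyr::where(is.list), lengths)))
  invisible(x)
}

# largest-remainder allocation of `total` slots proportional to `weights`
allocate_counts <- function(total, weights) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# deal ids into k folds of near-equal size (round-robin on shuffled order)
deal_folds <- function(ids, k) {
  lapply(seq_len(k), function(i) ids[seq(i, length(ids), by = k)])
}

#' Random-split (RS) validation plan
#'
#' Splits a dataset at random into an independent test set of size
#' `round(test_fraction * n)` and a training pool, then partitions the pool
#' into `cv_folds` cross-validation folds. Every fold row pairs the same test
#' set with one validation fold and the remaining pool as training set. With
#' `stratified = TRUE` (default) both the test draw and the folds preserve
#' the class balance to within one record per fold. Records from the same
#' chromosome may land on both sides of the split — that is the point of the
#' RS protocol, and why it is prone to chromosome-level leakage.
#'
#' @param data An [as_m6a_dataset()] tibble.
#' @param test_fraction Proportion held out for independent testing.
#' @param cv_folds Number of cross-validation folds over the training pool.
#' @param seed Integer seed.
#' @param stratified Stratify test draw and folds by label.
#' @return An `m6a_split_plan` with `mode = "RS"`; `folds` is a tibble with
#'   list-columns `train`, `validation`, `test` of record ids.
#' @export
random_split <- function(data, test_fraction = 0.2, cv_folds = 5, seed = 1,
                         stratified = TRUE) {
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  if (cv_folds < 2) stop("cv_folds must be at least 2", call. = FALSE)
  n <- nrow(data)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n) stop("degenerate test-set size ", n_test, call. = FALSE)

  with_seed(seed, {
    if (stratified) {
      classes <- split(data$id, data$label)
      take <- allocate_counts(n_test, lengths(classes))
      test_ids <- unlist(purrr::map2(classes, take, function(ids, m) {
        sample(ids, m)
      }), use.names = FALSE)
    } else {
      test_ids <- sample(data$id, n_test)
    }
    pool <- setdiff(data$id, test_ids)
    if (stratified) {
      pool_lab <- data$label[match(pool, data$id)]
      if (any(table(factor(pool_lab, levels = c(0, 1))) < cv_folds)) {
        stop("stratification error: a class has fewer training-pool records (",
             paste(table(factor(pool_lab, levels = c(0, 1))), collapse = "/"),
             ") than cv_folds = ", cv_folds, call. = FALSE)
      }
      per_class <- lapply(split(pool, pool_lab), function(ids) deal_folds(sample(ids), cv_folds))
      val_folds <- lapply(seq_len(cv_folds), function(i) {
        unlist(lapply(per_class, `[[`, i), use.names = FALSE)
      })
    } else {
      val_folds <- deal_folds(sample(pool), cv_folds)
    }
    folds <- tibble::tibble(
      fold = paste0("cv", seq_len(cv_folds)),
      train = lapply(val_folds, function(v) setdiff(pool, v)),
      validation = val_folds,
      test = replicate(cv_folds, test_ids, simplify = FALSE)
    )
    new_split_plan("RS", folds, seed)
  })
}

#' Leave-one-chromosome-out (LOCO) validation plan
#'
#' Builds one fold per distinct chromosome label, in natural sort order
#' (`chr2` before `chr10`). Each fold holds out *all* records of one
#' chromosome as the test set and trains on every other chromosome, so no
#' chromosome ever appears on both sides of a fold — the protocol that
#' eliminates chromosome-level leakage. Chromosome labels are opaque
#' strings; they are never renamed or reinterpreted. A chromosome whose
#' records are all one class is allowed but flagged with a warning, since
#' class-conditional test metrics will be undefined for that fold.
#'
#' @param data An [as_m6a_dataset()] tibble with at least two chromosomes.
#' @param seed Integer seed recorded on the plan (the fold structure itself
#'   is deterministic; the seed seeds any downstream inner cross-validation).
#' @return An `m6a_split_plan` with `mode = "LOCO"`; `validation` entries are
#'   `NULL` (inner CV folds are carved from the training pool at training
#'   time with [random_split()]-style dealing).
#' @export
loco_split <- function(data, seed = 1) {
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  chroms <- natural_sort(unique(data$chromosome))
  if (length(chroms) < 2) {
    stop("degenerate LOCO split: only one chromosome (training set would be empty)",
         call. = FALSE)
  }
  one_class <- vapply(chroms, function(ch) {
    length(unique(data$label[data$chromosome == ch])) < 2
  }, logical(1))
  if (any(one_class)) {
    warning("chromosome(s) with records in only one class: ",
            paste(chroms[one_class], collapse = ", "),
            " (their class-conditional test metrics will be undefined)",
            call. = FALSE)
  }
  folds <- tibble::tibble(
    fold = chroms,
    train = lapply(chroms, function(ch) data$id[data$chromosome != ch]),
    validation = replicate(length(chroms), NULL, simplify = FALSE),
    test = lapply(chroms, function(ch) data$id[data$chromosome == ch])
  )
  new_split_plan("LOCO", folds, seed)
}

# natural sort: chr2 before chr10; non-numeric suffixes after numeric ones
natural_sort <- function(x) {
  prefix <- sub("[0-9]+$", "", x)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", x)))
  x[order(prefix, is.na(num), num, x)]
}

#' Audit a split plan for leakage and partition violations
#'
#' Checks, for every fold: pairwise disjointness of train/validation/test;
#' that all ids exist in the dataset; for LOCO plans, that each test set is
#' exactly one chromosome, that no chromosome occurs in both train and test
#' of the same fold, and that the test sets across folds partition the
#' dataset; for RS plans, that the test set is constant across folds and the
#' validation folds partition the training pool. Any violation is an error
#' naming the fold — including on deliberately corrupted plans, which is how
#' the auditor itself is validated.
#'
#' @param plan An `m6a_split_plan`.
#' @param data The dataset the plan indexes.
#' @return Invisibly, a per-fold audit tibble (sizes and chromosome counts).
#' @export
audit_split <- function(plan, data) {
  stopifnot(inherits(plan, "m6a_split_plan"))
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  chrom_of <- stats::setNames(data$chromosome, data$id)
  folds <- plan$folds
  for (i in seq_len(nrow(folds))) {
    tr <- folds$train[[i]]; va <- folds$validation[[i]]; te <- folds$test[[i]]
    ids <- c(tr, va, te)
    unknown <- setdiff(ids, data$id)
    if (length(unknown) > 0) {
      stop("fold ", folds$fold[i], ": unknown record id(s) ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
    if (length(intersect(tr, te)) > 0 || length(intersect(tr, va)) > 0 ||
        length(intersect(va, te)) > 0) {
      stop("fold ", folds$fold[i], ": train/validation/test sets overlap",
           call. = FALSE)
    }
    if (plan$mode == "LOCO") {
      shared <- intersect(unique(chrom_of[tr]), unique(chrom_of[te]))
      if (length(shared) > 0) {
        stop("LOCO leakage in fold ", folds$fold[i],
             ": chromosome(s) in both train and test: ",
             paste(shared, collapse = ", "), call. = FALSE)
      }
      if (length(unique(chrom_of[te])) != 1) {
        stop("LOCO fold ", folds$fold[i], ": test set spans ",
             length(unique(chrom_of[te])), " chromosomes", call. = FALSE)
      }
    }
  }
  if (plan$mode == "LOCO") {
    all_test <- unlist(folds$test, use.names = FALSE)
    if (anyDuplicated(all_test) || !setequal(all_test, data$id)) {
      stop("LOCO test sets do not partition the dataset", call. = FALSE)
    }
  }
  if (plan$mode == "RS") {
    ref <- folds$test[[1]]
    same <- all(vapply(folds$test, function(t) setequal(t, ref), logical(1)))
    if (!same) stop("RS test set differs across CV folds", call. = FALSE)
    pool <- setdiff(data$id, ref)
    vals <- unlist(folds$validation, use.names = FALSE)
    if (anyDuplicated(vals) || !setequal(vals, pool)) {
      stop("RS validation folds do not partition the training pool", call. = FALSE)
    }
  }
  invisible(tibble::tibble(
    fold = folds$fold,
    n_train = lengths(folds$train),
    n_validation = lengths(folds$validation),
    n_test = lengths(folds$test),
    test_chromosomes = vapply(folds$test, function(t) {
      length(unique(chrom_of[t]))
    }, integer(1))
  ))
}

#' Serialize / restore a split plan as JSON
#'
#' The JSON document records mode, seed, and the full id lists of every
#' fold, so an experiment can be rerun on exactly the same partition.
#'
#' @param plan An `m6a_split_plan`.
#' @param path Output (or input) JSON path.
#' @return `split_to_json()` returns `path` invisibly; `split_from_json()`
#'   returns the restored `m6a_split_plan`.
#' @export
split_to_json <- function(plan, path) {
  stopifnot(inherits(plan, "m6a_split_plan"))
  doc <- list(
    mode = plan$mode, seed = plan$seed,
    folds = lapply(seq_len(nrow(plan$folds)), function(i) {
      list(fold = plan$folds$fold[i],
           train = plan$folds$train[[i]],
           validation = plan$folds$validation[[i]] %||% character(0),
           test = plan$folds$test[[i]])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname split_to_json
#' @export
split_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- tibble::tibble(
    fold = vapply(doc$folds, function(f) as.character(f$fold), character(1)),
    train = lapply(doc$folds, function(f) unlist(f$train, use.names = FALSE)),
    validation = lapply(doc$folds, function(f) {
      v <- unlist(f$validation, use.names = FALSE)
      if (length(v) == 0) NULL else v
    }),
    test = lapply(doc$folds, function(f) unlist(f$test, use.names = FALSE))
  )
  new_split_plan(doc$mode, folds, doc$seed)
}
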