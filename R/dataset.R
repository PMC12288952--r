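#' Labeled sequence window datasets
#'
#' An `m6a_dataset` is a tibble with one row per labeled window and columns
#' `id` (unique string), `chromosome` (non-empty string such as `"chr7"`),
#' `sequence` (nucleotide string over `A,C,G,T,N`, all the same length `L`)
#' and `label` (integer 0 = negative, 1 = positive). The shared window length
#' is stored in the `"L"` attribute and free-text provenance in
#' `"provenance"`.
#'
#' On construction sequences are uppercased, `U` is mapped to `T` (the
#' internal alphabet is DNA letters even for mRNA windows), and any other
#' non-`ACGTN` character is mapped to `N` with a warning. Windows whose
#' length disagrees with `L` are an error by default; `pad_policy` selects
#' center-cropping or symmetric `N`-padding instead. There is no silent
#' trimming: a fixed `L` is part of the model-architecture contract.
#'
#' @param x A data frame with columns `id`, `chromosome`, `sequence`,
#'   `label` (or coercible vectors thereof).
#' @param L Declared window length. Defaults to the most common sequence
#'   length in `x`.
#' @param pad_policy What to do with sequences whose length is not `L`:
#'   `"error"` (default, reports offending ids), `"center_crop"`, or
#'   `"n_pad"` (symmetric N-padding).
#' @param provenance Optional free-text metadata carried on the object.
#' @return A tibble of class `m6a_dataset`.
#' @examples
#' ds <- as_m6a_dataset(tibble::tibble(
#'   id = c("a", "b"), chromosome = c("chr1", "chr2"),
#'   sequence = c("ACGUA", "acgtn"), label = c(1, 0)
#' ))
#' attr(ds, "L")
#' @export
as_m6a_dataset <- function(x, L = NULL,
                           pad_policy = c("error", "center_crop", "n_pad"),
                           provenance = NULL) {
  pad_policy <- match.arg(pad_policy)
  x <- tibble::as_tibble(x)
  required <- c("id", "chromosome", "sequence", "label")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) {
    stop("dataset is empty (no records)", call. = FALSE)
  }

  x$id <- as.character(x$id)
  x$chromosome <- as.character(x$chromosome)
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    stop("record ids are not unique: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$chromosome) | x$chromosome == "")) {
    stop("chromosome labels must be non-empty strings", call. = FALSE)
  }

  lab <- x$label
  if (is.character(lab)) lab <- suppressWarnings(as.numeric(lab))
  bad_lab <- is.na(lab) | !(lab %in% c(0, 1))
  if (any(bad_lab)) {
    stop("labels must be 0 or 1; offending record(s): ",
         paste(utils::head(x$id[bad_lab], 5), collapse = ", "), call. = FALSE)
  }
  x$label <- as.integer(lab)

  x$sequence <- normalize_sequence(x$sequence)

  len <- nchar(x$sequence)
  if (is.null(L)) {
    tab <- table(len)
    L <- as.integer(names(tab)[which.max(tab)])
  }
  off <- which(len != L)
  if (length(off) > 0) {
    if (pad_policy == "error") {
      stop("sequence length differs from L = ", L, " for record(s): ",
           paste(utils::head(x$id[off], 5), collapse = ", "),
           if (length(off) > 5) paste0(" (and ", length(off) - 5, " more)"),
           call. = FALSE)
    }
    x$sequence[off] <- vapply(x$sequence[off], fit_to_length, character(1),
                              L = L, policy = pad_policy)
  }

  attr(x, "L") <- as.integer(L)
  attr(x, "provenance") <- provenance %||% "unspecified"
  class(x) <- c("m6a_dataset", class(x))
  x
}

# Uppercase, U->T, and anything outside {A,C,G,T,N} -> N (warned once).
normalize_sequence <- function(seq) {
  seq <- toupper(as.character(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  n_odd <- sum(nchar(gsub("[ACGTN]", "", seq)))
  if (n_odd > 0) {
    warning(n_odd, " non-ACGTN character(s) mapped to N", call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

fit_to_length <- function(s, L, policy) {
  n <- nchar(s)
  if (n > L) { # center crop
    start <- (n - L) %/% 2 + 1L
    substr(s, start, start + L - 1L)
  } else {
    left <- (L - n) %/% 2
    paste0(strrep("N", left), s, strrep("N", L - n - left))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.m6a_dataset <- function(x, ...) {
  cat(sprintf("# m6a_dataset: %d records, L = %d, %d chromosome(s), %d pos / %d neg\n",
              nrow(x), attr(x, "L"), length(unique(x$chromosome)),
              sum(x$label == 1), sum(x$label == 0)))
  NextMethod()
}

#' Read a labeled window dataset from a delimited file
#'
#' Reads a CSV or TSV file with one row per labeled window. The delimiter is
#' taken from the file extension (`.tsv`/`.tab` means tab) unless `delim` is
#' given. Column names are remapped through `columns`, whose *names* are the
#' canonical fields and whose *values* are the column names in the file.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param columns Named character vector mapping canonical fields
#'   (`id`, `chromosome`, `sequence`, `label`) to file column names.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @inheritParams as_m6a_dataset
#' @return An [as_m6a_dataset()] tibble.
#' @export
read_sequence_table <- function(path,
                                columns = c(id = "id", chromosome = "chrom",
                                            sequence = "sequence", label = "label"),
                                delim = NULL, L = NULL,
                                pad_policy = c("error", "center_crop", "n_pad")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else {
      first <- readLines(path, n = 1L)
      if (length(first) == 1 && grepl("\t", first)) "\t" else ","
    }
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) stop("empty dataset: ", path, call. = FALSE)
  need <- unname(columns)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("input file lacks declared column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    id = df[[columns[["id"]]]],
    chromosome = df[[columns[["chromosome"]]]],
    sequence = df[[columns[["sequence"]]]],
    label = df[[columns[["label"]]]]
  )
  as_m6a_dataset(out, L = L, pad_policy = pad_policy,
                 provenance = paste0("read_sequence_table(", path, ")"))
}

#' Read a labeled window dataset from FASTA plus a label sidecar
#'
#' Sequences come from a standard (wrapped or unwrapped) FASTA file; labels
#' and chromosome assignments come from a BED-like three-column sidecar
#' (`id`, `chromosome`, `label`, tab- or comma-separated, header optional).
#' Records are joined by id; an id present in only one of the two files is a
#' join error listing the orphans. Any genomic coordinates must already be
#' resolved to windows — the join is id-keyed, never coordinate-keyed.
#'
#' @param fasta Path to a FASTA file.
#' @param labels Path to the label sidecar.
#' @inheritParams as_m6a_dataset
#' @return An [as_m6a_dataset()] tibble.
#' @export
read_sequence_fasta <- function(fasta, labels, L = NULL,
                                pad_policy = c("error", "center_crop", "n_pad")) {
  if (!file.exists(fasta)) stop("file not found: ", fasta, call. = FALSE)
  if (!file.exists(labels)) stop("file not found: ", labels, call. = FALSE)
  ss <- Biostrings::readBStringSet(fasta)
  if (length(ss) == 0) stop("empty dataset: no FASTA records in ", fasta, call. = FALSE)
  fasta_ids <- sub("\\s.*$", "", names(ss))

  first <- readLines(labels, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("^id[,\t]", first)
  lab <- utils::read.table(labels, sep = delim, header = has_header,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "chromosome", "label"))
  lab$id <- as.character(lab$id)

  only_fasta <- setdiff(fasta_ids, lab$id)
  only_labels <- setdiff(lab$id, fasta_ids)
  if (length(only_fasta) + length(only_labels) > 0) {
    stop("id mismatch between FASTA and label file; FASTA-only: [",
         paste(utils::head(only_fasta, 5), collapse = ", "),
         "], labels-only: [",
         paste(utils::head(only_labels, 5), collapse = ", "), "]",
         call. = FALSE)
  }
  out <- tibble::tibble(id = fasta_ids, sequence = as.character(ss)) |>
    dplyr::left_join(tibble::as_tibble(lab), by = "id") |>
    dplyr::select("id", "chromosome", "sequence", "label")
  as_m6a_dataset(out, L = L, pad_policy = pad_policy,
                 provenance = paste0("read_sequence_fasta(", fasta, ")"))
}

#' Write a dataset to disk
#'
#' `format = "tabular"` writes a delimited file with header
#' `id,chrom,sequence,label` (tab-separated when `path` ends in `.tsv`).
#' `format = "fasta"` writes one FASTA record per window plus a three-column
#' label sidecar next to it (default `<path>.labels.tsv`), so that
#' [read_sequence_fasta()] round-trips the dataset exactly.
#'
#' @param data An [as_m6a_dataset()] tibble (or data frame coercible to one).
#' @param path Output path.
#' @param format `"tabular"` or `"fasta"`.
#' @param labels_path Sidecar path for `format = "fasta"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("tabular", "fasta"),
                          labels_path = NULL) {
  format <- match.arg(format)
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  if (nrow(data) == 0) stop("refusing to write an empty dataset", call. = FALSE)
  if (format == "tabular") {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
    out <- tibble::tibble(id = data$id, chrom = data$chromosome,
                          sequence = data$sequence, label = data$label)
    readr::write_delim(out, path, delim = delim, progress = FALSE)
  } else {
    ss <- Biostrings::BStringSet(data$sequence)
    names(ss) <- data$id
    Biostrings::writeXStringSet(ss, path, width = 80L)
    labels_path <- labels_path %||% paste0(path, ".labels.tsv")
    utils::write.table(
      data.frame(id = data$id, chromosome = data$chromosome, label = data$label),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
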