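#' Construct a labeled tweet corpus
#'
#' A corpus is an ordered collection of (id, text, label) records for the
#' six-way single-label subtype task. Texts are normalized (Unicode NFC,
#' collapsed whitespace, stripped ends — the task's "minimal preprocessing"),
#' labels are resolved to the canonical class names, missing ids are assigned
#' sequentially, and id uniqueness and text non-emptiness are enforced.
#'
#' @param text Character vector of post texts.
#' @param label Character vector of label strings (resolved via
#'   [normalize_label()]).
#' @param id Optional character vector of unique ids; sequential ids are
#'   assigned where missing.
#' @return A `subtype_corpus`: a data.frame with columns `id`, `text`,
#'   `label` (factor over the canonical six levels).
#' @examples
#' corpus(c("feeling low since the baby came", "all good here"),
#'        c("postpartum", "no depression"))
#' @export
corpus <- function(text, label, id = NULL) {
  text <- normalize_text(text)
  n <- length(text)
  if (length(label) != n) {
    stop("text and label must have equal length", call. = FALSE)
  }
  empty <- !nzchar(text)
  if (any(empty)) {
    stop("empty text after normalization at record(s): ",
         paste(which(empty), collapse = ", "), call. = FALSE)
  }
  label <- normalize_label(label)
  if (is.null(id)) {
    id <- as.character(seq_len(n))
  } else {
    id <- as.character(id)
    miss <- is.na(id) | !nzchar(id)
    id[miss] <- as.character(which(miss))
  }
  if (anyDuplicated(id)) {
    stop("duplicate ids: ", paste(unique(id[duplicated(id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    id = id,
    text = text,
    label = factor(label, levels = subtype_labels()),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subtype_corpus", "data.frame")
  out
}

#' @export
print.subtype_corpus <- function(x, ...) {
  cat(sprintf("<subtype_corpus> %d examples\n", nrow(x)))
  print(class_counts(x))
  invisible(x)
}

#' Read a labeled corpus from JSONL or CSV
#'
#' JSONL files hold one object per line with keys `id`, `text`, `label`;
#' CSV files have a header `id,text,label` (UTF-8, quoted texts). `id` may be
#' absent in either format. Label strings are matched case-insensitively with
#' spaces/hyphens/underscores unified; a string outside the six-class space is
#' an error naming the offending record.
#'
#' @param path Path to the file.
#' @param format "jsonl" or "csv"; guessed from the file extension when
#'   missing.
#' @return A [corpus()].
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    text <- vapply(recs, function(r) as.character(r$text %||% NA_character_),
                   character(1))
    label <- vapply(recs, function(r) as.character(r$label %||% NA_character_),
                    character(1))
    id <- vapply(recs, function(r) as.character(r$id %||% NA_character_),
                 character(1))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
    if (!all(c("text", "label") %in% names(df))) {
      stop("CSV must have 'text' and 'label' columns", call. = FALSE)
    }
    text <- df$text
    label <- df$label
    id <- if ("id" %in% names(df)) df$id else rep(NA_character_, nrow(df))
  }
  if (anyNA(text) || anyNA(label)) {
    bad <- which(is.na(text) | is.na(label))
    stop("record(s) missing text or label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # surface the record number on label/text failures
  tryCatch(
    corpus(text, label, id = if (all(is.na(id))) NULL else id),
    error = function(e) {
      stop(sprintf("while reading %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

#' Write a corpus to JSONL or CSV
#'
#' @param x A [corpus()].
#' @param path Output path.
#' @param format "jsonl" or "csv"; guessed from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- data.frame(id = x$id, text = x$text, label = as.character(x$label),
                   stringsAsFactors = FALSE)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, , drop = FALSE]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Remove exact-duplicate texts, keeping first occurrences
#'
#' Duplicates are judged on the normalized text (the corpus constructor has
#' already applied NFC + whitespace collapsing, so texts differing only in
#' whitespace are already identical). Survivor order is preserved.
#'
#' @param x A [corpus()].
#' @return A corpus with one example per distinct text.
#' @export
deduplicate <- function(x) {
  keep <- !duplicated(x$text)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("subtype_corpus", "data.frame")
  out
}

#' Per-class example counts
#'
#' @param x A [corpus()].
#' @return Named integer vector of six counts in canonical class order,
#'   summing to `nrow(x)`.
#' @export
class_counts <- function(x) {
  tab <- table(factor(x$label, levels = subtype_labels()))
  stats::setNames(as.integer(tab), subtype_labels())
}

#' Stratified train/validation/test split with text-leakage control
#'
#' Deduplicates the corpus (exact normalized-text match), then within each
#' class shuffles examples with a seeded PRNG and slices contiguously into
#' train/validation/test, with slice sizes chosen by largest-remainder
#' rounding of the ratios so each partition's per-class count is within one
#' of the stratified expectation. The three partitions are disjoint both by
#' id and by text, so no exact-duplicate text is shared across partitions.
#'
#' @param x A [corpus()].
#' @param ratios Three positive fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`; the split ratio is a configuration choice,
#'   not part of the benchmark definition).
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   partitions.
#' @return A `split_bundle`: list with corpora `train`, `validation`, `test`.
#' @export
stratified_split <- function(x, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three positive fractions summing to 1", call. = FALSE)
  }
  x <- deduplicate(x)
  counts <- class_counts(x)
  short <- counts > 0 & counts < 3
  if (any(short)) {
    stop("class(es) with fewer examples than partitions: ",
         paste(names(counts)[short], collapse = ", "), call. = FALSE)
  }
  assign_part <- rep(NA_integer_, nrow(x))
  with_local_seed(seed, {
    for (cl in subtype_labels()) {
      idx <- which(x$label == cl)
      if (length(idx) == 0) next
      idx <- idx[sample.int(length(idx))]
      sizes <- largest_remainder(length(idx), ratios)
      parts <- rep(1:3, times = sizes)
      assign_part[idx] <- parts
    }
  })
  take <- function(p) {
    out <- x[!is.na(assign_part) & assign_part == p, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("subtype_corpus", "data.frame")
    out
  }
  out <- list(train = take(1), validation = take(2), test = take(3))
  class(out) <- "split_bundle"
  out
}

#' @export
print.split_bundle <- function(x, ...) {
  cat("<split_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %5d examples\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write a split bundle and its manifest to a directory
#'
#' Writes `train.jsonl`, `val.jsonl`, `test.jsonl` plus `manifest.json`
#' recording per-class counts per partition.
#'
#' @param bundle A `split_bundle` from [stratified_split()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(train = "train.jsonl", validation = "val.jsonl", test = "test.jsonl")
  for (nm in names(files)) {
    write_corpus(bundle[[nm]], file.path(dir, files[[nm]]))
  }
  manifest <- lapply(bundle, function(part) as.list(class_counts(part)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
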