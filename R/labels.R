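#' The six-class depression-subtype label space
#'
#' The task is six-way single-label classification of short posts. The label
#' space is five depression subtypes plus a no-depression class, with a fixed
#' option-letter mapping used throughout the multiple-choice prompting
#' protocol: A = postpartum, B = major, C = bipolar, D = psychotic,
#' E = no_depression, F = atypical. This letter order is also the canonical
#' class order used for class counts, loss weights, confusion-matrix axes and
#' reports.
#'
#' @return Character vector of the six class names in canonical (letter)
#'   order, named by their option letters A-F.
#' @examples
#' subtype_labels()
#' @export
subtype_labels <- function() {
  c(
    A = "postpartum",
    B = "major",
    C = "bipolar",
    D = "psychotic",
    E = "no_depression",
    F = "atypical"
  )
}

#' @rdname subtype_labels
#' @return `subtype_letters()`: the six option letters, named by class name.
#' @export
subtype_letters <- function() {
  labs <- subtype_labels()
  stats::setNames(names(labs), labs)
}

#' Map between option letters and class names
#'
#' @param letter Option letter(s), one of "A".."F".
#' @param name Class name(s), one of [subtype_labels()].
#' @return The corresponding class name(s) or letter(s).
#' @examples
#' letter_to_label("C")
#' label_to_letter("bipolar")
#' @export
letter_to_label <- function(letter) {
  labs <- subtype_labels()
  bad <- !letter %in% names(labs)
  if (any(bad)) {
    stop("unknown option letter(s): ", paste(unique(letter[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(labs[letter])
}

#' @rdname letter_to_label
#' @export
label_to_letter <- function(name) {
  lets <- subtype_letters()
  bad <- !name %in% names(lets)
  if (any(bad)) {
    stop("unknown class name(s): ", paste(unique(name[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(lets[name])
}

#' Resolve a free-form label string to a canonical class name
#'
#' Matching is case-insensitive and tolerant of spaces, hyphens and
#' underscores ("No Depression", "no-depression" and "NO_DEPRESSION" all
#' resolve to `no_depression`). Strings outside the six-class space are an
#' error: the label space is closed (e.g. dysthymia is not representable).
#'
#' @param x Character vector of label strings.
#' @return Character vector of canonical class names.
#' @examples
#' normalize_label(c("No Depression", "Bipolar"))
#' @export
normalize_label <- function(x) {
  key <- tolower(gsub("[ _-]+", "", as.character(x)))
  canon <- subtype_labels()
  lookup <- stats::setNames(canon, tolower(gsub("[ _-]+", "", canon)))
  out <- lookup[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown label string(s): ", paste(sprintf("'%s'", bad), collapse = ", "),
         "; expected one of {", paste(canon, collapse = ", "), "}", call. = FALSE)
  }
  unname(out)
}

# Class proportions reported for the curated 14,983-tweet corpus, in canonical
# order. They are printed to one decimal and sum to 99.8%; consumers
# renormalize.
#' Reported class proportions of the curated tweet corpus
#'
#' Fractions of the six classes in the study corpus (postpartum 24.9%, major
#' 16.8%, bipolar 16.3%, psychotic 15.4%, no-depression 13.2%, atypical
#' 13.2%), in canonical order. The printed percentages sum to 99.8%, so
#' downstream consumers (the synthetic generator in particular) renormalize
#' them to sum to 1.
#'
#' @return Named numeric vector of six fractions (sum 0.998).
#' @examples
#' reported_proportions()
#' @export
reported_proportions <- function() {
  stats::setNames(
    c(0.249, 0.168, 0.163, 0.154, 0.132, 0.132),
    subtype_labels()
  )
}
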