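# shared helpers

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U")

#' Round half away from zero
#'
#' Standard "commercial" rounding: 0.005 rounds to 0.01. Used for printed
#' percentages, where base R's round-half-to-even convention would disagree
#' with hand-computed tables.
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Strip the version suffix from a Pfam accession (PF01822.14 -> PF01822)
#' @noRd
strip_acc_version <- function(acc) sub("\\.\\d+$", "", acc)

is_pfam_acc <- function(acc) grepl("^PF\\d{5}(\\.\\d+)?$", acc)

#' Read non-blank lines of a text file, optionally dropping '#' comments
#' @noRd
read_data_lines <- function(path, drop_comments = TRUE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (drop_comments) keep <- keep & !startsWith(trimws(lines), "#")
  lines[keep]
}

#' Split whitespace-delimited lines into token vectors
#' @noRd
split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Merge overlapping closed intervals; returns a tibble sorted by start
#' @noRd
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  ms <- starts[1]
  me <- ends[1]
  out_s <- integer()
  out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- starts[i]
      me <- ends[i]
    }
  }
  tibble(start = as.integer(c(out_s, ms)), end = as.integer(c(out_e, me)))
}

#' Overlap length of two closed intervals (0 if disjoint)
#' @noRd
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}
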