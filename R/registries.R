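# Loaders for the three reference resources the rules depend on. All three
# are plain text so users can substitute their own Pfam-derived lists; the
# files under inst/extdata/registries/demo are small illustrative examples,
# not the curated production lists.

#' Load an obligatory-localization registry
#'
#' Tab-separated file with columns `accession` and `compartment`
#' (`extracellular`, `cytoplasmic` or `nuclear`). A family listed for a
#' compartment is taken to occur exclusively there, so the three sets must
#' be pairwise disjoint; version suffixes are stripped on load.
#'
#' @param path Path to the TSV file.
#' @return A list of class `mp_loc_registry` with character-vector elements
#'   `extracellular`, `cytoplasmic`, `nuclear`.
#' @export
read_localization_registry <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0) {
    abort(sprintf("localization registry empty: %s", path))
  }
  if (!all(c("accession", "compartment") %in% names(tab))) {
    abort("localization registry needs columns 'accession' and 'compartment'")
  }
  compartments <- c("extracellular", "cytoplasmic", "nuclear")
  bad <- setdiff(unique(tab$compartment), compartments)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown compartment label(s): %s (expected %s)",
      paste(bad, collapse = ", "), paste(compartments, collapse = "/")
    ))
  }
  if (any(!is_pfam_acc(tab$accession))) {
    abort(sprintf(
      "malformed accession(s): %s",
      paste(tab$accession[!is_pfam_acc(tab$accession)], collapse = ", ")
    ))
  }
  tab$accession <- strip_acc_version(tab$accession)
  conflicting <- tab |>
    distinct(.data$accession, .data$compartment) |>
    dplyr::count(.data$accession) |>
    filter(.data$n > 1)
  if (nrow(conflicting) > 0) {
    abort(sprintf(
      "accession(s) assigned to more than one compartment: %s",
      paste(conflicting$accession, collapse = ", ")
    ))
  }
  reg <- lapply(compartments, function(cp) {
    sort(unique(tab$accession[tab$compartment == cp]))
  })
  names(reg) <- compartments
  structure(reg, class = "mp_loc_registry")
}

#' Load a domain-size reference registry
#'
#' Tab-separated file with columns `accession`, `reference_length` and
#' optionally `length_sd` and `source_n`. `length_sd = 0` means the family
#' length is fixed; a missing `length_sd` makes the size rule fall back to
#' fractional bounds (see [engine_config()]).
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `mp_size_registry` keyed by version-stripped
#'   accession.
#' @export
read_size_registry <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    accession = "c", reference_length = "d",
    .default = "d"
  ))
  if (nrow(tab) == 0) {
    abort(sprintf("size registry empty: %s", path))
  }
  if (!all(c("accession", "reference_length") %in% names(tab))) {
    abort("size registry needs columns 'accession' and 'reference_length'")
  }
  if (!"length_sd" %in% names(tab)) tab$length_sd <- NA_real_
  if (!"source_n" %in% names(tab)) tab$source_n <- NA_real_
  if (any(!is_pfam_acc(tab$accession))) {
    abort("size registry: malformed accession")
  }
  if (any(is.na(tab$reference_length) | tab$reference_length <= 0)) {
    abort("size registry: reference_length must be positive")
  }
  if (any(!is.na(tab$length_sd) & tab$length_sd < 0)) {
    abort("size registry: length_sd must be >= 0")
  }
  tab$accession <- strip_acc_version(tab$accession)
  dup <- tab |>
    distinct(.data$accession, .data$reference_length, .data$length_sd) |>
    dplyr::count(.data$accession) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "size registry: duplicate accession(s) with conflicting values: %s",
      paste(dup$accession, collapse = ", ")
    ))
  }
  out <- distinct(tab, .data$accession, .keep_all = TRUE) |>
    select("accession", "reference_length", "length_sd", "source_n")
  class(out) <- c("mp_size_registry", class(out))
  out
}

#' Load a known domain-architecture registry
#'
#' One architecture per line: comma-separated Pfam accessions in N-to-C
#' order. Blank lines and `#` comments are ignored. Keys are stored
#' version-stripped; consecutive repeats of the same family are collapsed
#' when `repeat_collapse` is on, so `PF00051,PF00051,PF01822` and
#' `PF00051,PF01822` denote the same architecture.
#'
#' @param path Path to the file.
#' @param repeat_collapse Collapse consecutive repeats (default `TRUE`).
#' @return A character vector of class `mp_arch_registry`; each element is
#'   an architecture key (accessions joined by `,`).
#' @export
read_architecture_registry <- function(path, repeat_collapse = TRUE) {
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    abort(sprintf("architecture registry empty: %s", path))
  }
  keys <- vapply(lines, function(ln) {
    accs <- trimws(strsplit(ln, ",")[[1]])
    accs <- accs[nzchar(accs)]
    if (length(accs) == 0) abort("architecture registry: empty architecture")
    if (any(!is_pfam_acc(accs))) {
      abort(sprintf("architecture registry: malformed accession in '%s'", ln))
    }
    architecture_key(accs, repeat_collapse = repeat_collapse)
  }, "", USE.NAMES = FALSE)
  structure(sort(unique(keys)), class = "mp_arch_registry")
}

#' Architecture key for a sequence of family accessions
#'
#' Version-strips the accessions and (optionally) collapses consecutive
#' repeats, then joins them with `,` in the given N-to-C order.
#'
#' @param accessions Character vector of Pfam accessions, N-to-C.
#' @param repeat_collapse Collapse consecutive repeats.
#' @return A single string, or `NA_character_` for zero accessions.
#' @export
architecture_key <- function(accessions, repeat_collapse = TRUE) {
  if (length(accessions) == 0) {
    return(NA_character_)
  }
  accs <- strip_acc_version(accessions)
  if (repeat_collapse) {
    accs <- accs[c(TRUE, accs[-1] != accs[-length(accs)])]
  }
  paste(accs, collapse = ",")
}

#' Load the three rule registries from a directory
#'
#' Expects `localization.tsv`, `domain_sizes.tsv` and `architectures.txt`
#' under `dir`. The package ships a small illustrative set under
#' `system.file("extdata/registries/demo", package = "mispredqc")`.
#'
#' @param dir Directory containing the three files.
#' @param repeat_collapse Passed to [read_architecture_registry()].
#' @return A list with elements `localization`, `sizes`, `architectures`.
#' @export
load_registries <- function(dir, repeat_collapse = TRUE) {
  paths <- file.path(dir, c("localization.tsv", "domain_sizes.tsv", "architectures.txt"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing registry file(s): %s", paste(missing, collapse = ", ")))
  }
  list(
    localization = read_localization_registry(paths[1]),
    sizes = read_size_registry(paths[2]),
    architectures = read_architecture_registry(paths[3], repeat_collapse)
  )
}

#' Demo registries bundled with the package
#'
#' Convenience wrapper around [load_registries()] for the illustrative
#' demo registry set (a handful of well-known Pfam families per
#' compartment with hand-chosen reference lengths — not curated
#' production lists).
#'
#' @inheritParams load_registries
#' @return A list with elements `localization`, `sizes`, `architectures`.
#' @export
demo_registries <- function(repeat_collapse = TRUE) {
  load_registries(
    system.file("extdata/registries/demo", package = "mispredqc"),
    repeat_collapse = repeat_collapse
  )
}
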