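# Parsers for the standard output dialects of the upstream predictors.
# Each parser targets one documented dialect version and fails loudly on
# anything else; all dialects here are whitespace-delimited, so runs of
# spaces/tabs are equivalent. Coordinates are converted to 1-based
# inclusive residue positions at this boundary.

#' Read protein sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header is the protein id;
#' the remainder is kept as the description. Sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("no sequences in FASTA file: %s", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate FASTA id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf(
      "empty sequence for id(s): %s", paste(ids[nchar(seqs) == 0], collapse = ", ")
    ))
  }
  tibble(protein_id = ids, description = desc, sequence = unname(seqs))
}

#' Read domain hits from a HMMER3 domtblout file
#'
#' Expects per-domain tabular output of `hmmscan` (query = protein, target
#' = profile). Hits with independent E-value above `e_value_max` are
#' dropped; overlapping hits of the same family with more than 50% mutual
#' overlap are merged, keeping the lower-E-value hit's coordinates; copy
#' indices are then assigned per family in N-to-C order.
#'
#' @param path Path to a domtblout file.
#' @param e_value_max Acceptance threshold on the independent E-value.
#' @param merge_overlaps Merge >50% mutually overlapping same-family hits.
#' @return A tibble with columns `protein_id` plus the domain-hit columns
#'   (`family_acc`, `family_name`, `copy_index`, `ali_start`, `ali_end`,
#'   `hmm_start`, `hmm_end`, `model_tag`, `score`, `e_value`).
#' @export
read_domtblout <- function(path, e_value_max = 1e-3, merge_overlaps = TRUE) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
  if (length(keep) == 0) {
    return(mutate(empty_domain_hits(), protein_id = character(), .before = 1))
  }
  fields <- split_fields(raw[keep])
  bad <- which(lengths(fields) < 22)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed domtblout line %d: expected >= 22 whitespace-delimited fields, got %d",
      keep[bad[1]], length(fields[[bad[1]]])
    ))
  }
  f <- function(i) vapply(fields, `[`, "", i)
  hits <- tibble(
    protein_id = f(4),
    family_acc = f(2),
    family_name = f(1),
    ali_start = as.integer(f(18)),
    ali_end = as.integer(f(19)),
    hmm_start = as.integer(f(16)),
    hmm_end = as.integer(f(17)),
    model_tag = "ls",
    score = as.numeric(f(14)),
    e_value = as.numeric(f(13))
  )
  if (anyNA(hits$ali_start) || anyNA(hits$e_value)) {
    abort(sprintf("malformed domtblout line %d: non-numeric coordinate or score",
      keep[which(is.na(hits$ali_start) | is.na(hits$e_value))[1]]
    ))
  }
  hits <- filter(hits, .data$e_value <= e_value_max)
  hits <- hits |>
    mutate(family_bare = strip_acc_version(.data$family_acc)) |>
    group_by(.data$protein_id, .data$family_bare)
  if (merge_overlaps) {
    hits <- hits |>
      dplyr::group_modify(~ drop_mutual_overlaps(.x)) |>
      group_by(.data$protein_id, .data$family_bare)
  }
  hits |>
    arrange(.data$ali_start, .by_group = TRUE) |>
    mutate(copy_index = row_number()) |>
    ungroup() |>
    select(-"family_bare") |>
    arrange(.data$protein_id, .data$ali_start) |>
    select(
      "protein_id", "family_acc", "family_name", "copy_index",
      "ali_start", "ali_end", "hmm_start", "hmm_end",
      "model_tag", "score", "e_value"
    )
}

# Greedy best-E filter: within one (protein, family) group, drop any hit
# whose span mutually overlaps (>50% of both spans) a better-E kept hit.
drop_mutual_overlaps <- function(hits) {
  hits <- arrange(hits, .data$e_value, .data$ali_start)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- interval_overlap(
        hits$ali_start[i], hits$ali_end[i],
        hits$ali_start[j], hits$ali_end[j]
      )
      len_i <- hits$ali_end[i] - hits$ali_start[i] + 1L
      len_j <- hits$ali_end[j] - hits$ali_start[j] + 1L
      if (ov > 0.5 * len_i && ov > 0.5 * len_j) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Read signal-peptide calls from SignalP 4 short-format output
#'
#' Expects the 12-column short format (`# SignalP-4.x` header): the
#' `?` column carries the Y/N decision and the `Ymax` position is the first
#' residue of the mature protein, so a positive call spans residues
#' 1 to `ypos - 1`.
#'
#' @param path Path to a SignalP short output file.
#' @return A tibble of predictor calls (`predictor`, `protein_id`,
#'   `feature_kind`, `start`, `end`, `score`, `called`).
#' @export
read_signalp_short <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0 || !grepl("^# SignalP", raw[1])) {
    abort("not SignalP short output: expected a '# SignalP-4.1 ...' header line")
  }
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(predictor_call_tbl())
  }
  fields <- split_fields(lines)
  bad <- which(lengths(fields) < 12)
  if (length(bad) > 0) {
    abort(sprintf("malformed SignalP line: '%s' (expected 12 fields)", lines[bad[1]]))
  }
  purrr::map_dfr(fields, function(x) {
    called <- identical(x[10], "Y")
    ypos <- as.integer(x[5])
    predictor_call_tbl(
      predictor = "SignalP", protein_id = x[1], feature_kind = "signal_peptide",
      start = if (called) 1L else NA_integer_,
      end = if (called) ypos - 1L else NA_integer_,
      score = as.numeric(x[9]), called = called
    )
  })
}

#' Read signal-peptide calls from a PrediSi-style table
#'
#' Simple whitespace-delimited table (a `# PrediSi` header line, then
#' `protein_id score cleavage_position decision`), with decision `Y`/`N`
#' and the cleavage position giving the last residue of the signal peptide.
#'
#' @param path Path to the table.
#' @return A tibble of predictor calls (see [read_signalp_short()]).
#' @export
read_predisi_table <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0 || !grepl("^# PrediSi", raw[1])) {
    abort("not a PrediSi-style table: expected a '# PrediSi' header line")
  }
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(predictor_call_tbl())
  }
  fields <- split_fields(lines)
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed PrediSi line: '%s' (expected 4 fields)", lines[bad[1]]))
  }
  purrr::map_dfr(fields, function(x) {
    called <- identical(x[4], "Y")
    predictor_call_tbl(
      predictor = "PrediSi", protein_id = x[1], feature_kind = "signal_peptide",
      start = if (called) 1L else NA_integer_,
      end = if (called) as.integer(x[3]) else NA_integer_,
      score = as.numeric(x[2]), called = called
    )
  })
}

#' Read transmembrane-helix calls from TMHMM 2 short-format output
#'
#' One line per protein:
#' `id len=L ExpAA=.. First60=.. PredHel=N Topology=o10-32i..`.
#' The `PredHel` count is expanded into helix spans taken from the
#' topology string; `PredHel=0` yields a single negative call.
#'
#' @param path Path to a TMHMM short output file.
#' @return A tibble of predictor calls.
#' @export
read_tmhmm_short <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(predictor_call_tbl())
  }
  fields <- split_fields(lines)
  bad <- which(!vapply(fields, function(x) any(grepl("^PredHel=", x)), logical(1)))
  if (length(bad) > 0) {
    abort(sprintf(
      "not TMHMM short output: line '%s' lacks a 'PredHel=' field", lines[bad[1]]
    ))
  }
  purrr::map_dfr(fields, function(x) {
    id <- x[1]
    nhel <- as.integer(sub("^PredHel=", "", x[grepl("^PredHel=", x)][1]))
    topo <- sub("^Topology=", "", x[grepl("^Topology=", x)][1])
    if (nhel == 0) {
      return(predictor_call_tbl(
        predictor = "TMHMM", protein_id = id, feature_kind = "tm_helix",
        called = FALSE
      ))
    }
    m <- stringr::str_match_all(topo, "(\\d+)-(\\d+)")[[1]]
    if (nrow(m) != nhel) {
      abort(sprintf(
        "TMHMM line for '%s': PredHel=%d but topology string has %d spans",
        id, nhel, nrow(m)
      ))
    }
    predictor_call_tbl(
      predictor = "TMHMM", protein_id = id, feature_kind = "tm_helix",
      start = as.integer(m[, 2]), end = as.integer(m[, 3]),
      called = TRUE
    )
  })
}

#' Read signal-peptide and helix calls from Phobius FT-row output
#'
#' Expects the long (feature-table) dialect: blocks of
#' `ID <protein>` / `FT SIGNAL 1 21` / `FT TRANSMEM 30 52` / `//`.
#' SIGNAL rows become signal-peptide calls; TRANSMEM rows become helix
#' calls; a block with no FT rows yields negative calls for both kinds.
#' Other FT row types (DOMAIN, TOPO_DOM, ...) are ignored.
#'
#' @param path Path to a Phobius output file.
#' @return A tibble of predictor calls.
#' @export
read_phobius <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(predictor_call_tbl())
  }
  if (!startsWith(trimws(lines[1]), "ID")) {
    abort("not Phobius FT output: expected a leading 'ID <protein>' line")
  }
  calls <- list()
  id <- NULL
  saw_sp <- FALSE
  saw_tm <- FALSE
  flush <- function() {
    out <- list()
    if (!saw_sp) {
      out <- c(out, list(predictor_call_tbl(
        predictor = "Phobius", protein_id = id,
        feature_kind = "signal_peptide", called = FALSE
      )))
    }
    if (!saw_tm) {
      out <- c(out, list(predictor_call_tbl(
        predictor = "Phobius", protein_id = id,
        feature_kind = "tm_helix", called = FALSE
      )))
    }
    out
  }
  for (ln in lines) {
    x <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (x[1] == "ID") {
      if (!is.null(id)) abort(sprintf("Phobius block for '%s' not closed with '//'", id))
      id <- x[2]
      saw_sp <- FALSE
      saw_tm <- FALSE
    } else if (x[1] == "//") {
      calls <- c(calls, flush())
      id <- NULL
    } else if (x[1] == "FT") {
      if (is.null(id)) abort("Phobius FT row outside an ID block")
      kind <- x[2]
      if (kind == "SIGNAL") {
        calls <- c(calls, list(predictor_call_tbl(
          predictor = "Phobius", protein_id = id, feature_kind = "signal_peptide",
          start = as.integer(x[3]), end = as.integer(x[4]), called = TRUE
        )))
        saw_sp <- TRUE
      } else if (kind == "TRANSMEM") {
        calls <- c(calls, list(predictor_call_tbl(
          predictor = "Phobius", protein_id = id, feature_kind = "tm_helix",
          start = as.integer(x[3]), end = as.integer(x[4]), called = TRUE
        )))
        saw_tm <- TRUE
      }
    } else {
      abort(sprintf(
        "not Phobius FT output: unexpected line '%s' (expected ID/FT///)", ln
      ))
    }
  }
  if (!is.null(id)) abort(sprintf("Phobius block for '%s' not closed with '//'", id))
  bind_rows(calls)
}

#' Read GPI-anchor calls from a DGPI-style table
#'
#' Whitespace-delimited table (a `# GPI` header line, then
#' `protein_id decision omega_site`), decision `Y`/`N`; the omega site is
#' the anchor attachment residue.
#'
#' @param path Path to the table.
#' @return A tibble of predictor calls.
#' @export
read_gpi_table <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0 || !grepl("^# GPI", raw[1])) {
    abort("not a GPI table: expected a '# GPI' header line")
  }
  lines <- read_data_lines(path)
  if (length(lines) == 0) {
    return(predictor_call_tbl())
  }
  fields <- split_fields(lines)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GPI table line: '%s' (expected 3 fields)", lines[bad[1]]))
  }
  purrr::map_dfr(fields, function(x) {
    called <- identical(x[2], "Y")
    omega <- if (called) as.integer(x[3]) else NA_integer_
    predictor_call_tbl(
      predictor = "DGPI", protein_id = x[1], feature_kind = "gpi_anchor",
      start = omega, end = omega, called = called
    )
  })
}

# typed predictor-call row(s); zero-argument call gives the empty table
predictor_call_tbl <- function(predictor = character(), protein_id = character(),
                               feature_kind = character(), start = NA_integer_,
                               end = NA_integer_, score = NA_real_,
                               called = logical()) {
  n <- max(length(protein_id), length(start[!is.na(start)]), length(called))
  if (length(protein_id) == 0) {
    return(mutate(empty_predictor_calls(), protein_id = character(), .before = 2))
  }
  tibble(
    predictor = rep_len(predictor, n),
    protein_id = rep_len(protein_id, n),
    feature_kind = rep_len(feature_kind, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    score = as.numeric(rep_len(score, n)),
    called = rep_len(called, n)
  )
}

#' Read genome mappings of coding segments from a BLAT PSL file
#'
#' Accepts PSL with or without the `psLayout` header. Query names follow
#' the convention `<protein_id>:seg<k>` (a bare name is treated as segment
#' 1). For each query segment only the top-scoring alignment is kept
#' (score = matches − mismatches − query gaps − target gaps); identity is
#' `matches / (matches + mismatches)` and coverage is aligned query bases
#' over query length. Alignments below the thresholds are discarded.
#'
#' @param path Path to a PSL file.
#' @param min_identity,min_coverage Acceptance thresholds (fractions).
#' @return A tibble with columns `protein_id`, `segment_index`,
#'   `chromosome`, `strand`, `identity`, `query_coverage`,
#'   `alignment_score`.
#' @export
read_psl <- function(path, min_identity = 0.95, min_coverage = 0.80) {
  lines <- read_data_lines(path, drop_comments = FALSE)
  # skip the optional psLayout header block: keep lines whose first token
  # is an integer (possibly malformed-negative, caught below)
  first_tok <- sub("^\\s*(\\S+).*$", "\\1", lines)
  lines <- lines[grepl("^-?\\d+$", first_tok)]
  if (length(lines) == 0) {
    return(mutate(empty_segment_mappings(), protein_id = character(), .before = 1))
  }
  fields <- split_fields(lines)
  bad <- which(lengths(fields) < 17)
  if (length(bad) > 0) {
    abort(sprintf("malformed PSL line: '%s' (expected >= 17 fields)", lines[bad[1]]))
  }
  f <- function(i) vapply(fields, `[`, "", i)
  num <- function(i) as.numeric(f(i))
  matches <- num(1)
  mismatches <- num(2)
  q_gaps <- num(5)
  t_gaps <- num(7)
  if (any(c(matches, mismatches, q_gaps, t_gaps) < 0, na.rm = TRUE) ||
    anyNA(matches)) {
    abort("malformed PSL line: negative or non-numeric counts")
  }
  qname <- f(10)
  seg <- stringr::str_match(qname, "^(.*):seg(\\d+)$")
  tab <- tibble(
    protein_id = ifelse(is.na(seg[, 2]), qname, seg[, 2]),
    segment_index = ifelse(is.na(seg[, 3]), 1L, as.integer(seg[, 3])),
    chromosome = f(14),
    strand = f(9),
    identity = matches / (matches + mismatches),
    query_coverage = (num(13) - num(12)) / num(11),
    alignment_score = matches - mismatches - q_gaps - t_gaps
  )
  tab |>
    group_by(.data$protein_id, .data$segment_index) |>
    arrange(dplyr::desc(.data$alignment_score), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    filter(.data$identity >= min_identity, .data$query_coverage >= min_coverage) |>
    arrange(.data$protein_id, .data$segment_index)
}
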