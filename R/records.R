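# The shared annotation model: one protein per row, feature tables nested in
# list-columns. All coordinates are 1-based inclusive residue positions.

# canonical (possibly empty) feature tables -----------------------------------

empty_alt_ids <- function() {
  tibble(db = character(), accession = character())
}

empty_domain_hits <- function() {
  tibble(
    family_acc = character(), family_name = character(),
    copy_index = integer(),
    ali_start = integer(), ali_end = integer(),
    hmm_start = integer(), hmm_end = integer(),
    model_tag = character(), score = double(), e_value = double()
  )
}

empty_predictor_calls <- function() {
  tibble(
    predictor = character(), feature_kind = character(),
    start = integer(), end = integer(),
    score = double(), called = logical()
  )
}

empty_segment_mappings <- function() {
  tibble(
    segment_index = integer(), chromosome = character(),
    strand = character(), identity = double(),
    query_coverage = double(), alignment_score = double()
  )
}

FEATURE_KINDS <- c("signal_peptide", "signal_anchor", "tm_helix", "gpi_anchor")

# record constructor ----------------------------------------------------------

#' Build a protein-record table from per-protein components
#'
#' Low-level constructor used by [assemble_records()] and the fixture
#' generator; most users will not call it directly. Each argument after
#' `sequence` is recycled to the number of proteins.
#'
#' @param protein_id Character vector of primary accessions (unique).
#' @param sequence Amino-acid sequences (20-letter alphabet plus X, B, Z, U).
#' @param species,description,analysis_date Per-protein metadata.
#' @param alt_ids,domain_hits,predictor_calls,segment_mappings Lists of
#'   per-protein feature tibbles (see the package vignette for the column
#'   contracts), or `NULL` for none.
#' @param topology List of per-protein consensus topologies as returned by
#'   [consensus_topology()], or `NULL` to compute them from
#'   `predictor_calls` under `config`.
#' @param config An [engine_config()], used when topology must be derived.
#' @return A tibble of class `mp_records`, one row per protein.
#' @export
protein_records <- function(protein_id, sequence,
                            species = "unknown", description = "",
                            analysis_date = format(Sys.Date()),
                            alt_ids = NULL, domain_hits = NULL,
                            predictor_calls = NULL, segment_mappings = NULL,
                            topology = NULL, config = engine_config()) {
  n <- length(protein_id)
  if (anyDuplicated(protein_id)) {
    abort("protein_id: duplicate identifiers in record set")
  }
  fill <- function(x, default) {
    if (is.null(x)) {
      return(rep(list(default), n))
    }
    # normalize degenerate entries (NULL, zero-column frames) to the typed
    # empty table so downstream column access is always well-defined
    lapply(x, function(el) {
      if (is.null(el) || ncol(el) == 0) default else el
    })
  }
  rec <- tibble(
    protein_id = as.character(protein_id),
    alt_ids = fill(alt_ids, empty_alt_ids()),
    species = rep_len(as.character(species), n),
    description = rep_len(as.character(description), n),
    sequence = toupper(as.character(sequence)),
    domain_hits = fill(domain_hits, empty_domain_hits()),
    predictor_calls = fill(predictor_calls, empty_predictor_calls()),
    segment_mappings = fill(segment_mappings, empty_segment_mappings()),
    analysis_date = rep_len(as.character(analysis_date), n)
  )
  if (is.null(topology)) {
    topology <- purrr::map2(
      rec$predictor_calls, nchar(rec$sequence),
      function(calls, len) consensus_topology(calls, len, config)
    )
  }
  rec$topology <- topology
  rec <- rec[, c(
    "protein_id", "alt_ids", "species", "description", "sequence",
    "domain_hits", "predictor_calls", "topology", "segment_mappings",
    "analysis_date"
  )]
  class(rec) <- c("mp_records", class(rec))
  rec
}

# validation ------------------------------------------------------------------

#' Validate a record set against the annotation-model invariants
#'
#' Hard invariant violations (illegal residues, feature coordinates outside
#' the sequence, malformed accessions, negative E-values, identity or
#' coverage outside \[0,1\]) raise an error naming the protein and field.
#' Softer oddities are returned as a warnings table: runs of 10 or more
#' `X` residues, a non-methionine start (possible N-terminal truncation),
#' ambiguous/selenocysteine residues (U, B, Z), and records with no feature
#' annotation at all.
#'
#' @param records An `mp_records` tibble.
#' @return A tibble with columns `protein_id`, `type`, `message`
#'   (zero rows when nothing is noteworthy).
#' @export
validate_records <- function(records) {
  stopifnot(inherits(records, "mp_records"))
  warn_rows <- purrr::pmap(records, validate_one)
  dplyr::bind_rows(warn_rows)
}

validate_one <- function(protein_id, sequence, domain_hits, predictor_calls,
                         topology, segment_mappings, ...) {
  len <- nchar(sequence)
  if (len == 0) {
    abort(sprintf("%s: field 'sequence' is empty", protein_id))
  }
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: field 'sequence' contains illegal residue(s): %s",
      protein_id, paste(bad, collapse = ", ")
    ))
  }
  h <- domain_hits
  if (nrow(h) > 0) {
    if (any(h$ali_start < 1 | h$ali_end > len | h$ali_start > h$ali_end)) {
      abort(sprintf(
        "%s: field 'domain_hits' has a residue span outside [1, %d]",
        protein_id, len
      ))
    }
    if (any(h$hmm_start < 1 | h$hmm_start > h$hmm_end)) {
      abort(sprintf("%s: field 'domain_hits' has an invalid HMM span", protein_id))
    }
    if (any(h$e_value < 0)) {
      abort(sprintf("%s: field 'domain_hits' has a negative E-value", protein_id))
    }
    if (any(!is_pfam_acc(h$family_acc))) {
      abort(sprintf("%s: field 'domain_hits' has a malformed accession", protein_id))
    }
  }
  m <- segment_mappings
  if (nrow(m) > 0) {
    if (any(m$identity < 0 | m$identity > 1 |
      m$query_coverage < 0 | m$query_coverage > 1)) {
      abort(sprintf(
        "%s: field 'segment_mappings' has identity or coverage outside [0,1]",
        protein_id
      ))
    }
    if (any(m$segment_index < 1)) {
      abort(sprintf("%s: field 'segment_mappings' has segment_index < 1", protein_id))
    }
  }
  sp <- topology$signal_peptide
  if (!is.null(sp) && sp$start != 1L) {
    abort(sprintf(
      "%s: field 'topology' signal peptide does not start at residue 1",
      protein_id
    ))
  }
  tm <- topology$tm_helices
  if (nrow(tm) > 1) {
    if (is.unsorted(tm$start) || any(tm$start[-1] <= tm$end[-nrow(tm)])) {
      abort(sprintf(
        "%s: field 'topology' TM helices overlap or are unsorted", protein_id
      ))
    }
  }

  warns <- list()
  if (grepl("X{10,}", sequence)) {
    warns <- c(warns, list(c("long_x_run", "run of 10 or more X residues")))
  }
  if (residues[1] != "M") {
    warns <- c(warns, list(c(
      "non_met_start", "sequence does not start with Met (possible N-terminal truncation)"
    )))
  }
  amb <- intersect(unique(residues), c("U", "B", "Z"))
  if (length(amb) > 0) {
    warns <- c(warns, list(c(
      "ambiguous_residue",
      paste0(
        "sequence contains ", paste(amb, collapse = ", "),
        "; upstream predictor behaviour on these residues is undefined"
      )
    )))
  }
  if (nrow(h) == 0 && nrow(predictor_calls) == 0 && nrow(m) == 0) {
    warns <- c(warns, list(c("no_features", "record carries no feature annotation")))
  }
  if (length(warns) == 0) {
    return(tibble(protein_id = character(), type = character(), message = character()))
  }
  tibble(
    protein_id = protein_id,
    type = vapply(warns, `[`, "", 1),
    message = vapply(warns, `[`, "", 2)
  )
}
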