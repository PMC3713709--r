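# Assembling parsed annotation tables into one record set, and the
# canonical on-disk JSON form of a record set.

#' Assemble protein records from parsed annotation tables
#'
#' Joins per-source annotation tables (all keyed by `protein_id`) onto the
#' sequence table, one record per FASTA entry. Annotation rows whose id is
#' absent from the sequence table are dropped with a warning; missing
#' annotation sources simply yield empty feature tables. The consensus
#' topology is computed from the predictor calls under `config` and stored
#' alongside the raw votes, so the consensus policy stays auditable and
#' re-derivable.
#'
#' @param seqs A tibble from [read_fasta()] (columns `protein_id`,
#'   `description`, `sequence`; a `species` column is honoured if present).
#' @param domain_hits Output of [read_domtblout()], or `NULL`.
#' @param predictor_calls Row-bound output of the predictor parsers
#'   ([read_signalp_short()], [read_predisi_table()], [read_tmhmm_short()],
#'   [read_phobius()], [read_gpi_table()]), or any tibble in the same
#'   shape (e.g. pre-annotated calls, including explicit `signal_anchor`
#'   rows), or `NULL`.
#' @param mappings Output of [read_psl()], or `NULL`.
#' @param alt_ids Optional tibble `protein_id`, `db`, `accession` of
#'   additional database identifiers for the same sequences.
#' @param species,analysis_date Per-corpus defaults for the record fields.
#' @param config An [engine_config()] (consensus policy and windows).
#' @return A tibble of class `mp_records`.
#' @export
assemble_records <- function(seqs, domain_hits = NULL, predictor_calls = NULL,
                             mappings = NULL, alt_ids = NULL,
                             species = "unknown",
                             analysis_date = format(Sys.Date()),
                             config = engine_config()) {
  stopifnot(all(c("protein_id", "sequence") %in% names(seqs)))
  ids <- seqs$protein_id

  pick <- function(tab, what, cols) {
    if (is.null(tab) || nrow(tab) == 0) {
      return(lapply(ids, function(i) cols))
    }
    ghost <- setdiff(unique(tab$protein_id), ids)
    if (length(ghost) > 0) {
      warn(sprintf(
        "%s for id(s) absent from FASTA, skipped: %s",
        what, paste(ghost, collapse = ", ")
      ))
      tab <- filter(tab, !.data$protein_id %in% ghost)
    }
    lapply(ids, function(i) {
      sub <- tab[tab$protein_id == i, setdiff(names(tab), "protein_id"), drop = FALSE]
      if (nrow(sub) == 0) cols else sub
    })
  }

  protein_records(
    protein_id = ids,
    sequence = seqs$sequence,
    species = if ("species" %in% names(seqs)) seqs$species else species,
    description = if ("description" %in% names(seqs)) seqs$description else "",
    analysis_date = analysis_date,
    alt_ids = pick(alt_ids, "alt ids", empty_alt_ids()),
    domain_hits = pick(domain_hits, "domain hits", empty_domain_hits()),
    predictor_calls = pick(predictor_calls, "predictor calls", empty_predictor_calls()),
    segment_mappings = pick(mappings, "segment mappings", empty_segment_mappings()),
    config = config
  )
}

#' Read a corpus directory of predictor outputs into records
#'
#' Reads the file set written by [emit_mock_tool_outputs()] (or any
#' directory following the same layout): `proteins.fasta` plus any of
#' `domains.domtblout`, `signalp.short`, `predisi.tsv`, `tmhmm.short`,
#' `phobius.txt`, `gpi.tsv`, `segments.psl`, `meta.tsv`. Missing files are
#' simply absent annotation sources.
#'
#' @param dir Directory containing the corpus files.
#' @param config An [engine_config()]; also supplies the domtblout and PSL
#'   acceptance thresholds.
#' @return A tibble of class `mp_records`.
#' @export
read_corpus_dir <- function(dir, config = engine_config()) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("proteins.fasta"))) {
    abort(sprintf("no proteins.fasta under %s", dir))
  }
  seqs <- read_fasta(p("proteins.fasta"))

  hits <- if (file.exists(p("domains.domtblout"))) {
    read_domtblout(p("domains.domtblout"), e_value_max = config$e_value_max)
  }
  calls <- list()
  if (file.exists(p("signalp.short"))) calls <- c(calls, list(read_signalp_short(p("signalp.short"))))
  if (file.exists(p("predisi.tsv"))) calls <- c(calls, list(read_predisi_table(p("predisi.tsv"))))
  if (file.exists(p("tmhmm.short"))) calls <- c(calls, list(read_tmhmm_short(p("tmhmm.short"))))
  if (file.exists(p("phobius.txt"))) calls <- c(calls, list(read_phobius(p("phobius.txt"))))
  if (file.exists(p("gpi.tsv"))) calls <- c(calls, list(read_gpi_table(p("gpi.tsv"))))
  calls <- if (length(calls) > 0) bind_rows(calls)
  maps <- if (file.exists(p("segments.psl"))) {
    read_psl(p("segments.psl"),
      min_identity = config$psl_min_identity,
      min_coverage = config$psl_min_coverage
    )
  }

  species <- "unknown"
  analysis_date <- format(Sys.Date())
  alt_ids <- NULL
  if (file.exists(p("meta.tsv"))) {
    meta <- readr::read_tsv(p("meta.tsv"), col_types = readr::cols(.default = "c"))
    one <- distinct(meta, .data$protein_id, .data$species, .data$analysis_date)
    seqs <- left_join(seqs, one, by = "protein_id")
    species <- seqs$species
    analysis_date <- seqs$analysis_date
    seqs <- select(seqs, "protein_id", "description", "sequence")
    alt_ids <- meta |>
      filter(!is.na(.data$db)) |>
      select("protein_id", "db", "accession")
  }

  assemble_records(
    seqs,
    domain_hits = hits, predictor_calls = calls, mappings = maps,
    alt_ids = alt_ids, species = species, analysis_date = analysis_date,
    config = config
  )
}

# canonical JSON serialization ------------------------------------------------

#' Write a record set to the canonical JSON form
#'
#' One JSON document per corpus. The predictor votes, not the derived
#' topology, are serialized (together with the engine configuration), so
#' reloading re-derives the identical consensus.
#'
#' @param records An `mp_records` tibble.
#' @param path Output file path.
#' @param config The [engine_config()] under which topologies were derived.
#' @return `path`, invisibly.
#' @export
write_records_json <- function(records, path, config = engine_config()) {
  doc <- list(
    format = "mispredqc-records/1",
    config = unclass(config),
    records = purrr::pmap(records, function(protein_id, alt_ids, species,
                                            description, sequence, domain_hits,
                                            predictor_calls, topology,
                                            segment_mappings, analysis_date) {
      list(
        protein_id = protein_id,
        alt_ids = alt_ids,
        species = species,
        description = description,
        sequence = sequence,
        domain_hits = domain_hits,
        predictor_calls = predictor_calls,
        segment_mappings = segment_mappings,
        analysis_date = analysis_date
      )
    })
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(path)
}

#' Read a record set from the canonical JSON form
#'
#' @param path Path written by [write_records_json()].
#' @return A tibble of class `mp_records`.
#' @export
read_records_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mispredqc-records/1")) {
    abort(sprintf("%s: not a mispredqc records document", path))
  }
  cfg_args <- doc$config
  cfg_args$enabled_rules <- unlist(cfg_args$enabled_rules)
  config <- do.call(engine_config, cfg_args)

  retype <- function(rows, template) {
    if (length(rows) == 0) {
      return(template)
    }
    tab <- bind_rows(lapply(rows, function(r) {
      as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
    }))
    for (col in names(template)) {
      if (!col %in% names(tab)) {
        tab[[col]] <- NA
      }
      mode_fun <- class(template[[col]])[1]
      tab[[col]] <- switch(mode_fun,
        integer = as.integer(tab[[col]]),
        numeric = as.numeric(tab[[col]]),
        character = as.character(tab[[col]]),
        logical = as.logical(tab[[col]]),
        tab[[col]]
      )
    }
    tab[, names(template), drop = FALSE]
  }

  recs <- doc$records
  protein_records(
    protein_id = vapply(recs, `[[`, "", "protein_id"),
    sequence = vapply(recs, `[[`, "", "sequence"),
    species = vapply(recs, `[[`, "", "species"),
    description = vapply(recs, `[[`, "", "description"),
    analysis_date = vapply(recs, `[[`, "", "analysis_date"),
    alt_ids = lapply(recs, function(r) retype(r$alt_ids, empty_alt_ids())),
    domain_hits = lapply(recs, function(r) retype(r$domain_hits, empty_domain_hits())),
    predictor_calls = lapply(recs, function(r) {
      retype(r$predictor_calls, empty_predictor_calls())
    }),
    segment_mappings = lapply(recs, function(r) {
      retype(r$segment_mappings, empty_segment_mappings())
    }),
    config = config
  )
}
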