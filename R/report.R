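# Per-protein report output (JSON and flat TSV) and the high-level
# check-everything entry point the CLI wraps.

#' Write a conflict report as a flat TSV
#'
#' One row per (protein, conflict); clean proteins appear once with an
#' empty rule column so the file enumerates the whole corpus.
#'
#' @param report An `mp_report` from [evaluate_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  flat <- report$proteins |>
    left_join(
      report$conflicts |>
        mutate(evidence = vapply(
          .data$evidence, paste, "",
          collapse = "; "
        )),
      by = "protein_id"
    ) |>
    select(
      "protein_id", "species", "clean", "rule_id", "rule_name", "evidence"
    )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write a conflict report as JSON
#'
#' Mirrors the three-part result layout of the original analysis pages:
#' per protein, a `protein` section (id, species), an `annotations`
#' section (counts of conflicts and skipped rules), and a `conclusions`
#' section listing the conflicts with their evidence.
#'
#' @inheritParams write_report_tsv
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  per_protein <- lapply(seq_len(nrow(report$proteins)), function(i) {
    id <- report$proteins$protein_id[i]
    conf <- report$conflicts[report$conflicts$protein_id == id, ]
    skip <- report$skipped[report$skipped$protein_id == id, ]
    list(
      protein = list(
        protein_id = id,
        species = report$proteins$species[i]
      ),
      annotations = list(
        n_conflicts = report$proteins$n_conflicts[i],
        skipped_rules = skip$rule_id
      ),
      conclusions = list(
        clean = report$proteins$clean[i],
        conflicts = lapply(seq_len(nrow(conf)), function(j) {
          list(
            rule_id = conf$rule_id[j],
            rule_name = conf$rule_name[j],
            message = conf$message[j],
            evidence = conf$evidence[[j]]
          )
        })
      )
    )
  })
  doc <- list(
    format = "mispredqc-report/1",
    n_proteins = report$n_proteins,
    n_flagged = sum(!report$proteins$clean),
    config = unclass(report$config),
    proteins = per_protein
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse annotation files, evaluate all rules, write reports
#'
#' The one-call pipeline behind the command-line `check` subcommand:
#' read the FASTA and whatever predictor outputs are supplied, assemble
#' records, run every enabled rule, and write `report.json` and
#' `report.tsv` under `out_dir`.
#'
#' @param fasta Path to the protein FASTA file (required).
#' @param domtblout,signalp,predisi,tmhmm,phobius,gpi,psl Optional paths
#'   to the corresponding predictor outputs.
#' @param registry_dir Directory with the three registry files (see
#'   [load_registries()]).
#' @param out_dir Output directory for `report.json` / `report.tsv`.
#' @param config An [engine_config()].
#' @param quiet Suppress per-stage record counts on stderr.
#' @return The `mp_report`, invisibly.
#' @export
run_check <- function(fasta, domtblout = NULL, signalp = NULL, predisi = NULL,
                      tmhmm = NULL, phobius = NULL, gpi = NULL, psl = NULL,
                      registry_dir, out_dir = ".",
                      config = engine_config(), quiet = FALSE) {
  registries <- load_registries(registry_dir, repeat_collapse = config$repeat_collapse)
  note <- function(...) if (!quiet) message(sprintf(...))

  seqs <- read_fasta(fasta)
  note("read %d sequence(s) from %s", nrow(seqs), fasta)

  hits <- NULL
  if (!is.null(domtblout)) {
    hits <- read_domtblout(domtblout, e_value_max = config$e_value_max)
    note("read %d domain hit(s)", nrow(hits))
  }
  calls <- list()
  if (!is.null(signalp)) calls <- c(calls, list(read_signalp_short(signalp)))
  if (!is.null(predisi)) calls <- c(calls, list(read_predisi_table(predisi)))
  if (!is.null(tmhmm)) calls <- c(calls, list(read_tmhmm_short(tmhmm)))
  if (!is.null(phobius)) calls <- c(calls, list(read_phobius(phobius)))
  if (!is.null(gpi)) calls <- c(calls, list(read_gpi_table(gpi)))
  calls <- if (length(calls) > 0) bind_rows(calls)
  if (!is.null(calls)) note("read %d predictor call(s)", nrow(calls))
  maps <- NULL
  if (!is.null(psl)) {
    maps <- read_psl(psl,
      min_identity = config$psl_min_identity,
      min_coverage = config$psl_min_coverage
    )
    note("read %d genome segment mapping(s)", nrow(maps))
  }

  records <- assemble_records(
    seqs,
    domain_hits = hits, predictor_calls = calls,
    mappings = maps, config = config
  )
  report <- evaluate_records(records, registries, config)
  note(
    "evaluated %d record(s): %d flagged, %d conflict(s), %d rule-skip notice(s)",
    report$n_proteins, sum(!report$proteins$clean),
    nrow(report$conflicts), nrow(report$skipped)
  )

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_report_json(report, file.path(out_dir, "report.json"))
  write_report_tsv(report, file.path(out_dir, "report.tsv"))
  invisible(report)
}
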