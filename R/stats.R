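# Corpus-level summary statistics: how contaminated is each source
# database / species, in the shape of the published summary tables.

#' Flagged-sequence statistics by database and species
#'
#' Counts analysed and flagged sequences per group and computes the
#' percentage at printed precision ([compute_flag_percentage()]). Grouping
#' by `source_db` uses the records' alternate-id table, so a sequence
#' deposited in several databases is counted once per database (records
#' without alternate ids fall into an `"unknown"` database).
#'
#' @param report An `mp_report` from [evaluate_records()].
#' @param records The `mp_records` the report was computed from; required
#'   when grouping by `source_db`.
#' @param by Grouping columns: any of `"source_db"`, `"species"`.
#' @return A tibble with the grouping columns plus `n_total`, `n_flagged`,
#'   `percent`.
#' @examples
#' reg <- demo_registries()
#' corpus <- generate_corpus(fixture_spec(seed = 1, n_clean = 4, planted = c("1" = 2)), reg)
#' report <- evaluate_records(corpus$records, reg)
#' flag_stats(report, corpus$records, by = c("source_db", "species"))
#' @export
flag_stats <- function(report, records = NULL, by = "species") {
  stopifnot(inherits(report, "mp_report"), all(by %in% c("source_db", "species")))
  if (report$n_proteins == 0) {
    abort("no reports: nothing to summarise")
  }
  tab <- report$proteins
  if ("source_db" %in% by) {
    if (is.null(records)) {
      abort("grouping by source_db needs the records (for their alternate ids)")
    }
    dbs <- purrr::map2_dfr(
      records$protein_id, records$alt_ids,
      function(id, a) {
        tibble(
          protein_id = id,
          source_db = if (nrow(a) == 0) "unknown" else unique(a$db)
        )
      }
    )
    tab <- left_join(tab, dbs, by = "protein_id")
  }
  tab |>
    group_by(across(all_of(by))) |>
    summarise(
      n_total = dplyr::n(),
      n_flagged = sum(!.data$clean),
      .groups = "drop"
    ) |>
    mutate(percent = compute_flag_percentage(.data$n_total, .data$n_flagged)) |>
    arrange(across(all_of(by)))
}
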