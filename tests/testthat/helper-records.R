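# Builders shared across test files. All fixtures are constructed in code;
# nothing is read from disk except files the tests themselves write.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic filler sequence with Met start
test_sequence <- function(len) {
  paste0("M", paste(rep_len(aa20, len - 1), collapse = ""))
}

call_row <- function(predictor, kind, start = NA_integer_, end = NA_integer_,
                     called = FALSE, score = NA_real_) {
  tibble::tibble(
    predictor = predictor, feature_kind = kind,
    start = as.integer(start), end = as.integer(end),
    score = score, called = called
  )
}

# votes for an abstract feature state; the explicit signal-anchor vote uses
# the pre-annotated route
state_calls <- function(sp = FALSE, anchor = FALSE, tm = FALSE, gpi = FALSE,
                        helix_start = 300L) {
  dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", if (sp) 1L else NA, if (sp) 22L else NA, sp, 0.8),
    call_row("PrediSi", "signal_peptide", if (sp) 1L else NA, if (sp) 22L else NA, sp, 0.7),
    call_row("curated", "signal_anchor", if (anchor) 2L else NA, if (anchor) 24L else NA, anchor),
    call_row("TMHMM", "tm_helix", if (tm) helix_start else NA, if (tm) helix_start + 22L else NA, tm),
    call_row("Phobius", "tm_helix", if (tm) helix_start else NA, if (tm) helix_start + 22L else NA, tm),
    call_row("DGPI", "gpi_anchor", if (gpi) 590L else NA, if (gpi) 590L else NA, gpi)
  )
}

hit_row <- function(acc, name, start, end, score = 100, e_value = 1e-20,
                    copy_index = 1L) {
  tibble::tibble(
    family_acc = acc, family_name = name, copy_index = as.integer(copy_index),
    ali_start = as.integer(start), ali_end = as.integer(end),
    hmm_start = 1L, hmm_end = as.integer(end - start + 1L),
    model_tag = "ls", score = as.numeric(score), e_value = e_value
  )
}

# one record per abstract boolean feature state, on a 600-residue protein:
# extracellular = Kringle at 100-181 (within its size range), cytoplasmic =
# SH2 at 200-290, nuclear = homeodomain at 350-409, helix mid-protein
state_record <- function(id, ext, cyto, nuc, sp, anchor, tm, gpi) {
  hits <- dplyr::bind_rows(
    if (ext) hit_row("PF00051", "Kringle", 100, 181),
    if (cyto) hit_row("PF00017", "SH2", 200, 290),
    if (nuc) hit_row("PF00046", "Homeodomain", 350, 409)
  )
  if (is.null(hits) || nrow(hits) == 0) hits <- mispredqc:::empty_domain_hits()
  protein_records(
    protein_id = id, sequence = test_sequence(600),
    domain_hits = list(hits),
    predictor_calls = list(state_calls(sp, anchor, tm, gpi))
  )
}

# worked example: a secreted protein with a cleaved signal peptide, one
# full-length Kringle domain and one truncated WSC domain
worked_example_record <- function() {
  protein_records(
    protein_id = "NP_TEST001.1",
    sequence = test_sequence(200),
    species = "Xenopus tropicalis",
    alt_ids = list(tibble::tibble(
      db = c("RefSeq", "TrEMBL"),
      accession = c("NP_TEST001.1", "Q0TEST_XENTR")
    )),
    domain_hits = list(dplyr::bind_rows(
      hit_row("PF00051.10", "Kringle", 25, 106, score = 84.6, e_value = 2.1e-24),
      hit_row("PF01822.14", "WSC", 120, 160, score = 30.2, e_value = 3.1e-9)
    )),
    predictor_calls = list(dplyr::bind_rows(
      call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.85),
      call_row("PrediSi", "signal_peptide", 1L, 22L, TRUE, 0.79),
      call_row("TMHMM", "tm_helix", called = FALSE),
      call_row("Phobius", "tm_helix", called = FALSE),
      call_row("Phobius", "signal_peptide", 1L, 22L, TRUE),
      call_row("DGPI", "gpi_anchor", called = FALSE)
    ))
  )
}

# independent truth table for the boolean-logic rules (1-3, 6-10), coded
# directly from the rule statements - kept deliberately separate from the
# engine implementation
oracle_conflicts <- function(ext, cyto, nuc, sp, anchor, tm, gpi) {
  out <- integer()
  if (ext && !sp && !anchor && !tm) out <- c(out, 1L)
  if (ext && cyto && !tm) out <- c(out, 2L)
  if (ext && nuc) out <- c(out, 3L)
  if (sp && cyto && !tm) out <- c(out, 6L)
  if (gpi && !sp) out <- c(out, 7L)
  if (gpi && cyto) out <- c(out, 8L)
  if (gpi && nuc) out <- c(out, 9L)
  if (gpi && tm) out <- c(out, 10L)
  out
}

conflict_set <- function(report, id) {
  sort(report$conflicts$rule_id[report$conflicts$protein_id == id])
}

write_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
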