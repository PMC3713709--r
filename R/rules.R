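# The eleven consistency rules. Each rule sees one protein's domain
# compartments, consensus topology and genome mappings and either fires
# (returning a conflict with evidence), stays silent, or reports that the
# evidence needed to decide is missing ("skipped").

RULE_NAMES <- c(
  "1" = "extracellular domain(s) without export signal",
  "2" = "extracellular and cytoplasmic domains without transmembrane helix",
  "3" = "co-occurrence of extracellular and nuclear domains",
  "4" = "domain size deviation",
  "5" = "interchromosomal chimeric protein",
  "6" = "signal peptide and cytoplasmic domains without transmembrane helix",
  "7" = "GPI anchor without secretory signal peptide",
  "8" = "co-occurrence of GPI anchor and cytoplasmic domains",
  "9" = "co-occurrence of GPI anchor and nuclear domains",
  "10" = "co-occurrence of GPI anchor and transmembrane helices",
  "11" = "domain architecture deviation"
)

#' Rule names used in conflict reports
#'
#' @return A named character vector mapping rule id (1-11) to the rule's
#'   report name.
#' @export
rule_names <- function() RULE_NAMES

# Per-record derived state, shared by all rules.
# Topology statuses are three-valued: TRUE / FALSE / NA (no predictor voted
# on that feature kind, so presence cannot be decided).
record_state <- function(protein_id, sequence, domain_hits, predictor_calls,
                         topology, segment_mappings, config, loc_registry) {
  len <- nchar(sequence)
  ev <- topology$evidence
  status <- function(kind, feature) {
    if (!isTRUE(ev[[kind]])) NA else !is.null(feature)
  }
  hits <- domain_hits
  bare <- strip_acc_version(hits$family_acc)
  list(
    protein_id = protein_id,
    len = len,
    hits = hits,
    bare_accs = bare,
    ext = hits[bare %in% loc_registry$extracellular, , drop = FALSE],
    cyto = hits[bare %in% loc_registry$cytoplasmic, , drop = FALSE],
    nuc = hits[bare %in% loc_registry$nuclear, , drop = FALSE],
    sp = status("signal_peptide", topology$signal_peptide),
    anchor = status("signal_anchor", topology$signal_anchor),
    tm_raw = if (isTRUE(ev[["tm_helix"]])) nrow(topology$tm_helices) else NA_integer_,
    tm_eff = if (isTRUE(ev[["tm_helix"]])) {
      nrow(effective_tm_helices(topology, len, config))
    } else {
      NA_integer_
    },
    gpi = status("gpi_anchor", topology$gpi_anchor),
    topology = topology,
    mappings = segment_mappings
  )
}

hit_evidence <- function(hits) {
  sprintf(
    "%s (%s) hit %d-%d", hits$family_acc, hits$family_name,
    hits$ali_start, hits$ali_end
  )
}

conflict <- function(rule_id, evidence) {
  list(
    rule_id = rule_id,
    rule_name = RULE_NAMES[[as.character(rule_id)]],
    evidence = evidence
  )
}

skipped <- function(rule_id, reason) list(rule_id = rule_id, reason = reason)

# Individual rules. Each returns NULL (clean), a conflict, or a skip marker.

rule_extracellular_without_export <- function(st) {
  if (nrow(st$ext) == 0) {
    return(NULL)
  }
  # any export signal rescues: cleaved signal peptide, signal anchor, or any
  # predicted helix (raw count: helices later excluded as predictor
  # artifacts still witness an export signal)
  signals <- c(st$sp, st$anchor, if (is.na(st$tm_raw)) NA else st$tm_raw > 0)
  if (any(signals, na.rm = TRUE)) {
    return(NULL)
  }
  if (anyNA(signals)) {
    return(skipped(1L, "insufficient evidence: topology predictors missing"))
  }
  conflict(1L, c(hit_evidence(st$ext), "no signal peptide, signal anchor or TM helix"))
}

rule_extra_cyto_without_tm <- function(st) {
  if (nrow(st$ext) == 0 || nrow(st$cyto) == 0) {
    return(NULL)
  }
  if (is.na(st$tm_eff)) {
    return(skipped(2L, "insufficient evidence: no TM-helix votes"))
  }
  if (st$tm_eff > 0) {
    return(NULL)
  }
  conflict(2L, c(
    hit_evidence(st$ext), hit_evidence(st$cyto),
    "no membrane-spanning helix"
  ))
}

rule_extra_nuclear_cooccur <- function(st) {
  # unconditional co-occurrence rule: no topology rescue
  if (nrow(st$ext) == 0 || nrow(st$nuc) == 0) {
    return(NULL)
  }
  conflict(3L, c(hit_evidence(st$ext), hit_evidence(st$nuc)))
}

rule_domain_size_deviation <- function(st, size_registry, config) {
  if (nrow(st$hits) == 0) {
    return(NULL)
  }
  idx <- match(st$bare_accs, size_registry$accession)
  flagged <- character()
  for (i in which(!is.na(idx))) {
    ref <- size_registry$reference_length[idx[i]]
    sd <- size_registry$length_sd[idx[i]]
    observed <- st$hits$ali_end[i] - st$hits$ali_start[i] + 1L
    bad <- if (!is.na(sd)) {
      abs(observed - ref) > config$size_rule_k * sd
    } else {
      ratio <- observed / ref
      ratio < config$size_rule_min_hmm_coverage ||
        ratio > 2 - config$size_rule_min_hmm_coverage
    }
    if (bad) {
      flagged <- c(flagged, sprintf(
        "%s copy %d: observed length %d vs reference %g%s",
        st$hits$family_acc[i], st$hits$copy_index[i], observed, ref,
        if (!is.na(sd)) sprintf(" (sd %g, k %g)", sd, config$size_rule_k) else ""
      ))
    }
  }
  if (length(flagged) == 0) {
    return(NULL)
  }
  conflict(4L, flagged)
}

rule_interchromosomal_chimera <- function(st) {
  if (nrow(st$mappings) == 0) {
    return(skipped(5L, "insufficient evidence: no genome mappings"))
  }
  chroms <- unique(st$mappings$chromosome)
  if (length(chroms) < 2) {
    return(NULL)
  }
  conflict(5L, sprintf(
    "coding segments map to %d chromosomes: %s",
    length(chroms), paste(sort(chroms), collapse = ", ")
  ))
}

rule_sp_cyto_without_tm <- function(st) {
  if (nrow(st$cyto) == 0) {
    return(NULL)
  }
  if (is.na(st$sp)) {
    return(skipped(6L, "insufficient evidence: no signal-peptide votes"))
  }
  if (!st$sp) {
    return(NULL)
  }
  if (is.na(st$tm_eff)) {
    return(skipped(6L, "insufficient evidence: no TM-helix votes"))
  }
  if (st$tm_eff > 0) {
    return(NULL)
  }
  conflict(6L, c(
    sprintf(
      "signal peptide 1-%d (%s)", st$topology$signal_peptide$end,
      paste(st$topology$signal_peptide$predictors, collapse = ", ")
    ),
    hit_evidence(st$cyto), "no membrane-spanning helix"
  ))
}

rule_gpi_without_sp <- function(st) {
  if (is.na(st$gpi)) {
    return(skipped(7L, "insufficient evidence: no GPI votes"))
  }
  if (!st$gpi) {
    return(NULL)
  }
  if (is.na(st$sp)) {
    return(skipped(7L, "insufficient evidence: no signal-peptide votes"))
  }
  if (st$sp) {
    return(NULL)
  }
  conflict(7L, sprintf(
    "GPI anchor at omega site %d but no secretory signal peptide",
    st$topology$gpi_anchor$omega_site
  ))
}

rule_gpi_with_compartment <- function(st, rule_id, hits) {
  if (nrow(hits) == 0) {
    return(NULL)
  }
  if (is.na(st$gpi)) {
    return(skipped(rule_id, "insufficient evidence: no GPI votes"))
  }
  if (!st$gpi) {
    return(NULL)
  }
  conflict(rule_id, c(
    sprintf("GPI anchor at omega site %d", st$topology$gpi_anchor$omega_site),
    hit_evidence(hits)
  ))
}

rule_gpi_with_tm <- function(st) {
  if (is.na(st$gpi)) {
    return(skipped(10L, "insufficient evidence: no GPI votes"))
  }
  if (!st$gpi) {
    return(NULL)
  }
  if (is.na(st$tm_eff)) {
    return(skipped(10L, "insufficient evidence: no TM-helix votes"))
  }
  if (st$tm_eff == 0) {
    return(NULL)
  }
  conflict(10L, c(
    sprintf("GPI anchor at omega site %d", st$topology$gpi_anchor$omega_site),
    sprintf("%d membrane-spanning helix(ces) retained", st$tm_eff)
  ))
}

rule_architecture_deviation <- function(st, arch_registry, config) {
  if (nrow(st$hits) == 0) {
    return(skipped(11L, "no domains: architecture undefined"))
  }
  ord <- order(st$hits$ali_start)
  key <- architecture_key(
    st$hits$family_acc[ord],
    repeat_collapse = config$repeat_collapse
  )
  if (key %in% arch_registry) {
    return(NULL)
  }
  conflict(11L, sprintf("domain architecture (%s) not among known architectures", key))
}

#' Evaluate the consistency rules over a record set
#'
#' Runs every enabled rule on every record and collects all conflicts
#' raised (not just the first). Rules whose verdict cannot be decided for
#' a record — no predictor voted on a feature kind the rule needs, no
#' genome mappings for the chimera rule, no domains for the architecture
#' rule — are recorded as skipped with a reason rather than silently
#' passed.
#'
#' @param records An `mp_records` tibble.
#' @param registries A list from [load_registries()] / [demo_registries()].
#' @param config An [engine_config()].
#' @return An object of class `mp_report`: a list with tibbles `conflicts`
#'   (`protein_id`, `rule_id`, `rule_name`, `message`, `evidence`
#'   list-column), `skipped` (`protein_id`, `rule_id`, `reason`) and
#'   `proteins` (`protein_id`, `species`, `n_conflicts`, `clean`), plus the
#'   `config` used. Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' reg <- demo_registries()
#' corpus <- generate_corpus(fixture_spec(seed = 1, n_clean = 2, planted = c("4" = 1)), reg)
#' evaluate_records(corpus$records, reg)
#' @export
evaluate_records <- function(records, registries, config = engine_config()) {
  stopifnot(inherits(records, "mp_records"))
  conflicts <- list()
  skips <- list()
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    # recompute consensus under this evaluation's config when votes exist;
    # records built with an injected topology keep it
    topo <- if (nrow(row$predictor_calls[[1]]) > 0) {
      consensus_topology(row$predictor_calls[[1]], nchar(row$sequence), config)
    } else {
      row$topology[[1]]
    }
    st <- record_state(
      row$protein_id, row$sequence, row$domain_hits[[1]],
      row$predictor_calls[[1]], topo, row$segment_mappings[[1]],
      config, registries$localization
    )
    results <- list()
    run <- function(id, res) {
      if (id %in% config$enabled_rules) list(res) else list()
    }
    results <- c(
      run(1L, rule_extracellular_without_export(st)),
      run(2L, rule_extra_cyto_without_tm(st)),
      run(3L, rule_extra_nuclear_cooccur(st)),
      run(4L, rule_domain_size_deviation(st, registries$sizes, config)),
      run(5L, rule_interchromosomal_chimera(st)),
      run(6L, rule_sp_cyto_without_tm(st)),
      run(7L, rule_gpi_without_sp(st)),
      run(8L, rule_gpi_with_compartment(st, 8L, st$cyto)),
      run(9L, rule_gpi_with_compartment(st, 9L, st$nuc)),
      run(10L, rule_gpi_with_tm(st)),
      run(11L, rule_architecture_deviation(st, registries$architectures, config))
    )
    for (res in results) {
      if (is.null(res)) next
      if (!is.null(res$reason)) {
        skips <- c(skips, list(tibble(
          protein_id = st$protein_id, rule_id = res$rule_id, reason = res$reason
        )))
      } else {
        conflicts <- c(conflicts, list(tibble(
          protein_id = st$protein_id,
          rule_id = res$rule_id,
          rule_name = res$rule_name,
          message = sprintf("conflict %d: %s", res$rule_id, res$rule_name),
          evidence = list(res$evidence)
        )))
      }
    }
  }
  conflicts <- if (length(conflicts) > 0) {
    bind_rows(conflicts)
  } else {
    tibble(
      protein_id = character(), rule_id = integer(), rule_name = character(),
      message = character(), evidence = list()
    )
  }
  skips <- if (length(skips) > 0) {
    bind_rows(skips)
  } else {
    tibble(protein_id = character(), rule_id = integer(), reason = character())
  }
  proteins <- tibble(
    protein_id = records$protein_id,
    species = records$species,
    n_conflicts = vapply(
      records$protein_id,
      function(id) sum(conflicts$protein_id == id), integer(1),
      USE.NAMES = FALSE
    )
  ) |>
    mutate(clean = .data$n_conflicts == 0L)
  structure(
    list(
      conflicts = conflicts, skipped = skips, proteins = proteins,
      config = config, n_proteins = nrow(records)
    ),
    class = "mp_report"
  )
}

#' @export
print.mp_report <- function(x, ...) {
  cat(sprintf(
    "<conflict report: %d protein(s), %d flagged, %d conflict(s)>\n",
    x$n_proteins, sum(!x$proteins$clean), nrow(x$conflicts)
  ))
  if (nrow(x$conflicts) > 0) {
    counts <- dplyr::count(x$conflicts, .data$rule_id, .data$rule_name)
    for (i in seq_len(nrow(counts))) {
      cat(sprintf(
        "  rule %2d  %-62s %d\n",
        counts$rule_id[i], counts$rule_name[i], counts$n[i]
      ))
    }
  }
  invisible(x)
}

#' Percentage of flagged sequences, at printed precision
#'
#' `100 * n_flagged / n_total`, rounded half-up to two decimals — the
#' convention used for published database-contamination percentages.
#'
#' @param n_total Total number of sequences analysed (> 0).
#' @param n_flagged Number of sequences flagged (0 <= n_flagged <= n_total).
#' @return Numeric percentage rounded to two decimals. Vectorized.
#' @examples
#' compute_flag_percentage(59000, 2245) # 3.81
#' @export
compute_flag_percentage <- function(n_total, n_flagged) {
  if (any(n_total <= 0)) {
    abort("n_total must be > 0: percentage undefined")
  }
  if (any(n_flagged < 0 | n_flagged > n_total)) {
    abort("n_flagged must lie in [0, n_total]")
  }
  round_half_up(100 * n_flagged / n_total, 2)
}
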