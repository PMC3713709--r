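# Consensus membrane topology: combine per-predictor votes into one set of
# features, and decide which predicted helices count as genuine
# membrane-spanning segments for the rules that care.

#' Combine predictor votes into a consensus topology
#'
#' Votes come from the signal-peptide predictors (SignalP, PrediSi), the
#' helix/topology predictors (TMHMM, Phobius), a GPI predictor (DGPI-style),
#' or a pre-annotated source supplying any feature kind directly. Under the
#' default `"any"` policy a feature is present when any predictor calls it
#' and absent only when every predictor that voted on that kind agrees it is
#' absent; `"majority"` requires more than half of the voting predictors.
#' The span of a present signal peptide or anchor is the union span of the
#' supporting calls; helices are the interval-union of supporting calls.
#'
#' Because none of the helix predictors report signal anchors explicitly, an
#' N-terminal consensus helix (starting within `config$sp_tm_overlap_window`
#' residues) in the absence of a cleaved signal peptide is classified as the
#' signal anchor and removed from the helix list.
#'
#' @param calls A predictor-call tibble for one protein with columns
#'   `predictor`, `feature_kind`, `start`, `end`, `score`, `called`.
#' @param seq_length Protein length in residues.
#' @param config An [engine_config()].
#' @return A list with elements `signal_peptide`, `signal_anchor`
#'   (`NULL` or `list(start, end, cleavage_site?, predictors)`),
#'   `tm_helices` (tibble of non-overlapping sorted spans), `gpi_anchor`
#'   (`NULL` or `list(omega_site, predictors)`), and `evidence`, a named
#'   logical recording which feature kinds received at least one vote.
#' @export
consensus_topology <- function(calls, seq_length, config = engine_config()) {
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- empty_predictor_calls()
  }
  stopifnot(all(calls$feature_kind %in% FEATURE_KINDS))

  evidence <- vapply(
    FEATURE_KINDS, function(k) any(calls$feature_kind == k), logical(1)
  )
  # signal-anchor knowledge is also implied by helix votes (an anchor would
  # have been reported as an N-terminal helix)
  evidence[["signal_anchor"]] <-
    evidence[["signal_anchor"]] || evidence[["tm_helix"]]

  present <- function(kind) {
    sub <- calls[calls$feature_kind == kind, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(list(ok = FALSE, sub = sub))
    }
    by_pred <- tapply(sub$called, sub$predictor, any)
    ok <- if (config$consensus_mode == "any") {
      any(by_pred)
    } else {
      sum(by_pred) > length(by_pred) / 2
    }
    list(ok = ok, sub = sub[sub$called, , drop = FALSE])
  }

  sp_vote <- present("signal_peptide")
  signal_peptide <- NULL
  if (sp_vote$ok) {
    end <- max(sp_vote$sub$end)
    signal_peptide <- list(
      start = 1L, end = as.integer(end), cleavage_site = as.integer(end),
      predictors = sort(unique(sp_vote$sub$predictor))
    )
  }

  an_vote <- present("signal_anchor")
  signal_anchor <- NULL
  if (an_vote$ok) {
    signal_anchor <- list(
      start = as.integer(min(an_vote$sub$start)),
      end = as.integer(max(an_vote$sub$end)),
      predictors = sort(unique(an_vote$sub$predictor))
    )
  }

  tm_vote <- present("tm_helix")
  tm_helices <- if (tm_vote$ok) {
    merge_intervals(tm_vote$sub$start, tm_vote$sub$end)
  } else {
    tibble(start = integer(), end = integer())
  }

  # reclassify an N-terminal helix as the signal anchor when no cleaved
  # signal peptide (or explicit anchor) was called
  if (is.null(signal_peptide) && is.null(signal_anchor) &&
    nrow(tm_helices) > 0 &&
    tm_helices$start[1] <= config$sp_tm_overlap_window) {
    signal_anchor <- list(
      start = tm_helices$start[1], end = tm_helices$end[1],
      predictors = sort(unique(tm_vote$sub$predictor))
    )
    tm_helices <- tm_helices[-1, , drop = FALSE]
  }

  gpi_vote <- present("gpi_anchor")
  gpi_anchor <- NULL
  if (gpi_vote$ok) {
    omega <- max(gpi_vote$sub$end, na.rm = TRUE)
    gpi_anchor <- list(
      omega_site = as.integer(omega),
      predictors = sort(unique(gpi_vote$sub$predictor))
    )
  }

  list(
    signal_peptide = signal_peptide,
    signal_anchor = signal_anchor,
    tm_helices = tm_helices,
    gpi_anchor = gpi_anchor,
    evidence = evidence
  )
}

#' Helices that count as genuine membrane-spanning segments
#'
#' Filters the consensus helix list for the rules that require a true
#' membrane pass (extracellular/cytoplasmic co-occurrence, signal peptide
#' with cytoplasmic domains, GPI-anchored proteins): a helix overlapping the
#' consensus signal peptide or anchor within the first
#' `sp_tm_overlap_window` residues is the export signal, not a membrane
#' pass; on a GPI-anchored protein a helix lying entirely within the
#' C-terminal `gpi_cterm_window` residues is the GPI attachment signal.
#'
#' @param topology A consensus topology from [consensus_topology()].
#' @param seq_length Protein length in residues.
#' @param config An [engine_config()].
#' @return A tibble of helix spans (`start`, `end`).
#' @export
effective_tm_helices <- function(topology, seq_length, config = engine_config()) {
  tm <- topology$tm_helices
  if (nrow(tm) == 0) {
    return(tm)
  }
  keep <- rep(TRUE, nrow(tm))
  for (sig in list(topology$signal_peptide, topology$signal_anchor)) {
    if (is.null(sig)) next
    ov <- vapply(
      seq_len(nrow(tm)),
      function(i) interval_overlap(tm$start[i], tm$end[i], sig$start, sig$end) > 0,
      logical(1)
    )
    keep <- keep & !(ov & tm$start <= config$sp_tm_overlap_window)
  }
  if (!is.null(topology$gpi_anchor)) {
    cterm_start <- seq_length - config$gpi_cterm_window + 1L
    keep <- keep & !(tm$start >= cterm_start)
  }
  tm[keep, , drop = FALSE]
}
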