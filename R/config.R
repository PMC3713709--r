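#' Rule-engine configuration
#'
#' Collects every tunable threshold of the consistency-rule engine in one
#' validated list. Defaults are the package's documented operating point;
#' all of them can be overridden per call.
#'
#' @param consensus_mode How predictor votes are combined into a consensus
#'   feature call. `"any"` (default): a feature is present if any predictor
#'   calls it and absent only when every predictor that voted agrees it is
#'   absent. `"majority"`: present when more than half of the voting
#'   predictors call it.
#' @param size_rule_k Multiplier on the registry standard deviation for the
#'   domain-size rule: a hit is flagged when
#'   `|observed - reference| > size_rule_k * length_sd`. Default 2.5.
#' @param size_rule_min_hmm_coverage Fallback fractional bound for families
#'   whose registry entry carries no standard deviation: a hit is flagged
#'   when `observed/reference` falls below this fraction or above
#'   `2 - fraction`. Default 0.70.
#' @param sp_tm_overlap_window N-terminal window (residues) within which a
#'   predicted transmembrane helix is interpreted as the export signal
#'   (signal anchor, or the hydrophobic core of a signal peptide it
#'   overlaps) rather than a genuine membrane-spanning helix. Default 45.
#' @param gpi_cterm_window C-terminal window (residues) within which a
#'   predicted helix on a GPI-anchored protein is treated as the GPI
#'   attachment signal and excluded from transmembrane counts. Default 40.
#' @param repeat_collapse Collapse consecutive repeats of the same family
#'   when forming domain-architecture keys (so `A,A,B` and `A,B` compare
#'   equal). Default `TRUE`.
#' @param enabled_rules Integer subset of 1:11 selecting which rules run.
#' @param e_value_max Domain-hit acceptance threshold applied when parsing
#'   HMMER domtblout files. Default 1e-3: permissive enough to retain
#'   truncated domains (which the size rule must see), strict enough to
#'   suppress noise.
#' @param psl_min_identity,psl_min_coverage Acceptance thresholds for
#'   genome alignments of coding segments. Defaults 0.95 and 0.80.
#'
#' @return A list of class `mp_config`.
#' @examples
#' engine_config(size_rule_k = 3)
#' @export
engine_config <- function(consensus_mode = c("any", "majority"),
                          size_rule_k = 2.5,
                          size_rule_min_hmm_coverage = 0.70,
                          sp_tm_overlap_window = 45L,
                          gpi_cterm_window = 40L,
                          repeat_collapse = TRUE,
                          enabled_rules = 1:11,
                          e_value_max = 1e-3,
                          psl_min_identity = 0.95,
                          psl_min_coverage = 0.80) {
  consensus_mode <- match.arg(consensus_mode)
  stopifnot(
    is.numeric(size_rule_k), size_rule_k >= 0,
    is.numeric(size_rule_min_hmm_coverage),
    size_rule_min_hmm_coverage > 0, size_rule_min_hmm_coverage <= 1,
    sp_tm_overlap_window > 0, gpi_cterm_window > 0,
    is.logical(repeat_collapse),
    all(enabled_rules %in% 1:11),
    e_value_max >= 0,
    psl_min_identity >= 0, psl_min_identity <= 1,
    psl_min_coverage >= 0, psl_min_coverage <= 1
  )
  structure(
    list(
      consensus_mode = consensus_mode,
      size_rule_k = size_rule_k,
      size_rule_min_hmm_coverage = size_rule_min_hmm_coverage,
      sp_tm_overlap_window = as.integer(sp_tm_overlap_window),
      gpi_cterm_window = as.integer(gpi_cterm_window),
      repeat_collapse = repeat_collapse,
      enabled_rules = sort(unique(as.integer(enabled_rules))),
      e_value_max = e_value_max,
      psl_min_identity = psl_min_identity,
      psl_min_coverage = psl_min_coverage
    ),
    class = "mp_config"
  )
}

#' Read an engine configuration from a key = value file
#'
#' Lines are `key = value` (or `key: value`); `#` comments and blank lines
#' are ignored. Keys are the arguments of [engine_config()];
#' `enabled_rules` is a comma-separated list.
#'
#' @param path Path to the configuration file.
#' @return A list of class `mp_config`.
#' @export
read_engine_config <- function(path) {
  lines <- read_data_lines(path)
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(sprintf("malformed config line: '%s'", lines[which(bad)[1]]))
  }
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  args <- list()
  for (key in names(vals)) {
    v <- vals[[key]]
    args[[key]] <- switch(key,
      consensus_mode = v,
      repeat_collapse = toupper(v) %in% c("TRUE", "YES", "1"),
      enabled_rules = as.integer(strsplit(v, ",")[[1]]),
      {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) abort(sprintf("non-numeric value for '%s': %s", key, v))
        num
      }
    )
  }
  do.call(engine_config, args)
}

#' @export
print.mp_config <- function(x, ...) {
  cat("<engine configuration>\n")
  for (k in names(x)) {
    cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ",")))
  }
  invisible(x)
}
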