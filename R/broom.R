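# tidy()/glance() and ggplot2 autoplot() methods for report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a conflict report
#'
#' @param x An `mp_report`.
#' @param ... Unused.
#' @return One row per (protein, conflict): `protein_id`, `rule_id`,
#'   `rule_name`, `message` and an `evidence` list-column.
#' @method tidy mp_report
#' @export
tidy.mp_report <- function(x, ...) {
  x$conflicts
}

#' One-row summary of a conflict report
#'
#' @param x An `mp_report`.
#' @param ... Unused.
#' @return A tibble with `n_proteins`, `n_flagged`, `percent_flagged`,
#'   `n_conflicts`, `n_rules_skipped`.
#' @method glance mp_report
#' @export
glance.mp_report <- function(x, ...) {
  tibble(
    n_proteins = x$n_proteins,
    n_flagged = sum(!x$proteins$clean),
    percent_flagged = compute_flag_percentage(
      max(x$n_proteins, 1L), sum(!x$proteins$clean)
    ),
    n_conflicts = nrow(x$conflicts),
    n_rules_skipped = nrow(x$skipped)
  )
}

#' Bar chart of conflicts per rule
#'
#' @param object An `mp_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mp_report
#' @export
autoplot.mp_report <- function(object, ...) {
  counts <- tibble(rule_id = factor(1:11, levels = 1:11)) |>
    left_join(
      dplyr::count(object$conflicts, rule_id = factor(.data$rule_id, levels = 1:11)),
      by = "rule_id"
    ) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$rule_id, y = .data$n)) +
    ggplot2::geom_col(fill = "#31688e") +
    ggplot2::labs(
      x = "consistency rule",
      y = "proteins in conflict",
      title = sprintf(
        "%d of %d proteins flagged",
        sum(!object$proteins$clean), object$n_proteins
      )
    ) +
    ggplot2::theme_minimal()
}

#' Feature map of one protein record
#'
#' Draws the sequence as a baseline with domain hits, consensus signal
#' peptide / anchor, TM helices and the GPI omega site, the way one would
#' sketch a domain architecture.
#'
#' @param records An `mp_records` tibble.
#' @param protein_id Which record to draw.
#' @return A ggplot object.
#' @export
plot_feature_map <- function(records, protein_id) {
  i <- match(protein_id, records$protein_id)
  if (is.na(i)) abort(sprintf("no record with protein_id '%s'", protein_id))
  len <- nchar(records$sequence[i])
  topo <- records$topology[[i]]
  segs <- list(tibble(
    start = 1, end = len, y = 0, kind = "sequence"
  ))
  h <- records$domain_hits[[i]]
  if (nrow(h) > 0) {
    segs <- c(segs, list(tibble(
      start = h$ali_start, end = h$ali_end, y = 1,
      kind = paste0(h$family_acc, " (", h$family_name, ")")
    )))
  }
  if (!is.null(topo$signal_peptide)) {
    segs <- c(segs, list(tibble(
      start = topo$signal_peptide$start, end = topo$signal_peptide$end,
      y = 2, kind = "signal peptide"
    )))
  }
  if (!is.null(topo$signal_anchor)) {
    segs <- c(segs, list(tibble(
      start = topo$signal_anchor$start, end = topo$signal_anchor$end,
      y = 2, kind = "signal anchor"
    )))
  }
  if (nrow(topo$tm_helices) > 0) {
    segs <- c(segs, list(tibble(
      start = topo$tm_helices$start, end = topo$tm_helices$end,
      y = 2, kind = "TM helix"
    )))
  }
  if (!is.null(topo$gpi_anchor)) {
    segs <- c(segs, list(tibble(
      start = topo$gpi_anchor$omega_site, end = topo$gpi_anchor$omega_site + 1,
      y = 2, kind = "GPI omega site"
    )))
  }
  dat <- bind_rows(segs)
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end, y = .data$y, yend = .data$y,
        colour = .data$kind
      ),
      linewidth = 4
    ) +
    ggplot2::scale_y_continuous(
      breaks = 0:2, labels = c("sequence", "domains", "topology"),
      limits = c(-0.5, 2.5)
    ) +
    ggplot2::labs(x = "residue", y = NULL, colour = NULL, title = protein_id) +
    ggplot2::theme_minimal()
}
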