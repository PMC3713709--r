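# Deterministic synthetic corpora with planted conflicts, plus writers that
# serialize them back out as mock predictor-output files. Sequences are
# uniform-random residues with a Met start: the rules never read residue
# identities beyond the alphabet check, so realism stops at feature
# placement.

FAMILY_NAMES <- c(
  PF00051 = "Kringle", PF01822 = "WSC", PF00008 = "EGF", PF00041 = "fn3",
  PF00084 = "Sushi", PF00057 = "Ldl_recept_a", PF00059 = "Lectin_C",
  PF01392 = "Fz", PF00431 = "CUB", PF00090 = "TSP_1", PF02210 = "Laminin_G_2",
  PF07679 = "I-set", PF00017 = "SH2", PF00018 = "SH3_1", PF00168 = "C2",
  PF00169 = "PH", PF00615 = "RGS", PF00620 = "RhoGAP", PF00621 = "RhoGEF",
  PF00640 = "PID", PF00786 = "PBD", PF00788 = "RA", PF02185 = "HR1",
  PF00611 = "FCH", PF00046 = "Homeodomain", PF00010 = "HLH",
  PF00170 = "bZIP_1", PF00249 = "Myb_DNA-binding", PF00250 = "Forkhead",
  PF00319 = "SRF-TF", PF00320 = "GATA", PF00505 = "HMG_box",
  PF00157 = "Pou", PF02864 = "STAT_bind", PF00104 = "Hormone_recep",
  PF00907 = "T-box"
)

#' Specification for a synthetic corpus
#'
#' @param seed Integer RNG seed; the same spec always yields a
#'   byte-identical corpus.
#' @param n_clean Number of conflict-free records (clean templates are
#'   cycled: secreted single-domain, cytoplasmic, nuclear, featureless,
#'   GPI-anchored, and a single-pass receptor).
#' @param planted Named counts of records to plant, e.g.
#'   `c("1" = 3, "4" = 2)`. Names are single rule ids `"1"`–`"11"` (each
#'   such record violates exactly that rule) or the documented
#'   multi-conflict templates `"6+8"` and `"1+3+7+9"`. Rule 8 cannot be
#'   violated in isolation (see the package vignette), so `"8"` raises an
#'   impossible-plant error — use `"6+8"`.
#' @param sequence_length_range Minimum and maximum sequence length in
#'   residues (minimum at least 50; records needing more room for their
#'   features get it).
#' @param registry_profile Name of the bundled registry set the corpus is
#'   built against (currently `"demo"`).
#' @return A list of class `mp_fixture_spec`.
#' @export
fixture_spec <- function(seed, n_clean = 5, planted = c("4" = 1),
                         sequence_length_range = c(150, 400),
                         registry_profile = "demo") {
  planted <- unlist(planted)
  if (length(planted) > 0 && is.null(names(planted))) {
    abort("planted must be a named vector, e.g. c('4' = 2)")
  }
  allowed <- c(as.character(1:11), "6+8", "1+3+7+9")
  bad <- setdiff(names(planted), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown plant template(s): %s", paste(bad, collapse = ", ")))
  }
  if ("8" %in% names(planted) && planted[["8"]] > 0) {
    abort(paste(
      "impossible plant: rule 8 (GPI anchor + cytoplasmic domain) cannot be",
      "violated in isolation - any such protein also violates rule 6, 7 or 10.",
      "Use the multi-conflict template '6+8'."
    ))
  }
  stopifnot(
    length(seed) == 1, seed == as.integer(seed),
    n_clean >= 0, all(planted >= 0),
    length(sequence_length_range) == 2,
    sequence_length_range[1] >= 50,
    sequence_length_range[1] <= sequence_length_range[2]
  )
  structure(
    list(
      seed = as.integer(seed), n_clean = as.integer(n_clean),
      planted = planted,
      sequence_length_range = as.integer(sequence_length_range),
      registry_profile = registry_profile
    ),
    class = "mp_fixture_spec"
  )
}

# feature plans ---------------------------------------------------------------
# A plan lists what the record should carry; build_fixture_record() turns it
# into coordinates. dom entries are (accession, observed length).

fixture_plans <- function() {
  dom <- function(...) {
    v <- c(...)
    if (length(v) == 0) {
      return(tibble(acc = character(), len = integer()))
    }
    m <- matrix(v, ncol = 2, byrow = TRUE)
    tibble(acc = m[, 1], len = as.integer(m[, 2]))
  }
  none <- dom()
  clean <- list(
    list(label = "clean secreted", sp = TRUE, doms = dom("PF00051", 80)),
    list(label = "clean cytoplasmic", sp = FALSE, doms = dom("PF00017", 95)),
    list(label = "clean nuclear", sp = FALSE, doms = dom("PF00046", 60)),
    list(label = "clean featureless", sp = FALSE, doms = none),
    list(
      label = "clean GPI-anchored", sp = TRUE, gpi = TRUE,
      doms = dom("PF00059", 110)
    ),
    list(
      label = "clean receptor", sp = TRUE, helices = "mid",
      doms = dom("PF00041", 85, "PF00017", 95)
    )
  )
  planted <- list(
    "1" = list(sp = FALSE, doms = dom("PF00051", 80)),
    "2" = list(sp = FALSE, helices = "nterm", doms = dom("PF00041", 85, "PF00017", 95)),
    "3" = list(sp = TRUE, doms = dom("PF00051", 80, "PF00046", 60)),
    "4" = list(sp = TRUE, doms = dom("PF00051", 82, "PF01822", 41)),
    "5" = list(sp = TRUE, doms = dom("PF00051", 80), chimeric = TRUE),
    "6" = list(sp = TRUE, doms = dom("PF00017", 95)),
    "7" = list(sp = FALSE, gpi = TRUE, doms = none),
    "9" = list(sp = TRUE, gpi = TRUE, doms = dom("PF00046", 60)),
    "10" = list(sp = TRUE, gpi = TRUE, helices = "mid", doms = none),
    "11" = list(sp = TRUE, doms = dom("PF01822", 92, "PF00051", 80)),
    "6+8" = list(sp = TRUE, gpi = TRUE, doms = dom("PF00017", 95)),
    "1+3+7+9" = list(sp = FALSE, gpi = TRUE, doms = dom("PF00051", 80, "PF00046", 60))
  )
  list(clean = clean, planted = planted)
}

plan_defaults <- function(plan) {
  defaults <- list(
    sp = FALSE, gpi = FALSE, helices = "none", chimeric = FALSE,
    doms = tibble(acc = character(), len = integer())
  )
  for (k in names(defaults)) {
    if (is.null(plan[[k]])) plan[[k]] <- defaults[[k]]
  }
  plan
}

# turn one plan into a full set of record components
build_fixture_record <- function(id, plan, len_range, species, db) {
  plan <- plan_defaults(plan)
  sp_end <- 22L
  cur <- if (plan$helices == "nterm") 36L else if (plan$sp) 31L else 25L
  doms <- plan$doms
  dom_rows <- vector("list", nrow(doms))
  for (i in seq_len(nrow(doms))) {
    dom_rows[[i]] <- tibble(
      family_acc = doms$acc[i],
      family_name = unname(FAMILY_NAMES[doms$acc[i]]),
      copy_index = NA_integer_,
      ali_start = cur, ali_end = cur + doms$len[i] - 1L,
      hmm_start = 1L, hmm_end = doms$len[i],
      model_tag = "ls",
      score = as.numeric(as.character(round(stats::runif(1, 40, 250), 1))),
      e_value = as.numeric(sprintf(
        "%.1fe-%d", stats::runif(1, 1, 9.9), sample(5:40, 1)
      ))
    )
    cur <- cur + doms$len[i] - 1L + 12L
  }
  hits <- bind_rows(dom_rows)
  if (nrow(hits) > 0) {
    hits <- hits |>
      group_by(strip_acc_version(.data$family_acc)) |>
      mutate(copy_index = row_number()) |>
      ungroup() |>
      select(all_of(names(empty_domain_hits())))
  } else {
    hits <- empty_domain_hits()
  }

  helices <- tibble(start = integer(), end = integer())
  if (plan$helices == "nterm") {
    helices <- tibble(start = 3L, end = 25L)
  } else if (plan$helices == "mid") {
    hstart <- cur + 20L
    helices <- tibble(start = hstart, end = hstart + 22L)
    cur <- hstart + 22L
  }

  needed <- max(cur, sp_end, if (nrow(helices) > 0) max(helices$end) else 0L) + 30L
  extra <- sample(0:40, 1)
  len <- max(len_range[1], min(len_range[2], needed + extra), needed)
  sequence <- paste0(
    "M", paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
      len - 1L,
      replace = TRUE
    ), collapse = "")
  )
  omega <- len - 8L

  calls <- fixture_predictor_calls(plan, sp_end, helices, omega)
  mappings <- fixture_mappings(len, chimeric = plan$chimeric)

  list(
    protein_id = id,
    sequence = sequence,
    species = species,
    description = if (is.null(plan$label)) "synthetic planted record" else paste("synthetic", plan$label, "record"),
    domain_hits = hits,
    predictor_calls = calls,
    segment_mappings = mappings,
    alt_ids = tibble(db = db, accession = paste0(id, ".1"))
  )
}

# votes in the exact order read_corpus_dir() reproduces them:
# SignalP, PrediSi, TMHMM, Phobius (positives in file order, then negative
# rows signal-peptide first), DGPI
fixture_predictor_calls <- function(plan, sp_end, helices, omega) {
  sp <- plan$sp
  sp_score <- function(hi) {
    as.numeric(as.character(round(stats::runif(1, if (hi) 0.6 else 0.02, if (hi) 0.95 else 0.3), 3)))
  }
  rows <- list(
    predictor_call_tbl(
      predictor = "SignalP", protein_id = "x", feature_kind = "signal_peptide",
      start = if (sp) 1L else NA_integer_, end = if (sp) sp_end else NA_integer_,
      score = sp_score(sp), called = sp
    ),
    predictor_call_tbl(
      predictor = "PrediSi", protein_id = "x", feature_kind = "signal_peptide",
      start = if (sp) 1L else NA_integer_, end = if (sp) sp_end else NA_integer_,
      score = sp_score(sp), called = sp
    )
  )
  rows <- c(rows, list(
    if (nrow(helices) > 0) {
      predictor_call_tbl(
        predictor = "TMHMM", protein_id = "x", feature_kind = "tm_helix",
        start = helices$start, end = helices$end, called = TRUE
      )
    } else {
      predictor_call_tbl(
        predictor = "TMHMM", protein_id = "x", feature_kind = "tm_helix",
        called = FALSE
      )
    }
  ))
  # Phobius block: positive rows (SIGNAL then TRANSMEM), then negatives
  phob <- list()
  if (sp) {
    phob <- c(phob, list(predictor_call_tbl(
      predictor = "Phobius", protein_id = "x", feature_kind = "signal_peptide",
      start = 1L, end = sp_end, called = TRUE
    )))
  }
  if (nrow(helices) > 0) {
    phob <- c(phob, list(predictor_call_tbl(
      predictor = "Phobius", protein_id = "x", feature_kind = "tm_helix",
      start = helices$start, end = helices$end, called = TRUE
    )))
  }
  if (!sp) {
    phob <- c(phob, list(predictor_call_tbl(
      predictor = "Phobius", protein_id = "x", feature_kind = "signal_peptide",
      called = FALSE
    )))
  }
  if (nrow(helices) == 0) {
    phob <- c(phob, list(predictor_call_tbl(
      predictor = "Phobius", protein_id = "x", feature_kind = "tm_helix",
      called = FALSE
    )))
  }
  rows <- c(rows, phob, list(
    predictor_call_tbl(
      predictor = "DGPI", protein_id = "x", feature_kind = "gpi_anchor",
      start = if (plan$gpi) omega else NA_integer_,
      end = if (plan$gpi) omega else NA_integer_,
      called = plan$gpi
    )
  ))
  select(bind_rows(rows), -"protein_id")
}

# genome mappings rebuilt from PSL-level integer counts, so that parsing the
# emitted PSL reproduces them exactly
fixture_mappings <- function(len, chimeric = FALSE) {
  chroms <- paste0("chr", 1:22)
  c1 <- sample(chroms, 1)
  c2 <- if (chimeric) sample(setdiff(chroms, c1), 1) else c1
  sizes <- c(floor(len / 2), len - floor(len / 2))
  tibble(
    segment_index = 1:2,
    chromosome = c(c1, c2),
    strand = "+",
    identity = (sizes - 1) / sizes,
    query_coverage = 1,
    alignment_score = as.numeric(sizes - 2)
  )
}

#' Generate a synthetic corpus with planted conflicts
#'
#' Builds `n_clean` conflict-free records plus, for each planted template,
#' records engineered to violate exactly that conflict set and nothing
#' else. The engine itself is run at generation time and the corpus is
#' rejected (an internal error) if any record's conflict set differs from
#' its plan, so the returned `expected` table is guaranteed to match
#' [evaluate_records()] under the same registries and configuration.
#'
#' @param spec A [fixture_spec()].
#' @param registries Registries to verify against (default the bundled
#'   demo set, which the plan templates are written for).
#' @param config An [engine_config()].
#' @return A list with `records` (an `mp_records` tibble), `expected`
#'   (tibble `protein_id`, `rule_ids` list-column, `clean`), and `spec`.
#' @export
generate_corpus <- function(spec, registries = demo_registries(),
                            config = engine_config()) {
  stopifnot(inherits(spec, "mp_fixture_spec"))
  plans <- fixture_plans()
  species_pool <- c("Homo sapiens", "Mus musculus", "Danio rerio")
  db_pool <- c("SwissProt", "TrEMBL", "RefSeq", "EnsEMBL")

  todo <- list()
  for (i in seq_len(spec$n_clean)) {
    tpl <- plans$clean[[(i - 1) %% length(plans$clean) + 1]]
    todo <- c(todo, list(list(plan = tpl, rules = integer())))
  }
  for (key in names(spec$planted)) {
    n <- spec$planted[[key]]
    if (n == 0) next
    rules <- sort(as.integer(strsplit(key, "\\+")[[1]]))
    for (j in seq_len(n)) {
      todo <- c(todo, list(list(plan = plans$planted[[key]], rules = rules)))
    }
  }
  if (length(todo) == 0) {
    abort("fixture spec requests an empty corpus")
  }

  built <- withr::with_seed(spec$seed, {
    lapply(seq_along(todo), function(i) {
      build_fixture_record(
        id = sprintf("SYN%04d", i),
        plan = todo[[i]]$plan,
        len_range = spec$sequence_length_range,
        species = species_pool[(i - 1) %% length(species_pool) + 1],
        db = db_pool[(i - 1) %% length(db_pool) + 1]
      )
    })
  })

  records <- protein_records(
    protein_id = vapply(built, `[[`, "", "protein_id"),
    sequence = vapply(built, `[[`, "", "sequence"),
    species = vapply(built, `[[`, "", "species"),
    description = vapply(built, `[[`, "", "description"),
    analysis_date = "2026-01-15",
    alt_ids = lapply(built, `[[`, "alt_ids"),
    domain_hits = lapply(built, `[[`, "domain_hits"),
    predictor_calls = lapply(built, `[[`, "predictor_calls"),
    segment_mappings = lapply(built, `[[`, "segment_mappings"),
    config = config
  )
  expected <- tibble(
    protein_id = records$protein_id,
    rule_ids = lapply(todo, `[[`, "rules")
  ) |>
    mutate(clean = lengths(.data$rule_ids) == 0L)

  report <- evaluate_records(records, registries, config)
  got <- lapply(records$protein_id, function(id) {
    sort(report$conflicts$rule_id[report$conflicts$protein_id == id])
  })
  mismatch <- which(!mapply(identical, got, lapply(expected$rule_ids, as.integer)))
  if (length(mismatch) > 0) {
    abort(sprintf(
      "internal fixture error: %s planted {%s} but engine found {%s}",
      records$protein_id[mismatch[1]],
      paste(expected$rule_ids[[mismatch[1]]], collapse = ","),
      paste(got[[mismatch[1]]], collapse = ",")
    ))
  }
  list(records = records, expected = expected, spec = spec)
}

# emitters --------------------------------------------------------------------

#' Write a record set back out as mock predictor-output files
#'
#' Produces the full input file set a real run would consume — FASTA,
#' HMMER3 domtblout, SignalP short, PrediSi table, TMHMM short, Phobius FT,
#' GPI table, BLAT PSL, plus a `meta.tsv` sidecar carrying species,
#' analysis date and alternate database ids. Reading the directory back
#' with [read_corpus_dir()] reproduces the records exactly.
#'
#' @param records An `mp_records` tibble.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
emit_mock_tool_outputs <- function(records, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", dir))
  }
  wrap60 <- function(s) {
    gsub("(.{60})", "\\1\n", s)
  }
  p <- function(f) file.path(dir, f)

  fasta <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- if (nzchar(records$description[i])) {
      paste0(">", records$protein_id[i], " ", records$description[i])
    } else {
      paste0(">", records$protein_id[i])
    }
    c(hdr, strsplit(wrap60(records$sequence[i]), "\n")[[1]])
  }))
  writeLines(fasta, p("proteins.fasta"))

  dom_lines <- c("# mock hmmscan --domtblout output", "#")
  sp_lines <- c("# SignalP-4.1 euk predictions", "# name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks-used")
  pre_lines <- "# PrediSi-style table: protein_id score cleavage_pos decision"
  tm_lines <- character()
  phob_lines <- character()
  gpi_lines <- "# GPI table: protein_id decision omega_site"
  psl_lines <- character()
  meta_lines <- "protein_id\tspecies\tanalysis_date\tdb\taccession"

  for (i in seq_len(nrow(records))) {
    id <- records$protein_id[i]
    len <- nchar(records$sequence[i])
    h <- records$domain_hits[[i]]
    for (j in seq_len(nrow(h))) {
      dom_lines <- c(dom_lines, paste(
        h$family_name[j], h$family_acc[j], h$hmm_end[j],
        id, "-", len,
        as.character(h$e_value[j]), as.character(h$score[j]), "0.0",
        h$copy_index[j], max(h$copy_index[strip_acc_version(h$family_acc) ==
          strip_acc_version(h$family_acc[j])]),
        as.character(h$e_value[j]), as.character(h$e_value[j]),
        as.character(h$score[j]), "0.0",
        h$hmm_start[j], h$hmm_end[j], h$ali_start[j], h$ali_end[j],
        h$ali_start[j], h$ali_end[j], "0.98", "-"
      ))
    }

    calls <- records$predictor_calls[[i]]
    sp_call <- calls[calls$predictor == "SignalP", ]
    if (nrow(sp_call) == 1) {
      called <- sp_call$called
      pos <- if (called) sp_call$end + 1L else 2L
      d <- as.character(sp_call$score)
      sp_lines <- c(sp_lines, paste(
        id, "0.300", pos, "0.300", pos, "0.300", pos, "0.300", d,
        if (called) "Y" else "N", "0.450", "SignalP-noTM"
      ))
    }
    pre_call <- calls[calls$predictor == "PrediSi", ]
    if (nrow(pre_call) == 1) {
      pre_lines <- c(pre_lines, paste(
        id, as.character(pre_call$score),
        if (pre_call$called) pre_call$end else 0L,
        if (pre_call$called) "Y" else "N"
      ))
    }
    tmh <- calls[calls$predictor == "TMHMM" & calls$called, ]
    topo <- if (nrow(tmh) == 0) {
      "o"
    } else {
      sides <- rep(c("o", "i"), length.out = nrow(tmh) + 1)
      paste0(paste0(sides[seq_len(nrow(tmh))], tmh$start, "-", tmh$end,
        collapse = ""
      ), sides[nrow(tmh) + 1])
    }
    tm_lines <- c(tm_lines, paste(
      id, paste0("len=", len), "ExpAA=0.00", "First60=0.00",
      paste0("PredHel=", nrow(tmh)), paste0("Topology=", topo)
    ))

    phob <- calls[calls$predictor == "Phobius" & calls$called, ]
    blk <- paste("ID", id)
    sp_rows <- phob[phob$feature_kind == "signal_peptide", ]
    tm_rows <- phob[phob$feature_kind == "tm_helix", ]
    for (j in seq_len(nrow(sp_rows))) {
      blk <- c(blk, paste("FT", "SIGNAL", sp_rows$start[j], sp_rows$end[j]))
    }
    for (j in seq_len(nrow(tm_rows))) {
      blk <- c(blk, paste("FT", "TRANSMEM", tm_rows$start[j], tm_rows$end[j]))
    }
    phob_lines <- c(phob_lines, blk, "//")

    gpi_call <- calls[calls$predictor == "DGPI", ]
    if (nrow(gpi_call) == 1) {
      gpi_lines <- c(gpi_lines, paste(
        id, if (gpi_call$called) "Y" else "N",
        if (gpi_call$called) gpi_call$end else 0L
      ))
    }

    m <- records$segment_mappings[[i]]
    for (j in seq_len(nrow(m))) {
      qsize <- round(m$alignment_score[j]) + 2L
      matches <- qsize - 1L
      psl_lines <- c(psl_lines, paste(
        matches, 1L, 0L, 0L, 0L, 0L, 0L, 0L, m$strand[j],
        paste0(id, ":seg", m$segment_index[j]), qsize, 0L, qsize,
        m$chromosome[j], 200000000L, 1000L, 1000L + 3L * qsize,
        1L, paste0(qsize, ","), "0,", "1000,"
      ))
    }

    a <- records$alt_ids[[i]]
    for (j in seq_len(nrow(a))) {
      meta_lines <- c(meta_lines, paste(
        id, records$species[i], records$analysis_date[i],
        a$db[j], a$accession[j],
        sep = "\t"
      ))
    }
  }

  files <- c(
    "proteins.fasta", "domains.domtblout", "signalp.short", "predisi.tsv",
    "tmhmm.short", "phobius.txt", "gpi.tsv", "segments.psl", "meta.tsv"
  )
  writeLines(dom_lines, p("domains.domtblout"))
  writeLines(sp_lines, p("signalp.short"))
  writeLines(pre_lines, p("predisi.tsv"))
  writeLines(tm_lines, p("tmhmm.short"))
  writeLines(phob_lines, p("phobius.txt"))
  writeLines(gpi_lines, p("gpi.tsv"))
  writeLines(psl_lines, p("segments.psl"))
  writeLines(meta_lines, p("meta.tsv"))
  invisible(file.path(dir, files))
}
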