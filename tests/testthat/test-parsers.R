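# parsers for FASTA and the predictor output dialects

test_that("FASTA parsing: ids, descriptions, wrapping, duplicates", {
  path <- write_tmp(c(
    ">P1 first protein", "MKT",
    ">P2", "MKTACDEF", "GHIKLMNP"
  ), ext = ".fasta")
  tab <- read_fasta(path)
  expect_equal(tab$protein_id, c("P1", "P2"))
  expect_equal(tab$sequence[1], "MKT")
  expect_equal(tab$sequence[2], "MKTACDEFGHIKLMNP") # wrapped lines concatenated
  expect_equal(tab$description, c("first protein", ""))

  dup <- write_tmp(c(">P1", "MKT", ">P1", "MAA"), ext = ".fasta")
  expect_error(read_fasta(dup), "duplicate")
})

test_that("domtblout hits map coordinates, scores and E-values field-for-field", {
  line <- paste(
    "Kringle PF00051.10 85 P1 - 300",
    "2.1e-24 84.6 0.1 1 1 4e-24 2.1e-24 84.6 0.1",
    "1 85 25 106 24 107 0.98 -"
  )
  tab <- read_domtblout(write_tmp(c("# comment", line)))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$ali_start, 25L)
  expect_equal(tab$ali_end, 106L)
  expect_equal(tab$hmm_start, 1L)
  expect_equal(tab$hmm_end, 85L)
  expect_equal(tab$score, 84.6)
  expect_equal(tab$e_value, 2.1e-24)
  expect_equal(tab$family_acc, "PF00051.10")
})

test_that("domtblout filtering, copy indexing and overlap merging", {
  mk <- function(id, acc, s, e, ev) {
    paste(
      "fam", acc, "85", id, "-", "400", ev, "50", "0.1", "1", "1",
      ev, ev, "50", "0.1", "1", as.character(e - s + 1), s, e, s, e, "0.9", "-"
    )
  }
  path <- write_tmp(c(
    mk("P1", "PF00051.10", 10, 80, "1e-20"),
    mk("P1", "PF00051.10", 200, 270, "1e-10"),
    mk("P1", "PF00041.3", 300, 380, "1.0"), # above threshold: dropped
    mk("P2", "PF00051.10", 15, 90, "1e-8"),
    mk("P2", "PF00051.12", 20, 92, "1e-15") # >50% mutual overlap, better E
  ))
  tab <- read_domtblout(path, e_value_max = 1e-3)
  p1 <- tab[tab$protein_id == "P1", ]
  expect_equal(p1$copy_index, c(1L, 2L)) # N-to-C order
  expect_false(any(tab$e_value > 1e-3))
  p2 <- tab[tab$protein_id == "P2", ]
  expect_equal(nrow(p2), 1) # merged, lower-E hit kept
  expect_equal(p2$ali_start, 20L)

  expect_error(read_domtblout(write_tmp("too few fields here")), "line 1")
})

test_that("SignalP short lines carry decision, cleavage and D-score", {
  path <- write_tmp(c(
    "# SignalP-4.1 euk predictions",
    "# name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks-used",
    "P1 0.3 23 0.4 23 0.5 12 0.4 0.82 Y 0.45 SignalP-noTM",
    "P2 0.1 2 0.1 2 0.1 2 0.1 0.12 N 0.45 SignalP-noTM"
  ))
  tab <- read_signalp_short(path)
  yes <- tab[tab$protein_id == "P1", ]
  # cleavage between 22|23: the signal peptide spans residues 1-22
  expect_equal(c(yes$start, yes$end), c(1L, 22L))
  expect_true(yes$called)
  expect_equal(yes$score, 0.82)
  expect_false(tab$called[tab$protein_id == "P2"])

  expect_error(read_signalp_short(write_tmp("P1 0.3 23")), "header")
})

test_that("TMHMM short lines expand PredHel counts into helix spans", {
  path <- write_tmp(c(
    "P1 len=600 ExpAA=44.5 First60=0.0 PredHel=2 Topology=o200-222i300-322o",
    "P2 len=100 ExpAA=0.0 First60=0.0 PredHel=0 Topology=o"
  ))
  tab <- read_tmhmm_short(path)
  p1 <- tab[tab$protein_id == "P1", ]
  expect_equal(p1$start, c(200L, 300L))
  expect_equal(p1$end, c(222L, 322L))
  expect_true(all(p1$called))
  p2 <- tab[tab$protein_id == "P2", ]
  expect_false(p2$called)

  expect_error(read_tmhmm_short(write_tmp("P1 len=600 nothing")), "PredHel")
})

test_that("Phobius FT rows distinguish SIGNAL from TRANSMEM", {
  path <- write_tmp(c(
    "ID P1",
    "FT SIGNAL 1 21",
    "//",
    "ID P2",
    "FT TRANSMEM 30 52",
    "FT TRANSMEM 70 92",
    "//",
    "ID P3",
    "//"
  ))
  tab <- read_phobius(path)
  sp <- tab[tab$protein_id == "P1" & tab$feature_kind == "signal_peptide", ]
  expect_equal(c(sp$start[1], sp$end[1]), c(1L, 21L))
  tm <- tab[tab$protein_id == "P2" & tab$feature_kind == "tm_helix" & tab$called, ]
  expect_equal(nrow(tm), 2)
  # a block with no FT rows still votes: explicit absence for both kinds
  p3 <- tab[tab$protein_id == "P3", ]
  expect_equal(nrow(p3), 2)
  expect_false(any(p3$called))

  expect_error(read_phobius(write_tmp("P1 2 Y n8-22c26/27o")), "ID")
})

test_that("GPI tables record omega sites", {
  tab <- read_gpi_table(write_tmp(c("# GPI table", "P1 Y 292", "P2 N 0")))
  expect_equal(tab$end[tab$protein_id == "P1"], 292L)
  expect_true(tab$called[tab$protein_id == "P1"])
  expect_false(tab$called[tab$protein_id == "P2"])
})

test_that("PSL keeps the top-scoring alignment per segment and filters", {
  psl <- function(matches, mism, qname, qsize, chrom) {
    paste(
      matches, mism, 0, 0, 0, 0, 0, 0, "+", qname, qsize, 0, qsize,
      chrom, 2e8, 1000, 1000 + 3 * qsize, 1, paste0(qsize, ","), "0,", "1000,"
    )
  }
  path <- write_tmp(c(
    psl(99, 1, "P1:seg1", 100, "chr3"), # score 98
    psl(50, 10, "P1:seg1", 100, "chr9"), # worse score, same segment
    psl(99, 1, "P1:seg2", 100, "chr3"),
    psl(90, 10, "P2:seg1", 100, "chr5") # identity 0.9 < 0.95: dropped
  ))
  tab <- read_psl(path, min_identity = 0.95, min_coverage = 0.80)
  p1 <- tab[tab$protein_id == "P1", ]
  expect_equal(nrow(p1), 2)
  expect_true(all(p1$chromosome == "chr3"))
  expect_equal(p1$identity, c(0.99, 0.99))
  expect_false("P2" %in% tab$protein_id)

  expect_error(read_psl(write_tmp(psl(-5, 1, "P1:seg1", 100, "chr1"))), "negative")
})

test_that("whitespace runs between fields do not change any parse", {
  reg <- demo_registries()
  corpus <- generate_corpus(
    fixture_spec(seed = 5, n_clean = 3, planted = c("5" = 1, "10" = 1)), reg
  )
  dir <- withr::local_tempdir()
  emit_mock_tool_outputs(corpus$records, dir)

  fuzz <- function(path, seed) {
    lines <- readLines(path)
    withr::with_seed(seed, {
      vapply(lines, function(ln) {
        if (startsWith(ln, "#") || !grepl("[ \t]", ln)) {
          return(ln)
        }
        toks <- strsplit(ln, "[ \t]+")[[1]]
        seps <- vapply(seq_len(length(toks) - 1), function(i) {
          paste(sample(c(" ", "\t"), sample(1:3, 1), replace = TRUE), collapse = "")
        }, "")
        paste0(paste0(toks[-length(toks)], seps, collapse = ""), toks[length(toks)])
      }, "", USE.NAMES = FALSE)
    })
  }
  cases <- list(
    list("signalp.short", read_signalp_short),
    list("predisi.tsv", read_predisi_table),
    list("tmhmm.short", read_tmhmm_short),
    list("phobius.txt", read_phobius),
    list("gpi.tsv", read_gpi_table),
    list("domains.domtblout", read_domtblout),
    list("segments.psl", read_psl)
  )
  for (case in cases) {
    orig <- case[[2]](file.path(dir, case[[1]]))
    fz <- write_tmp(fuzz(file.path(dir, case[[1]]), seed = 99))
    expect_identical(case[[2]](fz), orig)
  }
})

test_that("assembly joins annotations by id and warns about ghosts", {
  seqs <- tibble::tibble(
    protein_id = c("P1", "P2"), description = "", sequence = test_sequence(120)
  )
  hits <- dplyr::bind_rows(
    dplyr::mutate(hit_row("PF00051", "Kringle", 10, 90), protein_id = "P1"),
    dplyr::mutate(hit_row("PF00051", "Kringle", 10, 90), protein_id = "ghost")
  )
  expect_warning(
    recs <- assemble_records(seqs, domain_hits = hits),
    "ghost"
  )
  expect_equal(nrow(recs), 2)
  expect_equal(nrow(recs$domain_hits[[1]]), 1)
  expect_equal(nrow(recs$domain_hits[[2]]), 0) # missing source: empty features
  expect_false("ghost" %in% recs$protein_id)
})
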