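# the eleven consistency rules and the evaluation engine

reg <- demo_registries()

test_that("boolean-logic rules match the independent truth table on all 128 states", {
  cfg <- engine_config(enabled_rules = c(1:3, 6:10))
  states <- tidyr::expand_grid(
    ext = c(FALSE, TRUE), cyto = c(FALSE, TRUE), nuc = c(FALSE, TRUE),
    sp = c(FALSE, TRUE), anchor = c(FALSE, TRUE), tm = c(FALSE, TRUE),
    gpi = c(FALSE, TRUE)
  )
  expect_equal(nrow(states), 128)
  recs <- dplyr::bind_rows(lapply(seq_len(nrow(states)), function(i) {
    s <- states[i, ]
    state_record(sprintf("S%03d", i), s$ext, s$cyto, s$nuc, s$sp, s$anchor, s$tm, s$gpi)
  }))
  class(recs) <- c("mp_records", class(recs))
  report <- evaluate_records(recs, reg, cfg)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    expect_identical(
      conflict_set(report, sprintf("S%03d", i)),
      sort(oracle_conflicts(s$ext, s$cyto, s$nuc, s$sp, s$anchor, s$tm, s$gpi)),
      label = sprintf(
        "state ext=%d cyto=%d nuc=%d sp=%d anchor=%d tm=%d gpi=%d",
        s$ext, s$cyto, s$nuc, s$sp, s$anchor, s$tm, s$gpi
      )
    )
  }
})

test_that("domain-size rule applies mean +/- k*sd, fixed-length and fractional bounds", {
  cfg <- engine_config() # k = 2.5
  mk <- function(len, acc = "PF00051", name = "Kringle") {
    protein_records(
      protein_id = "P1", sequence = test_sequence(600),
      domain_hits = list(hit_row(acc, name, 100, 100 + len - 1)),
      predictor_calls = list(state_calls(sp = TRUE))
    )
  }
  # reference 80, sd 6: |64-80| = 16 > 2.5*6 = 15 -> conflict
  expect_true(4L %in% conflict_set(evaluate_records(mk(64), reg, cfg), "P1"))
  # |66-80| = 14 <= 15 -> clean
  expect_false(4L %in% conflict_set(evaluate_records(mk(66), reg, cfg), "P1"))
  # observed exactly the reference -> clean
  expect_false(4L %in% conflict_set(evaluate_records(mk(80), reg, cfg), "P1"))

  # family with no sd (PF00008, ref 38): fractional bounds 0.70 / 1.30
  expect_true(4L %in% conflict_set(
    evaluate_records(mk(26, "PF00008", "EGF"), reg, cfg), "P1"
  )) # 26/38 = 0.68 < 0.70
  expect_false(4L %in% conflict_set(
    evaluate_records(mk(30, "PF00008", "EGF"), reg, cfg), "P1"
  )) # 0.79

  # family absent from the size registry: rule stays silent
  rec <- protein_records(
    protein_id = "P1", sequence = test_sequence(600),
    domain_hits = list(hit_row("PF00017", "SH2", 100, 120)),
    predictor_calls = list(state_calls())
  )
  expect_false(4L %in% conflict_set(evaluate_records(rec, reg, cfg), "P1"))
})

test_that("chimera rule needs two chromosomes and skips without mappings", {
  maps <- function(chroms) {
    tibble::tibble(
      segment_index = seq_along(chroms), chromosome = chroms, strand = "+",
      identity = 0.99, query_coverage = 1, alignment_score = 100
    )
  }
  mk <- function(m) {
    protein_records(
      protein_id = "P1", sequence = test_sequence(300),
      predictor_calls = list(state_calls()),
      segment_mappings = if (is.null(m)) NULL else list(m)
    )
  }
  rep5 <- evaluate_records(mk(maps(c("chr3", "chr7"))), reg)
  expect_identical(conflict_set(rep5, "P1"), 5L)
  expect_identical(conflict_set(evaluate_records(mk(maps(c("chr3", "chr3"))), reg), "P1"), integer(0))
  skip_rep <- evaluate_records(mk(NULL), reg)
  expect_identical(conflict_set(skip_rep, "P1"), integer(0))
  expect_true(5L %in% skip_rep$skipped$rule_id)
})

test_that("architecture rule is order-sensitive, collapses repeats, skips empties", {
  cfg <- engine_config()
  mk <- function(hits) {
    protein_records(
      protein_id = "P1", sequence = test_sequence(600),
      domain_hits = list(hits),
      predictor_calls = list(state_calls(sp = TRUE))
    )
  }
  known <- dplyr::bind_rows(
    hit_row("PF00051.10", "Kringle", 30, 111),
    hit_row("PF01822.14", "WSC", 130, 221)
  )
  expect_false(11L %in% conflict_set(evaluate_records(mk(known), reg, cfg), "P1"))

  # same two families in reverse N-to-C order: novel architecture
  reversed <- dplyr::bind_rows(
    hit_row("PF01822.14", "WSC", 30, 121),
    hit_row("PF00051.10", "Kringle", 140, 221)
  )
  expect_true(11L %in% conflict_set(evaluate_records(mk(reversed), reg, cfg), "P1"))

  # tandem repeat collapses onto the known single-copy key
  tandem <- dplyr::bind_rows(
    hit_row("PF00051.10", "Kringle", 30, 111),
    hit_row("PF00051.10", "Kringle", 120, 201, copy_index = 2L),
    hit_row("PF01822.14", "WSC", 220, 311)
  )
  expect_false(11L %in% conflict_set(evaluate_records(mk(tandem), reg, cfg), "P1"))
  no_collapse <- engine_config(repeat_collapse = FALSE)
  expect_true(11L %in% conflict_set(evaluate_records(mk(tandem), reg, no_collapse), "P1"))

  # zero domains: rule skipped, not fired
  bare <- evaluate_records(
    protein_records(
      protein_id = "P1", sequence = test_sequence(100),
      predictor_calls = list(state_calls())
    ),
    reg, cfg
  )
  expect_false(11L %in% conflict_set(bare, "P1"))
  expect_true(11L %in% bare$skipped$rule_id)
})

test_that("missing predictor evidence skips the rules that need it", {
  # extracellular domain but no topology votes at all: rule 1 undecidable
  rec <- protein_records(
    protein_id = "P1", sequence = test_sequence(300),
    domain_hits = list(hit_row("PF00051", "Kringle", 30, 111))
  )
  report <- evaluate_records(rec, reg)
  expect_identical(conflict_set(report, "P1"), integer(0))
  expect_true(all(c(1L, 7L, 10L) %in% report$skipped$rule_id))
})

test_that("the worked secreted-protein example raises only the size conflict", {
  rec <- worked_example_record()
  report <- evaluate_records(rec, reg)
  expect_identical(conflict_set(report, rec$protein_id), 4L)
  conf <- report$conflicts
  expect_identical(conf$rule_name, "domain size deviation")
  expect_match(conf$evidence[[1]], "PF01822", all = FALSE)
})

test_that("an engineered multi-conflict record raises the full conflict set", {
  # extracellular + nuclear domains, GPI anchor, no signal peptide
  rec <- protein_records(
    protein_id = "P1", sequence = test_sequence(600),
    domain_hits = list(dplyr::bind_rows(
      hit_row("PF00051", "Kringle", 100, 181),
      hit_row("PF00046", "Homeodomain", 350, 409)
    )),
    predictor_calls = list(state_calls(gpi = TRUE))
  )
  report <- evaluate_records(rec, reg, engine_config(enabled_rules = c(1:3, 6:10)))
  expect_identical(conflict_set(report, "P1"), c(1L, 3L, 7L, 9L))
})

test_that("adding an export signal never creates the export-signal conflict", {
  states <- tidyr::expand_grid(
    ext = c(FALSE, TRUE), cyto = c(FALSE, TRUE), gpi = c(FALSE, TRUE)
  )
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    with_sp <- state_record("P1", s$ext, s$cyto, FALSE, TRUE, FALSE, FALSE, s$gpi)
    expect_false(1L %in% conflict_set(evaluate_records(with_sp, reg), "P1"))
  }
})

test_that("removing all GPI evidence clears the GPI-dependent conflicts", {
  rec <- protein_records(
    protein_id = "P1", sequence = test_sequence(600),
    domain_hits = list(dplyr::bind_rows(
      hit_row("PF00017", "SH2", 200, 290),
      hit_row("PF00046", "Homeodomain", 350, 409)
    )),
    predictor_calls = list(state_calls(tm = TRUE, gpi = TRUE))
  )
  with_gpi <- evaluate_records(rec, reg)
  expect_true(all(c(7L, 8L, 9L, 10L) %in% conflict_set(with_gpi, "P1")))

  no_gpi <- rec
  no_gpi$predictor_calls[[1]] <- dplyr::mutate(
    no_gpi$predictor_calls[[1]],
    called = ifelse(.data$feature_kind == "gpi_anchor", FALSE, .data$called)
  )
  cleared <- evaluate_records(no_gpi, reg)
  expect_false(any(c(7L, 8L, 9L, 10L) %in% conflict_set(cleared, "P1")))
})

test_that("evaluation is deterministic and rules disable independently", {
  corpus <- generate_corpus(
    fixture_spec(seed = 21, n_clean = 4, planted = c("3" = 1, "6" = 1, "11" = 1)),
    reg
  )
  a <- evaluate_records(corpus$records, reg)
  b <- evaluate_records(corpus$records, reg)
  expect_identical(a$conflicts, b$conflicts)

  full <- a$conflicts
  for (k in c(3L, 6L, 11L)) {
    cfg <- engine_config(enabled_rules = setdiff(1:11, k))
    partial <- evaluate_records(corpus$records, reg, cfg)$conflicts
    expect_identical(
      partial,
      dplyr::filter(full, .data$rule_id != k),
      label = sprintf("disabling rule %d", k)
    )
  }
})

test_that("flag percentages reproduce printed-table rounding", {
  expect_equal(compute_flag_percentage(59000, 2245), 3.81)
  expect_equal(compute_flag_percentage(20215, 762), 3.77)
  expect_equal(compute_flag_percentage(1000, 0), 0)
  # half-up at the second decimal, where round-to-even would differ
  expect_equal(compute_flag_percentage(1000, 25), 2.5)
  expect_equal(compute_flag_percentage(10000, 125), 1.25)
  expect_equal(compute_flag_percentage(80000, 100), 0.13)
  expect_error(compute_flag_percentage(0, 0), "undefined")
  expect_error(compute_flag_percentage(10, 11), "n_flagged")
})
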