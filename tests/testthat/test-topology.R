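# consensus policy and the effective-helix disambiguation layer

test_that("any-mode consensus: present on any yes, absent only on unanimity", {
  cfg <- engine_config()
  # SignalP yes + PrediSi no -> present
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8),
    call_row("PrediSi", "signal_peptide", called = FALSE)
  ), 300, cfg)
  expect_false(is.null(topo$signal_peptide))
  expect_equal(topo$signal_peptide$end, 22L)
  expect_equal(topo$signal_peptide$predictors, "SignalP")

  # both helix predictors agree absent -> absent, with evidence recorded
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("TMHMM", "tm_helix", called = FALSE),
    call_row("Phobius", "tm_helix", called = FALSE)
  ), 300, cfg)
  expect_equal(nrow(topo$tm_helices), 0)
  expect_true(topo$evidence[["tm_helix"]])

  # a single predictor suffices: two helices survive as two spans
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("TMHMM", "tm_helix", 100L, 122L, TRUE),
    call_row("TMHMM", "tm_helix", 200L, 222L, TRUE)
  ), 300, cfg)
  expect_equal(nrow(topo$tm_helices), 2)
})

test_that("majority mode needs more than half of the voting predictors", {
  cfg <- engine_config(consensus_mode = "majority")
  split_vote <- dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8),
    call_row("PrediSi", "signal_peptide", called = FALSE)
  )
  expect_null(consensus_topology(split_vote, 300, cfg)$signal_peptide)
  both <- dplyr::mutate(split_vote, called = TRUE, start = 1L, end = 22L)
  expect_false(is.null(consensus_topology(both, 300, cfg)$signal_peptide))
})

test_that("no votes for a kind leaves its evidence flag down", {
  topo <- consensus_topology(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8), 300
  )
  expect_true(topo$evidence[["signal_peptide"]])
  expect_false(topo$evidence[["tm_helix"]])
  expect_false(topo$evidence[["gpi_anchor"]])
})

test_that("span of a present feature is the union of supporting calls", {
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8),
    call_row("PrediSi", "signal_peptide", 1L, 25L, TRUE, 0.7),
    call_row("TMHMM", "tm_helix", 100L, 120L, TRUE),
    call_row("Phobius", "tm_helix", 110L, 126L, TRUE)
  ), 300)
  expect_equal(topo$signal_peptide$end, 25L)
  expect_equal(nrow(topo$tm_helices), 1) # overlapping votes merged
  expect_equal(c(topo$tm_helices$start, topo$tm_helices$end), c(100L, 126L))
})

test_that("an N-terminal helix without a cleaved signal peptide becomes the anchor", {
  calls <- dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", called = FALSE),
    call_row("TMHMM", "tm_helix", 5L, 25L, TRUE)
  )
  topo <- consensus_topology(calls, 300)
  expect_false(is.null(topo$signal_anchor))
  expect_equal(nrow(topo$tm_helices), 0)

  # with a signal peptide present the helix stays a helix (and is handled
  # by the effective-helix exclusion instead)
  calls$called[1] <- TRUE
  calls$start[1] <- 1L
  calls$end[1] <- 22L
  topo <- consensus_topology(calls, 300)
  expect_null(topo$signal_anchor)
  expect_equal(nrow(topo$tm_helices), 1)
})

test_that("effective helices drop export-signal and GPI-signal artifacts", {
  cfg <- engine_config()
  # helix (5,25) overlapping the signal peptide (1,22): excluded
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8),
    call_row("TMHMM", "tm_helix", 5L, 25L, TRUE),
    call_row("TMHMM", "tm_helix", 200L, 222L, TRUE)
  ), 600, cfg)
  eff <- effective_tm_helices(topo, 600, cfg)
  expect_equal(nrow(topo$tm_helices), 2)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$start, 200L) # mid-protein helix retained

  # GPI protein of length 300: helix (270,292) sits in the C-terminal
  # window and is the attachment signal, not a membrane pass
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8),
    call_row("TMHMM", "tm_helix", 270L, 292L, TRUE),
    call_row("DGPI", "gpi_anchor", 292L, 292L, TRUE)
  ), 300, cfg)
  expect_equal(nrow(effective_tm_helices(topo, 300, cfg)), 0)

  # same helix without the GPI anchor is a real TM
  topo <- consensus_topology(dplyr::bind_rows(
    call_row("SignalP", "signal_peptide", 1L, 22L, TRUE, 0.8),
    call_row("TMHMM", "tm_helix", 270L, 292L, TRUE)
  ), 300, cfg)
  expect_equal(nrow(effective_tm_helices(topo, 300, cfg)), 1)
})
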