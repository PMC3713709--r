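# mispredqc

Quality control for predicted protein sequences. Public protein databases
built on computational gene prediction are contaminated with truncated,
chimeric and otherwise mispredicted entries. `mispredqc` flags such
sequences by checking each protein's annotated features against eleven
consistency rules — the MisPred rules — built on a simple premise: a
predicted protein is suspect when its features contradict basic protein
biology.

The rules combine three evidence layers:

* **domain content** — Pfam-style hits, with registries of *obligatory*
  extracellular / cytoplasmic / nuclear families, per-family reference
  lengths, and known domain architectures;
* **membrane topology** — consensus signal peptide, signal anchor, TM
  helices and GPI anchor derived from predictor votes (SignalP, PrediSi,
  TMHMM, Phobius, DGPI-style tools);
* **genomic provenance** — chromosome assignment of the coding segments
  (BLAT PSL).

A protein is flagged when, for example, it carries an obligatory
extracellular domain but no export signal (rule 1), mixes extracellular and
nuclear domains (rule 3), has a domain hit whose length `L` deviates from
its family reference by more than `k·sd` with `k = 2.5` (rule 4, "domain
size deviation"), maps to two chromosomes (rule 5), or shows a domain
architecture absent from the known-architecture registry (rule 11). The
full rule table, the consensus policy and every threshold are documented in
`vignettes/consistency-rules.Rmd`.

The package does **not** run the upstream predictors; it parses their
standard output formats (HMMER3 `domtblout`, SignalP 4 short, TMHMM 2
short, Phobius feature rows, DGPI-style and PrediSi-style tables, PSL) and
judges consistency. A deterministic synthetic-corpus generator with planted
conflicts makes the whole pipeline testable end-to-end with no external
software or downloads.

## Worked example

Generate a small corpus with two planted errors (a truncated domain and an
interchromosomal chimera), evaluate it, and summarise:

```r
library(mispredqc)

reg <- demo_registries()
corpus <- generate_corpus(
  fixture_spec(seed = 1, n_clean = 4, planted = c("4" = 1, "5" = 1)), reg
)
report <- evaluate_records(corpus$records, reg)
report
#> <conflict report: 6 protein(s), 2 flagged, 2 conflict(s)>
#>   rule  4  domain size deviation                                          1
#>   rule  5  interchromosomal chimeric protein                              1

tidy(report)
#> # A tibble: 2 x 5
#>   protein_id rule_id rule_name                         message          evidence
#>   <chr>        <int> <chr>                             <chr>            <list>
#> 1 SYN0005          4 domain size deviation             conflict 4: dom~ <chr>
#> 2 SYN0006          5 interchromosomal chimeric protein conflict 5: int~ <chr>

glance(report)
#> # A tibble: 1 x 5
#>   n_proteins n_flagged percent_flagged n_conflicts n_rules_skipped
#>        <int>     <int>           <dbl>       <int>           <int>
#> 1          6         2            33.3           2               1

flag_stats(report, corpus$records, by = "species")
#> # A tibble: 3 x 4
#>   species      n_total n_flagged percent
#>   <chr>          <int>     <int>   <dbl>
#> 1 Danio rerio        2         1      50
#> 2 Homo sapiens       2         0       0
#> 3 Mus musculus       2         1      50
```

Both planted conflicts are recovered, the four clean records stay clean,
and `flag_stats()` reports contamination percentages per group the way
published database summaries print them (`compute_flag_percentage(59000,
2245)` is `3.81`). `autoplot(report)` draws conflicts per rule;
`plot_feature_map(corpus$records, "SYN0005")` sketches one record's domain
and topology annotation.

To run the same pipeline from predictor output files on disk:

```r
report <- run_check(
  fasta = "proteins.fasta", domtblout = "domains.domtblout",
  signalp = "signalp.short", tmhmm = "tmhmm.short",
  phobius = "phobius.txt", gpi = "gpi.tsv", psl = "segments.psl",
  registry_dir = system.file("extdata/registries/demo", package = "mispredqc"),
  out_dir = "qc_out"
)
```

which writes `report.json` (three sections per protein: basic info,
annotations, conclusions) and a flat `report.tsv`. A thin command-line
wrapper with `check` / `stats` / `fixtures` subcommands ships as
`inst/cli/mispredqc.R`.

## Registry files

The rules read three plain-text resources from `--registry-dir` /
`load_registries(dir)`:

* `localization.tsv` — columns `accession`, `compartment`
  (`extracellular` | `cytoplasmic` | `nuclear`); compartments must be
  disjoint.
* `domain_sizes.tsv` — columns `accession`, `reference_length`, optional
  `length_sd` (0 = fixed length, absent = fractional bounds), optional
  `source_n`.
* `architectures.txt` — one known architecture per line, comma-separated
  accessions in N→C order; `#` comments allowed.

The bundled `demo` registry set is illustrative test data (real Pfam
accessions, hand-chosen values), not a curated production resource; supply
your own Pfam-derived lists for real analyses.

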