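tax <- default_taxonomy()

test_that("the same seed gives byte-identical outputs", {
  cfg <- sim_config(list(sim_event(30, "gain", clade = "aga")),
                    sequence_length = 80L, missing_taxon_prob = 0.1,
                    row_gap_prob = 0.2, seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$alignment$rows, b$alignment$rows)
  expect_identical(a$flatfile, b$flatfile)
  expect_identical(a$truth, b$truth)
})

test_that("a human-branch gain is carried by humans alone", {
  cfg <- sim_config(list(sim_event(30, "gain", clade = "hum")),
                    sequence_length = 60L, seed = 1)
  sim <- simulate_dataset(cfg)
  rows <- sim$alignment$rows
  expect_length(rows, 62L)
  has_motif <- vapply(rows, function(s) {
    ch <- strsplit(s, "")[[1]]
    isTRUE(is_sequon(ch[30], ch[31], ch[32]))
  }, TRUE)
  expect_true(has_motif[["human"]])
  expect_equal(sum(has_motif), 1L)
  expect_equal(sim$truth$timing, "hum")
  expect_equal(sim$truth$expected, "pass")
})

test_that("clade gains are inherited by every descendant species", {
  for (clade in c("hac", "gra", "cat", "eua")) {
    cfg <- sim_config(list(sim_event(40, "gain", clade = clade)),
                      sequence_length = 60L, seed = 3)
    rows <- simulate_dataset(cfg)$alignment$rows
    has_motif <- vapply(rows, function(s) {
      ch <- strsplit(s, "")[[1]]
      isTRUE(is_sequon(ch[40], ch[41], ch[42]))
    }, TRUE)
    expect_setequal(names(rows)[has_motif], clade_members(tax, clade))
  }
})

test_that("independent outgroup gains set the ancestral fraction", {
  cfg <- sim_config(list(sim_event(30, "gain", clade = "sim"),
                         sim_event(30, "outgroup_gain",
                                   species = c("cow", "killer_whale"))),
                    sequence_length = 60L, seed = 4)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth[sim$truth$kind == "gain", ]
  expect_equal(tr$outgroup_fraction, 2 / 49)
  expect_equal(tr$expected, "pass")
  gs <- parse_uniprot_glycosites(sim$flatfile)
  scr <- run_screen(gs, stats::setNames(list(sim$alignment), "SIM1"),
                    taxonomy = tax)
  expect_equal(scr$records$outgroup_fraction, 2 / 49)
  expect_equal(scr$records$timing, "sim")
})

test_that("conserved background sites are produced and rejected", {
  cfg <- sim_config(make_background_conserved_site(30),
                    sequence_length = 60L, seed = 9)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$truth$outgroup_fraction, 1.0)
  expect_equal(sim$truth$expected, "discard")
  gs <- parse_uniprot_glycosites(sim$flatfile)
  scr <- run_screen(gs, stats::setNames(list(sim$alignment), "SIM1"),
                    taxonomy = tax)
  expect_equal(scr$records$status, "fail")
  expect_match(scr$records$reasons, "ANCESTRAL")
  # decayed in 80% of outgroups: fraction ~0.2, kept by the 30% rule
  cfg2 <- sim_config(make_background_conserved_site(30, decay_fraction = 0.8),
                     sequence_length = 60L, seed = 9)
  sim2 <- simulate_dataset(cfg2)
  expect_lt(sim2$truth$outgroup_fraction[1], 0.30)
  gs2 <- parse_uniprot_glycosites(sim2$flatfile)
  scr2 <- run_screen(gs2, stats::setNames(list(sim2$alignment), "SIM1"),
                     taxonomy = tax)
  expect_equal(scr2$records$status, "pass")
})

test_that("simulated outputs parse cleanly through the readers", {
  cfg <- sim_config(list(sim_event(30, "gain", clade = "pri")),
                    sequence_length = 60L, row_gap_prob = 0.2,
                    missing_taxon_prob = 0.1, seed = 10)
  sim <- simulate_dataset(cfg)
  back <- read_ortholog_alignment(write_ortho_fasta(sim$alignment),
                                  dialect = "protein", taxonomy = tax,
                                  gene = "SIM1")
  expect_equal(back$rows, sim$alignment$rows)
  gs <- parse_uniprot_glycosites(sim$flatfile)
  expect_equal(gs$position, 30L)
  expect_true(all(gs$evidence_ok))
  expect_equal(nchar(attr(gs, "sequences")[["SIM1"]]), 60L)
})

test_that("invalid event sets are rejected", {
  expect_error(sim_config(list(sim_event(30, "gain", clade = "hum"),
                               sim_event(30, "gain", clade = "sim")),
                          seed = 1), "colliding")
  expect_error(sim_config(list(sim_event(30, "loss", species = "mouse")),
                          seed = 1), "does not match")
  expect_error(sim_config(list(sim_event(5, "gain", clade = "hum")),
                          seed = 1), "window")
  expect_error(sim_config(list(sim_event(30, "outgroup_gain",
                                         species = "gorilla")),
                          seed = 1), "non-Euarchonta")
  expect_error(sim_config(list(sim_event(30, "gain", clade = "hum"))),
               "seed")
  expect_error(sim_event(30, "gain"), "ladder clade")
})
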