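tax <- default_taxonomy()

test_that("the ancestral-conservation fraction uses informative outgroups", {
  out49 <- tax$species$id[!tax$species$group %in% ladder_clades()]
  # a few independent outgroup acquisitions stay well below the threshold
  st <- make_states(tax, sequon = c("human", "cow", "sheep", "dolphin"))
  f <- ancestral_conservation_fraction(st, tax)
  expect_equal(as.numeric(f), 3 / 49)
  expect_lt(as.numeric(f), 0.30)
  # all outgroups carrying -> 1.0, discarded
  st2 <- make_states(tax, sequon = c("human", out49))
  expect_equal(as.numeric(ancestral_conservation_fraction(st2, tax)), 1.0)
  # exactly 30% is kept: the discard rule is strictly "more than"
  st3 <- make_states(tax, sequon = c("human", out49[1:3]),
                     missing = out49[11:49])
  f3 <- ancestral_conservation_fraction(st3, tax)
  expect_equal(as.numeric(f3), 0.30)
  expect_equal(attr(f3, "n_informative"), 10L)
  expect_false(as.numeric(f3) > screening_config()$ancestral_threshold)
  # zero informative outgroups is flagged, not a division
  st4 <- make_states(tax, sequon = "human", missing = out49)
  f4 <- ancestral_conservation_fraction(st4, tax)
  expect_true(is.nan(as.numeric(f4)))
  expect_equal(attr(f4, "n_informative"), 0L)
})

test_that("curation rules flag paralogy, non-consensus, chimp and coverage", {
  cfg <- screening_config()
  s <- paste0(strrep("A", 29), "NGS", strrep("A", 28))   # Asn at 30
  st <- make_states(tax, sequon = c("human", "chimpanzee"))
  expect_true(curation_filter(st, s, 30L, cfg, uniprot_seq = s)$pass)
  # three mismatching residues fail, two pass
  mut <- function(x, at) {
    for (i in at) substr(x, i, i) <- "W"
    x
  }
  r3 <- curation_filter(st, s, 30L, cfg, uniprot_seq = mut(s, c(1, 2, 3)))
  expect_false(r3$pass)
  expect_true("UNIPROT_MISMATCH" %in% r3$reasons)
  expect_true(curation_filter(st, s, 30L, cfg, uniprot_seq = mut(s, c(1, 2)))$pass)
  # a length difference counts toward the mismatch total
  r_len <- curation_filter(st, s, 30L, cfg,
                           uniprot_seq = paste0(mut(s, 1), "AA"))
  expect_false(r_len$pass)
  # annotated residue not at a consensus motif
  r_nc <- curation_filter(st, s, 31L, cfg, uniprot_seq = s)
  expect_true("NOT_CONSENSUS" %in% r_nc$reasons)
  # chimpanzee absent
  st_noch <- st[st$species != "chimpanzee", ]
  r_ch <- curation_filter(st_noch, s, 30L, cfg, uniprot_seq = s)
  expect_true("NO_CHIMP" %in% r_ch$reasons)
  # low coverage
  st_low <- make_states(tax, sequon = c("human", "chimpanzee"),
                        missing = setdiff(tax$species$id,
                                          c("human", "chimpanzee")))
  r_lc <- curation_filter(st_low, s, 30L, cfg, uniprot_seq = s)
  expect_true("LOW_COVERAGE" %in% r_lc$reasons)
})

test_that("timing assignment finds the clade where the motif emerged", {
  cfg <- screening_config()
  # human-specific pattern
  expect_equal(assign_timing(make_states(tax, sequon = "human"), tax, cfg),
               "hum")
  # shared by all apes (human..gibbon), absent from catarrhine monkeys out
  apes <- clade_members(tax, "ape")
  expect_equal(assign_timing(make_states(tax, sequon = apes), tax, cfg), "ape")
  # all euarchonts carry it
  eua <- clade_members(tax, "eua")
  expect_equal(assign_timing(make_states(tax, sequon = eua), tax, cfg), "eua")
  # a missing great ape is excluded from the denominator
  gra <- clade_members(tax, "gra")
  st_gor <- make_states(tax, sequon = setdiff(gra, "gorilla"),
                        missing = "gorilla")
  expect_equal(assign_timing(st_gor, tax, cfg), "gra")
  # human without the sequon cannot be dated
  expect_error(assign_timing(make_states(tax, sequon = "chimpanzee"),
                             tax, cfg), "human")
})

test_that("unsampled distinguishing taxa stop the dating by default", {
  simians <- clade_members(tax, "sim")
  st <- make_states(tax, sequon = setdiff(simians, "bushbaby"),
                    missing = "bushbaby")
  # with the bushbaby missing, primates-wide presence rests on no data
  expect_equal(assign_timing(st, tax, screening_config()), "sim")
  expect_equal(
    assign_timing(st, tax, screening_config(timing_unsampled = "extend")),
    "pri")
})

test_that("secondary-loss tolerance widens the dated clade", {
  cats <- clade_members(tax, "cat")
  st <- make_states(tax, sequon = setdiff(cats, "baboon"))  # baboon lost it
  expect_equal(assign_timing(st, tax, screening_config()), "ape")
  expect_equal(
    assign_timing(st, tax, screening_config(timing_loss_tolerance = 0.2)),
    "cat")
})

test_that("run_screen keeps a complete decision trail", {
  cfg <- sim_config(list(sim_event(30, "gain", clade = "hum"),
                         sim_event(60, "gain", clade = "sim"),
                         make_background_conserved_site(100)[[1]]),
                    sequence_length = 150L, seed = 5)
  sim <- simulate_dataset(cfg)
  gs <- parse_uniprot_glycosites(sim$flatfile)
  scr <- run_screen(gs, stats::setNames(list(sim$alignment), "SIM1"),
                    taxonomy = tax)
  rec <- scr$records
  expect_equal(nrow(rec), nrow(gs))             # every site appears once
  expect_equal(rec$timing[rec$position == 30], "hum")
  expect_equal(rec$timing[rec$position == 60], "sim")
  expect_equal(rec$status[rec$position == 100], "fail")
  expect_match(rec$reasons[rec$position == 100], "ANCESTRAL")
  expect_true(all(nzchar(rec$reasons[rec$status == "fail"])))
  expect_true(all(rec$flags[rec$status == "pass"] == "RARE_VARIANT_UNCHECKED"))
})

test_that("degraded inputs are flagged, not silently dropped", {
  cfg <- sim_config(list(sim_event(30, "gain", clade = "hum")),
                    sequence_length = 60L, seed = 6)
  sim <- simulate_dataset(cfg)
  gs <- parse_uniprot_glycosites(sim$flatfile)
  # chimpanzee row deleted -> NO_CHIMP
  aln <- sim$alignment
  aln$rows <- aln$rows[names(aln$rows) != "chimpanzee"]
  scr <- run_screen(gs, stats::setNames(list(aln), "SIM1"), taxonomy = tax)
  expect_equal(scr$records$status, "fail")
  expect_match(scr$records$reasons, "NO_CHIMP")
  # no alignment for the gene
  scr2 <- run_screen(gs, list(), taxonomy = tax)
  expect_equal(scr2$records$status, "fail")
  expect_match(scr2$records$reasons, "NO_ALIGNMENT")
  # evidence-less sites are excluded up front
  gs$evidence_ok <- FALSE
  scr3 <- run_screen(gs, stats::setNames(list(sim$alignment), "SIM1"),
                     taxonomy = tax)
  expect_match(scr3$records$reasons, "NO_EVIDENCE")
  # empty input, empty output
  scr4 <- run_screen(gs[0, ], list(), taxonomy = tax)
  expect_equal(nrow(scr4$records), 0L)
})

test_that("lowering the ancestral threshold never adds passing records", {
  events <- c(list(sim_event(30, "gain", clade = "cat")),
              make_background_conserved_site(60, decay_fraction = 0.8),
              list(sim_event(100, "gain", clade = "hum"),
                   sim_event(100, "outgroup_gain",
                             species = c("cow", "sheep", "dolphin", "mouse",
                                         "rat", "pig"))))
  cfg <- sim_config(events, sequence_length = 150L, seed = 8)
  sim <- simulate_dataset(cfg)
  gs <- parse_uniprot_glycosites(sim$flatfile)
  alns <- stats::setNames(list(sim$alignment), "SIM1")
  n_pass <- vapply(seq(0, 0.5, by = 0.05), function(th) {
    scr <- run_screen(gs, alns, taxonomy = tax,
                      config = screening_config(ancestral_threshold = th))
    sum(scr$records$status == "pass")
  }, 1L)
  expect_true(all(diff(n_pass) >= 0L))
})
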