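test_that("ungapped positions map to alignment columns and back", {
  expect_equal(ungapped_to_column("M-AN", 2L), 3L)
  expect_equal(ungapped_to_column("MAN", 3L), 3L)   # gapless: identity
  expect_equal(column_to_ungapped("M-AN", 3L), 2L)
  expect_true(is.na(column_to_ungapped("M-AN", 2L)))
  expect_error(ungapped_to_column("M-AN", 4L), "exceeds")
  expect_error(column_to_ungapped("M-AN", 9L), "out of range")
})

test_that("coordinate mapping round-trips on enumerated gapped strings", {
  # every gap pattern of length 6 with at least one residue
  for (mask in 1:(2^6 - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:5)))
    chars <- ifelse(bits, "A", "-")
    s <- paste(chars, collapse = "")
    n_res <- sum(bits)
    for (p in seq_len(n_res)) {
      col <- ungapped_to_column(s, p)
      expect_equal(column_to_ungapped(s, col), p)
    }
    for (col in which(bits)) {
      expect_equal(ungapped_to_column(s, column_to_ungapped(s, col)), col)
    }
  }
})

test_that("species motif states are read off the homologous columns", {
  aln <- panel_fixture_alignment()
  st <- species_motif_state(aln, 13L)
  get <- function(sp) st$state[st$species == sp]
  expect_equal(get("human"), "sequon")
  expect_equal(get("chimpanzee"), "no_sequon")   # DGS at the same columns
  expect_equal(get("gorilla"), "no_sequon")
  expect_equal(get("mouse"), "no_sequon")
  expect_equal(get("platypus"), "missing")       # all-gap window
  expect_equal(st$triplet[st$species == "human"], "NGS")
})

test_that("a site not at a consensus Asn is rejected", {
  aln <- panel_fixture_alignment()
  expect_error(species_motif_state(aln, 5L), "not at consensus")
  expect_error(species_motif_state(aln, 21L), "not at consensus")
})

test_that("states are invariant under an all-gap column outside the motif", {
  aln <- panel_fixture_alignment()
  st0 <- species_motif_state(aln, 13L)
  shifted <- aln
  shifted$rows <- vapply(aln$rows, function(s)
    paste0(substr(s, 1, 2), "-", substr(s, 3, nchar(s))), "")
  st1 <- species_motif_state(shifted, 13L)
  expect_equal(st1$state, st0$state)
  expect_equal(st1$triplet, st0$triplet)
})

test_that("columns and species_local modes agree without in-motif insertions", {
  for (seed in 1:5) {
    cfg <- sim_config(list(sim_event(25, "gain", clade = "cat")),
                      sequence_length = 50L, row_gap_prob = 0.3, seed = seed)
    sim <- simulate_dataset(cfg)
    a <- species_motif_state(sim$alignment, 25L, mode = "columns")
    b <- species_motif_state(sim$alignment, 25L, mode = "species_local")
    expect_equal(a$state, b$state)
  }
})

test_that("reference states agree with the sequon scanner", {
  set.seed(104)
  for (i in 1:10) {
    s <- random_protein(60)
    hits <- scan_sequons(s)$position
    hits <- hits[hits >= 3 & hits <= 49]
    aln <- ortho_alignment(c(human = s, chimpanzee = s), gene = "R")
    for (p in hits) {
      st <- species_motif_state(aln, p)
      expect_equal(st$state[st$species == "human"], "sequon")
    }
  }
})
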