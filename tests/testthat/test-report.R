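tax <- default_taxonomy()

test_that("clade counts aggregate passing records and satisfy the sum rule", {
  rec <- data.frame(status = c("pass", "pass", "pass", "fail"),
                    timing = c("hum", "hum", "sim", NA),
                    stringsAsFactors = FALSE)
  cc <- clade_counts(rec)
  expect_equal(unclass(cc)[["hum"]], 2L)
  expect_equal(unclass(cc)[["sim"]], 1L)
  expect_equal(attr(cc, "total"), 3L)
  expect_equal(sum(unclass(cc)), sum(rec$status == "pass"))
  empty <- clade_counts(rec[0, ])
  expect_true(all(unclass(empty) == 0L))
  expect_equal(attr(empty, "total"), 0L)
})

test_that("clade counts reproduce a simulated corpus profile", {
  corpus <- simulate_corpus(c("hum", "hum", "ape", "sim", "sim", "sim", "eua"),
                            seed = 12)
  scr <- run_screen(corpus$glycosites, corpus$alignments, taxonomy = tax)
  cc <- clade_counts(scr)
  expect_equal(attr(cc, "total"), sum(scr$records$status == "pass"))
  expect_equal(unclass(cc)[c("hum", "ape", "sim", "eua")],
               c(hum = 2L, ape = 1L, sim = 3L, eua = 1L))
})

test_that("alignment panels dot-encode against the spelled-out human row", {
  aln <- panel_fixture_alignment()
  panel <- render_alignment_panel(aln, 13L, taxonomy = tax)
  txt <- unclass(panel)
  human_line <- txt[grep("^human", txt)]
  win <- sub("^\\S+\\s+\\S+\\s+", "", human_line)
  # the human row is the literal window, never dots
  expect_false(grepl(".", win, fixed = TRUE))
  expect_equal(substr(win, 11, 13), "NGS")
  # chimp: a residue at the Asn column, dots where identical
  chimp_win <- sub("^\\S+\\s+\\S+\\s+", "", txt[grep("^chimpanzee", txt)])
  expect_equal(substr(chimp_win, 11, 11), "D")
  expect_equal(substr(chimp_win, 12, 13), "..")
  # gaps stay dashes; species identical to human would be all dots
  plat_win <- sub("^\\S+\\s+\\S+\\s+", "", txt[grep("^platypus", txt)])
  expect_match(plat_win, "^-+$")
  # ladder order: human first, chimpanzee second
  sp_lines <- txt[-1]
  expect_match(sp_lines[1], "^human")
  expect_match(sp_lines[2], "^chimpanzee")
})

test_that("dot-encoding round-trips the original residues", {
  aln <- panel_fixture_alignment()
  panel <- unclass(render_alignment_panel(aln, 13L, taxonomy = tax))
  wins <- sub("^\\S+\\s+\\S+\\s+", "", panel[-1])
  ids <- sub("\\s.*$", "", panel[-1])
  human_win <- wins[ids == "human"]
  for (k in seq_along(ids)) {
    decoded <- decode_panel_window(wins[k], human_win)
    chars <- strsplit(aln$rows[[ids[k]]], "")[[1]]
    # window columns 3..22 of this alignment (site 13, no human gaps)
    expect_equal(decoded, paste(chars[3:22], collapse = ""))
  }
})

test_that("a species identical to human renders as all dots", {
  rows <- c(human = "AAAANGSAAAAAAAAAAAAAA",
            chimpanzee = "AAAANGSAAAAAAAAAAAAAA")
  aln <- ortho_alignment(rows, gene = "X")
  panel <- unclass(render_alignment_panel(aln, 5L, taxonomy = tax))
  chimp_win <- sub("^\\S+\\s+\\S+\\s+", "", panel[grep("^chimpanzee", panel)])
  expect_match(chimp_win, "^-+\\.+$")   # left padding, then all dots
  expect_equal(sum(strsplit(chimp_win, "")[[1]] == "."), 14L)
})
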