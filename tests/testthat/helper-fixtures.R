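# Shared fixtures, built in code.

# Published branch/branch-site log-likelihoods for the three human-specific
# glycoprotein genes (six primate taxa each).
PUBLISHED_LNL <- list(
  APMAP = list(m0 = -2042.0968, free = -2035.7572, two = -2038.4530,
               modelA = -2038.4530, nullA = -2039.0253),
  CD166 = list(m0 = -2713.8934, free = -2709.9951, two = -2713.8904,
               modelA = -2713.8934, nullA = -2713.8934),
  TG    = list(m0 = -15128.0999, free = -15121.3529, two = -15124.3983,
               modelA = -15103.5548, nullA = -15104.1308)
)

# The published 20-mer windows around the three human-specific sites.
PUBLISHED_WINDOWS <- c(
  CD166 = "DDVPEYKDRLNLSENYTLSI",
  APMAP = "LSSETPIEGKNMSFVNDLTV",
  TG    = "DGRSCWCVGANGSEVLGSRQ"
)

# codeml-style main output with a given lnL/np (and optional omega lines /
# BEB block), for parser tests.
make_codeml_text <- function(lnL, np = 12L, ntime = 9L, omega = NULL,
                             branch_w = NULL, foreground_w = NULL,
                             beb = NULL) {
  lines <- c(
    "CODONML (in paml version 4.8a, August 2014)",
    "Model: One dN/dS ratio,",
    "",
    sprintf("lnL(ntime: %2d  np: %2d):  %s      +0.000000",
            ntime, np, formatC(lnL, format = "f", digits = 6))
  )
  if (!is.null(omega)) {
    lines <- c(lines, sprintf("omega (dN/dS) =  %.5f", omega))
  }
  if (!is.null(branch_w)) {
    lines <- c(lines, paste("w (dN/dS) for branches: ",
                            paste(formatC(branch_w, format = "f", digits = 5),
                                  collapse = "  ")))
  }
  if (!is.null(foreground_w)) {
    lines <- c(lines,
               "MLEs of dN/dS (w) for site classes (K=4)",
               paste("foreground w    ",
                     paste(formatC(foreground_w, format = "f", digits = 5),
                           collapse = "  ")))
  }
  if (!is.null(beb)) {
    lines <- c(lines,
               "Bayes Empirical Bayes (BEB) analysis (Yang, Wong & Nielsen 2005)",
               "Positively selected sites",
               sprintf("   %3d %s      %.3f", beb$position, beb$residue,
                       beb$posterior))
  }
  paste(lines, collapse = "\n")
}

# A small UniProt-style flat file: two entries, mixed evidence.
UNIPROT_FIXTURE <- paste(c(
  "ID   APMAP_HUMAN             Reviewed;         416 AA.",
  "AC   Q9HDC9; Q53T59;",
  "GN   Name=APMAP;",
  "FT   CARBOHYD    160    160       N-linked (GlcNAc...) asparagine;",
  "FT                                Potential.",
  "FT   CARBOHYD    196    196       N-linked (GlcNAc...) asparagine.",
  "FT   CARBOHYD    305    305       O-linked (GalNAc...) threonine.",
  "//",
  "ID   TEST2_HUMAN             Reviewed;          50 AA.",
  "AC   P00002;",
  "GN   Name=TEST2;",
  "FT   CARBOHYD     20     20       N-linked (GlcNAc...) (by similarity).",
  "FT   CARBOHYD     30     30       N-linked (GlcNAc...) asparagine.",
  "SQ   SEQUENCE   50 AA;",
  "     MKTAYIAKQR QISFVKSHFS RQLEERLGLI EVQAPILSRV GDGTQDNLSG",
  "//"), collapse = "\n")

# Hand-built five-species protein alignment with a human-specific sequon.
# Human NGS at ungapped position 13; chimpanzee DGS (the thyroglobulin-like
# pattern); one gapped row; one all-gap-window row.
panel_fixture_alignment <- function() {
  rows <- c(
    human      = "MDGRSCWCVGAVNGSEVLGSRQ",
    chimpanzee = "MDGRSCWCVGAVDGSEVLGSRQ",
    gorilla    = "MDGRSCWCVGAVDGSEVLGSRQ",
    mouse      = "MDGKSCWCVGAVDGSE--GSRQ",
    platypus   = "M---------------------"
  )
  ortho_alignment(rows, gene = "TGX", reference = "human")
}

# Build site_states directly (bypassing an alignment) for timing tests.
make_states <- function(taxonomy, sequon = character(),
                        missing = character()) {
  sp <- taxonomy$species$id
  state <- ifelse(sp %in% sequon, "sequon",
                  ifelse(sp %in% missing, "missing", "no_sequon"))
  structure(
    data.frame(species = sp, state = state,
               triplet = ifelse(state == "sequon", "NGS", "DGS"),
               stringsAsFactors = FALSE),
    gene = "FAKE", human_position = 50L, reference = "human",
    mode = "columns",
    class = c("site_states", "data.frame")
  )
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
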