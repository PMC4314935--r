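## Synthetic ortholog alignments with planted sequon gains/losses and known
## ground truth.  The generator emulates the pattern the screen assumes:
## a conserved background evolving by random substitutions down the
## human-lineage ladder, single motif gains on chosen ladder branches,
## optional independent outgroup gains (the whale/ruminant pattern),
## secondary losses, missing taxa and gap runs.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Declare a planted event for the simulator
#'
#' @param position 1-based position of the motif Asn on the simulated
#'   sequence.
#' @param kind \code{"gain"} (motif written on the branch into a ladder
#'   clade, inherited by all its species), \code{"ancestral_gain"} (motif
#'   present at the root of all mammals), \code{"loss"} (the Asn of an
#'   existing gain overwritten in chosen species), or
#'   \code{"outgroup_gain"} (motif written independently into chosen
#'   non-Euarchonta species).
#' @param clade Ladder clade code (gains only).
#' @param species Character vector of species (losses and outgroup gains).
#' @return A \code{sim_event} list.
#' @export
sim_event <- function(position,
                      kind = c("gain", "ancestral_gain", "loss",
                               "outgroup_gain"),
                      clade = NULL, species = NULL) {
  kind <- match.arg(kind)
  if (kind == "gain" && (is.null(clade) || !clade %in% ladder_clades())) {
    stop("a gain event needs a ladder clade code")
  }
  if (kind %in% c("loss", "outgroup_gain") && is.null(species)) {
    stop(kind, " events need target species")
  }
  structure(list(position = as.integer(position), kind = kind,
                 clade = clade, species = species),
            class = "sim_event")
}

#' Simulator configuration
#'
#' @param events List of [sim_event()] objects.
#' @param sequence_length Length of the simulated protein (default 300).
#' @param branch_rate Poisson mean of substitutions per site per branch
#'   (default 0.02); replacements are drawn uniformly from the 19
#'   alternative residues.  Substitutions never touch planted motif
#'   triplets.
#' @param missing_taxon_prob Probability that a non-human species is
#'   dropped from the alignment (default 0).
#' @param row_gap_prob Probability that a non-human row receives one gap
#'   run of 5-20 columns (default 0); gap runs avoid planted motifs so the
#'   planted truth stays well defined.
#' @param gene,accession Labels written to the outputs.
#' @param seed Mandatory integer seed; the same seed gives byte-identical
#'   outputs.
#' @param taxonomy A \code{glygain_taxonomy} (default: the 62-mammal
#'   roster).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(events, sequence_length = 300L, branch_rate = 0.02,
                       missing_taxon_prob = 0, row_gap_prob = 0,
                       gene = "SIM1", accession = "P99901", seed,
                       taxonomy = default_taxonomy()) {
  if (missing(seed)) stop("a seed is mandatory")
  if (inherits(events, "sim_event")) events <- list(events)
  pos <- vapply(events, function(e) e$position, 1L)
  if (any(pos < 11L) || any(pos > sequence_length - 9L)) {
    stop("planted positions must lie in [11, length - 9] so the 20-mer ",
         "window fits")
  }
  gainish <- vapply(events, function(e) e$kind %in% c("gain", "ancestral_gain"),
                    TRUE)
  if (anyDuplicated(pos[gainish])) {
    stop("colliding events: two gains planted at one position")
  }
  for (e in events) {
    if (e$kind == "loss" && !e$position %in% pos[gainish]) {
      stop("loss event at position ", e$position,
           " does not match any planted gain")
    }
    if (e$kind == "outgroup_gain" &&
        any(vapply(e$species, function(s) is_euarchont(taxonomy, s), TRUE))) {
      stop("outgroup_gain targets must be non-Euarchonta species")
    }
  }
  structure(list(events = events, sequence_length = as.integer(sequence_length),
                 branch_rate = branch_rate,
                 missing_taxon_prob = missing_taxon_prob,
                 row_gap_prob = row_gap_prob, gene = gene,
                 accession = accession, seed = seed, taxonomy = taxonomy),
            class = "sim_config")
}

## substitutions on one branch: n ~ Poisson(rate * L), positions uniform
## outside the protected set, replacement uniform over the 19 alternatives
mutate_branch <- function(chars, rate, protected) {
  n <- stats::rpois(1L, rate * length(chars))
  free <- setdiff(seq_along(chars), protected)
  if (n == 0L || length(free) == 0L) return(chars)
  at <- sample(free, min(n, length(free)), replace = FALSE)
  for (i in at) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

write_motif <- function(chars, p) {
  chars[p] <- "N"
  chars[p + 1L] <- sample(setdiff(AA20, "P"), 1L)
  chars[p + 2L] <- sample(c("S", "T"), 1L)
  chars
}

write_non_motif <- function(chars, p) {
  chars[p] <- sample(setdiff(AA20, "N"), 1L)
  chars[p + 1L] <- sample(AA20, 1L)
  chars[p + 2L] <- sample(setdiff(AA20, c("S", "T")), 1L)
  chars
}

#' Simulate an ortholog alignment with planted sequon events
#'
#' The root sequence is drawn uniformly over the 20 amino acids, with
#' planted positions rewritten to a guaranteed non-motif baseline (or to the
#' motif, for ancestral gains).  The sequence then evolves down the ladder:
#' each internal node applies Poisson substitutions to its parent's
#' sequence, gain events write the motif at their clade's ancestor so every
#' descendant inherits it, loss and outgroup-gain events edit the chosen
#' tips, and missing taxa / gap runs are applied per the configuration.
#' Outgroup species hang from their group's ancestor as a star (only clade
#' membership, not outgroup topology, matters to the screen).
#'
#' @param config A [sim_config()].
#' @return A list with \code{alignment} (an \code{ortho_alignment} over the
#'   taxonomy roster), \code{flatfile} (UniProt-style feature-table text
#'   listing every planted human-carried site as an experimentally verified
#'   CARBOHYD feature), and \code{truth} (data frame: position, kind, true
#'   timing clade, expected screen outcome).
#' @export
simulate_dataset <- function(config) {
  tax <- config$taxonomy
  with_seed(config$seed, {
    L <- config$sequence_length
    events <- config$events
    protected <- unique(unlist(lapply(events, function(e) e$position + 0:2)))

    root <- sample(AA20, L, replace = TRUE)
    for (e in events) {
      if (e$kind == "ancestral_gain") {
        root <- write_motif(root, e$position)
      } else if (e$kind %in% c("gain")) {
        root <- write_non_motif(root, e$position)
      }
    }
    ## outgroup_gain positions without a ladder gain also start as non-motif
    for (e in events) {
      if (e$kind == "outgroup_gain" &&
          !any(vapply(events, function(x)
            x$kind %in% c("gain", "ancestral_gain") &&
            x$position == e$position, TRUE))) {
        root <- write_non_motif(root, e$position)
      }
    }

    mu <- config$branch_rate
    node_seq <- list(root = root)
    ladder_inward <- rev(ladder_clades())   # eua, pri, ..., hum
    parent <- c(stats::setNames(c("root", ladder_inward[-length(ladder_inward)]),
                                ladder_inward),
                stats::setNames(rep("root", 6L), outgroup_clades()))
    for (node in c(ladder_inward, outgroup_clades())) {
      s <- mutate_branch(node_seq[[parent[node]]], mu, protected)
      for (e in events) {
        if (e$kind == "gain" && identical(e$clade, node)) {
          s <- write_motif(s, e$position)
        }
      }
      node_seq[[node]] <- s
    }

    sp <- tax$species
    rows <- character(nrow(sp))
    names(rows) <- sp$id
    for (i in seq_len(nrow(sp))) {
      id <- sp$id[i]
      s <- mutate_branch(node_seq[[sp$group[i]]], mu, protected)
      for (e in events) {
        if (e$kind == "loss" && id %in% e$species) {
          s[e$position] <- sample(setdiff(AA20, "N"), 1L)
        }
        if (e$kind == "outgroup_gain" && id %in% e$species) {
          s <- write_motif(s, e$position)
        }
      }
      rows[id] <- paste(s, collapse = "")
    }

    ## missing taxa and gap runs (never the human reference row)
    non_ref <- setdiff(names(rows), "human")
    drop <- non_ref[stats::runif(length(non_ref)) < config$missing_taxon_prob]
    rows <- rows[!names(rows) %in% drop]
    if (config$row_gap_prob > 0) {
      for (id in setdiff(names(rows), "human")) {
        if (stats::runif(1L) >= config$row_gap_prob) next
        len <- sample(5:20, 1L)
        for (try in 1:20) {
          start <- sample(seq_len(L - len + 1L), 1L)
          if (!any(seq(start, start + len - 1L) %in% protected)) {
            chars <- strsplit(rows[[id]], "")[[1]]
            chars[seq(start, start + len - 1L)] <- "-"
            rows[id] <- paste(chars, collapse = "")
            break
          }
        }
      }
    }

    aln <- ortho_alignment(rows, gene = config$gene, reference = "human")

    ## truth and flatfile: which planted sites does the human row carry?
    human_chars <- strsplit(rows[["human"]], "")[[1]]
    truth <- do.call(rbind, lapply(events, function(e) {
      n_out <- sum(!vapply(sp$id, function(s) is_euarchont(tax, s), TRUE))
      og <- sum(vapply(events, function(x)
        x$kind %in% c("outgroup_gain") && x$position == e$position,
        TRUE) * vapply(events, function(x) length(x$species), 1L))
      n_loss_out <- sum(unlist(lapply(events, function(x) {
        if (x$kind == "loss" && x$position == e$position) {
          sum(!vapply(x$species, function(s) is_euarchont(tax, s), TRUE))
        } else 0L
      })))
      frac <- switch(e$kind,
        ancestral_gain = (n_out - n_loss_out) / n_out,
        (og) / n_out)
      timing <- switch(e$kind,
        gain = e$clade,
        ancestral_gain = "eua",
        NA_character_)
      human_has <- e$kind %in% c("gain", "ancestral_gain") &&
        !any(vapply(events, function(x)
          x$kind == "loss" && x$position == e$position &&
            "human" %in% x$species, TRUE))
      expected <- if (!human_has) {
        "not_annotated"
      } else if (frac > 0.30) {
        "discard"
      } else {
        "pass"
      }
      data.frame(position = e$position, kind = e$kind,
                 timing = timing, outgroup_fraction = frac,
                 expected = expected, human_carries = human_has,
                 stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL

    annotated <- truth$position[truth$human_carries]
    seq_str <- paste(human_chars, collapse = "")
    ft <- vapply(sort(annotated), function(p) {
      sprintf("FT   CARBOHYD    %5d %6d       N-linked (GlcNAc...) asparagine.",
              p, p)
    }, "")
    starts <- seq(1L, nchar(seq_str), by = 60L)
    sq <- paste0("     ",
                 substring(seq_str, starts,
                           pmin(starts + 59L, nchar(seq_str))))
    flat <- paste(c(
      sprintf("ID   %s_HUMAN            Reviewed;      %d AA.",
              config$gene, L),
      sprintf("AC   %s;", config$accession),
      sprintf("GN   Name=%s;", config$gene),
      ft,
      sprintf("SQ   SEQUENCE   %d AA;", L),
      sq,
      "//"), collapse = "\n")

    list(alignment = aln, flatfile = flat, truth = truth, config = config)
  })
}

#' Simulate a corpus of single-site ortholog alignments
#'
#' Generates one small alignment per planted gain (one gene, one site each)
#' and pools the feature-file records, ready for [run_screen()].  Used for
#' the timing-recovery studies: the default planted-timing mix follows the
#' empirically observed per-branch gain profile in the human lineage
#' (3/2/10/4/12/16/45/15/5 for hum..eua), scaled to the requested corpus
#' size.
#'
#' @param clades Character vector of planted ladder clades, one per site
#'   (e.g. \code{profile_clades(200)}).
#' @param sequence_length,branch_rate,missing_taxon_prob,row_gap_prob
#'   Passed to [sim_config()] per site.
#' @param seed Mandatory base seed; site \code{i} uses \code{seed + i}.
#' @param taxonomy A \code{glygain_taxonomy}.
#' @return A list with \code{glycosites} (pooled feature data frame with
#'   attached human sequences), \code{alignments} (named list of
#'   \code{ortho_alignment}), and \code{truth} (data frame with gene,
#'   position and planted timing).
#' @export
simulate_corpus <- function(clades, sequence_length = 60L, branch_rate = 0.02,
                            missing_taxon_prob = 0, row_gap_prob = 0, seed,
                            taxonomy = default_taxonomy()) {
  if (missing(seed)) stop("a seed is mandatory")
  n <- length(clades)
  alignments <- vector("list", n)
  glyco <- vector("list", n)
  seqs <- character(n)
  genes <- sprintf("SIM%04d", seq_len(n))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- 11L + ((seed + i) %% (sequence_length - 19L))
    cfg <- sim_config(list(sim_event(pos, "gain", clade = clades[i])),
                      sequence_length = sequence_length,
                      branch_rate = branch_rate,
                      missing_taxon_prob = missing_taxon_prob,
                      row_gap_prob = row_gap_prob,
                      gene = genes[i],
                      accession = sprintf("P9%05d", i),
                      seed = seed + i, taxonomy = taxonomy)
    sim <- simulate_dataset(cfg)
    alignments[[i]] <- sim$alignment
    gs <- parse_uniprot_glycosites(sim$flatfile)
    glyco[[i]] <- gs
    seqs[i] <- attr(gs, "sequences")[[genes[i]]]
    truth[[i]] <- data.frame(gene = genes[i], position = pos,
                             timing = clades[i], stringsAsFactors = FALSE)
  }
  names(alignments) <- genes
  glycosites <- do.call(rbind, glyco)
  attr(glycosites, "sequences") <- stats::setNames(seqs, genes)
  list(glycosites = glycosites, alignments = alignments,
       truth = do.call(rbind, truth))
}

#' Planted-clade profile for a simulated corpus
#'
#' The per-branch gain counts observed in the human lineage
#' (hum 3, hac 2, aga 10, gra 4, ape 12, cat 16, sim 45, pri 15, eua 5;
#' total 112), scaled to \code{n} sites by largest-remainder rounding.
#'
#' @param n Corpus size (default 112, the unscaled profile).
#' @return Character vector of length \code{n} of ladder clade codes.
#' @export
profile_clades <- function(n = 112L) {
  profile <- c(hum = 3, hac = 2, aga = 10, gra = 4, ape = 12, cat = 16,
               sim = 45, pri = 15, eua = 5)
  raw <- profile * n / sum(profile)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  rep(names(profile), counts)
}

#' Planted event set for an ancestrally conserved site
#'
#' Produces the discard class the screen must reject: the motif is present
#' at the root of all mammals and retained in a chosen fraction of outgroup
#' species.  With \code{decay_fraction = 0} every outgroup carries it
#' (ancestral fraction 1.0, discarded); decaying it in more than 70\% of
#' outgroups drops the fraction below the 30\% threshold (a designed false
#' positive for threshold studies).  Decayed species are the first
#' \code{k} outgroup species in roster order, so the event set is
#' deterministic.
#'
#' @param position 1-based motif position.
#' @param decay_fraction Fraction of outgroup species in which the motif has
#'   decayed (default 0).
#' @param taxonomy A \code{glygain_taxonomy}.
#' @return A list of [sim_event()] objects.
#' @export
make_background_conserved_site <- function(position, decay_fraction = 0,
                                           taxonomy = default_taxonomy()) {
  out_sp <- taxonomy$species$id[!taxonomy$species$group %in% ladder_clades()]
  k <- round(decay_fraction * length(out_sp))
  ev <- list(sim_event(position, "ancestral_gain"))
  if (k > 0L) {
    ev <- c(ev, list(sim_event(position, "loss", species = out_sp[seq_len(k)])))
  }
  ev
}
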