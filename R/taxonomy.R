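## Clade ladder and species roster.
##
## The human-lineage clade ladder is the nested series
## hum < hac < aga < gra < ape < cat < sim < pri < eua
## (humans; humans+chimpanzees; African great apes; great apes; apes;
## catarrhines; simians; primates; Euarchonta).  Everything outside eua is
## partitioned into the outgroup groups gli (Glires), lau (Laurasiatheria),
## afr (Afrotheria), xen (Xenarthra), mar (Marsupialia), mon (Monotremata).

#' Clade codes of the human-lineage ladder
#'
#' Ordered innermost (humans) to outermost (Euarchonta).
#' @return Character vector of the nine ladder clade codes.
#' @export
ladder_clades <- function() {
  c("hum", "hac", "aga", "gra", "ape", "cat", "sim", "pri", "eua")
}

#' Outgroup group codes
#'
#' The six non-Euarchonta groups, in the conventional rendering order.
#' @return Character vector of the six outgroup codes.
#' @export
outgroup_clades <- function() {
  c("gli", "lau", "afr", "xen", "mar", "mon")
}

norm_species_id <- function(x) {
  gsub("[ .-]+", "_", tolower(trimws(x)))
}

#' Read a taxonomy configuration file
#'
#' The file is tab-separated text with one species per line:
#' \code{id <TAB> group <TAB> comma-separated-aliases} (aliases optional).
#' \code{group} is the innermost ladder clade the species belongs to, or one
#' of the outgroup codes.  Lines starting with \code{#} are comments.
#' Species ids and aliases are matched case-insensitively after trimming;
#' spaces, dots and hyphens are treated as underscores.
#'
#' On load the ladder nesting invariant is checked: every ladder clade must
#' have at least one member so that the cumulative clade sizes are strictly
#' increasing from \code{hum} to \code{eua}.
#'
#' @param path Path to the config file.
#' @return A \code{glygain_taxonomy} object.
#' @seealso [default_taxonomy()]
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed taxonomy line (need at least id<TAB>group): ",
         lines[bad[1]])
  }
  id <- norm_species_id(vapply(parts, `[`, "", 1L))
  group <- tolower(trimws(vapply(parts, `[`, "", 2L)))
  aliases <- lapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(trimws(p[3L]))) {
      norm_species_id(strsplit(p[3L], ",", fixed = TRUE)[[1L]])
    } else {
      character()
    }
  })
  new_taxonomy(data.frame(id = id, group = group, stringsAsFactors = FALSE),
               aliases)
}

new_taxonomy <- function(species, aliases) {
  codes <- c(ladder_clades(), outgroup_clades())
  if (anyDuplicated(species$id)) {
    stop("duplicate species id: ",
         species$id[duplicated(species$id)][1L])
  }
  unknown <- setdiff(species$group, codes)
  if (length(unknown)) {
    stop("unknown clade code(s): ", paste(unknown, collapse = ", "))
  }
  ## alias map: alias -> canonical id (ids map to themselves)
  amap <- stats::setNames(species$id, species$id)
  for (i in seq_along(aliases)) {
    al <- aliases[[i]]
    clash <- intersect(al, names(amap))
    if (length(clash)) stop("alias clashes with existing id/alias: ", clash[1L])
    amap[al] <- species$id[i]
  }
  tax <- structure(
    list(species = species, alias_map = amap),
    class = "glygain_taxonomy"
  )
  ## ladder nesting: cumulative sizes strictly increasing
  sizes <- vapply(ladder_clades(), function(cl) length(clade_members(tax, cl)), 1L)
  if (any(diff(sizes) <= 0L) || sizes[1L] < 1L) {
    stop("ladder nesting violated: every ladder clade needs >= 1 member ",
         "so cumulative sizes increase strictly (got ",
         paste(sizes, collapse = " < "), ")")
  }
  tax
}

#' Default 62-mammal taxonomy
#'
#' The packaged roster: humans plus 12 other Euarchonta species, 13 Glires,
#' 25 Laurasiatheria, 6 Afrotheria, 1 Xenarthra, 3 Marsupialia and
#' 1 Monotremata species, with UCSC genome-assembly codes as aliases.
#'
#' @return A \code{glygain_taxonomy} with 62 species.
#' @export
default_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "mammals62.tsv", package = "glygain",
                            mustWork = TRUE))
}

#' Resolve a species id or alias to its canonical id
#'
#' @param taxonomy A \code{glygain_taxonomy}.
#' @param id Species id or alias (case-insensitive).
#' @param quiet If \code{TRUE}, return \code{NA} instead of erroring on an
#'   unknown id.
#' @return Canonical species id.
#' @export
resolve_species <- function(taxonomy, id, quiet = FALSE) {
  key <- norm_species_id(id)
  hit <- taxonomy$alias_map[key]
  if (is.na(hit)) {
    if (quiet) return(NA_character_)
    stop("unknown species id: '", id, "'")
  }
  unname(hit)
}

species_group <- function(taxonomy, id) {
  id <- resolve_species(taxonomy, id)
  taxonomy$species$group[match(id, taxonomy$species$id)]
}

#' Members of a clade
#'
#' For a ladder clade the member set is cumulative (e.g. \code{aga} contains
#' humans, chimpanzees and gorillas); for an outgroup code it is that group.
#'
#' @param taxonomy A \code{glygain_taxonomy}.
#' @param clade A clade code.
#' @return Character vector of species ids.
#' @export
clade_members <- function(taxonomy, clade) {
  lad <- ladder_clades()
  sp <- taxonomy$species
  if (clade %in% lad) {
    keep <- lad[seq_len(match(clade, lad))]
    sp$id[sp$group %in% keep]
  } else if (clade %in% outgroup_clades()) {
    sp$id[sp$group == clade]
  } else {
    stop("unknown clade code: ", clade)
  }
}

#' Ladder clades containing a species
#'
#' @param taxonomy A \code{glygain_taxonomy}.
#' @param species Species id or alias.
#' @return For a Euarchonta species, the contiguous suffix of the ladder from
#'   its innermost clade outwards (innermost first); for an outgroup species,
#'   an empty character vector.
#' @examples
#' tax <- default_taxonomy()
#' clades_containing(tax, "human")       # all nine ladder clades
#' clades_containing(tax, "chimpanzee")  # hac .. eua
#' clades_containing(tax, "mouse")       # character(0)
#' @export
clades_containing <- function(taxonomy, species) {
  g <- species_group(taxonomy, species)
  lad <- ladder_clades()
  if (!g %in% lad) return(character())
  lad[seq(match(g, lad), length(lad))]
}

#' Is a species a euarchont?
#'
#' @inheritParams clades_containing
#' @return \code{TRUE} iff the species belongs to the Euarchonta clade
#'   (primates and treeshrews).
#' @export
is_euarchont <- function(taxonomy, species) {
  species_group(taxonomy, species) %in% ladder_clades()
}

#' Deepest ladder clade shared by a set of species
#'
#' @param taxonomy A \code{glygain_taxonomy}.
#' @param species Non-empty character vector of species ids/aliases.
#' @return The innermost (least inclusive) ladder clade containing every
#'   member, or \code{NA_character_} if any member is a non-Euarchonta
#'   outgroup species.
#' @export
deepest_shared_clade <- function(taxonomy, species) {
  if (length(species) == 0L) stop("empty species set")
  groups <- vapply(species, function(s) species_group(taxonomy, s), "")
  lad <- ladder_clades()
  if (!all(groups %in% lad)) return(NA_character_)
  lad[max(match(groups, lad))]
}

#' @export
print.glygain_taxonomy <- function(x, ...) {
  n <- nrow(x$species)
  lad <- ladder_clades()
  sizes <- vapply(lad, function(cl) length(clade_members(x, cl)), 1L)
  cat("glygain taxonomy:", n, "species\n")
  cat("  ladder: ", paste(sprintf("%s(%d)", lad, sizes), collapse = " < "),
      "\n", sep = "")
  og <- vapply(outgroup_clades(),
               function(cl) sum(x$species$group == cl), 1L)
  cat("  outgroups: ",
      paste(sprintf("%s(%d)", names(og), og), collapse = " "), "\n", sep = "")
  invisible(x)
}
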