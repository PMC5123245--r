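# Five-field structural annotation of mt-tRNA positions:
# Sprinzl number; tRNA type; cloverleaf domain; mature nucleotide; folding flag.

# Canonical cloverleaf layout over Sprinzl numbers 1-73 (CCA end excluded):
# acceptor stem 1-7/66-72, D arm 10-13/14-21/22-25, anticodon arm 27-31/32-38/
# 39-43 (anticodon 34-36), variable loop 44-48, T arm 49-53/54-60/61-65,
# junctions 8-9 and 26, discriminator 73 (3' end, E).
canonical_domain_table <- function() {
  data.frame(
    from = c(1L, 8L, 10L, 14L, 22L, 26L, 27L, 32L, 39L, 44L, 49L, 54L, 61L, 66L, 73L),
    to   = c(7L, 9L, 13L, 21L, 25L, 26L, 31L, 38L, 43L, 48L, 53L, 60L, 65L, 72L, 73L),
    domain = c("AS", "-", "DS", "DL", "DS", "-", "CS", "CL", "CS", "VL",
               "TS", "TL", "TS", "AS", "E"),
    stringsAsFactors = FALSE)
}

# The three canonical base triplets stabilizing the L-shaped fold.
CANONICAL_TRIPLETS <- list(c(10L, 25L, 45L), c(9L, 12L, 23L), c(13L, 22L, 46L))
# D-loop/T-loop pairing of quasi-canonical (type 0) tRNAs.
DT_LOOP_PAIRS <- list(c(18L, 55L), c(19L, 56L))

new_trna_annotation <- function(gene, sprinzl, trna_type, domain, mature_nt, folding) {
  structure(list(gene = gene, sprinzl = sprinzl, trna_type = trna_type,
                 domain = domain, mature_nt = mature_nt, folding = folding),
            class = "trna_annotation")
}

#' Structural annotation of one rCRS position inside a tRNA gene
#'
#' The gene offset is computed along the tRNA's own 5'->3' direction (reverse
#' order for light-strand-transcribed genes). Positions shared by two
#' overlapping tRNA genes are annotated in the context of the gene starting
#' first. Returns `NULL` outside tRNA genes.
#'
#' @param pos rCRS coordinate.
#' @param bundle a loaded reference bundle.
#' @return a `trna_annotation` or `NULL`.
#' @examples
#' a <- annotate_trna_position(4450, default_bundle())
#' format_trna_annotation(a)  # "53;II;TS;G;N"
#' @export
annotate_trna_position <- function(pos, bundle) {
  loci <- locate_position(pos, bundle)
  loci <- loci[loci$biotype == "tRNA", , drop = FALSE]
  if (!nrow(loci)) return(NULL)
  gene <- as.list(loci[1L, ])
  map <- bundle$trna_maps[[gene$name]]
  if (is.null(map))
    mva_stop("no structure map for tRNA gene ", gene$name,
             class = "mva_data_integrity_error")
  offset <- if (identical(gene$strand, "L")) gene$end - pos + 1L else pos - gene$start + 1L
  row <- map$positions[map$positions$offset == offset, , drop = FALSE]
  if (nrow(row) != 1L)
    mva_stop("structure map of ", gene$name, " does not cover offset ", offset,
             class = "mva_data_integrity_error")
  new_trna_annotation(gene$name, row$sprinzl, map$trna_type, row$domain,
                      row$mature_nt, row$folding)
}

#' Format the five-field tRNA annotation string
#'
#' Fields are semicolon-separated with no spaces; an unmapped Sprinzl position
#' renders as "-" in the first field.
#' @param a a `trna_annotation`.
#' @export
format_trna_annotation <- function(a) {
  stopifnot(inherits(a, "trna_annotation"))
  if (!a$domain %in% TRNA_DOMAINS)
    mva_stop("unknown cloverleaf domain code '", a$domain, "'",
             class = "mva_format_error")
  if (!a$trna_type %in% TRNA_TYPES)
    mva_stop("unknown tRNA type '", a$trna_type, "'", class = "mva_format_error")
  paste(c(if (is.na(a$sprinzl)) "-" else as.character(a$sprinzl),
          a$trna_type, a$domain, a$mature_nt, a$folding), collapse = ";")
}

#' Parse a five-field tRNA annotation string
#' @param s string as produced by [format_trna_annotation()].
#' @param gene optional gene symbol to attach.
#' @export
parse_trna_annotation <- function(s, gene = NA_character_) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  if (length(parts) != 5L)
    mva_stop("tRNA annotation must have five ';'-separated fields: '", s, "'",
             class = "mva_format_error")
  if (!parts[3L] %in% TRNA_DOMAINS)
    mva_stop("unknown cloverleaf domain code '", parts[3L], "'",
             class = "mva_format_error")
  new_trna_annotation(gene,
                      if (parts[1L] == "-") NA_integer_ else as.integer(parts[1L]),
                      parts[2L], parts[3L], parts[4L], parts[5L])
}

#' @export
print.trna_annotation <- function(x, ...) {
  cat(sprintf("<trna_annotation> %s %s\n",
              if (is.na(x$gene)) "" else x$gene, format_trna_annotation(x)))
  invisible(x)
}

#' Assemble and validate a tRNA structure map
#'
#' @param gene list or one-row data frame with `name`, `start`, `end`,
#'   `strand` (gene locus on the reference).
#' @param sprinzl_alignment data frame with columns `offset`, `sprinzl`
#'   (integer or NA for structural-alignment gaps) and `base` (DNA base of the
#'   gene read 5'->3'), one row per gene offset.
#' @param domains data frame `from`,`to`,`domain` partitioning Sprinzl 1-73;
#'   defaults to the canonical cloverleaf layout.
#' @param mods modification records (`position`, `modomics_symbol`, `trna`);
#'   mature nucleotides are overridden wherever (species, Sprinzl) matches.
#' @param tertiary list of integer vectors (pairs/triplets of Sprinzl numbers
#'   participating in tertiary folding).
#' @param trna_type one of "0", "I", "II", "III".
#' @param species tRNA species name used for modification lookup.
#' @param provenance free-text provenance label stored with the map.
#' @return a validated `trna_structure_map`.
#' @export
build_structure_map <- function(gene, sprinzl_alignment,
                                domains = canonical_domain_table(),
                                mods = NULL, tertiary = list(),
                                trna_type = "II",
                                species = unname(TRNA_SPECIES[gene$name]),
                                provenance = "curated") {
  gene <- as.list(gene)
  aln <- sprinzl_alignment
  stopifnot(all(c("offset", "sprinzl", "base") %in% names(aln)))
  aln <- aln[order(aln$offset), , drop = FALSE]
  if (!identical(as.integer(aln$offset), seq_len(nrow(aln))))
    mva_stop("alignment must cover every gene offset exactly once",
             class = "mva_build_error")
  sp <- aln$sprinzl[!is.na(aln$sprinzl)]
  if (length(sp) > 1L && any(diff(sp) <= 0L))
    mva_stop("alignment is non-monotone: Sprinzl numbers must increase with offset",
             class = "mva_build_error")
  cover <- rep(NA_character_, 73L)
  for (i in seq_len(nrow(domains))) {
    idx <- domains$from[i]:domains$to[i]
    if (any(!is.na(cover[idx])))
      mva_stop("domain ranges overlap at Sprinzl ",
               idx[!is.na(cover[idx])][1L], class = "mva_build_error")
    cover[idx] <- domains$domain[i]
  }
  if (any(is.na(cover)))
    mva_stop("domain ranges must partition Sprinzl 1..73",
             class = "mva_build_error")
  if (any(cover[34:36] != "CL"))
    mva_stop("Sprinzl 34-36 (anticodon triplet) must be assigned domain CL",
             class = "mva_build_error")

  domain <- ifelse(is.na(aln$sprinzl), "-", cover[aln$sprinzl])
  tert_members <- unique(unlist(tertiary))
  folding <- ifelse(!is.na(aln$sprinzl) & aln$sprinzl %in% tert_members, "Y", "N")
  mature <- dna_to_rna(toupper(aln$base))
  if (!is.null(mods) && !is.na(species)) {
    gm <- mods[mods$trna == species, , drop = FALSE]
    for (i in seq_len(nrow(aln))) {
      if (is.na(aln$sprinzl[i])) next
      hit <- gm[gm$position == aln$sprinzl[i], , drop = FALSE]
      if (nrow(hit)) {
        # Alternative modifications at one residue: prefer human evidence,
        # then bovine, then model organisms; first table row breaks ties.
        pref <- order(match(hit$evidence, c("human", "bovine", "model_organism")))
        mature[i] <- hit$modomics_symbol[pref[1L]]
      }
    }
  }
  map <- structure(list(
    gene = gene$name, species = species %||% NA_character_,
    trna_type = trna_type, provenance = provenance,
    positions = data.frame(offset = as.integer(aln$offset),
                           sprinzl = as.integer(aln$sprinzl),
                           domain = domain, mature_nt = mature,
                           folding = folding, stringsAsFactors = FALSE),
    tertiary = tertiary), class = "trna_structure_map")
  validate_structure_map(map, gene,
                         mods %||% data.frame(position = integer(),
                                              modomics_symbol = character(),
                                              trna = character()),
                         max(gene$end, gene$start))
  map
}
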