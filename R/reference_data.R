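# Reference bundle: curated annotation tables on rCRS coordinates, their
# on-disk format, cross-validation at load time, and position-to-locus lookup.

BUNDLE_FILES <- c("manifest.json", "genes.tsv", "trna_structure.tsv",
                  "trna_tertiary.tsv", "modifications.tsv", "rna_patho.tsv",
                  "passthrough.tsv")

GENE_BIOTYPES <- c("tRNA", "rRNA", "protein_coding", "control", "other")
TRNA_DOMAINS <- c("AS", "DS", "DL", "CS", "CL", "VL", "TS", "TL", "E", "-")
TRNA_TYPES <- c("0", "I", "II", "III")

#' tRNA species encoded by each human mt-tRNA gene
#'
#' Amino-acid three-letter code with codon-family suffix where a species is
#' duplicated (Leu(UUR)/Leu(CUN), Ser(UCN)/Ser(AGY)), the naming used by the
#' modification table.
#' @export
TRNA_SPECIES <- c(
  "MT-TF" = "Phe", "MT-TV" = "Val", "MT-TL1" = "Leu(UUR)", "MT-TI" = "Ile",
  "MT-TQ" = "Gln", "MT-TM" = "Met", "MT-TW" = "Trp", "MT-TA" = "Ala",
  "MT-TN" = "Asn", "MT-TC" = "Cys", "MT-TY" = "Tyr", "MT-TS1" = "Ser(UCN)",
  "MT-TD" = "Asp", "MT-TK" = "Lys", "MT-TG" = "Gly", "MT-TR" = "Arg",
  "MT-TH" = "His", "MT-TS2" = "Ser(AGY)", "MT-TL2" = "Leu(CUN)",
  "MT-TE" = "Glu", "MT-TT" = "Thr", "MT-TP" = "Pro")

# DNA base each Modomics symbol derives from (gene-level identity of the
# modified residue). Symbols follow the modification table exactly.
MODOMICS_PARENT_BASE <- c(
  "\"" = "A",      # 1-methyladenosine
  "K"  = "G",      # 1-methylguanosine
  "L"  = "G",      # N2-methylguanosine
  "D"  = "T",      # dihydrouridine
  "R"  = "G",      # N2,N2-dimethylguanosine
  "P"  = "T",      # pseudouridine
  "'"  = "C",      # 3-methylcytidine
  "Ê" = "T",  # 5-taurinomethyluridine
  "Q"  = "G",      # queuosine
  "Ǝ" = "T",  # 5-taurinomethyl-2-thiouridine
  ">"  = "C",      # 5-formylcytidine
  "6"  = "A",      # N6-threonylcarbamoyladenosine
  "+"  = "A",      # N6-isopentenyladenosine
  "*"  = "A",      # 2-methylthio-N6-isopentenyladenosine
  "?"  = "C",      # 5-methylcytidine
  "T"  = "T")      # 5-methyluridine (ribothymidine)

#' Number of reference positions covered by a locus
#'
#' Handles a locus wrapping the origin of the circular genome (end < start).
#' @param start,end 1-based inclusive coordinates.
#' @param genome_length circular genome length.
#' @export
locus_length <- function(start, end, genome_length = RCRS_LENGTH) {
  ifelse(end >= start, end - start + 1L, genome_length - start + 1L + end)
}

# Reference positions of a locus in its transcription (5'->3') order.
locus_positions <- function(gene, genome_length = RCRS_LENGTH) {
  fwd <- if (gene$end >= gene$start) seq.int(gene$start, gene$end)
         else c(seq.int(gene$start, genome_length), seq.int(1L, gene$end))
  if (identical(gene$strand, "L")) rev(fwd) else fwd
}

#' Resolve a genomic position to the loci containing it
#'
#' @param pos 1-based rCRS coordinate.
#' @param bundle a loaded reference bundle.
#' @return data frame of gene loci (possibly 0-row) ordered by start.
#' @examples
#' b <- default_bundle()
#' locate_position(4450, b)$name  # "MT-TM"
#' @export
locate_position <- function(pos, bundle) {
  stopifnot(inherits(bundle, "mito_bundle"))
  gl <- genome_length(bundle)
  if (!is.numeric(pos) || length(pos) != 1L || is.na(pos) || pos < 1 || pos > gl)
    mva_stop("position ", pos, " outside genome bounds 1..", gl,
             class = "mva_range_error")
  g <- bundle$genes
  hit <- ifelse(g$end >= g$start,
                pos >= g$start & pos <= g$end,
                pos >= g$start | pos <= g$end)
  out <- g[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Genome length declared by a bundle's manifest
#' @param bundle a loaded reference bundle.
#' @export
genome_length <- function(bundle) as.integer(bundle$manifest$genome_length)

parse_structure_table <- function(struct, tert, genes, mods) {
  maps <- list()
  for (gname in unique(struct$gene)) {
    rows <- struct[struct$gene == gname, , drop = FALSE]
    rows <- rows[order(as.integer(rows$offset)), , drop = FALSE]
    members <- tert$members[tert$gene == gname]
    tertiary <- lapply(strsplit(members, ";", fixed = TRUE), as.integer)
    maps[[gname]] <- structure(list(
      gene = gname,
      species = rows$species[1L],
      trna_type = rows$trna_type[1L],
      provenance = rows$provenance[1L],
      positions = data.frame(
        offset = as.integer(rows$offset),
        sprinzl = suppressWarnings(as.integer(ifelse(rows$sprinzl == "-", NA,
                                                     rows$sprinzl))),
        domain = rows$domain,
        mature_nt = rows$mature_nt,
        folding = rows$folding,
        stringsAsFactors = FALSE),
      tertiary = tertiary), class = "trna_structure_map")
  }
  maps
}

#' Load and cross-validate a reference bundle from disk
#'
#' The bundle directory holds tab-delimited UTF-8 tables plus a JSON manifest
#' declaring row counts, genome length and schema version. All structural
#' invariants (Sprinzl monotonicity, anticodon-loop rule, folding/tertiary
#' consistency, score normalization self-consistency, gene-map cardinalities
#' for the human map) are checked at load time.
#'
#' @param dir_path bundle directory.
#' @return object of class `mito_bundle`.
#' @export
load_reference_bundle <- function(dir_path) {
  missing <- BUNDLE_FILES[!file.exists(file.path(dir_path, BUNDLE_FILES))]
  if (length(missing))
    mva_stop("reference bundle at '", dir_path, "' is missing required file(s): ",
             paste(missing, collapse = ", "), class = "mva_load_error")

  manifest <- jsonlite::read_json(file.path(dir_path, "manifest.json"),
                                  simplifyVector = TRUE)
  genes <- read_tsv_utf8(file.path(dir_path, "genes.tsv"))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  struct <- read_tsv_utf8(file.path(dir_path, "trna_structure.tsv"))
  tert <- read_tsv_utf8(file.path(dir_path, "trna_tertiary.tsv"))
  mods <- read_tsv_utf8(file.path(dir_path, "modifications.tsv"))
  mods$position <- as.integer(mods$position)
  patho <- read_tsv_utf8(file.path(dir_path, "rna_patho.tsv"))
  patho$position <- as.integer(patho$position)
  patho$raw_score <- as.integer(patho$raw_score)
  patho$normalized_score <- as.numeric(patho$normalized_score)
  passthrough <- read_tsv_utf8(file.path(dir_path, "passthrough.tsv"))
  passthrough$position <- as.integer(passthrough$position)

  bundle <- structure(list(
    dir = normalizePath(dir_path),
    manifest = manifest,
    genes = genes,
    trna_maps = parse_structure_table(struct, tert, genes, mods),
    mods = mods,
    patho = patho,
    passthrough = passthrough), class = "mito_bundle")
  validate_bundle(bundle)
  bundle
}

#' Serialize a bundle back to its on-disk table format
#' @param bundle a `mito_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mito_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_utf8(bundle$genes, file.path(dir, "genes.tsv"))
  struct <- do.call(rbind, lapply(bundle$trna_maps, function(m) {
    data.frame(gene = m$gene, species = m$species, trna_type = m$trna_type,
               provenance = m$provenance, offset = m$positions$offset,
               sprinzl = ifelse(is.na(m$positions$sprinzl), "-",
                                as.character(m$positions$sprinzl)),
               domain = m$positions$domain, mature_nt = m$positions$mature_nt,
               folding = m$positions$folding, stringsAsFactors = FALSE)
  }))
  rownames(struct) <- NULL
  write_tsv_utf8(struct, file.path(dir, "trna_structure.tsv"))
  tert <- do.call(rbind, lapply(bundle$trna_maps, function(m) {
    if (!length(m$tertiary))
      return(data.frame(gene = character(), members = character()))
    data.frame(gene = m$gene,
               members = vapply(m$tertiary, paste, character(1), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(tert) <- NULL
  write_tsv_utf8(tert, file.path(dir, "trna_tertiary.tsv"))
  write_tsv_utf8(bundle$mods, file.path(dir, "modifications.tsv"))
  patho <- bundle$patho
  patho$normalized_score <- sprintf("%.3f", patho$normalized_score)
  write_tsv_utf8(patho, file.path(dir, "rna_patho.tsv"))
  write_tsv_utf8(bundle$passthrough, file.path(dir, "passthrough.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

validation_fail <- function(table, where, rule) {
  mva_stop("bundle validation failed [", table, ", ", where, "]: ", rule,
           class = "mva_validation_error")
}

# Mature nucleotide expected for a plain (unmodified) position.
is_plain_rna_base <- function(x) x %in% c("A", "C", "G", "U")

validate_structure_map <- function(map, gene, mods, genome_len) {
  p <- map$positions
  n <- locus_length(gene$start, gene$end, genome_len)
  if (!identical(p$offset, seq_len(nrow(p))) || nrow(p) != n)
    validation_fail("trna_structure.tsv", map$gene,
                    paste0("map must cover offsets 1..", n, " exactly once"))
  if (!map$trna_type %in% TRNA_TYPES)
    validation_fail("trna_structure.tsv", map$gene, "unknown tRNA type")
  bad_dom <- which(!p$domain %in% TRNA_DOMAINS)
  if (length(bad_dom))
    validation_fail("trna_structure.tsv",
                    paste0(map$gene, " offset ", p$offset[bad_dom[1L]]),
                    "unknown cloverleaf domain code")
  sp <- p$sprinzl[!is.na(p$sprinzl)]
  if (length(sp) && (any(sp < 1L | sp > 73L)))
    validation_fail("trna_structure.tsv", map$gene, "Sprinzl numbers must lie in 1..73")
  if (length(sp) > 1L && any(diff(sp) <= 0L))
    validation_fail("trna_structure.tsv", map$gene,
                    "Sprinzl numbers must be strictly increasing with offset")
  # Anticodon rule: Sprinzl 34-36 are the anticodon triplet and sit in the
  # anticodon loop; CL appears nowhere outside the loop (32-38).
  ac <- p[!is.na(p$sprinzl) & p$sprinzl %in% 34:36, , drop = FALSE]
  if (any(ac$domain != "CL"))
    validation_fail("trna_structure.tsv",
                    paste0(map$gene, " Sprinzl ",
                           ac$sprinzl[ac$domain != "CL"][1L]),
                    "anticodon triplet positions (Sprinzl 34-36) must have domain CL")
  stray <- p[p$domain == "CL" & (is.na(p$sprinzl) | p$sprinzl < 32L | p$sprinzl > 38L), ,
             drop = FALSE]
  if (nrow(stray))
    validation_fail("trna_structure.tsv",
                    paste0(map$gene, " offset ", stray$offset[1L]),
                    "domain CL is restricted to the anticodon loop (Sprinzl 32-38)")
  un <- p[is.na(p$sprinzl), , drop = FALSE]
  if (any(un$domain != "-") || any(un$folding != "N"))
    validation_fail("trna_structure.tsv", map$gene,
                    "unmapped positions must carry domain '-' and folding N")
  tert_members <- unique(unlist(map$tertiary))
  fold_y <- p$sprinzl[p$folding == "Y" & !is.na(p$sprinzl)]
  if (!setequal(fold_y, intersect(tert_members, p$sprinzl)))
    validation_fail("trna_structure.tsv", map$gene,
                    "folding=Y exactly at mapped Sprinzl numbers of the tertiary set")
  if (length(setdiff(tert_members, p$sprinzl)))
    validation_fail("trna_tertiary.tsv", map$gene,
                    "tertiary interaction references an unmapped Sprinzl number")
  # Mature nucleotide: plain RNA base unless the (species, Sprinzl) pair is in
  # the modification table, in which case the Modomics symbol is required.
  gene_mods <- mods[mods$trna == map$species, , drop = FALSE]
  mapped <- !is.na(p$sprinzl)
  modified <- mapped & p$sprinzl %in% gene_mods$position
  if (any(!is_plain_rna_base(p$mature_nt[!modified])))
    validation_fail("trna_structure.tsv", map$gene,
                    "mature nucleotide must be a plain base (A/C/G/U) at unmodified positions")
  for (i in which(modified)) {
    allowed <- gene_mods$modomics_symbol[gene_mods$position == p$sprinzl[i]]
    if (!p$mature_nt[i] %in% allowed)
      validation_fail("trna_structure.tsv",
                      paste0(map$gene, " Sprinzl ", p$sprinzl[i]),
                      "modified position must carry a Modomics symbol from the modification table")
  }
  invisible(TRUE)
}

#' Validate every invariant of a loaded bundle
#'
#' Human-map cardinalities (22 tRNA / 2 rRNA / 13 protein-coding genes, one
#' type-I and one type-III tRNA) are enforced when the manifest declares
#' `flavor: "rCRS"`; structural rules are enforced for every bundle flavor.
#' @param bundle a `mito_bundle`.
#' @export
validate_bundle <- function(bundle) {
  g <- bundle$genes
  gl <- genome_length(bundle)
  need <- c("name", "start", "end", "strand", "biotype")
  if (!all(need %in% names(g)))
    validation_fail("genes.tsv", "header", "missing required columns")
  if (any(!g$strand %in% c("H", "L")))
    validation_fail("genes.tsv", g$name[!g$strand %in% c("H", "L")][1L],
                    "strand must be H or L")
  if (any(!g$biotype %in% GENE_BIOTYPES))
    validation_fail("genes.tsv", g$name[!g$biotype %in% GENE_BIOTYPES][1L],
                    "unknown biotype")
  if (any(g$start < 1L | g$start > gl | g$end < 1L | g$end > gl))
    validation_fail("genes.tsv", "coordinates",
                    paste0("coordinates must lie in 1..", gl))
  if (sum(g$end < g$start) > 1L)
    validation_fail("genes.tsv", "coordinates",
                    "at most one locus may wrap the origin")

  rcrs <- identical(bundle$manifest$flavor, "rCRS")
  if (rcrs) {
    counts <- table(factor(g$biotype, levels = GENE_BIOTYPES))
    if (counts[["tRNA"]] != 22L)
      validation_fail("genes.tsv", "biotype=tRNA", "human map must contain 22 tRNA genes")
    if (counts[["rRNA"]] != 2L)
      validation_fail("genes.tsv", "biotype=rRNA", "human map must contain 2 rRNA genes")
    if (counts[["protein_coding"]] != 13L)
      validation_fail("genes.tsv", "biotype=protein_coding",
                      "human map must contain 13 protein-coding genes")
    types <- vapply(bundle$trna_maps, `[[`, character(1), "trna_type")
    if (sum(types == "I") != 1L || sum(types == "III") != 1L)
      validation_fail("trna_structure.tsv", "trna_type",
                      "human map must contain exactly one type-I and one type-III tRNA")
  }

  trna_genes <- g[g$biotype == "tRNA", , drop = FALSE]
  absent <- setdiff(trna_genes$name, names(bundle$trna_maps))
  if (length(absent))
    validation_fail("trna_structure.tsv", absent[1L],
                    "every tRNA locus needs a structure map")
  for (gname in names(bundle$trna_maps)) {
    grow <- g[g$name == gname, , drop = FALSE]
    if (!nrow(grow))
      validation_fail("trna_structure.tsv", gname, "structure map for unknown gene")
    validate_structure_map(bundle$trna_maps[[gname]], as.list(grow[1L, ]),
                           bundle$mods, gl)
  }

  m <- bundle$mods
  if (anyDuplicated(m[, c("position", "mod_name", "trna")]))
    validation_fail("modifications.tsv", "keys",
                    "(position, mod_name, trna) triples must be unique")
  sym_per_name <- tapply(m$modomics_symbol, m$mod_name,
                         function(x) length(unique(x)))
  if (any(sym_per_name != 1L))
    validation_fail("modifications.tsv", names(sym_per_name)[sym_per_name != 1L][1L],
                    "Modomics symbol must be constant for a modification name")

  p <- bundle$patho
  for (i in seq_len(nrow(p))) {
    scheme <- scoring_scheme(p$scheme[i])
    if (p$raw_score[i] < 0L || p$raw_score[i] > scheme$max_raw)
      validation_fail("rna_patho.tsv", paste0("row ", i), "raw score out of range")
    if (abs(p$normalized_score[i] - normalize_score(p$raw_score[i], scheme)) > 1e-9)
      validation_fail("rna_patho.tsv", paste0("row ", i),
                      "stored normalized score must equal raw/max to 3 decimals")
    if (!p$prediction[i] %in% scheme$label_map)
      validation_fail("rna_patho.tsv", paste0("row ", i), "unknown prediction label")
  }

  mc <- bundle$manifest$counts
  if (!is.null(mc$trna_positions)) {
    tot <- sum(locus_length(trna_genes$start, trna_genes$end, gl))
    if (tot != mc$trna_positions)
      validation_fail("manifest.json", "counts.trna_positions",
                      paste0("gene map sums to ", tot, " tRNA positions"))
  }
  if (!is.null(mc$trna_positions_unique)) {
    uniq <- length(unique(unlist(lapply(seq_len(nrow(trna_genes)), function(i)
      locus_positions(as.list(trna_genes[i, ]), gl)))))
    if (uniq != mc$trna_positions_unique)
      validation_fail("manifest.json", "counts.trna_positions_unique",
                      paste0("gene map covers ", uniq, " unique tRNA positions"))
  }
  invisible(TRUE)
}

#' Count distinct modification types, records and modified residues
#'
#' The bundled table keeps one record per (position, modification, tRNA
#' species); a residue carrying two alternative modifications is therefore
#' listed twice, and `residues` counts unique (position, species) pairs.
#' @param bundle a `mito_bundle`.
#' @return list with `types`, `records`, `residues`.
#' @export
modification_summary <- function(bundle) {
  m <- bundle$mods
  list(types = length(unique(m$mod_name)),
       records = nrow(m),
       residues = nrow(unique(m[, c("position", "trna")])))
}

.bundle_cache <- new.env(parent = emptyenv())

#' The packaged rCRS reference bundle
#'
#' Loads (and caches) the bundle shipped under `inst/extdata/bundle`. The
#' MT-TM structure map is curated from the real rCRS sequence; the remaining
#' 21 structure maps are synthetic stand-ins generated by
#' [generate_trna_map()] with real gene lengths, tRNA types, anticodons and
#' modification placements (see the package vignette).
#' @export
default_bundle <- function() {
  if (is.null(.bundle_cache$bundle)) {
    dir <- system.file("extdata", "bundle", package = "MitoVarAnnot",
                       mustWork = TRUE)
    .bundle_cache$bundle <- load_reference_bundle(dir)
  }
  .bundle_cache$bundle
}

#' @export
print.mito_bundle <- function(x, ...) {
  cat("<mito_bundle>", x$manifest$flavor %||% "custom",
      "genome length", genome_length(x), "\n")
  cat("  genes:", nrow(x$genes),
      sprintf("(tRNA %d, rRNA %d, protein_coding %d)",
              sum(x$genes$biotype == "tRNA"), sum(x$genes$biotype == "rRNA"),
              sum(x$genes$biotype == "protein_coding")), "\n")
  cat("  tRNA structure maps:", length(x$trna_maps), "\n")
  cat("  modification records:", nrow(x$mods),
      "| scored RNA variants:", nrow(x$patho), "\n")
  invisible(x)
}
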