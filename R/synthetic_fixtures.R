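# Deterministic synthetic fixtures: tRNA structure maps, toy circular genomes
# with coding (and optionally tRNA) genes, and variant lists with ground
# truth. Ground-truth effects are computed by an embedded brute-force oracle
# (string mutation + Biostrings translation), independent of the codon-wise
# classifier under test.

# Sprinzl numbers that may be dropped to emulate the shortened loops of
# mt-tRNAs without touching anticodon, stems or tertiary-interaction anchors.
droppable_sprinzl <- function(tertiary) {
  keep <- unique(unlist(tertiary))
  setdiff(c(16L, 17L, 20L, 21L,        # D loop
            44L, 47L, 48L,             # variable loop
            57L, 59L, 60L),            # T loop
          keep)
}

default_tertiary <- function(trna_type) {
  switch(trna_type,
         "0" = c(CANONICAL_TRIPLETS, DT_LOOP_PAIRS),
         "I" = CANONICAL_TRIPLETS,
         "II" = CANONICAL_TRIPLETS,
         "III" = list())   # no D-stem: the canonical anchors are absent
}

# Anticodons (tRNA 5'->3', DNA alphabet of the coding gene strand).
TRNA_ANTICODON <- c(
  "Phe" = "GAA", "Val" = "TAC", "Leu(UUR)" = "TAA", "Ile" = "GAT",
  "Gln" = "TTG", "Met" = "CAT", "Trp" = "TCA", "Ala" = "TGC", "Asn" = "GTT",
  "Cys" = "GCA", "Tyr" = "GTA", "Ser(UCN)" = "TGA", "Asp" = "GTC",
  "Lys" = "TTT", "Gly" = "TCC", "Arg" = "TCG", "His" = "GTG",
  "Ser(AGY)" = "GCT", "Leu(CUN)" = "TAG", "Glu" = "TTC", "Thr" = "TGT",
  "Pro" = "TGG")

#' Generate a synthetic tRNA structure map
#'
#' Builds a structurally valid map of the requested type on the canonical
#' cloverleaf layout: type III lacks the D-stem, type I carries an extended
#' (atypical) anticodon stem, type 0 keeps the D-loop/T-loop tertiary
#' pairing and type II omits it. `gap_count` loop positions are removed
#' (seeded choice) to emulate the shortened loops of mt-tRNAs;
#' `insert_count` adds Sprinzl-unmapped positions in the D-loop.
#'
#' @param seed integer seed driving all random choices.
#' @param trna_type "0", "I", "II" or "III".
#' @param gap_count number of loop positions to drop (beyond the structural
#'   D-stem loss of type III).
#' @param gene,species gene symbol and tRNA species of the synthetic map.
#' @param insert_count number of extra unmapped positions.
#' @param mods optional modification records applied to mature nucleotides.
#' @param at_rich use the A/U/C-rich base composition typical of mt-tRNAs.
#' @return list with `map` (a `trna_structure_map`) and `alignment` (the raw
#'   offset/Sprinzl/base table, kept as the independent test oracle).
#' @export
generate_trna_map <- function(seed, trna_type = c("0", "I", "II", "III"),
                              gap_count = 0L, gene = "SYN-T1", species = NA,
                              insert_count = 0L, mods = NULL, at_rich = FALSE) {
  trna_type <- match.arg(trna_type)
  tertiary <- default_tertiary(trna_type)
  sprinzl <- 1:73
  if (trna_type == "III") sprinzl <- setdiff(sprinzl, c(10:13, 22:25))
  pool <- droppable_sprinzl(tertiary)
  # 59 mapped positions is the human minimum (the D-armless Ser(AGY) gene).
  if (gap_count > length(pool) || (length(sprinzl) - gap_count) < 59L)
    mva_stop("infeasible gap_count: at least 59 mapped positions are required",
             class = "mva_generation_error")
  domains <- canonical_domain_table()
  if (trna_type == "I") {
    # atypical anticodon stem extending into the variable region
    domains$domain[domains$from == 44L] <- "CS"
    domains <- rbind(domains[domains$from != 44L, ],
                     data.frame(from = c(44L, 46L), to = c(45L, 48L),
                                domain = c("CS", "VL")))
  }
  with_seed(seed, {
    if (gap_count > 0L)
      sprinzl <- setdiff(sprinzl, sort(sample(pool, gap_count)))
    n <- length(sprinzl) + insert_count
    prob <- if (at_rich) c(A = .35, C = .25, G = .1, T = .3) else rep(.25, 4)
    base <- sample(DNA_BASES, n, replace = TRUE, prob = prob)
    aln_sprinzl <- rep(NA_integer_, n)
    insert_at <- if (insert_count > 0L) {
      after <- which(sprinzl <= 21L & sprinzl >= 14L)  # D-loop insertions
      sort(sample(after, insert_count, replace = FALSE))
    } else integer(0)
    # interleave: mapped positions in Sprinzl order, unmapped rows after the
    # chosen D-loop offsets
    idx_map <- setdiff(seq_len(n), insert_at + seq_along(insert_at))
    aln_sprinzl[idx_map] <- sprinzl
    # pin the anticodon to the species anticodon, and modified residues to
    # their parent base, so modification overrides are chemically consistent
    if (!is.na(species) && species %in% names(TRNA_ANTICODON)) {
      ac <- strsplit(TRNA_ANTICODON[[species]], "")[[1L]]
      base[match(34:36, aln_sprinzl)] <- ac
    }
    if (!is.null(mods) && !is.na(species)) {
      gm <- mods[mods$trna == species, , drop = FALSE]
      for (k in seq_len(nrow(gm))) {
        i <- match(gm$position[k], aln_sprinzl)
        if (!is.na(i)) base[i] <- MODOMICS_PARENT_BASE[[gm$modomics_symbol[k]]]
      }
    }
    alignment <- data.frame(offset = seq_len(n), sprinzl = aln_sprinzl,
                            base = base, stringsAsFactors = FALSE)
  })
  gene_locus <- list(name = gene, start = 1L, end = nrow(alignment), strand = "H")
  map <- build_structure_map(gene_locus, alignment, domains = domains,
                             mods = mods, tertiary = tertiary,
                             trna_type = trna_type, species = species,
                             provenance = "synthetic")
  list(map = map, alignment = alignment)
}

# ---- toy genomes ----------------------------------------------------------

random_sense_codons <- function(n, code) {
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

# Brute-force oracle: mutate the raw coding sequence, re-translate with
# Biostrings, compare amino-acid strings.
oracle_classify <- function(cds, j, alt_coding, code) {
  mut <- cds
  substr(mut, j, j) <- alt_coding
  n_cod <- nchar(cds) %/% 3L
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, 3L * n_cod)),
    genetic.code = code, no.init.codon = TRUE))
  ref_aa <- strsplit(tr(cds), "")[[1L]]
  alt_aa <- strsplit(tr(mut), "")[[1L]]
  d <- which(ref_aa != alt_aa)
  if (!length(d)) return("synonymous")
  if (alt_aa[d[1L]] == "*") return("stop_gain")
  if (ref_aa[d[1L]] == "*") return("stop_loss")
  "nonsynonymous"
}

#' Generate a toy circular genome with known mutational ground truth
#'
#' Coding genes start ATG/ATA, contain random sense codons and end in a
#' vertebrate-mitochondrial stop; strands alternate. The effect class of
#' every possible coding substitution is pre-computed by the embedded
#' brute-force oracle and stored as ground truth. Optionally adds tRNA genes
#' backed by synthetic structure maps.
#'
#' @param seed integer seed; regeneration is bit-identical.
#' @param n_genes number of coding genes (>= 1).
#' @param codons_per_gene total codons per gene (>= 2), start and stop codon
#'   included.
#' @param n_trna number of additional synthetic tRNA genes.
#' @param spacer intergenic spacer length.
#' @param at_rich AT-rich intergenic composition.
#' @return a `synthetic_truth` list: `genome`, `genes`, `trna_maps`,
#'   `truth` (classified substitutions), `bundle` (a loadable
#'   `mito_bundle`), `seed`.
#' @export
generate_toy_genome <- function(seed, n_genes = 2L, codons_per_gene = 5L,
                                n_trna = 0L, spacer = 6L, at_rich = FALSE) {
  if (n_genes < 1L) mva_stop("n_genes must be >= 1", class = "mva_generation_error")
  if (codons_per_gene < 2L)
    mva_stop("codons_per_gene must be >= 2", class = "mva_generation_error")
  code <- mito_genetic_code()
  stops <- c("TAA", "TAG", "AGA", "AGG")
  trna_species <- names(TRNA_ANTICODON)

  pieces <- character(0); genes <- list(); maps <- list(); alignments <- list()
  with_seed(seed, {
    cursor <- 1L
    prob <- if (at_rich) c(A = .35, C = .25, G = .1, T = .3) else rep(.25, 4)
    add_spacer <- function() {
      s <- paste(sample(DNA_BASES, spacer, replace = TRUE, prob = prob),
                 collapse = "")
      pieces <<- c(pieces, s); cursor <<- cursor + spacer
    }
    add_spacer()
    for (i in seq_len(n_genes)) {
      cds <- paste(c(sample(c("ATG", "ATA"), 1L),
                     random_sense_codons(codons_per_gene - 2L, code),
                     sample(stops, 1L)), collapse = "")
      strand <- if (i %% 2L == 0L) "L" else "H"
      gseq <- if (strand == "L") revcomp(cds) else cds
      genes[[length(genes) + 1L]] <- data.frame(
        name = sprintf("TOY-CDS%d", i), start = cursor,
        end = cursor + nchar(gseq) - 1L, strand = strand,
        biotype = "protein_coding", stringsAsFactors = FALSE)
      pieces <- c(pieces, gseq); cursor <- cursor + nchar(gseq)
      add_spacer()
    }
    for (i in seq_len(n_trna)) {
      sp <- sample(trna_species, 1L)
      tm <- generate_trna_map(seed + 1000L + i,
                              trna_type = sample(c("0", "II"), 1L),
                              gap_count = sample(0:4, 1L),
                              gene = sprintf("TOY-TRNA%d", i), species = sp,
                              at_rich = at_rich)
      strand <- if (i %% 2L == 0L) "L" else "H"
      gseq <- paste(tm$alignment$base, collapse = "")
      if (strand == "L") gseq <- revcomp(gseq)
      genes[[length(genes) + 1L]] <- data.frame(
        name = sprintf("TOY-TRNA%d", i), start = cursor,
        end = cursor + nchar(gseq) - 1L, strand = strand, biotype = "tRNA",
        stringsAsFactors = FALSE)
      tm$map$gene <- sprintf("TOY-TRNA%d", i)
      maps[[sprintf("TOY-TRNA%d", i)]] <- tm$map
      alignments[[sprintf("TOY-TRNA%d", i)]] <-
        list(alignment = tm$alignment, trna_type = tm$map$trna_type,
             tertiary = tm$map$tertiary)
      pieces <- c(pieces, gseq); cursor <- cursor + nchar(gseq)
      add_spacer()
    }
  })
  genome <- paste(pieces, collapse = "")
  genes <- do.call(rbind, genes)

  truth <- do.call(rbind, c(lapply(which(genes$biotype == "protein_coding"),
                                   function(i) {
    gene <- as.list(genes[i, ])
    cds <- gene_coding_seq(gene, genome, nchar(genome))
    len <- nchar(cds)
    rows <- lapply(seq_len(len), function(j) {
      coding_ref <- substr(cds, j, j)
      do.call(rbind, lapply(setdiff(DNA_BASES, coding_ref), function(a) {
        pos <- coding_index_to_pos(gene, j, nchar(genome))
        data.frame(gene = gene$name, pos = pos,
                   ref = toupper(substr(genome, pos, pos)),
                   alt = if (gene$strand == "L") comp_base(a) else a,
                   effect = oracle_classify(cds, j, a, code),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  }), list(empty_substitutions()[, c("gene", "pos", "ref", "alt", "effect")])))
  rownames(truth) <- NULL

  structure(list(genome = genome, genes = genes, trna_maps = maps,
                 trna_alignments = alignments, truth = truth, seed = seed,
                 bundle = toy_bundle(genome, genes, maps)),
            class = "synthetic_truth")
}

# Wrap toy components as a loadable bundle object (same shape as the packaged
# one, with an empty modification/score/pass-through payload).
toy_bundle <- function(genome, genes, maps) {
  structure(list(
    dir = NA_character_,
    manifest = list(schema_version = "1.0", flavor = "synthetic",
                    genome_length = nchar(genome)),
    genes = genes,
    trna_maps = maps,
    mods = data.frame(position = integer(), mod_name = character(),
                      modomics_symbol = character(), trna = character(),
                      evidence = character(), stringsAsFactors = FALSE),
    patho = data.frame(position = integer(), ref = character(),
                       alt = character(), scheme = character(),
                       raw_score = integer(), normalized_score = numeric(),
                       prediction = character(), source_citation = character(),
                       stringsAsFactors = FALSE),
    passthrough = data.frame(position = integer(), ref = character(),
                             alt = character(), stringsAsFactors = FALSE)),
    class = "mito_bundle")
}

#' Sample variants with expected annotations from a synthetic truth set
#'
#' Variants are drawn without replacement across coding, tRNA and intergenic
#' sites of the toy genome; each row carries the expected locus, five-field
#' tRNA annotation and coding effect for end-to-end pipeline checks.
#'
#' @param seed integer seed.
#' @param truth a `synthetic_truth`.
#' @param n number of variants.
#' @return data frame: `pos`, `ref`, `alt`, `expected_locus`,
#'   `expected_trna_annotation`, `expected_effect`.
#' @export
generate_variants <- function(seed, truth, n) {
  stopifnot(inherits(truth, "synthetic_truth"))
  gl <- nchar(truth$genome)
  if (n > gl)
    mva_stop("n exceeds the number of distinct sites", class = "mva_generation_error")
  if (n == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      expected_locus = character(),
                      expected_trna_annotation = character(),
                      expected_effect = character(), stringsAsFactors = FALSE))
  with_seed(seed, {
    pos <- sort(sample(gl, n))
    ref <- vapply(pos, function(p) toupper(substr(truth$genome, p, p)), character(1))
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1),
                  USE.NAMES = FALSE)
  })
  # Expectations are derived from the raw generator tables (brute-force
  # interval scan + raw alignment lookup), not from the annotation modules.
  g <- truth$genes
  dom_cover <- rep(NA_character_, 73L)
  dt <- canonical_domain_table()
  for (i in seq_len(nrow(dt))) dom_cover[dt$from[i]:dt$to[i]] <- dt$domain[i]
  expected <- lapply(seq_len(n), function(i) {
    inside <- g$start <= pos[i] & g$end >= pos[i]
    loci <- g$name[inside][order(g$start[inside])]
    trna <- ""
    tg <- g[inside & g$biotype == "tRNA", , drop = FALSE]
    if (nrow(tg)) {
      tg <- tg[1L, ]
      al <- truth$trna_alignments[[tg$name]]
      off <- if (tg$strand == "L") tg$end - pos[i] + 1L else pos[i] - tg$start + 1L
      arow <- al$alignment[al$alignment$offset == off, ]
      sp <- arow$sprinzl
      trna <- paste(c(if (is.na(sp)) "-" else sp,
                      al$trna_type,
                      if (is.na(sp)) "-" else dom_cover[sp],
                      dna_to_rna(arow$base),
                      if (!is.na(sp) && sp %in% unlist(al$tertiary)) "Y" else "N"),
                    collapse = ";")
    }
    eff <- truth$truth[truth$truth$pos == pos[i] & truth$truth$alt == alt[i], ,
                       drop = FALSE]
    list(locus = paste(loci, collapse = ","),
         trna = trna,
         effect = paste(unique(eff$effect), collapse = ","))
  })
  data.frame(pos = pos, ref = ref, alt = alt,
             expected_locus = vapply(expected, `[[`, character(1), "locus"),
             expected_trna_annotation = vapply(expected, `[[`, character(1), "trna"),
             expected_effect = vapply(expected, `[[`, character(1), "effect"),
             stringsAsFactors = FALSE)
}
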