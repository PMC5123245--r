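#!/usr/bin/env Rscript
# Builds the packaged reference bundle under inst/extdata/bundle.
#
# Gene coordinates follow the RefSeq/MITOMAP annotation of the rCRS
# (NC_012920.1 / J01415.2). The MT-TM structure map is curated by hand from
# the real gene sequence; the other 21 tRNA maps are generated with the
# package's structure-map generator (real lengths, types, anticodons,
# modification placements) and labelled "synthetic". Run from the repo root:
#   Rscript tools/make_bundle.R

devtools::load_all(".", quiet = TRUE)

out_dir <- file.path("inst", "extdata", "bundle")

# ---- gene map -------------------------------------------------------------
genes <- read.table(text = "
MT-DLOOP 16024 576 H control
MT-TF 577 647 H tRNA
MT-RNR1 648 1601 H rRNA
MT-TV 1602 1670 H tRNA
MT-RNR2 1671 3229 H rRNA
MT-TL1 3230 3304 H tRNA
MT-ND1 3307 4262 H protein_coding
MT-TI 4263 4331 H tRNA
MT-TQ 4329 4400 L tRNA
MT-TM 4402 4469 H tRNA
MT-ND2 4470 5511 H protein_coding
MT-TW 5512 5579 H tRNA
MT-TA 5587 5655 L tRNA
MT-TN 5657 5729 L tRNA
MT-TC 5761 5826 L tRNA
MT-TY 5826 5891 L tRNA
MT-CO1 5904 7445 H protein_coding
MT-TS1 7446 7514 L tRNA
MT-TD 7518 7585 H tRNA
MT-CO2 7586 8269 H protein_coding
MT-TK 8295 8364 H tRNA
MT-ATP8 8366 8572 H protein_coding
MT-ATP6 8527 9207 H protein_coding
MT-CO3 9207 9990 H protein_coding
MT-TG 9991 10058 H tRNA
MT-ND3 10059 10404 H protein_coding
MT-TR 10405 10469 H tRNA
MT-ND4L 10470 10766 H protein_coding
MT-ND4 10760 12137 H protein_coding
MT-TH 12138 12206 H tRNA
MT-TS2 12207 12265 H tRNA
MT-TL2 12266 12336 H tRNA
MT-ND5 12337 14148 H protein_coding
MT-ND6 14149 14673 L protein_coding
MT-TE 14674 14742 L tRNA
MT-CYB 14747 15887 H protein_coding
MT-TT 15888 15953 H tRNA
MT-TP 15956 16023 L tRNA
", col.names = c("name", "start", "end", "strand", "biotype"),
  stringsAsFactors = FALSE)

# ---- post-transcriptional modification table (16 types, 116 records) ------
mods_rows <- list()
M <- function(pos, name, sym, h = character(), b = character(), m = character()) {
  for (x in h) mods_rows[[length(mods_rows) + 1L]] <<-
    data.frame(position = pos, mod_name = name, modomics_symbol = sym,
               trna = x, evidence = "human")
  for (x in b) mods_rows[[length(mods_rows) + 1L]] <<-
    data.frame(position = pos, mod_name = name, modomics_symbol = sym,
               trna = x, evidence = "bovine")
  for (x in m) mods_rows[[length(mods_rows) + 1L]] <<-
    data.frame(position = pos, mod_name = name, modomics_symbol = sym,
               trna = x, evidence = "model_organism")
}
M(9, "1-methyladenosine", "\"", h = c("Asp", "Leu(CUN)", "Lys", "Pro"),
  b = c("Ala", "Glu", "Phe", "Gly", "His", "Asn", "Arg", "Thr", "Val", "Trp"))
M(9, "1-methylguanosine", "K", h = c("Ile", "Leu(UUR)"), b = c("Cys", "Gln", "Tyr"))
M(10, "N2-methylguanosine", "L", h = c("Leu(UUR)", "Leu(CUN)", "Lys", "Asp"),
  b = c("Ala", "Phe", "Gly", "His", "Asn", "Val", "Trp", "Tyr"))
M(20, "dihydrouridine", "D", h = "Leu(UUR)")
M(26, "N2-methylguanosine", "L", h = c("Ala", "Glu"))
M(26, "N2,N2-dimethylguanosine", "R", h = "Ile")
M(27, "pseudouridine", "P",
  h = c("Asp", "Ile", "Leu(UUR)", "Leu(CUN)", "Lys", "Met", "Pro"),
  b = c("Cys", "His"))
M(28, "pseudouridine", "P", h = c("Ile", "Lys", "Leu(CUN)", "Pro"),
  b = c("Cys", "Glu", "Asn", "Ser(UCN)", "Tyr"))
M(29, "pseudouridine", "P", h = "Ser(UCN)")
M(31, "pseudouridine", "P", h = "Leu(CUN)")
M(32, "3-methylcytidine", "'", h = c("Ser(UCN)", "Thr"))
M(32, "pseudouridine", "P", h = "Pro", b = "Cys")
M(34, "5-taurinomethyluridine", "Ê", h = "Leu(UUR)",
  b = c("Glu", "Gln", "Trp"))
M(34, "queuosine", "Q", h = "Asp", b = c("His", "Asn", "Tyr"))
M(34, "5-taurinomethyl-2-thiouridine", "Ǝ", h = "Lys", b = c("Glu", "Gln"))
M(34, "5-formylcytidine", ">", h = "Met")
M(37, "N6-threonylcarbamoyladenosine", "6", h = c("Ile", "Lys", "Ser(AGY)"),
  b = c("Asn", "Thr"))
M(37, "N6-isopentenyladenosine", "+",
  m = c("Cys", "Phe", "Ser(UCN)", "Trp", "Tyr"))
M(37, "2-methylthio-N6-isopentenyladenosine", "*",
  h = c("Phe", "Ser(UCN)", "Trp", "Tyr"))
M(37, "1-methylguanosine", "K", h = c("Leu(CUN)", "Pro"), b = "Gln")
M(38, "pseudouridine", "P", h = "Pro")
M(39, "pseudouridine", "P",
  h = c("Ala", "Cys", "Phe", "Gly", "His", "Gln", "Arg", "Tyr"))
M(40, "pseudouridine", "P", h = c("Glu", "Gln"))
M(48, "5-methylcytidine", "?", h = "Leu(UUR)")
M(49, "5-methylcytidine", "?", h = "Glu")
M(50, "pseudouridine", "P", h = "Met")
M(54, "5-methyluridine", "T", h = c("Leu(UUR)", "Pro"))
M(55, "pseudouridine", "P", h = c("Leu(UUR)", "Pro"),
  b = c("Glu", "Gln", "Ser(UCN)", "Tyr"))
M(58, "1-methyladenosine", "\"", h = c("Ser(AGY)", "Leu(UUR)"),
  b = c("Cys", "Ser(UCN)"), m = "Glu")
M(72, "5-methylcytidine", "?", h = "Thr")
mods <- do.call(rbind, mods_rows)
stopifnot(length(unique(mods$mod_name)) == 16L, nrow(mods) == 116L,
          nrow(unique(mods[, c("position", "trna")])) == 110L)

# ---- MT-TM: curated structure map (rCRS 4402-4469, heavy strand) ----------
# Offsets 1..68 read 5'->3'; Sprinzl gaps at 16,17,18 (D loop), 47 (variable
# loop) and 60 (T loop); discriminator A73 encoded. Anticodon CAT at offsets
# 31-33 = Sprinzl 34-36; rCRS 4450 is offset 49 = Sprinzl 53 (T-stem, G).
mttm_seq <- "AGTAAGGTCAGCTAAATAAGCTATCGGGCCCATACCCCGAAAATGTTGGTTATACCCTTCCCGTACTA"
stopifnot(nchar(mttm_seq) == 68L, substr(mttm_seq, 49, 49) == "G",
          substr(mttm_seq, 31, 33) == "CAT")
mttm_sprinzl <- c(1:15, 19:46, 48:59, 61:73)
stopifnot(length(mttm_sprinzl) == 68L)
mttm_aln <- data.frame(offset = 1:68, sprinzl = mttm_sprinzl,
                       base = strsplit(mttm_seq, "")[[1L]])
mttm_map <- build_structure_map(
  gene = list(name = "MT-TM", start = 4402L, end = 4469L, strand = "H"),
  sprinzl_alignment = mttm_aln, mods = mods,
  tertiary = MitoVarAnnot:::CANONICAL_TRIPLETS,
  trna_type = "II", species = "Met", provenance = "curated")
stopifnot(with(mttm_map$positions[49, ],
               sprinzl == 53 && domain == "TS" && mature_nt == "G" && folding == "N"))

# ---- remaining 21 maps: generated, labelled synthetic ---------------------
trna_types <- c("MT-TF" = "0", "MT-TL1" = "0", "MT-TL2" = "0", "MT-TQ" = "0",
                "MT-TE" = "0", "MT-TS1" = "I", "MT-TS2" = "III")
maps <- list(`MT-TM` = mttm_map)
trna_genes <- genes[genes$biotype == "tRNA" & genes$name != "MT-TM", ]
for (i in seq_len(nrow(trna_genes))) {
  g <- trna_genes[i, ]
  len <- g$end - g$start + 1L
  type <- if (g$name %in% names(trna_types)) trna_types[[g$name]] else "II"
  base_mapped <- if (type == "III") 65L else 73L
  gap <- max(0L, base_mapped - len)
  ins <- max(0L, len - base_mapped)
  tm <- generate_trna_map(seed = 20160 + i, trna_type = type, gap_count = gap,
                          gene = g$name, species = TRNA_SPECIES[[g$name]],
                          insert_count = ins, mods = mods, at_rich = TRUE)
  stopifnot(nrow(tm$map$positions) == len)
  maps[[g$name]] <- tm$map
}

# ---- literature-scored RNA variants (worked example + synthetic demos) ----
patho <- data.frame(
  position = c(4450L, 4271L, 12148L, 850L, 2300L),
  ref = c("G", "A", "T", "A", "T"),
  alt = c("A", "G", "C", "G", "C"),
  scheme = c("tRNA", "tRNA", "tRNA", "rRNA", "rRNA"),
  raw_score = c(13L, 3L, 11L, 1L, 4L),
  stringsAsFactors = FALSE)
patho$normalized_score <- vapply(seq_len(nrow(patho)), function(i)
  normalize_score(patho$raw_score[i], scoring_scheme(patho$scheme[i])),
  numeric(1))
patho$prediction <- vapply(seq_len(nrow(patho)), function(i)
  prediction_label(patho$raw_score[i], scoring_scheme(patho$scheme[i])),
  character(1))
patho$source_citation <- c("curated", "synthetic-example", "synthetic-example",
                           "synthetic-example", "synthetic-example")

# ---- pass-through annotation columns (worked-example row) -----------------
passthrough <- data.frame(
  position = 4450L, ref = "G", alt = "A",
  nt_variability = "0.00E+00",
  mitomap_diseases = "Myopathy",
  mitomap_homoplasmy = "N",
  mitomap_heteroplasmy = "Y",
  clinvar = "", dbsnp = "", omim = "",
  mamit_trna = "http://mamit-trna.u-strasbg.fr/mutations.asp?idAA=19",
  phastcons20way = "0.889764",
  phylop20way = "0.797921",
  stringsAsFactors = FALSE)

# ---- manifest -------------------------------------------------------------
tg <- genes[genes$biotype == "tRNA", ]
rg <- genes[genes$biotype == "rRNA", ]
trna_positions <- sum(tg$end - tg$start + 1L)
trna_unique <- length(unique(unlist(lapply(seq_len(nrow(tg)), function(i)
  seq.int(tg$start[i], tg$end[i])))))
rrna_positions <- sum(rg$end - rg$start + 1L)
manifest <- list(
  schema_version = "1.0",
  flavor = "rCRS",
  reference = "rCRS (GenBank J01415.2 / NC_012920.1), RefSeq-style gene map",
  genome_length = 16569L,
  counts = list(
    trna_genes = nrow(tg), rrna_genes = nrow(rg),
    protein_coding_genes = sum(genes$biotype == "protein_coding"),
    trna_positions = trna_positions,
    trna_positions_unique = trna_unique,
    rrna_positions = rrna_positions,
    modification_types = length(unique(mods$mod_name)),
    modification_records = nrow(mods),
    modified_residues = nrow(unique(mods[, c("position", "trna")])),
    scored_rna_variants = nrow(patho)),
  notes = paste("modified_residues counts unique (position, tRNA) pairs;",
                "residues carrying two alternative modifications appear as",
                "two modification_records. Structure maps other than MT-TM",
                "are synthetic stand-ins (provenance column)."))

bundle <- structure(list(dir = out_dir, manifest = manifest, genes = genes,
                         trna_maps = maps, mods = mods, patho = patho,
                         passthrough = passthrough), class = "mito_bundle")
validate_bundle(bundle)
write_reference_bundle(bundle, out_dir)
reloaded <- load_reference_bundle(out_dir)
cat("bundle written:", out_dir, "\n")
print(reloaded)
cat("tRNA positions:", trna_positions, "unique:", trna_unique,
    "rRNA positions:", rrna_positions, "\n")
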