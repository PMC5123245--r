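# Shared fixtures: all built in code at test time.

bundle_dir <- function() {
  system.file("extdata", "bundle", package = "MitoVarAnnot", mustWork = TRUE)
}

# A writable copy of the packaged bundle for corruption tests.
copy_bundle <- function() {
  dst <- withr::local_tempdir(.local_envir = parent.frame())
  file.copy(list.files(bundle_dir(), full.names = TRUE), dst)
  dst
}

# Minimal hand-rolled coding bundle: explicit genome string + gene models.
manual_coding_bundle <- function(genome, genes) {
  structure(list(
    dir = NA_character_,
    manifest = list(schema_version = "1.0", flavor = "synthetic",
                    genome_length = nchar(genome)),
    genes = genes, trna_maps = list(),
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

coding_gene <- function(name, start, end, strand = "H") {
  data.frame(name = name, start = start, end = end, strand = strand,
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

write_vcf <- function(variants, path, chrom = "chrM") {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chrM,length=16569>",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, variants$pos, variants$ref,
            variants$alt)
  } else character(0)
  writeLines(c(header, body), path)
  path
}

write_variants_tsv <- function(variants, path) {
  writeLines(c("pos\tref\talt",
               sprintf("%d\t%s\t%s", variants$pos, variants$ref, variants$alt)),
             path)
  path
}

# Independent annotation expectation from a raw alignment table (oracle used
# against annotate_trna_position).
expected_annotation_from_alignment <- function(alignment, trna_type, tertiary,
                                               offset) {
  dt <- MitoVarAnnot:::canonical_domain_table()
  cover <- rep(NA_character_, 73L)
  for (i in seq_len(nrow(dt))) cover[dt$from[i]:dt$to[i]] <- dt$domain[i]
  row <- alignment[alignment$offset == offset, ]
  sp <- row$sprinzl
  paste(c(if (is.na(sp)) "-" else sp, trna_type,
          if (is.na(sp)) "-" else cover[sp],
          MitoVarAnnot:::dna_to_rna(row$base),
          if (!is.na(sp) && sp %in% unlist(tertiary)) "Y" else "N"),
        collapse = ";")
}
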