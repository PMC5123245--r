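# Independent brute-force oracle for a whole toy genome: mutate the raw
# genome string, extract and translate each gene with Biostrings, diff.
oracle_effect <- function(genome, gene, pos, alt) {
  code <- mito_genetic_code()
  mut <- genome
  substr(mut, pos, pos) <- alt
  tr <- function(g) {
    cds <- MitoVarAnnot:::gene_coding_seq(as.list(gene), g, nchar(g))
    n <- nchar(cds) %/% 3L
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1L, 3L * n)),
      genetic.code = code, no.init.codon = TRUE))
  }
  ref_aa <- strsplit(tr(genome), "")[[1L]]
  alt_aa <- strsplit(tr(mut), "")[[1L]]
  d <- which(ref_aa != alt_aa)
  if (!length(d)) return("synonymous")
  if (alt_aa[d[1L]] == "*") return("stop_gain")
  if (ref_aa[d[1L]] == "*") return("stop_loss")
  "nonsynonymous"
}

test_that("codon-level classification matches brute force on known codons", {
  # gene ATG TAT TAA on a toy circular genome
  genome <- paste0("CCCC", "ATGTATTAA", "CCCC")
  gene <- coding_gene("TOY", 5L, 13L)
  bundle <- manual_coding_bundle(genome, gene)

  # TAT codon, third position T->A: stop gain (TAA)
  sub <- classify_substitution(gene, 10L, "A", genome)
  expect_equal(sub$effect, "stop_gain")
  expect_equal(sub$ref_codon, "TAT")
  expect_equal(sub$alt_codon, "TAA")

  # all nine substitutions of the TAT codon agree with the oracle
  for (pos in 8:10) {
    ref <- substr(genome, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      expect_equal(classify_substitution(gene, pos, alt, genome)$effect,
                   oracle_effect(genome, gene, pos, alt),
                   info = paste(pos, alt))
    }
  }

  # stop codon TAA, first position T->C: stop loss (CAA = Gln)
  expect_equal(classify_substitution(gene, 11L, "C", genome)$effect,
               "stop_loss")

  # TTT codon can never gain a stop by one substitution
  genome2 <- paste0("AA", "ATGTTTTAA", "AA")
  gene2 <- coding_gene("TOY2", 3L, 11L)
  for (pos in 6:8) {
    ref <- substr(genome2, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref))
      expect_false(classify_substitution(gene2, pos, alt, genome2)$effect ==
                     "stop_gain", info = paste(pos, alt))
  }

  # TGA is tryptophan under the vertebrate mitochondrial code, so TGG->TGA is
  # synonymous, not stop-gain
  genome3 <- paste0("ATGTGGTAA")
  gene3 <- coding_gene("TOY3", 1L, 9L)
  expect_equal(classify_substitution(gene3, 6L, "A", genome3)$effect,
               "synonymous")
  expect_error(classify_substitution(gene3, 6L, "G", genome3),
               class = "mva_domain_error")  # alt equal to ref
})

test_that("toy-genome enumeration equals the independent oracle", {
  for (seed in 1:5) {
    truth <- generate_toy_genome(seed, n_genes = 3L, codons_per_gene = 6L)
    enum <- enumerate_coding_space(truth$bundle, truth$genome)
    got <- enum$substitutions[, c("gene", "pos", "ref", "alt", "effect")]
    key <- function(d) paste(d$gene, d$pos, d$ref, d$alt)
    expect_setequal(key(got), key(truth$truth))
    m <- merge(got, truth$truth, by = c("gene", "pos", "ref", "alt"))
    expect_equal(nrow(m), nrow(truth$truth))
    expect_equal(m$effect.x, m$effect.y)
    # conservation: the effect classes partition all 3L substitutions
    for (g in unique(got$gene)) {
      gene <- truth$genes[truth$genes$name == g, ]
      L <- gene$end - gene$start + 1L
      expect_equal(sum(got$gene == g), 3L * L)
    }
  }
})

test_that("complementary-strand genes classify identically after genome flip", {
  truth <- generate_toy_genome(42, n_genes = 2L, codons_per_gene = 8L)
  g <- truth$genes[truth$genes$strand == "L", ][1L, ]
  gl <- nchar(truth$genome)
  enum_L <- enumerate_coding_space(manual_coding_bundle(truth$genome, g),
                                   truth$genome)
  # reverse-complement the whole genome and re-place the gene on strand H
  flipped <- MitoVarAnnot:::revcomp(truth$genome)
  g2 <- coding_gene(g$name, gl - g$end + 1L, gl - g$start + 1L, "H")
  enum_H <- enumerate_coding_space(manual_coding_bundle(flipped, g2), flipped)
  expect_equal(enum_L$summary$counts, enum_H$summary$counts)
  # record-level agreement under the coordinate/allele transformation
  a <- enum_L$substitutions
  b <- enum_H$substitutions
  a_key <- sort(paste(gl - a$pos + 1L, MitoVarAnnot:::comp_base(a$ref),
                      MitoVarAnnot:::comp_base(a$alt), a$effect))
  b_key <- sort(paste(b$pos, b$ref, b$alt, b$effect))
  expect_equal(a_key, b_key)
})

test_that("incomplete terminal codons follow the declared convention", {
  # gene ATG GCT TA : 8 nt, incomplete terminal codon "TA"
  genome <- paste0("AAAA", "ATGGCTTA", "AAAA")
  gene <- coding_gene("TOYI", 5L, 12L)
  bundle <- manual_coding_bundle(genome, gene)

  enum <- enumerate_coding_space(bundle, genome)
  expect_equal(nrow(enum$substitutions), 18L)     # 6 complete-codon positions
  expect_equal(enum$summary$skipped_incomplete_positions, 2L)
  expect_error(classify_substitution(gene, 11L, "C", genome),
               class = "mva_incomplete_codon_error")

  enum2 <- enumerate_coding_space(bundle, genome,
                                  include_incomplete_stops = TRUE)
  expect_equal(nrow(enum2$substitutions), 24L)    # + the 2 real TA positions
  expect_equal(enum2$summary$skipped_incomplete_positions, 0L)
  # A-completion makes the terminal codon TAA; mutating it can lose the stop
  term <- enum2$substitutions[enum2$substitutions$pos >= 11L, ]
  expect_true(any(term$effect == "stop_loss"))
})

test_that("degenerate inputs: zero genes, bad reference", {
  genome <- strrep("ACGT", 10L)
  empty <- manual_coding_bundle(genome, coding_gene("X", 1L, 4L)[0L, ])
  enum <- enumerate_coding_space(empty, genome)
  expect_equal(nrow(enum$substitutions), 0L)
  expect_equal(unlist(enum$summary$counts), c(synonymous = 0L,
               nonsynonymous = 0L, stop_gain = 0L, stop_loss = 0L))
  bundle <- manual_coding_bundle(genome, coding_gene("X", 1L, 6L))
  expect_error(enumerate_coding_space(bundle, "ACGT"),
               class = "mva_validation_error")   # length mismatch
  expect_error(enumerate_coding_space(bundle, NULL), class = "mva_load_error")
})

test_that("overlapping genes yield per-context records plus dedup counts", {
  # two overlapping in-frame genes sharing 6 positions
  genome <- paste0("ATGCATAGAATGGCTTGGTAA")      # 21 nt
  genes <- rbind(coding_gene("OVA", 1L, 9L),     # ATG CAT AGA
                 coding_gene("OVB", 7L, 21L))    # AGA ATG ... wait stop first
  # OVB starts inside OVA's stop codon; both frames are enumerated as-is
  bundle <- manual_coding_bundle(genome, genes)
  enum <- enumerate_coding_space(bundle, genome)
  expect_equal(nrow(enum$substitutions), 3L * (9L + 15L))
  dedup <- unique(enum$substitutions[, c("pos", "ref", "alt", "effect")])
  expect_equal(unlist(enum$summary$counts_dedup),
               unlist(MitoVarAnnot:::count_effects(dedup)))
  expect_true(sum(unlist(enum$summary$counts_dedup)) <
                sum(unlist(enum$summary$counts)))
})
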