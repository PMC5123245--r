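test_that("generation is deterministic under a fixed seed", {
  expect_identical(generate_trna_map(7, "0", 2L), generate_trna_map(7, "0", 2L))
  t1 <- generate_toy_genome(7, n_genes = 2L, codons_per_gene = 4L, n_trna = 1L)
  t2 <- generate_toy_genome(7, n_genes = 2L, codons_per_gene = 4L, n_trna = 1L)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$truth, t2$truth)
  expect_identical(generate_variants(3, t1, 10L), generate_variants(3, t2, 10L))
  # a different seed changes the genome
  expect_false(identical(
    t1$genome, generate_toy_genome(8, n_genes = 2L, codons_per_gene = 4L,
                                   n_trna = 1L)$genome))
})

test_that("a 3-codon single-gene genome yields 27 classified substitutions", {
  truth <- generate_toy_genome(7, n_genes = 1L, codons_per_gene = 3L)
  expect_equal(nrow(truth$truth), 27L)
  expect_setequal(unique(truth$truth$effect),
                  intersect(c("synonymous", "nonsynonymous", "stop_gain",
                              "stop_loss"), truth$truth$effect))
  gene <- truth$genes[1L, ]
  expect_equal(gene$end - gene$start + 1L, 9L)
  # the gene really starts ATG/ATA and ends in a mitochondrial stop
  cds <- MitoVarAnnot:::gene_coding_seq(as.list(gene), truth$genome)
  expect_true(substr(cds, 1, 3) %in% c("ATG", "ATA"))
  expect_true(substr(cds, 7, 9) %in% c("TAA", "TAG", "AGA", "AGG"))
})

test_that("generated structure maps satisfy the structural invariants", {
  for (seed in 1:8) {
    type <- c("0", "I", "II", "III")[(seed %% 4) + 1L]
    gaps <- seed %% 4
    tm <- generate_trna_map(seed, type, gap_count = gaps)
    p <- tm$map$positions
    sp <- p$sprinzl[!is.na(p$sprinzl)]
    expect_true(all(diff(sp) > 0L), info = seed)
    expect_equal(p$domain[!is.na(p$sprinzl) & p$sprinzl %in% 34:36],
                 rep("CL", 3L), info = seed)
    tert <- as.integer(unique(unlist(tm$map$tertiary)))
    expect_setequal(as.integer(p$sprinzl[p$folding == "Y" & !is.na(p$sprinzl)]),
                    intersect(tert, as.integer(p$sprinzl)))
    if (type == "III") expect_equal(sum(p$domain == "DS"), 0L)
  }
})

test_that("variant sampling honours n and attaches usable expectations", {
  truth <- generate_toy_genome(11, n_genes = 2L, codons_per_gene = 5L,
                               n_trna = 2L)
  expect_equal(nrow(generate_variants(1, truth, 0L)), 0L)
  expect_error(generate_variants(1, truth, nchar(truth$genome) + 1L),
               class = "mva_generation_error")
  vars <- generate_variants(2, truth, 40L)
  expect_equal(nrow(vars), 40L)
  expect_true(all(vars$ref != vars$alt))
  # tRNA sites carry a five-field expectation, intergenic sites an empty locus
  in_trna <- nzchar(vars$expected_trna_annotation)
  expect_true(all(lengths(strsplit(
    vars$expected_trna_annotation[in_trna], ";")) == 5L))
  # end-to-end: the pipeline reproduces every expectation
  ann <- annotate_variants(new_variants(vars$pos, vars$ref, vars$alt),
                           truth$bundle)
  expect_equal(ann$locus, vars$expected_locus)
  expect_equal(ann$trna_annotation, vars$expected_trna_annotation)
})

test_that("synthetic truth serializes through the production bundle loaders", {
  truth <- generate_toy_genome(13, n_genes = 1L, codons_per_gene = 4L,
                               n_trna = 2L)
  dir <- withr::local_tempdir()
  write_reference_bundle(truth$bundle, dir)
  reloaded <- load_reference_bundle(dir)
  expect_equal(reloaded$genes, truth$bundle$genes)
  for (g in names(truth$trna_maps))
    expect_equal(reloaded$trna_maps[[g]]$positions,
                 truth$trna_maps[[g]]$positions, info = g)
  # annotation through the reloaded bundle matches the in-memory one
  gene <- truth$genes[truth$genes$biotype == "tRNA", ][1L, ]
  pos <- gene$start + 5L
  expect_equal(format_trna_annotation(annotate_trna_position(pos, reloaded)),
               format_trna_annotation(annotate_trna_position(pos, truth$bundle)))
})
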