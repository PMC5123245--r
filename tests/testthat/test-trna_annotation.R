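test_that("the tRNA-Met worked example annotates fully", {
  b <- default_bundle()
  a <- annotate_trna_position(4450, b)
  expect_equal(a$gene, "MT-TM")
  expect_equal(a$sprinzl, 53L)
  expect_equal(a$trna_type, "II")
  expect_equal(a$domain, "TS")
  expect_equal(a$mature_nt, "G")
  expect_equal(a$folding, "N")
  expect_equal(format_trna_annotation(a), "53;II;TS;G;N")
})

test_that("positions outside tRNA genes return NULL", {
  b <- default_bundle()
  expect_null(annotate_trna_position(5000, b))   # MT-ND2
  expect_null(annotate_trna_position(200, b))    # control region
  expect_null(annotate_trna_position(1000, b))   # MT-RNR1
})

test_that("light-strand tRNAs are annotated along their own 5'->3' direction", {
  b <- default_bundle()
  # MT-TQ (4329-4400, L): gene offset 1 is reference position 4400
  a_first <- annotate_trna_position(4400, b)
  expect_equal(a_first$gene, "MT-TQ")
  first_mapped <- b$trna_maps[["MT-TQ"]]$positions[1L, ]
  expect_equal(a_first$sprinzl, first_mapped$sprinzl)
  # anticodon (Sprinzl 34-36) must land in the CL domain for every gene
  for (g in names(b$trna_maps)) {
    p <- b$trna_maps[[g]]$positions
    expect_equal(p$domain[!is.na(p$sprinzl) & p$sprinzl %in% 34:36],
                 rep("CL", 3L), info = g)
  }
})

test_that("format/parse are exact inverses, with '-' for unmapped", {
  a <- parse_trna_annotation("53;II;TS;G;N")
  expect_equal(format_trna_annotation(a), "53;II;TS;G;N")
  expect_equal(format_trna_annotation(parse_trna_annotation("34;0;CL;Q;N")),
               "34;0;CL;Q;N")
  u <- parse_trna_annotation("-;II;-;A;N")
  expect_true(is.na(u$sprinzl))
  expect_equal(format_trna_annotation(u), "-;II;-;A;N")
  expect_error(parse_trna_annotation("53;II;TS;G"), class = "mva_format_error")
  expect_error(parse_trna_annotation("53;II;XX;G;N"), class = "mva_format_error")
  bad <- parse_trna_annotation("53;II;TS;G;N")
  bad$domain <- "ZZ"
  expect_error(format_trna_annotation(bad), class = "mva_format_error")
})

test_that("build_structure_map enforces anticodon, monotonicity and partition", {
  gene <- list(name = "SYN-T1", start = 1L, end = 68L, strand = "H")
  aln <- generate_trna_map(11, "II", gap_count = 5L)$alignment

  dom <- MitoVarAnnot:::canonical_domain_table()
  dom$domain[dom$from == 32L] <- "CS"     # anticodon loop mislabelled
  expect_error(build_structure_map(gene, aln, domains = dom, species = NA),
               class = "mva_build_error")

  shuffled <- aln
  shuffled$sprinzl[c(10, 20)] <- shuffled$sprinzl[c(20, 10)]
  expect_error(build_structure_map(gene, shuffled, species = NA),
               class = "mva_build_error")

  overlapping <- MitoVarAnnot:::canonical_domain_table()
  overlapping$from[overlapping$from == 49L] <- 48L  # VL/TS overlap
  expect_error(build_structure_map(gene, aln, domains = overlapping, species = NA),
               class = "mva_build_error")
})

test_that("folding flags trace the tertiary set exactly", {
  gene <- list(name = "SYN-T1", start = 1L, end = 73L, strand = "H")
  aln <- generate_trna_map(3, "0", gap_count = 0L)$alignment
  map <- build_structure_map(gene, aln, tertiary = list(c(10L, 25L, 45L)),
                             species = NA)
  p <- map$positions
  expect_setequal(p$sprinzl[p$folding == "Y"], c(10L, 25L, 45L))
  expect_true(all(p$folding[!p$sprinzl %in% c(10L, 25L, 45L)] == "N"))
})

test_that("generated maps have the requested shape", {
  g0 <- generate_trna_map(1, "0", gap_count = 0L)
  expect_equal(nrow(g0$map$positions), 73L)
  expect_true(any(vapply(g0$map$tertiary, function(x)
    setequal(x, c(18L, 55L)), logical(1))))   # D/T-loop pairing present

  g2 <- generate_trna_map(1, "II", gap_count = 0L)
  expect_false(any(vapply(g2$map$tertiary, function(x)
    setequal(x, c(18L, 55L)), logical(1))))   # type II loses it

  g3 <- generate_trna_map(2, "III", gap_count = 4L)
  expect_equal(sum(g3$map$positions$domain == "DS"), 0L)  # no D-stem

  g5 <- generate_trna_map(9, "II", gap_count = 5L)
  expect_equal(nrow(g5$map$positions), 68L)
  expect_equal(sum(is.na(g5$map$positions$sprinzl)), 0L)
  expect_length(setdiff(1:73, g5$map$positions$sprinzl), 5L)

  gi <- generate_trna_map(4, "II", gap_count = 0L, insert_count = 2L)
  expect_equal(nrow(gi$map$positions), 75L)
  expect_equal(sum(is.na(gi$map$positions$sprinzl)), 2L)
  expect_error(generate_trna_map(1, "II", gap_count = 20L),
               class = "mva_generation_error")
})

test_that("annotation is exhaustive and matches the raw-alignment oracle", {
  b <- default_bundle()
  gl <- genome_length(b)
  for (g in b$genes$name[b$genes$biotype == "tRNA"]) {
    gene <- b$genes[b$genes$name == g, ]
    for (pos in seq.int(gene$start, gene$end)) {
      a <- annotate_trna_position(pos, b)
      expect_false(is.null(a), info = paste(g, pos))
    }
    p <- b$trna_maps[[g]]$positions
    sp <- p$sprinzl[!is.na(p$sprinzl)]
    expect_true(all(diff(sp) > 0L), info = g)   # Sprinzl monotonicity
  }

  # synthetic maps: annotation of every position equals raw-alignment lookup
  for (seed in 1:5) {
    truth <- generate_toy_genome(seed, n_genes = 1L, codons_per_gene = 3L,
                                 n_trna = 2L)
    for (g in names(truth$trna_maps)) {
      gene <- truth$genes[truth$genes$name == g, ]
      al <- truth$trna_alignments[[g]]
      for (pos in seq.int(gene$start, gene$end)) {
        off <- if (gene$strand == "L") gene$end - pos + 1L else pos - gene$start + 1L
        a <- annotate_trna_position(pos, truth$bundle)
        expect_equal(format_trna_annotation(a),
                     expected_annotation_from_alignment(
                       al$alignment, al$trna_type, al$tertiary, off),
                     info = paste(seed, g, pos))
      }
    }
  }
})
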