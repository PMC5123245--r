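test_that("packaged bundle loads with the full human gene map", {
  b <- default_bundle()
  expect_s3_class(b, "mito_bundle")
  expect_equal(genome_length(b), 16569L)
  expect_equal(sum(b$genes$biotype == "tRNA"), 22L)
  expect_equal(sum(b$genes$biotype == "rRNA"), 2L)
  expect_equal(sum(b$genes$biotype == "protein_coding"), 13L)
  expect_length(b$trna_maps, 22L)
  types <- vapply(b$trna_maps, `[[`, character(1), "trna_type")
  expect_equal(sum(types == "I"), 1L)    # one atypical-anticodon-stem tRNA
  expect_equal(sum(types == "III"), 1L)  # one D-armless tRNA
  # only the wrapping control region has end < start
  expect_equal(b$genes$name[b$genes$end < b$genes$start], "MT-DLOOP")
})

test_that("locate_position resolves loci, overlaps, wrap and bounds", {
  b <- default_bundle()
  expect_equal(locate_position(4450, b)$name, "MT-TM")
  # spacer between MT-TW and MT-TA is outside every annotated locus
  expect_equal(nrow(locate_position(5583, b)), 0L)
  # MT-TI / MT-TQ overlap: both loci, ordered by start
  expect_equal(locate_position(4330, b)$name, c("MT-TI", "MT-TQ"))
  # the control region wraps the origin
  expect_true("MT-DLOOP" %in% locate_position(16300, b)$name)
  expect_true("MT-DLOOP" %in% locate_position(300, b)$name)
  expect_error(locate_position(0, b), class = "mva_range_error")
  expect_error(locate_position(16570, b), class = "mva_range_error")
})

test_that("every genome position resolves and manifest cardinalities hold", {
  b <- default_bundle()
  gl <- genome_length(b)
  probe <- c(1L, 576L, 577L, 648L, 3307L, 8366L, 16024L, gl,
             sample.int(gl, 200L))
  for (p in probe) expect_s3_class(locate_position(p, b), "data.frame")
  tg <- b$genes[b$genes$biotype == "tRNA", ]
  expect_equal(sum(locus_length(tg$start, tg$end, gl)),
               b$manifest$counts$trna_positions)
  uniq <- length(unique(unlist(lapply(seq_len(nrow(tg)), function(i)
    seq.int(tg$start[i], tg$end[i])))))
  expect_equal(uniq, b$manifest$counts$trna_positions_unique)
})

test_that("bundle serialization round-trips to identical records", {
  b <- default_bundle()
  dir <- withr::local_tempdir()
  write_reference_bundle(b, dir)
  b2 <- load_reference_bundle(dir)
  expect_equal(b2$genes, b$genes)
  expect_equal(b2$mods, b$mods)
  expect_equal(b2$patho, b$patho)
  expect_equal(names(b2$trna_maps), names(b$trna_maps))
  for (g in names(b$trna_maps)) {
    expect_equal(b2$trna_maps[[g]]$positions, b$trna_maps[[g]]$positions,
                 info = g)
    expect_equal(b2$trna_maps[[g]]$tertiary, b$trna_maps[[g]]$tertiary,
                 info = g)
  }
})

test_that("missing files and corrupted rows are rejected by name and rule", {
  empty <- withr::local_tempdir()
  err <- tryCatch(load_reference_bundle(empty), error = identity)
  expect_s3_class(err, "mva_load_error")
  for (f in MitoVarAnnot:::BUNDLE_FILES)
    expect_match(conditionMessage(err), f, fixed = TRUE)

  # a CL-domain record outside the anticodon loop violates the anticodon rule
  dir <- copy_bundle()
  struct <- read.delim(file.path(dir, "trna_structure.tsv"), quote = "",
                       colClasses = "character")
  i <- which(struct$sprinzl == "20")[1L]
  struct$domain[i] <- "CL"
  MitoVarAnnot:::write_tsv_utf8(struct, file.path(dir, "trna_structure.tsv"))
  err <- tryCatch(load_reference_bundle(dir), error = identity)
  expect_s3_class(err, "mva_validation_error")
  expect_match(conditionMessage(err), "anticodon loop")

  # a mangled normalized score violates normalization self-consistency
  dir2 <- copy_bundle()
  patho <- read.delim(file.path(dir2, "rna_patho.tsv"), quote = "",
                      colClasses = "character")
  patho$normalized_score[1L] <- "0.999"
  MitoVarAnnot:::write_tsv_utf8(patho, file.path(dir2, "rna_patho.tsv"))
  expect_error(load_reference_bundle(dir2), class = "mva_validation_error")
})

test_that("modification table follows the published counting convention", {
  b <- default_bundle()
  s <- modification_summary(b)
  expect_equal(s$types, 16L)
  expect_equal(s$residues, 110L)
  expect_equal(s$records, 116L)
  # one Modomics symbol per modification name
  per_name <- tapply(b$mods$modomics_symbol, b$mods$mod_name,
                     function(x) length(unique(x)))
  expect_true(all(per_name == 1L))
})
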