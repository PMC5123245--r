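# Exhaustive enumeration and classification of the single-nucleotide
# mutational space of mitochondrial protein-coding genes under the vertebrate
# mitochondrial genetic code (TGA=Trp, ATA=Met, AGA/AGG=stop).

EFFECT_CLASSES <- c("synonymous", "nonsynonymous", "stop_gain", "stop_loss")

#' The vertebrate mitochondrial genetic code
#'
#' Named character vector mapping DNA codons to one-letter amino acids, with
#' "*" for the four stops (TAA, TAG, AGA, AGG).
#' @export
mito_genetic_code <- function() {
  Biostrings::getGeneticCode("SGC1")
}

# Coding-orientation sequence of a gene on a circular reference.
gene_coding_seq <- function(gene, ref_seq, genome_length = nchar(ref_seq)) {
  gene <- as.list(gene)
  if (gene$end >= gene$start) {
    s <- substr(ref_seq, gene$start, gene$end)
  } else {
    s <- paste0(substr(ref_seq, gene$start, genome_length),
                substr(ref_seq, 1L, gene$end))
  }
  if (identical(gene$strand, "L")) revcomp(s) else toupper(s)
}

# rCRS position of coding-orientation index j within a gene (wrap-aware).
coding_index_to_pos <- function(gene, j, genome_length) {
  gene <- as.list(gene)
  if (identical(gene$strand, "L")) {
    p <- gene$end - j + 1L
    ifelse(p >= 1L, p, p + genome_length)
  } else {
    p <- gene$start + j - 1L
    ifelse(p <= genome_length, p, p - genome_length)
  }
}

classify_codon_change <- function(ref_codon, alt_codon, code) {
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa))
    mva_stop("codon not in genetic code table: ", ref_codon, "/", alt_codon,
             class = "mva_domain_error")
  if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stop_gain"
  else if (ref_aa == "*") "stop_loss"
  else "nonsynonymous"
}

#' Classify one coding substitution
#'
#' `ref` and `alt` are given as forward (reference-strand) alleles; codons are
#' reported in coding orientation, complemented for genes transcribed from the
#' complementary strand.
#'
#' @param gene one gene locus (list or one-row data frame with `name`,
#'   `start`, `end`, `strand`).
#' @param pos rCRS coordinate inside the gene.
#' @param alt alternate base (forward strand).
#' @param ref_seq reference genome as a character string.
#' @param code genetic code table, by default the vertebrate mitochondrial one.
#' @param genome_length circular genome length.
#' @return one-row data frame (`CodingSubstitution`).
#' @export
classify_substitution <- function(gene, pos, alt, ref_seq,
                                  code = mito_genetic_code(),
                                  genome_length = nchar(ref_seq)) {
  gene <- as.list(gene)
  cds <- gene_coding_seq(gene, ref_seq, genome_length)
  len <- nchar(cds)
  j <- if (identical(gene$strand, "L")) gene$end - pos + 1L else pos - gene$start + 1L
  if (j < 1L) j <- j + genome_length
  if (j < 1L || j > len)
    mva_stop("position ", pos, " is not inside gene ", gene$name,
             class = "mva_domain_error")
  if (j > 3L * (len %/% 3L))
    mva_stop("position ", pos, " falls in the incomplete terminal codon of ",
             gene$name, "; enumerate with include_incomplete_stops=TRUE",
             class = "mva_incomplete_codon_error")
  alt <- toupper(alt)
  ref_fwd <- toupper(substr(ref_seq, pos, pos))
  if (!is_single_base(alt) || alt == ref_fwd)
    mva_stop("alt must be a single base different from the reference base",
             class = "mva_domain_error")
  coding_ref <- substr(cds, j, j)
  coding_alt <- if (identical(gene$strand, "L")) comp_base(alt) else alt
  codon_index <- (j - 1L) %/% 3L + 1L
  codon_pos <- (j - 1L) %% 3L + 1L
  ref_codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- coding_alt
  data.frame(gene = gene$name, pos = pos, ref = ref_fwd, alt = alt,
             codon_index = codon_index, codon_pos = codon_pos,
             ref_codon = ref_codon, alt_codon = alt_codon,
             effect = classify_codon_change(ref_codon, alt_codon, code),
             stringsAsFactors = FALSE)
}

enumerate_gene <- function(gene, ref_seq, code, genome_length,
                           include_incomplete_stops = FALSE) {
  gene <- as.list(gene)
  cds <- gene_coding_seq(gene, ref_seq, genome_length)
  len <- nchar(cds)
  rem <- len %% 3L
  eff_cds <- cds
  eff_len <- len
  if (rem != 0L) {
    if (include_incomplete_stops) {
      # Polyadenylation-completed terminal codon: pad with A's.
      eff_cds <- paste0(cds, strrep("A", 3L - rem))
      eff_len <- len           # only real positions are enumerated
    } else {
      eff_len <- len - rem     # incomplete terminal codon excluded
    }
  }
  n <- eff_len * 3L
  if (n == 0L)
    return(list(records = empty_substitutions(), skipped_incomplete = rem))
  bases <- strsplit(eff_cds, "", fixed = TRUE)[[1L]]
  j <- rep(seq_len(eff_len), each = 3L)
  coding_ref <- bases[j]
  coding_alt <- unlist(lapply(seq_len(eff_len),
                              function(i) setdiff(DNA_BASES, bases[i])),
                       use.names = FALSE)
  codon_index <- (j - 1L) %/% 3L + 1L
  codon_pos <- (j - 1L) %% 3L + 1L
  ref_codon <- vapply(codon_index, function(ci)
    paste(bases[(3L * ci - 2L):(3L * ci)], collapse = ""), character(1))
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- coding_alt  # vectorized over rows
  pos <- coding_index_to_pos(gene, j, genome_length)
  is_L <- identical(gene$strand, "L")
  effect <- vapply(seq_len(n), function(k)
    classify_codon_change(ref_codon[k], alt_codon[k], code), character(1))
  data.frame(gene = gene$name, pos = pos,
             ref = if (is_L) comp_base(coding_ref) else coding_ref,
             alt = if (is_L) comp_base(coding_alt) else coding_alt,
             codon_index = codon_index, codon_pos = codon_pos,
             ref_codon = ref_codon, alt_codon = alt_codon, effect = effect,
             stringsAsFactors = FALSE) -> records
  list(records = records, skipped_incomplete = if (include_incomplete_stops) 0L else rem)
}

empty_substitutions <- function() {
  data.frame(gene = character(), pos = integer(), ref = character(),
             alt = character(), codon_index = integer(), codon_pos = integer(),
             ref_codon = character(), alt_codon = character(),
             effect = character(), stringsAsFactors = FALSE)
}

count_effects <- function(records) {
  tab <- table(factor(records$effect, levels = EFFECT_CLASSES))
  as.list(as.integer(tab)) |> stats::setNames(EFFECT_CLASSES)
}

#' Enumerate the complete coding-gene mutational space
#'
#' Every position of every protein-coding gene is substituted with the three
#' alternate bases and classified under the vertebrate mitochondrial code.
#' Positions inside overlapping genes yield one record per gene context;
#' `summary$counts_dedup` additionally reports counts over unique
#' (pos, ref, alt, effect) tuples. Incomplete terminal codons (completed by
#' polyadenylation in vivo) are excluded by default and counted in
#' `summary$skipped_incomplete_positions`.
#'
#' @param bundle a `mito_bundle` providing the gene models.
#' @param ref_seq reference genome as a character string (circular).
#' @param include_incomplete_stops treat incomplete terminal codons as
#'   A-completed stops and enumerate their real positions.
#' @param code genetic code table.
#' @return list with `substitutions` (data frame) and `summary`.
#' @export
enumerate_coding_space <- function(bundle, ref_seq,
                                   include_incomplete_stops = FALSE,
                                   code = mito_genetic_code()) {
  if (missing(ref_seq) || is.null(ref_seq) || !nzchar(ref_seq))
    mva_stop("a reference sequence is required for coding-space enumeration",
             class = "mva_load_error")
  gl <- genome_length(bundle)
  if (nchar(ref_seq) != gl)
    mva_stop("reference length ", nchar(ref_seq),
             " does not match the bundle genome length ", gl,
             class = "mva_validation_error")
  genes <- bundle$genes[bundle$genes$biotype == "protein_coding", , drop = FALSE]
  parts <- lapply(seq_len(nrow(genes)), function(i)
    enumerate_gene(genes[i, ], ref_seq, code, gl, include_incomplete_stops))
  records <- do.call(rbind, c(lapply(parts, `[[`, "records"),
                              list(empty_substitutions())))
  rownames(records) <- NULL
  per_gene <- lapply(stats::setNames(nm = genes$name), function(g)
    count_effects(records[records$gene == g, , drop = FALSE]))
  dedup <- unique(records[, c("pos", "ref", "alt", "effect")])
  list(substitutions = records,
       summary = list(
         n_genes = nrow(genes),
         n_records = nrow(records),
         counts = count_effects(records),
         counts_dedup = count_effects(dedup),
         per_gene = per_gene,
         skipped_incomplete_positions =
           sum(vapply(parts, `[[`, integer(1), "skipped_incomplete")),
         include_incomplete_stops = include_incomplete_stops))
}
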