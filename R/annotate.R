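# The annotated variant table: one row per input variant with locus context,
# the five-field tRNA annotation, RNA pathogenicity scoring and pass-through
# database columns.

#' Column set of the annotated variant table
#'
#' Fixed order; empty cells are empty strings, matching the convention that
#' absent annotations are omitted rather than printed as NA.
#' @export
ANNOTATION_COLUMNS <- c(
  "pos", "ref", "alt", "kind", "hgvs", "locus", "trna_annotation",
  "rna_raw_score", "rna_norm_score", "rna_prediction", "rna_class",
  "nt_variability", "mitomap_diseases", "mitomap_homoplasmy",
  "mitomap_heteroplasmy", "clinvar", "dbsnp", "omim", "mamit_trna",
  "phastcons20way", "phylop20way")

PASSTHROUGH_COLUMNS <- c("nt_variability", "mitomap_diseases",
                         "mitomap_homoplasmy", "mitomap_heteroplasmy",
                         "clinvar", "dbsnp", "omim", "mamit_trna",
                         "phastcons20way", "phylop20way")

annotate_one <- function(pos, ref, alt, kind, hgvs, bundle) {
  loci <- locate_position(pos, bundle)
  row <- stats::setNames(as.list(rep("", length(ANNOTATION_COLUMNS))),
                         ANNOTATION_COLUMNS)
  row$pos <- pos; row$ref <- ref; row$alt <- alt; row$kind <- kind; row$hgvs <- hgvs
  row$locus <- paste(loci$name, collapse = ",")
  ann <- annotate_trna_position(pos, bundle)
  if (!is.null(ann)) row$trna_annotation <- format_trna_annotation(ann)
  rec <- lookup_rna_prediction(pos, ref, alt, bundle)
  if (!is.null(rec)) {
    scheme <- scoring_scheme(rec$scheme)
    row$rna_raw_score <- as.character(rec$raw_score)
    row$rna_norm_score <- as.character(rec$normalized_score)
    row$rna_prediction <- rec$prediction
    row$rna_class <- classify_rna_variant(rec$normalized_score, scheme)
  }
  pt <- bundle$passthrough
  hit <- pt[pt$position == pos & pt$ref == ref & pt$alt == alt, , drop = FALSE]
  if (nrow(hit)) {
    for (col in intersect(PASSTHROUGH_COLUMNS, names(hit)))
      row[[col]] <- hit[[col]][1L]
  }
  row
}

#' Annotate a variant table against the reference bundle
#'
#' @param variants data frame from [read_variants()] / [new_variants()].
#' @param bundle a `mito_bundle`.
#' @return data frame with the [ANNOTATION_COLUMNS] column set, one row per
#'   input variant, input order preserved.
#' @examples
#' v <- new_variants(4450, "G", "A")
#' annotate_variants(v, default_bundle())[, c("locus", "trna_annotation",
#'                                            "rna_norm_score")]
#' @export
annotate_variants <- function(variants, bundle) {
  stopifnot(is.data.frame(variants))
  rows <- lapply(seq_len(nrow(variants)), function(i)
    annotate_one(variants$pos[i], variants$ref[i], variants$alt[i],
                 variants$kind[i], variants$hgvs[i], bundle))
  schema <- as.data.frame(lapply(stats::setNames(nm = ANNOTATION_COLUMNS),
                                 function(x) character(0)),
                          stringsAsFactors = FALSE, check.names = FALSE)
  out <- do.call(rbind, c(lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)), list(schema)))
  out$pos <- as.integer(out$pos)
  rownames(out) <- NULL
  out[, ANNOTATION_COLUMNS]
}

#' Summary statistics of an annotation run
#'
#' @param annotated output of [annotate_variants()].
#' @param bundle the bundle used.
#' @return list of counts (per biotype, per variant kind, damaging/neutral).
#' @export
annotation_summary <- function(annotated, bundle) {
  biotype_of <- function(locus) {
    if (!nzchar(locus)) return("intergenic")
    first <- strsplit(locus, ",", fixed = TRUE)[[1L]][1L]
    bundle$genes$biotype[bundle$genes$name == first][1L]
  }
  biotypes <- vapply(annotated$locus, biotype_of, character(1), USE.NAMES = FALSE)
  list(n_variants = nrow(annotated),
       by_biotype = as.list(table(biotypes)),
       by_kind = as.list(table(annotated$kind)),
       scored = sum(nzchar(annotated$rna_norm_score)),
       damaging = sum(annotated$rna_class == "damaging"),
       neutral = sum(annotated$rna_class == "neutral"))
}
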