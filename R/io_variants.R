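# Variant input (VCF / tab-delimited), substitution-class typing and HGVS
# naming for mitochondrial variants.

VARIANT_KINDS <- c("transition", "transversion", "insertion", "deletion", "other")

#' Substitution class of a variant
#'
#' Transition for single-base A<->G / C<->T changes, transversion for the
#' other single-base changes; insertion/deletion by allele-length comparison;
#' "other" for equal-length multi-base replacements.
#' @param ref,alt allele strings (DNA alphabet).
#' @export
variant_kind <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  mapply(function(r, a) {
    if (nchar(a) > nchar(r)) return("insertion")
    if (nchar(a) < nchar(r)) return("deletion")
    if (nchar(r) == 1L && is_single_base(r) && is_single_base(a)) {
      if (paste0(r, a) %in% c("AG", "GA", "CT", "TC")) "transition" else "transversion"
    } else "other"
  }, ref, alt, USE.NAMES = FALSE)
}

#' Construct a normalized variant table
#' @param pos 1-based rCRS positions.
#' @param ref,alt allele strings.
#' @return data frame with `pos`, `ref`, `alt`, `kind`, `hgvs`.
#' @export
new_variants <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- toupper(ref); alt <- toupper(alt)
  if (any(is.na(pos)) || any(!nzchar(ref) & !nzchar(alt)))
    mva_stop("variants need a numeric position and at least one allele",
             class = "mva_parse_error")
  if (any(ref == alt))
    mva_stop("ref and alt alleles must differ", class = "mva_parse_error")
  data.frame(pos = pos, ref = ref, alt = alt,
             kind = variant_kind(ref, alt),
             hgvs = hgvs_name(pos, ref, alt), stringsAsFactors = FALSE)
}

#' HGVS name of a mitochondrial variant
#'
#' Substitutions render as `m.<pos><ref>><alt>`; deletions as `m.<pos>del` /
#' `m.<start>_<end>del`; insertions as `m.<pos>_<pos+1>ins<seq>`; other
#' replacements as `m.<start>_<end>delins<seq>`. VCF-style anchored indel
#' alleles (shared leading base) are trimmed first.
#' @param pos,ref,alt variant in 1-based coordinates, DNA alleles.
#' @export
hgvs_name <- function(pos, ref, alt) {
  mapply(function(p, r, a) {
    r <- toupper(r); a <- toupper(a)
    if (!nzchar(r) && !nzchar(a))
      mva_stop("empty alleles cannot be named", class = "mva_format_error")
    if (r == a)
      mva_stop("ref and alt alleles must differ", class = "mva_format_error")
    if (nchar(r) == 1L && nchar(a) == 1L && nzchar(r) && nzchar(a))
      return(sprintf("m.%d%s>%s", p, r, a))
    # trim a shared leading (anchor) base, VCF convention
    while (nchar(r) && nchar(a) && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
    }
    if (!nchar(a)) {          # deletion of r starting at p
      if (nchar(r) == 1L) sprintf("m.%ddel", p)
      else sprintf("m.%d_%ddel", p, p + nchar(r) - 1L)
    } else if (!nchar(r)) {   # insertion between p-1 and p
      sprintf("m.%d_%dins%s", p - 1L, p, a)
    } else if (nchar(r) == 1L && nchar(a) == 1L) {
      sprintf("m.%d%s>%s", p, r, a)
    } else {
      sprintf("m.%d_%ddelins%s", p, p + nchar(r) - 1L, a)
    }
  }, as.integer(pos), ref, alt, USE.NAMES = FALSE)
}

read_variants_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(new_variants(integer(), character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  has_header <- is.na(suppressWarnings(as.integer(first[1L])))
  if (has_header) fields <- fields[-1L]
  if (!length(fields)) return(new_variants(integer(), character(), character()))
  bad <- which(vapply(fields, length, integer(1)) < 3L |
                 is.na(suppressWarnings(vapply(fields, function(f)
                   as.integer(f[1L]), integer(1)))))
  if (length(bad))
    mva_stop("malformed variant row at line ",
             bad[1L] + if (has_header) 1L else 0L, " of ", path,
             class = "mva_parse_error")
  new_variants(vapply(fields, function(f) as.integer(f[1L]), integer(1)),
               vapply(fields, `[[`, character(1), 2L),
               vapply(fields, `[[`, character(1), 3L))
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(new_variants(integer(), character(), character()))
  on_mt <- fix$CHROM %in% MT_CONTIG_ALIASES
  if (any(!on_mt))
    warning(sum(!on_mt), " record(s) on non-mitochondrial contig(s) skipped",
            call. = FALSE)
  fix <- fix[on_mt, , drop = FALSE]
  if (!nrow(fix)) return(new_variants(integer(), character(), character()))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)   # split multi-allelic records
  n <- lengths(alts)
  new_variants(rep(as.integer(fix$POS), n), rep(fix$REF, n), unlist(alts))
}

#' Read a variant list from VCF or tab-delimited text
#'
#' The tab-delimited format is 1-based position, ref allele, alt allele
#' (optional further columns ignored), with or without a header line.
#' Multi-allelic VCF records are split into one variant per alternate allele;
#' records on non-mitochondrial contigs are skipped with a warning.
#' @param path input file.
#' @param format "vcf" or "tsv" (default guessed from the extension).
#' @return normalized variant data frame, see [new_variants()].
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    mva_stop("variant file not found: ", path, class = "mva_load_error")
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
}
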