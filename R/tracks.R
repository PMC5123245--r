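# GFF3 custom tracks: MT-patho.CDS, MT-patho.STOP, MT-patho.RNA, MT-RNA.
# Records are plain data frames (seqid, source, type, start, end, score,
# strand, phase, attributes); the writer is strict GFF3 version 3 and
# re-parsing goes through rtracklayer.

TRACK_NAMES <- c("MT-patho.CDS", "MT-patho.STOP", "MT-patho.RNA", "MT-RNA")
GFF3_SOURCE <- "MitoVarAnnot"
SEQID_DIALECTS <- c("chrM", "MT", "NC_012920.1")

# Percent-encoding of characters reserved in GFF3 attribute values.
gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

# Build the column-9 attribute string from a named list, dropping empties.
gff3_attributes <- function(...) {
  kv <- list(...)
  kv <- kv[vapply(kv, function(v) length(v) > 0 && nzchar(as.character(v)),
                  logical(1))]
  paste(vapply(names(kv), function(k)
    paste0(k, "=", gff3_encode(as.character(kv[[k]]))), character(1)),
    collapse = ";")
}

new_gff3_records <- function(seqid, type, start, end, score, strand, attributes) {
  if (any(end < start)) mva_stop("GFF3 record with end < start",
                                 class = "mva_validation_error")
  n <- length(start)
  data.frame(seqid = seqid, source = rep(GFF3_SOURCE, n), type = type,
             start = as.integer(start), end = as.integer(end),
             score = score, strand = strand, phase = rep(".", n),
             attributes = attributes, stringsAsFactors = FALSE)
}

empty_gff3 <- function() {
  new_gff3_records(character(), character(), integer(), integer(),
                   character(), character(), character())
}

sort_track <- function(df) {
  out <- df[order(df$start, df$end, df$attributes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write one track as a GFF3 version 3 file
#' @param records track data frame as produced by [build_tracks()].
#' @param path output file.
#' @param genome_length declared in the `##sequence-region` pragma.
#' @export
write_gff3 <- function(records, path, genome_length = RCRS_LENGTH) {
  if (is.unsorted(records$start))
    mva_stop("track records must be sorted by start before writing",
             class = "mva_internal_error")
  seqid <- if (nrow(records)) records$seqid[1L] else "chrM"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               paste("##sequence-region", seqid, 1L, genome_length),
               if (nrow(records))
                 do.call(paste, c(records[, c("seqid", "source", "type", "start",
                                              "end", "score", "strand", "phase",
                                              "attributes")], sep = "\t"))),
             con = con, useBytes = TRUE)
  invisible(path)
}

#' Read a GFF3 track back into the package's record form
#'
#' Parsing is delegated to [rtracklayer::import()]; attribute key=value pairs
#' are re-assembled (keys sorted) so that a written track and its re-parsed
#' form are comparable record sets.
#' @param path GFF3 file.
#' @export
read_gff3_track <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(empty_gff3())
  md <- S4Vectors::mcols(gr)
  core <- c("source", "type", "score", "phase")
  attr_cols <- setdiff(colnames(md), core)
  attrs <- vapply(seq_along(gr), function(i) {
    kv <- character(0)
    for (k in sort(attr_cols)) {
      v <- md[[k]][i]
      if (is.list(v) || inherits(v, "CharacterList")) v <- unlist(v)
      if (length(v) && !all(is.na(v)) && nzchar(paste(v, collapse = "")))
        kv <- c(kv, paste0(k, "=", gff3_encode(paste(v, collapse = ","))))
    }
    paste(kv, collapse = ";")
  }, character(1))
  strand <- as.character(BiocGenerics::strand(gr))
  new_gff3_records(as.character(GenomeInfoDb::seqnames(gr)),
                   as.character(md$type),
                   BiocGenerics::start(gr), BiocGenerics::end(gr),
                   ifelse(is.na(md$score), ".", sprintf("%.3f", md$score)),
                   ifelse(strand == "*", ".", strand),
                   attrs)
}

# Canonical comparable form of a track data frame (attribute keys sorted).
canonical_track <- function(df) {
  norm_attr <- function(a) {
    parts <- sort(strsplit(a, ";", fixed = TRUE)[[1L]])
    paste(parts, collapse = ";")
  }
  out <- df
  out$attributes <- vapply(df$attributes, norm_attr, character(1), USE.NAMES = FALSE)
  out$score <- ifelse(out$score == ".", ".",
                      sprintf("%.3f", as.numeric(out$score)))
  out$source <- NULL
  out$phase <- NULL
  sort_track(out)
}

variant_track_records <- function(pos, ref, alt, seqid, score, strand, extra) {
  kind <- variant_kind(ref, alt)
  hgvs <- hgvs_name(pos, ref, alt)
  type <- ifelse(kind %in% c("transition", "transversion"), "SNV",
                 ifelse(kind == "insertion", "insertion",
                        ifelse(kind == "deletion", "deletion", "sequence_alteration")))
  end <- pos + pmax(nchar(ref), 1L) - 1L
  attrs <- vapply(seq_along(pos), function(i)
    do.call(gff3_attributes,
            c(list(ID = sprintf("%s_%05d", gsub("[^A-Za-z]", "", extra$track[i]), i),
                   Name = hgvs[i], ref = ref[i], alt = alt[i], kind = kind[i]),
              lapply(extra[setdiff(names(extra), "track")], `[[`, i))),
    character(1))
  new_gff3_records(seqid, type, pos, end, score, strand, attrs)
}

#' Build the four GFF3 custom tracks
#'
#' * `MT-patho.CDS`: all possible non-synonymous substitutions in the
#'   protein-coding genes (requires `enumeration`).
#' * `MT-patho.STOP`: all possible stop-gain and stop-loss substitutions
#'   (requires `enumeration`).
#' * `MT-patho.RNA`: the literature-scored tRNA/rRNA variants with normalized
#'   scores (GFF3 score column) and damaging/neutral calls.
#' * `MT-RNA`: one record per position of every tRNA and rRNA gene, carrying
#'   the five-field tRNA annotation where applicable.
#'
#' Variant records carry their HGVS name in the `Name` attribute; all tracks
#' are sorted by start.
#'
#' @param bundle a `mito_bundle`.
#' @param enumeration output of [enumerate_coding_space()], or `NULL` to emit
#'   the two coding tracks empty.
#' @param seqid GFF3 sequence identifier dialect.
#' @return named list of four track data frames.
#' @export
build_tracks <- function(bundle, enumeration = NULL,
                         seqid = c("chrM", "MT", "NC_012920.1")) {
  seqid <- match.arg(seqid)
  gl <- genome_length(bundle)

  coding <- function(effects) {
    if (is.null(enumeration)) return(empty_gff3())
    s <- enumeration$substitutions
    s <- s[s$effect %in% effects, , drop = FALSE]
    if (!nrow(s)) return(empty_gff3())
    variant_track_records(s$pos, s$ref, s$alt, seqid, ".", ".",
                          list(track = rep("pathocds", nrow(s)), gene = s$gene,
                               effect = s$effect, ref_codon = s$ref_codon,
                               alt_codon = s$alt_codon))
  }

  p <- bundle$patho
  rna_patho <- if (nrow(p)) {
    variant_track_records(p$position, p$ref, p$alt, seqid,
                          sprintf("%.3f", p$normalized_score), ".",
                          list(track = rep("pathorna", nrow(p)),
                               scheme = p$scheme,
                               raw_score = as.character(p$raw_score),
                               prediction = p$prediction,
                               class = vapply(seq_len(nrow(p)), function(i)
                                 classify_rna_variant(p$normalized_score[i],
                                                      scoring_scheme(p$scheme[i])),
                                 character(1))))
  } else empty_gff3()

  rna_genes <- bundle$genes[bundle$genes$biotype %in% c("tRNA", "rRNA"), , drop = FALSE]
  mt_rna <- if (nrow(rna_genes)) {
    parts <- lapply(seq_len(nrow(rna_genes)), function(i) {
      gene <- as.list(rna_genes[i, ])
      positions <- locus_positions(gene, gl)
      ann <- if (gene$biotype == "tRNA") {
        m <- bundle$trna_maps[[gene$name]]
        vapply(seq_along(positions), function(o)
          format_trna_annotation(new_trna_annotation(
            gene$name, m$positions$sprinzl[o], m$trna_type,
            m$positions$domain[o], m$positions$mature_nt[o],
            m$positions$folding[o])), character(1))
      } else rep("", length(positions))
      attrs <- vapply(seq_along(positions), function(o)
        gff3_attributes(ID = sprintf("%s_%03d", gene$name, o),
                        gene = gene$name, biotype = gene$biotype,
                        annotation = ann[o]), character(1))
      new_gff3_records(seqid, "region", positions, positions, ".",
                       if (gene$strand == "H") "+" else "-", attrs)
    })
    do.call(rbind, parts)
  } else empty_gff3()

  lapply(stats::setNames(list(coding("nonsynonymous"),
                              coding(c("stop_gain", "stop_loss")),
                              rna_patho, mt_rna), TRACK_NAMES), sort_track)
}

#' Write the four tracks to a directory
#' @param tracks output of [build_tracks()].
#' @param dir output directory.
#' @param genome_length for the `##sequence-region` pragma.
#' @return named vector of file paths.
#' @export
write_tracks <- function(tracks, dir, genome_length = RCRS_LENGTH) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stats::setNames(file.path(dir, paste0(names(tracks), ".gff3")),
                           names(tracks))
  for (nm in names(tracks)) write_gff3(tracks[[nm]], paths[[nm]], genome_length)
  paths
}
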