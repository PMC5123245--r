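# Normalization and classification of literature RNA pathogenicity scores.
# tRNA variants: integer scale 0-20, damaging threshold 0.350 (raw 7).
# rRNA variants: integer scale 0-5, damaging threshold 0.600 (raw 3).

TRNA_LABELS <- c("Neutral", "Possibly pathogenic",
                 "Possibly/definitely pathogenic", "Definitely pathogenic")
RRNA_LABELS <- c("Unlikely pathogenic", "Undetermined", "Not enough evidence",
                 "Likely pathogenic", "Expectedly pathogenic", "Proven pathogenic")

#' Scoring scheme for RNA-gene pathogenicity scores
#'
#' Raw literature scores are the citable source of truth; they are divided by
#' the scheme maximum to a 0-1 range. `label_map` gives the published
#' prediction label for every attainable raw score.
#'
#' @param name "tRNA" or "rRNA".
#' @return list with `name`, `max_raw`, `threshold`, `label_map` (named by
#'   raw score 0..max_raw).
#' @export
scoring_scheme <- function(name = c("tRNA", "rRNA")) {
  name <- match.arg(name)
  if (name == "tRNA") {
    label_map <- stats::setNames(
      c(rep("Neutral", 7),                            # 0-6
        rep("Possibly pathogenic", 4),                # 7-10
        rep("Possibly/definitely pathogenic", 3),     # 11-13
        rep("Definitely pathogenic", 7)),             # 14-20
      0:20)
    list(name = "tRNA", max_raw = 20L, threshold = 0.350, label_map = label_map)
  } else {
    label_map <- stats::setNames(
      c("Unlikely pathogenic", "Undetermined", "Not enough evidence",
        "Likely pathogenic", "Expectedly pathogenic", "Proven pathogenic"),
      0:5)
    list(name = "rRNA", max_raw = 5L, threshold = 0.600, label_map = label_map)
  }
}

#' Normalize a raw pathogenicity score to the 0-1 range
#'
#' @param raw integer raw score in 0..`scheme$max_raw`.
#' @param scheme a [scoring_scheme()].
#' @return `raw / max_raw`, rounded half-even to 3 decimals.
#' @examples
#' normalize_score(13, scoring_scheme("tRNA"))  # 0.65
#' normalize_score(3, scoring_scheme("rRNA"))   # 0.6
#' @export
normalize_score <- function(raw, scheme) {
  if (!is.numeric(raw) || length(raw) != 1L || is.na(raw) ||
      raw != trunc(raw) || raw < 0 || raw > scheme$max_raw)
    mva_stop("raw score must be an integer in 0..", scheme$max_raw,
             class = "mva_domain_error")
  round(raw / scheme$max_raw, 3)
}

#' Published prediction label for a raw score
#' @inheritParams normalize_score
#' @export
prediction_label <- function(raw, scheme) {
  if (raw < 0 || raw > scheme$max_raw)
    mva_stop("raw score must be an integer in 0..", scheme$max_raw,
             class = "mva_domain_error")
  unname(scheme$label_map[as.character(as.integer(raw))])
}

#' Damaging/neutral call for a normalized score
#'
#' Damaging iff the normalized score is greater than or equal to the scheme
#' threshold (the boundary is inclusive).
#' @param normalized normalized score in [0, 1].
#' @param scheme a [scoring_scheme()].
#' @return "damaging" or "neutral".
#' @export
classify_rna_variant <- function(normalized, scheme) {
  if (!is.numeric(normalized) || is.na(normalized) ||
      normalized < 0 || normalized > 1)
    mva_stop("normalized score must lie in [0, 1]", class = "mva_domain_error")
  if (normalized >= scheme$threshold) "damaging" else "neutral"
}

#' Allele-aware lookup of a scored RNA variant
#'
#' Matches on (position, ref, alt) exactly; distinct substitutions at the same
#' site carry distinct published scores, so there is no position-only
#' fallback.
#' @param pos,ref,alt substitution in reference (forward-strand) alleles.
#' @param bundle a `mito_bundle`.
#' @return one-row data frame (`RnaPathoRecord`) or `NULL`.
#' @export
lookup_rna_prediction <- function(pos, ref, alt, bundle) {
  p <- bundle$patho
  hit <- p[p$position == pos & p$ref == toupper(ref) & p$alt == toupper(alt), ,
           drop = FALSE]
  if (!nrow(hit)) return(NULL)
  hit[1L, , drop = FALSE]
}
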