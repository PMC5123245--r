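# Shared low-level helpers.

#' Length of the rCRS human mitochondrial genome (bp)
#' @export
RCRS_LENGTH <- 16569L

# Contig names accepted as "the" mitochondrial sequence in variant inputs.
MT_CONTIG_ALIASES <- c("chrM", "chrMT", "MT", "M", "NC_012920.1", "J01415.2", "rCRS")

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Reverse-complement of a DNA string (character scalar or vector of scalars).
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

is_single_base <- function(x) nchar(x) == 1L & toupper(x) %in% DNA_BASES

# stop() with a consistent condition class so callers/tests can target errors.
mva_stop <- function(..., class = "mva_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic RNG scope: run `expr` under a local seed without touching the
# caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

read_tsv_utf8 <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, con = con, useBytes = TRUE)
  invisible(path)
}
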