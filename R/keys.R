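#' Mutation keys
#'
#' A mutation is identified everywhere in this package by the 4-tuple
#' (chromosome, 1-based position, reference allele, alternate allele),
#' serialized as `"chrom:pos:ref:alt"`. Positions are 1-based and fully
#' closed; indels use the ref/alt slash style of the source tables (e.g. a
#' `TG/T` row is a 1-bp deletion). No left-normalisation is performed: keys
#' must match the input dialect exactly.
#'
#' @param chrom Chromosome label (e.g. `"chr1"`).
#' @param pos 1-based position (numeric).
#' @param ref,alt Allele strings; `ref != alt`.
#' @return `mut_key()` returns a character vector of keys.
#' @examples
#' mut_key("chr1", 26779439, "TG", "T")
#' parse_mut_key("chr 1: 26 779 439:TG/T")
#' @export
mut_key <- function(chrom, pos, ref, alt) {
  stopifnot(all(pos >= 1), all(ref != alt))
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ref, alt, sep = ":")
}

#' Parse a printed mutation label
#'
#' Accepts the report-style dialect `"chr 1: 26 779 439:TG/T"`: grouping
#' spaces inside the chromosome label and position are stripped, and the
#' trailing `ref/alt` pair is split on the slash.
#'
#' @param x Character vector of printed labels.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `key`.
#' @export
parse_mut_key <- function(x) {
  squeezed <- gsub("[[:space:]]+", "", x)
  m <- regmatches(squeezed, regexec("^(chr[0-9XYMT]+):([0-9]+):([ACGTN]+)/([ACGTN]+)$", squeezed))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("cannot parse mutation label(s): ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  chrom <- vapply(m, `[[`, character(1), 2L)
  pos <- as.numeric(vapply(m, `[[`, character(1), 3L))
  ref <- vapply(m, `[[`, character(1), 4L)
  alt <- vapply(m, `[[`, character(1), 5L)
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 key = mut_key(chrom, pos, ref, alt))
}

# effect classes the annotation column may take (closed set)
EFFECT_CLASSES <- c("MODIFIER", "LOW", "MODERATE", "HIGH")
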