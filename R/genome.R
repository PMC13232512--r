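#' Genome layout
#'
#' A minimal description of the genome the analysis runs on: an ordered set of
#' chromosomes with their lengths in base pairs. All coordinates in the
#' package are 0-based half-open (`[start, end)`, BED convention) and must
#' fall within `[0, length)` of their chromosome.
#'
#' @param chroms character vector of unique chromosome names, in order.
#' @param lengths integer-ish vector of chromosome lengths (bp), all > 0.
#'
#' @return An object of class `genome_layout`: a `data.table` with columns
#'   `chrom` and `length`, ordered as given.
#' @export
#' @examples
#' genome_layout(c("chrI", "chrII"), c(5e6, 3e6))
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths)) {
    stop("`chroms` and `lengths` must have the same length")
  }
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  out <- data.table(chrom = chroms, length = lengths)
  setattr(out, "class", c("genome_layout", class(out)))
  out[]
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosome(s), ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  NextMethod()
}

#' Look up chromosome lengths
#' @param layout a [genome_layout()].
#' @param chrom chromosome name(s).
#' @return numeric vector of lengths (bp); errors on unknown names.
#' @export
chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Tile a genome into fixed-width bins
#'
#' Produces the non-overlapping bin grid used throughout the pipeline
#' (2 kb recombination bins, 100 kb scan windows, 5 Mb correlation windows).
#' The last bin of each chromosome may be shorter than `width`; it is kept and
#' identifiable by `end - start < width`.
#'
#' @param layout a [genome_layout()].
#' @param width bin width in bp (> 0).
#'
#' @return `data.table` with columns `chrom`, `start`, `end` (half-open).
#' @export
tile_genome <- function(layout, width) {
  stopifnot(width > 0)
  out <- as.data.table(layout)[, {
    s <- seq(0, length - 1L, by = width)
    .(start = s, end = pmin(s + width, length))
  }, by = chrom]
  setattr(out, "class", c("data.table", "data.frame"))
  out[]
}
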