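#' Construct a set of genomic regions
#'
#' Regions use BED conventions: 0-based half-open `[start, end)`. On
#' construction intervals are sorted and overlapping or book-ended
#' intervals are merged, so the representation is canonical and invariant
#' to input order.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param label category name carried by the set (e.g. "hd", "exon").
#' @return A data frame of class `region_set` with columns chrom, start,
#'   end, sorted and merged, and a `label` attribute.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = "region") {
  if (any(start >= end))
    stop_format("region_set: start >= end for %d interval(s)", sum(start >= end))
  if (length(chrom) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start + 1L, end)))
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr))
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("region_set", "data.frame"), label = label)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d interval(s), %s bp\n",
              attr(x, "label"), nrow(x),
              format(sum(x$end - x$start), big.mark = ",")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

region_label <- function(x) attr(x, "label")

# GRanges view (1-based closed) of a region_set
regions_gr <- function(x) {
  if (nrow(x) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Read a BED file of regions
#'
#' Accepts 3+ column BED (0-based half-open). Intervals are merged and
#' sorted on load; malformed lines abort with their line number.
#'
#' @param path path to a BED file.
#' @param label category name to attach.
#' @return A [region_set()].
#' @export
read_regions <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(region_set(label = label))
  parts <- strsplit(lines, "[ \t]+")
  nfield <- lengths(parts)
  if (any(nfield < 3))
    stop_format("%s: line %d has fewer than 3 BED fields", path,
                which(nfield < 3)[1])
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop_format("%s: line %d has non-numeric coordinates", path, which(bad)[1])
  if (any(start >= end))
    stop_format("%s: line %d has start >= end", path, which(start >= end)[1])
  region_set(chrom, start, end, label = label)
}

#' Write a region set as BED
#' @param x a [region_set()].
#' @param path output path.
#' @export
write_regions <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Dilate every interval of a region set
#'
#' Used e.g. to turn gene bodies into "gene +/- 100 kb" context windows for
#' the intergenic classification.
#'
#' @param x a [region_set()].
#' @param pad_bp basepairs added on each side (starts floored at 0).
#' @export
dilate_regions <- function(x, pad_bp) {
  if (nrow(x) == 0) return(x)
  region_set(x$chrom, pmax(x$start - pad_bp, 0L), x$end + pad_bp,
             label = paste0(region_label(x), "+", pad_bp, "bp"))
}

#' Membership of SNP positions in a region set
#'
#' A 1-based SNP position `pos` is inside a BED interval `[start, end)`
#' when `start < pos <= end`.
#'
#' @param chrom,pos vectors of SNP coordinates (1-based positions), or a
#'   `genotype_panel` as the first argument.
#' @param regions a [region_set()].
#' @return Logical vector.
#' @export
snp_in_regions <- function(chrom, pos, regions) {
  if (inherits(chrom, "genotype_panel")) {
    regions <- pos
    pos <- chrom$snps$pos
    chrom <- chrom$snps$chrom
  }
  if (nrow(regions) == 0) return(rep(FALSE, length(pos)))
  snp_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # chromosomes absent from either side simply do not overlap; the
  # seqlevel-mismatch warning is noise for point queries
  suppressWarnings(IRanges::overlapsAny(snp_gr, regions_gr(regions)))
}
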