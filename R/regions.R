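#' Read a BED file of benchmark regions
#'
#' Reads the first three columns of a BED file (0-based, half-open
#' intervals) and returns a normalized region set: per chromosome, sorted,
#' with overlapping or touching intervals merged.
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t10", "chr1\t5\t15"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#", progress = FALSE,
    show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0) {
    return(empty_regions())
  }
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns.")
  regions <- tibble(
    chrom = raw[[1]],
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]]))
  )
  bad <- which(is.na(regions$start) | is.na(regions$end) |
    regions$start >= regions$end | regions$chrom == "")
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid BED interval(s) at row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  normalize_regions(regions)
}

empty_regions <- function() {
  tibble(chrom = character(), start = integer(), end = integer())
}

#' Normalize a region set
#'
#' Sorts regions and merges overlapping or touching intervals per
#' chromosome, so that the result is the canonical representation of the
#' covered set of bases.
#'
#' @param regions Tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A normalized region tibble.
#' @export
normalize_regions <- function(regions) {
  regions <- as_tibble(regions)[c("chrom", "start", "end")]
  if (nrow(regions) == 0) {
    return(empty_regions())
  }
  # IRanges is 1-based closed; merge adjacency with the default gap rule.
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  red <- GenomicRanges::reduce(gr)
  red <- GenomicRanges::sort(red)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  ) |> arrange(.data$chrom, .data$start)
}

#' Union of region sets
#'
#' Set-theoretic union of any number of region sets, returned normalized.
#' Commutative, associative, and idempotent.
#'
#' @param ... Region tibbles (or a single list of them).
#' @return A normalized region tibble covering the union.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
#' b <- tibble::tibble(chrom = "chr1", start = 5L, end = 15L)
#' union_regions(a, b)
#' @export
union_regions <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  normalize_regions(bind_rows(lapply(sets, as_tibble)))
}

#' Test whether calls' reference spans fall inside a region set
#'
#' A call's reference span is `[pos - 1, pos - 1 + nchar(ref))` in 0-based
#' half-open coordinates (VCF positions are 1-based). A call is inside the
#' region set only if its whole span is contained in a single region —
#' deliberately conservative for indels near region edges.
#'
#' @param calls Calls tibble with `chrom`, `pos`, `ref`.
#' @param regions Normalized region tibble.
#' @return Logical vector, one element per call.
#' @export
span_in_regions <- function(calls, regions) {
  if (nrow(calls) == 0) {
    return(logical(0))
  }
  if (nrow(regions) == 0) {
    return(rep(FALSE, nrow(calls)))
  }
  shared <- intersect(unique(calls$chrom), unique(regions$chrom))
  qr <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(start = calls$pos, width = nchar(calls$ref))
  )
  rr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  if (length(shared) == 0) {
    return(rep(FALSE, nrow(calls)))
  }
  GenomicRanges::countOverlaps(qr, rr, type = "within") > 0
}

#' Write a region set to a BED file
#'
#' @param regions Region tibble (normalized first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- normalize_regions(regions)
  readr::write_tsv(regions, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
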