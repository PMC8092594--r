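# Replicate-consensus filtering: regions supported at FDR < threshold in
# every treatment replicate and overlapping no qualifying control peak.

#' Filter peaks by false-discovery rate
#'
#' Retains peaks with FDR strictly below `fdr_threshold`. narrowPeak stores
#' the FDR as -log10(q) in the `qValue` column, so "FDR < 0.001" is the
#' strict inequality `qValue > 3`; a peak sitting exactly on the boundary is
#' removed. Input order is preserved.
#'
#' @param peaks peak `GRanges` (see [read_narrowpeak()]).
#' @param fdr_threshold FDR cutoff in (0, 1); default 0.001.
#' @return The qualifying subset of `peaks`.
#' @export
filter_by_fdr <- function(peaks, fdr_threshold = 0.001) {
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be a single number in (0, 1)")
  }
  peaks[peaks$qValue > -log10(fdr_threshold)]
}

#' Intersect peak calls across replicates
#'
#' Returns the maximal genomic intervals in which every replicate has at
#' least one covering peak: the base-wise intersection of the replicates'
#' peak coverage (common intersection, not pairwise chaining). Each region
#' records, per replicate, a representative supporting peak -- the
#' overlapping peak with the leftmost start, ties broken by lexicographic
#' peak name -- and its centre (interval midpoint, rounded towards the
#' lower coordinate). Strand is ignored throughout.
#'
#' @param replicate_peaks named list (length >= 1) of peak `GRanges`, one
#'   per replicate; unnamed lists get labels `rep1`, `rep2`, ...
#' @return `GRanges` of disjoint consensus regions, sorted, with metadata
#'   columns `region_id`, `center` (1-based position) and `support`
#'   (`"rep:peak_name"` entries joined by `,`).
#' @export
intersect_replicates <- function(replicate_peaks) {
  stopifnot(is.list(replicate_peaks), length(replicate_peaks) >= 1L)
  if (is.null(names(replicate_peaks))) {
    names(replicate_peaks) <- sprintf("rep%d", seq_along(replicate_peaks))
  }
  # AND of replicate coverage, chromosome by chromosome, as run-length
  # algebra: a base is consensus iff every replicate's coverage is positive
  covs <- lapply(replicate_peaks, function(p) {
    GenomicRanges::reduce(GenomicRanges::granges(p), ignore.strand = TRUE)
  })
  chroms <- sort(unique(unlist(lapply(covs, function(g) {
    as.character(unique(GenomeInfoDb::seqnames(g)))
  }))))
  per_chrom <- lapply(chroms, function(chrom) {
    irs <- lapply(covs, function(g) {
      IRanges::ranges(g[as.character(GenomeInfoDb::seqnames(g)) == chrom])
    })
    if (any(lengths(irs) == 0L)) return(NULL)
    W <- max(vapply(irs, function(ir) max(BiocGenerics::end(ir)), numeric(1)))
    covered <- Reduce(`&`, lapply(irs, function(ir) {
      IRanges::coverage(ir, width = W) > 0L
    }))
    runs <- IRanges::IRanges(covered)
    if (!length(runs)) return(NULL)
    GenomicRanges::GRanges(rep(chrom, length(runs)), runs)
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  regions <- if (length(per_chrom)) {
    suppressWarnings(do.call(c, per_chrom))
  } else GenomicRanges::GRanges()
  support <- character(length(regions))
  if (length(regions)) {
    per_rep <- lapply(names(replicate_peaks), function(r) {
      p <- replicate_peaks[[r]]
      hits <- GenomicRanges::findOverlaps(regions, p, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      # representative peak: leftmost start, then lexicographic name
      o <- order(qh, BiocGenerics::start(p)[sh], p$name[sh], method = "radix")
      keep <- o[!duplicated(qh[o])]
      out <- rep(NA_character_, length(regions))
      out[qh[keep]] <- paste0(r, ":", p$name[sh[keep]])
      out
    })
    support <- do.call(paste, c(per_rep, sep = ","))
  }
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    region_id = sprintf("cr%05d", seq_along(regions)),
    center = region_center(regions),
    support = support
  )
  regions
}

# midpoint of an interval, rounded towards the lower coordinate
region_center <- function(regions) {
  (BiocGenerics::start(regions) + BiocGenerics::end(regions)) %/% 2L
}

#' Remove consensus regions overlapping control peaks
#'
#' Drops any region sharing at least one base with a control peak that
#' itself passes the FDR filter at the same threshold used for treatment
#' peaks; surviving regions are returned unchanged, in order. Applying the
#' filter twice is a no-op.
#'
#' @param regions consensus `GRanges` from [intersect_replicates()].
#' @param control_peaks list of control peak `GRanges`.
#' @param fdr_threshold FDR cutoff applied to the control peaks.
#' @return The surviving subset of `regions`.
#' @export
exclude_control <- function(regions, control_peaks, fdr_threshold = 0.001) {
  if (!length(control_peaks) || !length(regions)) return(regions)
  qualifying <- Reduce(c, lapply(unname(control_peaks), function(p) {
    GenomicRanges::granges(filter_by_fdr(p, fdr_threshold))
  }))
  if (!length(qualifying)) return(regions)
  hit <- IRanges::overlapsAny(regions, qualifying, ignore.strand = TRUE)
  regions[!hit]
}

#' Write consensus regions to BED
#'
#' BED5 with the region id and its per-replicate support provenance packed
#' into the name column as `id|rep:peak,rep:peak,...`.
#'
#' @param regions consensus `GRanges`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_consensus_bed <- function(regions, file) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0",
                   as.character(GenomeInfoDb::seqnames(regions)),
                   BiocGenerics::start(regions) - 1L,
                   BiocGenerics::end(regions),
                   regions$region_id, regions$support)
  writeLines(lines, file)
  invisible(file)
}

#' Read consensus regions from BED
#'
#' Inverse of [write_consensus_bed()].
#'
#' @param file path to a consensus BED file.
#' @return Consensus `GRanges` with `region_id`, `center`, `support`.
#' @export
read_consensus_bed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      region_id = character(0), center = integer(0), support = character(0))
    return(gr)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) stop("consensus BED needs >= 4 columns")
  name <- vapply(f, `[`, character(1), 4L)
  parts <- strsplit(name, "|", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    vapply(f, `[`, character(1), 1L),
    IRanges::IRanges(as.integer(vapply(f, `[`, character(1), 2L)) + 1L,
                     as.integer(vapply(f, `[`, character(1), 3L)))
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    region_id = vapply(parts, `[`, character(1), 1L),
    center = region_center(gr),
    support = vapply(parts, function(p) if (length(p) > 1L) p[2L] else "",
                     character(1))
  )
  gr
}
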