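# Peak-to-gene assignment: a consensus region is associated with a gene
# when its centre falls within the gene's window (default 3 kb upstream to
# 1.5 kb downstream of the coding span, strand-aware, boundaries inclusive)
# and no other gene's transcribed span lies between the centre and the
# gene's anchor span. A region may be assigned to several genes (divergent
# promoters); the intervening-gene veto applies per candidate gene.

#' Build strand-aware gene windows
#'
#' Extends each gene's anchor span (coding by default, transcribed
#' optionally) by `upstream_bp` on its 5' side and `downstream_bp` on its 3'
#' side, clipping at chromosome boundaries. A position exactly
#' `upstream_bp` before the anchor start (or `downstream_bp` past its end)
#' is inside the window: "within" is read inclusively.
#'
#' @param annotation annotation `GRanges` (see [gene_annotation()]).
#' @param upstream_bp,downstream_bp window extensions in bp.
#' @param anchor `"coding"` (default) or `"transcript"`: which span the
#'   window extends.
#' @return `GRanges` of windows with metadata columns `gene_id`,
#'   `anchor_start`, `anchor_end` (1-based closed anchor span).
#' @export
build_windows <- function(annotation, upstream_bp = 3000L,
                          downstream_bp = 1500L,
                          anchor = c("coding", "transcript")) {
  anchor <- match.arg(anchor)
  validate_annotation(annotation)
  if (upstream_bp < 0 || downstream_bp < 0) {
    stop("window extensions must be >= 0")
  }
  a <- anchor_span(annotation, anchor)
  minus <- as.character(BiocGenerics::strand(annotation)) == "-"
  left <- ifelse(minus, downstream_bp, upstream_bp)
  right <- ifelse(minus, upstream_bp, downstream_bp)
  sl <- GenomeInfoDb::seqlengths(annotation)[
    as.character(GenomeInfoDb::seqnames(annotation))]
  win <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(annotation),
    IRanges::IRanges(pmax(1L, a$start - as.integer(left)),
                     pmin(as.integer(sl), a$end + as.integer(right))),
    strand = BiocGenerics::strand(annotation),
    seqinfo = GenomeInfoDb::seqinfo(annotation)
  )
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(
    gene_id = annotation$gene_id, anchor_start = a$start, anchor_end = a$end
  )
  win
}

# anchor span coordinates (1-based closed) for every gene
anchor_span <- function(annotation, anchor) {
  if (anchor == "coding") {
    list(start = annotation$cds_start, end = annotation$cds_end)
  } else {
    list(start = BiocGenerics::start(annotation),
         end = BiocGenerics::end(annotation))
  }
}

#' Assign consensus regions to genes
#'
#' Tests each region's centre against every gene window; a (region, gene)
#' pair is kept iff the centre lies in the window and no other gene's
#' transcribed span overlaps the open interval between the centre and the
#' nearest boundary of the candidate's anchor span (no veto is possible
#' when the centre lies inside the anchor span). Zone and signed offset are
#' computed strand-aware relative to the anchor span: `promoter` offsets
#' are negative (bp before the anchor start), `transcribed` offsets count
#' 5'->3' from 0 within the anchor, `downstream` offsets are positive bp
#' past the anchor end.
#'
#' @param regions consensus `GRanges` from [intersect_replicates()] (or any
#'   `GRanges` with `region_id` and `center` columns).
#' @param windows windows from [build_windows()].
#' @param annotation the annotation the windows were built from.
#' @return data.frame with columns `region_id`, `gene_id`, `zone`,
#'   `offset`, `chrom`, `center`, sorted by (region_id, gene_id).
#' @export
assign_regions <- function(regions, windows, annotation) {
  empty <- data.frame(region_id = character(0), gene_id = character(0),
                      zone = character(0), offset = integer(0),
                      chrom = character(0), center = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(regions)) return(empty)
  centers <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(regions),
    IRanges::IRanges(regions$center, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(centers, windows, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  ri <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  ctr <- regions$center[ri]
  a_start <- windows$anchor_start[wi]
  a_end <- windows$anchor_end[wi]
  minus <- as.character(BiocGenerics::strand(windows))[wi] == "-"
  zone <- ifelse(ctr < a_start, ifelse(minus, "downstream", "promoter"),
          ifelse(ctr > a_end, ifelse(minus, "promoter", "downstream"),
                 "transcribed"))
  offset <- integer(length(ri))
  left <- ctr < a_start
  right <- ctr > a_end
  inside <- !left & !right
  offset[left] <- ifelse(minus[left], a_start[left] - ctr[left],
                         ctr[left] - a_start[left])
  offset[right] <- ifelse(minus[right], a_end[right] - ctr[right],
                          ctr[right] - a_end[right])
  offset[inside] <- ifelse(minus[inside], a_end[inside] - ctr[inside],
                           ctr[inside] - a_start[inside])

  # intervening-gene veto: any other gene's tx span overlapping the open
  # interval between the centre and the nearest anchor boundary
  gap_lo <- ifelse(left, ctr + 1L, a_end + 1L)
  gap_hi <- ifelse(left, a_start - 1L, ctr - 1L)
  check <- !inside & gap_lo <= gap_hi
  veto <- logical(length(ri))
  if (any(check)) {
    gaps <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(centers)[ri[check]],
      IRanges::IRanges(gap_lo[check], gap_hi[check])
    )
    gh <- GenomicRanges::findOverlaps(gaps, annotation, ignore.strand = TRUE)
    other <- annotation$gene_id[S4Vectors::subjectHits(gh)] !=
      windows$gene_id[wi[check]][S4Vectors::queryHits(gh)]
    veto[check] <- tabulate(S4Vectors::queryHits(gh)[other],
                            nbins = sum(check)) > 0L
  }
  keep <- !veto
  out <- data.frame(
    region_id = regions$region_id[ri[keep]],
    gene_id = windows$gene_id[wi[keep]],
    zone = zone[keep],
    offset = offset[keep],
    chrom = as.character(GenomeInfoDb::seqnames(regions))[ri[keep]],
    center = ctr[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$region_id, out$gene_id, method = "radix"), , drop = FALSE]
}

#' Collapse assignments to a target gene set
#'
#' @param assignments data.frame from [assign_regions()].
#' @return Sorted character vector of unique target gene IDs.
#' @export
target_gene_set <- function(assignments) {
  sort(unique(assignments$gene_id))
}

#' Write assignments as TSV
#'
#' @param assignments data.frame from [assign_regions()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_assignments <- function(assignments, file) {
  utils::write.table(assignments, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
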