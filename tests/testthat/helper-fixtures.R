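# Shared fixture builders and independent oracles. Coordinates in helpers
# are 1-based closed (the internal GRanges convention) unless a helper name
# says otherwise. Calls are namespace-qualified so the helpers work both
# against an installed package and under pkgload.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# peak GRanges from parallel vectors; qscore on the -log10 FDR scale
mk_peaks <- function(chrom, start, end, name = sprintf("p%d", seq_along(start)),
                     qscore = 10, summit = NA_integer_, seqlen = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlengths(gr) <- seqlen[GenomeInfoDb::seqlevels(gr)]
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = name, score = 0,
    signalValue = rep_len(1, length(gr)), pValue = rep_len(1, length(gr)),
    qValue = rep_len(qscore, length(gr)),
    peak = rep_len(as.integer(summit), length(gr))
  )
  gr
}

# annotation with explicit spans; cds defaults to tx
mk_annotation <- function(chrom, tx_start, tx_end, strand = "+",
                          gene_id = sprintf("g%d", seq_along(tx_start)),
                          cds_start = NA_integer_, cds_end = NA_integer_,
                          seqlen = c(chr1 = 1000000L)) {
  tx <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tx_start, tx_end),
                               strand = strand)
  GenomeInfoDb::seqlengths(tx) <- seqlen[GenomeInfoDb::seqlevels(tx)]
  gene_annotation(tx, gene_id, cds_start, cds_end)
}

# consensus regions by per-base boolean AND: a position belongs to a region
# iff every replicate has a peak covering it; maximal runs extracted by rle
oracle_consensus <- function(replicate_peaks, seqlens) {
  out <- list()
  for (chrom in names(seqlens)) {
    L <- seqlens[[chrom]]
    covered <- rep(TRUE, L)
    for (p in replicate_peaks) {
      pc <- p[as.character(GenomeInfoDb::seqnames(p)) == chrom]
      # per-base coverage depth from +1/-1 edge marks, then depth > 0
      d <- integer(L + 1L)
      s <- BiocGenerics::start(pc)
      e <- pmin(BiocGenerics::end(pc), L)
      for (i in seq_along(pc)) {
        d[s[i]] <- d[s[i]] + 1L
        d[e[i] + 1L] <- d[e[i] + 1L] - 1L
      }
      covered <- covered & (cumsum(d)[seq_len(L)] > 0L)
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                 end = ends[keep])
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  d <- do.call(rbind, out)
  BiocGenerics::sort(GenomicRanges::GRanges(d$chrom,
                                            IRanges::IRanges(d$start, d$end)),
                     ignore.strand = TRUE)
}

# literal all-pairs assignment oracle: for each region centre, window
# membership is tested against every gene, and every candidate is checked
# against every other gene's transcribed span for an intervening overlap --
# the rule applied verbatim, with the per-gene comparisons vectorised
oracle_assign <- function(centers, chroms, region_ids, annotation,
                          up = 3000L, down = 1500L, anchor = "coding") {
  g_chrom <- as.character(GenomeInfoDb::seqnames(annotation))
  minus_g <- as.character(BiocGenerics::strand(annotation)) == "-"
  if (anchor == "coding") {
    a_start <- annotation$cds_start; a_end <- annotation$cds_end
  } else {
    a_start <- BiocGenerics::start(annotation)
    a_end <- BiocGenerics::end(annotation)
  }
  tx_start <- BiocGenerics::start(annotation)
  tx_end <- BiocGenerics::end(annotation)
  win_lo <- a_start - ifelse(minus_g, down, up)
  win_hi <- a_end + ifelse(minus_g, up, down)
  rows <- list()
  for (i in seq_along(centers)) {
    ctr <- centers[i]
    same <- g_chrom == chroms[i]
    for (g in which(same & ctr >= win_lo & ctr <= win_hi)) {
      minus <- minus_g[g]
      # open interval between the centre and the nearest anchor boundary
      if (ctr < a_start[g]) {
        lo <- ctr + 1L; hi <- a_start[g] - 1L
      } else if (ctr > a_end[g]) {
        lo <- a_end[g] + 1L; hi <- ctr - 1L
      } else {
        lo <- 1L; hi <- 0L  # inside the anchor: nothing to check
      }
      if (lo <= hi &&
          any(same & seq_along(annotation) != g &
              tx_start <= hi & tx_end >= lo)) next
      if (ctr < a_start[g]) {
        zone <- if (minus) "downstream" else "promoter"
        off <- if (minus) a_start[g] - ctr else ctr - a_start[g]
      } else if (ctr > a_end[g]) {
        zone <- if (minus) "promoter" else "downstream"
        off <- if (minus) a_end[g] - ctr else ctr - a_end[g]
      } else {
        zone <- "transcribed"
        off <- if (minus) a_end[g] - ctr else ctr - a_start[g]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = region_ids[i], gene_id = annotation$gene_id[g],
        zone = zone, offset = off, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(region_id = character(0), gene_id = character(0),
                      zone = character(0), offset = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$region_id, out$gene_id, method = "radix"), , drop = FALSE]
}

# two-tailed Fisher p by exhaustive enumeration of the hypergeometric
# support, probability-mass rule with the conventional 1e-7 relative slack
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  ra <- a + b; cb <- a + c
  if (ra == 0 || cb == 0 || ra == N || cb == N) return(1)
  ks <- max(0, ra + cb - N):min(ra, cb)
  pk <- stats::dhyper(ks, cb, N - cb, ra)
  pobs <- stats::dhyper(a, cb, N - cb, ra)
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
}

# regions GRanges with ids/centres from bare positions (width-1 regions)
mk_regions <- function(chrom, center, seqlen = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(center, center))
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlengths(gr) <- seqlen[GenomeInfoDb::seqlevels(gr)]
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    region_id = sprintf("r%05d", seq_along(gr)),
    center = as.integer(center),
    support = rep("", length(gr)))
  gr
}
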