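# Positional enrichment: where do consensus regions sit relative to their
# target genes? Region centres are classified into promoter / transcribed /
# downstream zones, summarised as a metagene histogram anchored at the
# transcript start and end, and compared with a bootstrap null of sites
# placed uniformly at random within the same target-gene windows.

ZONES <- c("promoter", "transcribed", "downstream")

#' Classify positions into gene zones
#'
#' Strand-aware classification of genomic positions against a gene's anchor
#' span: within `upstream_bp` before the anchor start -> `promoter`; inside
#' the span -> `transcribed`; within `downstream_bp` past the anchor end ->
#' `downstream`; otherwise `outside`. Boundary positions (exactly
#' `upstream_bp` before / `downstream_bp` after) are inside their zone.
#'
#' @param positions integer vector of 1-based genomic positions.
#' @param genes annotation `GRanges` rows parallel to `positions` (a single
#'   gene is recycled).
#' @param upstream_bp,downstream_bp zone extents in bp.
#' @param anchor `"transcript"` (default, as used for the positional
#'   analysis) or `"coding"` (as used for target assignment).
#' @return character vector of zone labels.
#' @export
classify_zone <- function(positions, genes, upstream_bp = 3000L,
                          downstream_bp = 1500L,
                          anchor = c("transcript", "coding")) {
  anchor <- match.arg(anchor)
  if (length(genes) == 1L && length(positions) > 1L) {
    genes <- rep(genes, length(positions))
  }
  stopifnot(length(genes) == length(positions))
  a <- anchor_span(genes, anchor)
  minus <- as.character(BiocGenerics::strand(genes)) == "-"
  # distance 5' of the anchor (positive when upstream), 3' past it
  up_dist <- ifelse(minus, positions - a$end, a$start - positions)
  down_dist <- ifelse(minus, a$start - positions, positions - a$end)
  ifelse(up_dist > 0 & up_dist <= upstream_bp, "promoter",
  ifelse(down_dist > 0 & down_dist <= downstream_bp, "downstream",
  ifelse(positions >= a$start & positions <= a$end, "transcribed",
         "outside")))
}

#' Zone counts of observed assignments
#'
#' Classifies each assigned region centre against its assigned gene and
#' tabulates the zones. The positional analysis anchors on the transcribed
#' span by default even though assignment anchors on the coding span; both
#' are parameters.
#'
#' @param assignments data.frame from [assign_regions()].
#' @param annotation the matching annotation.
#' @inheritParams classify_zone
#' @return One-row data.frame with columns `promoter`, `transcribed`,
#'   `downstream`, `total` (total counts located zones only).
#' @export
observed_zone_counts <- function(assignments, annotation,
                                 upstream_bp = 3000L, downstream_bp = 1500L,
                                 anchor = "transcript") {
  gi <- match(assignments$gene_id, annotation$gene_id)
  if (anyNA(gi)) stop("assignments reference genes absent from annotation")
  z <- classify_zone(assignments$center, annotation[gi],
                     upstream_bp, downstream_bp, anchor)
  zone_counts(z[z != "outside"])
}

#' Tabulate zone labels into counts
#'
#' @param zones character vector of zone labels (`promoter`, `transcribed`,
#'   `downstream`); other labels are ignored by the zone columns but not
#'   counted in `total`.
#' @return One-row data.frame with columns `promoter`, `transcribed`,
#'   `downstream`, `total`.
#' @export
zone_counts <- function(zones) {
  k <- vapply(ZONES, function(z) sum(zones == z), integer(1))
  data.frame(promoter = k[[1]], transcribed = k[[2]], downstream = k[[3]],
             total = sum(k))
}

#' Metagene histogram of region centres
#'
#' Bins each assigned region centre by its signed offset from the
#' transcript start (promoter and 5' half of the span) or from the
#' transcript end (downstream and 3' half), the span being split at its
#' midpoint. Offsets are strand-aware: negative values lie upstream of the
#' start anchor and downstream offsets past the end anchor are positive.
#'
#' @param assignments data.frame from [assign_regions()].
#' @param annotation the matching annotation.
#' @param bin_width bin width in bp.
#' @param upstream_bp,downstream_bp positional extents, as elsewhere.
#' @return data.frame of class `metagene_histogram` with columns `anchor`
#'   (`"start"` or `"end"`), `bin_start`, `bin_end` (half-open offset bin)
#'   and `count`; bin totals equal the number of located regions.
#' @export
metagene_histogram <- function(assignments, annotation, bin_width = 100L,
                               upstream_bp = 3000L, downstream_bp = 1500L) {
  gi <- match(assignments$gene_id, annotation$gene_id)
  if (anyNA(gi)) stop("assignments reference genes absent from annotation")
  g <- annotation[gi]
  minus <- as.character(BiocGenerics::strand(g)) == "-"
  s <- BiocGenerics::start(g); e <- BiocGenerics::end(g)
  ctr <- assignments$center
  o_start <- ifelse(minus, e - ctr, ctr - s)       # 0 at transcript start
  o_end <- ifelse(minus, s - ctr, ctr - e)         # 0 at transcript end
  len <- BiocGenerics::width(g)
  located <- o_start >= -upstream_bp & o_end <= downstream_bp
  use_start <- 2L * o_start < len                  # 5' half (and promoter)
  o <- ifelse(use_start, o_start, o_end)[located]
  anchor <- ifelse(use_start, "start", "end")[located]
  if (!length(o)) {
    out <- data.frame(anchor = character(0), bin_start = integer(0),
                      bin_end = integer(0), count = integer(0))
    class(out) <- c("metagene_histogram", "data.frame")
    return(out)
  }
  bin_start <- as.integer(floor(o / bin_width) * bin_width)
  agg <- stats::aggregate(
    list(count = rep(1L, length(o))),
    by = list(anchor = anchor, bin_start = bin_start), FUN = sum)
  agg <- agg[order(agg$anchor, agg$bin_start), , drop = FALSE]
  out <- data.frame(anchor = agg$anchor, bin_start = agg$bin_start,
                    bin_end = agg$bin_start + as.integer(bin_width),
                    count = agg$count, row.names = NULL)
  class(out) <- c("metagene_histogram", "data.frame")
  out
}

#' Partition target-gene windows into zone-labelled fragments
#'
#' Splits the union of the target genes' windows into disjoint fragments,
#' each carrying the zone (promoter / transcribed / downstream) and gene it
#' belongs to. Where windows of different genes overlap, the earlier gene in
#' positional order takes precedence, so every covered base has exactly one
#' zone. This is the sampling frame of [bootstrap_null()]; precompute it
#' once when running many bootstrap draws on the same target set.
#'
#' @param annotation annotation `GRanges`.
#' @param target_genes character vector of target gene IDs.
#' @param upstream_bp,downstream_bp,anchor zone geometry, as in
#'   [classify_zone()].
#' @return `GRanges` of disjoint fragments with metadata columns `zone` and
#'   `gene_id`.
#' @export
zone_partition <- function(annotation, target_genes, upstream_bp = 3000L,
                           downstream_bp = 1500L, anchor = "transcript") {
  sub <- annotation[annotation$gene_id %in% target_genes]
  if (!length(sub)) stop("no target genes found in the annotation")
  a <- anchor_span(sub, anchor)
  minus <- as.character(BiocGenerics::strand(sub)) == "-"
  sl <- GenomeInfoDb::seqlengths(sub)[as.character(GenomeInfoDb::seqnames(sub))]
  piece <- function(lo, hi, zone) {
    lo <- pmax(1L, as.integer(lo)); hi <- pmin(as.integer(sl), as.integer(hi))
    ok <- lo <= hi
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(sub)[ok],
                                 IRanges::IRanges(lo[ok], hi[ok]),
                                 seqinfo = GenomeInfoDb::seqinfo(sub))
    gr$zone <- rep(zone, length(gr))
    gr$gene_id <- sub$gene_id[ok]
    gr$.ord <- which(ok)
    gr
  }
  zp <- c(
    piece(ifelse(minus, a$end + 1L, a$start - upstream_bp),
          ifelse(minus, a$end + upstream_bp, a$start - 1L), "promoter"),
    piece(a$start, a$end, "transcribed"),
    piece(ifelse(minus, a$start - downstream_bp, a$end + 1L),
          ifelse(minus, a$start - 1L, a$end + downstream_bp), "downstream")
  )
  zp <- zp[order(zp$.ord, match(zp$zone, ZONES))]
  frag <- GenomicRanges::disjoin(zp)
  first <- GenomicRanges::findOverlaps(frag, zp, select = "first")
  frag$zone <- zp$zone[first]
  frag$gene_id <- zp$gene_id[first]
  frag
}

#' Bootstrap null distribution of zone counts
#'
#' Simulates the zone composition expected if binding sites fell at random
#' genome positions within the windows of the target genes: positions are
#' drawn uniformly over the bases covered by any target window (the
#' distribution a uniform genome-wide draw induces after discarding
#' positions outside the windows), classified into zones, and tabulated;
#' each of the `B` simulations retains exactly `n_observed` positions so
#' null fractions are exchangeable with the observed fraction.
#'
#' @param annotation annotation `GRanges`.
#' @param target_genes character vector of target gene IDs.
#' @param n_observed positions retained per simulation (the observed region
#'   count).
#' @param B number of simulations.
#' @param seed RNG seed; output is a pure function of the arguments.
#' @param upstream_bp,downstream_bp,anchor zone geometry, as in
#'   [classify_zone()].
#' @param partition optional precomputed [zone_partition()] of the same
#'   windows, reused across calls; when supplied, `annotation` and
#'   `target_genes` are ignored.
#' @return data.frame with `B` rows and columns `promoter`, `transcribed`,
#'   `downstream`, `total`.
#' @export
bootstrap_null <- function(annotation, target_genes, n_observed, B = 10000L,
                           seed, upstream_bp = 3000L, downstream_bp = 1500L,
                           anchor = "transcript", partition = NULL) {
  stopifnot(B >= 1L, n_observed >= 0L)
  frag <- if (is.null(partition)) {
    zone_partition(annotation, target_genes, upstream_bp, downstream_bp,
                   anchor)
  } else partition
  w <- BiocGenerics::width(frag)
  W <- sum(as.numeric(w))
  if (W < 1) stop("target windows cover zero bases")
  if (n_observed == 0L) {
    return(data.frame(promoter = integer(B), transcribed = integer(B),
                      downstream = integer(B), total = integer(B)))
  }
  zcode <- match(frag$zone, ZONES)
  cum <- c(0, cumsum(as.numeric(w)))
  counts <- withr::with_seed(seed, {
    total <- as.numeric(n_observed) * B
    chunk <- 2e6  # draws per block, keeps memory flat at large B
    acc <- matrix(0L, nrow = 3L, ncol = B)
    done <- 0
    while (done < total) {
      m <- as.integer(min(chunk, total - done))
      u <- floor(stats::runif(m) * W) + 1  # uniform over covered bases
      fi <- findInterval(u - 1, cum, rightmost.closed = FALSE)
      sim <- ((done + seq_len(m)) - 1) %/% n_observed + 1
      acc <- acc + matrix(tabulate(zcode[fi] + 3L * (sim - 1L), nbins = 3L * B),
                          nrow = 3L)
      done <- done + m
    }
    acc
  })
  data.frame(promoter = counts[1L, ], transcribed = counts[2L, ],
             downstream = counts[3L, ], total = colSums(counts))
}

#' Empirical enrichment test per zone
#'
#' Compares the observed zone fractions with the bootstrap null using the
#' add-one empirical p-value: `p_enriched = (#\{null >= observed\} + 1) /
#' (B + 1)` and symmetrically for depletion, so p never reaches 0 and its
#' floor is `1/(B+1)`. A zone is called `enriched` when `p_enriched <=
#' alpha`, `depleted` when `p_depleted <= alpha`, otherwise `neither`.
#'
#' @param observed one-row data.frame of observed zone counts (see
#'   [observed_zone_counts()]).
#' @param null data.frame of null zone counts from [bootstrap_null()].
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per zone: `zone`, `observed_fraction`,
#'   `null_mean`, `null_sd`, `p_enriched`, `p_depleted`, `direction`.
#' @export
enrichment_test <- function(observed, null, alpha = 0.05) {
  if (!nrow(null)) stop("null distribution is empty")
  if (observed$total <= 0) stop("observed total must be > 0")
  if (any(null$total <= 0)) stop("null totals must be > 0")
  B <- nrow(null)
  res <- lapply(ZONES, function(z) {
    obs <- observed[[z]] / observed$total
    nf <- null[[z]] / null$total
    pe <- (sum(nf >= obs) + 1) / (B + 1)
    pd <- (sum(nf <= obs) + 1) / (B + 1)
    data.frame(zone = z, observed_fraction = obs, null_mean = mean(nf),
               null_sd = stats::sd(nf), p_enriched = pe, p_depleted = pd,
               direction = if (pe <= alpha) "enriched"
                           else if (pd <= alpha) "depleted" else "neither")
  })
  do.call(rbind, res)
}
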