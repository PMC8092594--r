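# Annotation and peak I/O.
#
# Internal convention: all intervals live in GRanges objects, 1-based
# closed, as throughout GenomicRanges. GFF3 (1-based closed) maps directly;
# BED/narrowPeak (0-based half-open) is converted at the I/O boundary by
# rtracklayer. Chromosome lengths travel in the seqinfo of every object.

#' Construct a gene annotation
#'
#' A gene annotation is a `GRanges` holding one range per gene (the
#' transcribed span, stranded) with metadata columns `gene_id`, `cds_start`
#' and `cds_end` (1-based closed coding span) and chromosome lengths in its
#' `seqinfo`. Genes without an annotated coding region carry their
#' transcribed span as the coding span, so downstream window rules remain
#' total.
#'
#' @param tx_span `GRanges` of transcribed spans, strand `+` or `-`, with
#'   `seqlengths` set.
#' @param gene_id character vector of unique gene identifiers, parallel to
#'   `tx_span`.
#' @param cds_start,cds_end integer vectors (1-based closed) giving the
#'   coding span of each gene; `NA` entries default to the transcribed span.
#' @return A validated annotation `GRanges`, sorted by position.
#' @export
gene_annotation <- function(tx_span, gene_id, cds_start = NA_integer_,
                            cds_end = NA_integer_) {
  stopifnot(methods::is(tx_span, "GRanges"))
  n <- length(tx_span)
  gene_id <- as.character(gene_id)
  cds_start <- as.integer(rep_len(cds_start, n))
  cds_end <- as.integer(rep_len(cds_end, n))
  cds_start[is.na(cds_start)] <- BiocGenerics::start(tx_span)[is.na(cds_start)]
  cds_end[is.na(cds_end)] <- BiocGenerics::end(tx_span)[is.na(cds_end)]
  ann <- tx_span
  S4Vectors::mcols(ann) <- S4Vectors::DataFrame(
    gene_id = gene_id, cds_start = cds_start, cds_end = cds_end
  )
  ann <- GenomicRanges::sort(ann, ignore.strand = TRUE)
  validate_annotation(ann)
  ann
}

#' Validate a gene annotation
#'
#' Checks the structural invariants of an annotation object: unique gene
#' identifiers, coding spans contained in transcribed spans, explicit
#' strands, and transcribed spans within the recorded chromosome lengths.
#'
#' @param annotation annotation `GRanges` (see [gene_annotation()]).
#' @return The annotation, invisibly; errors describe the first violation.
#' @export
validate_annotation <- function(annotation) {
  stopifnot(methods::is(annotation, "GRanges"))
  m <- S4Vectors::mcols(annotation)
  need <- c("gene_id", "cds_start", "cds_end")
  if (!all(need %in% colnames(m))) {
    stop("annotation lacks metadata columns: ",
         paste(setdiff(need, colnames(m)), collapse = ", "))
  }
  dup <- unique(m$gene_id[duplicated(m$gene_id)])
  if (length(dup)) {
    stop("duplicate gene ID(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(S4Vectors::decode(BiocGenerics::strand(annotation)) == "*")) {
    stop("all genes must be stranded (+ or -)")
  }
  bad <- m$cds_start < BiocGenerics::start(annotation) |
    m$cds_end > BiocGenerics::end(annotation) | m$cds_start > m$cds_end
  if (any(bad)) {
    stop("coding span outside transcribed span for gene(s): ",
         paste(utils::head(m$gene_id[bad], 5), collapse = ", "))
  }
  sl <- GenomeInfoDb::seqlengths(annotation)
  if (any(is.na(sl))) stop("annotation seqinfo lacks chromosome lengths")
  over <- BiocGenerics::end(annotation) >
    sl[as.character(GenomeInfoDb::seqnames(annotation))]
  if (any(over)) {
    stop("gene(s) extend past chromosome end: ",
         paste(utils::head(m$gene_id[over], 5), collapse = ", "))
  }
  invisible(annotation)
}

#' Read a gene annotation from GFF3
#'
#' Consumes `gene`, `mRNA` and `CDS` features (all other feature types are
#' ignored); the coding span of a gene is the minimal interval covering its
#' CDS features, resolved through `Parent` attributes either directly or via
#' mRNA. Chromosome lengths come from `##sequence-region` pragmas unless
#' overridden by `seqlengths`.
#'
#' @param file path to a GFF3 file.
#' @param seqlengths optional named integer vector of chromosome lengths,
#'   overriding the `##sequence-region` pragmas.
#' @return An annotation `GRanges` (see [gene_annotation()]).
#' @export
read_gff3 <- function(file, seqlengths = NULL) {
  lines <- readLines(file)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GFF3 line ", bad, ": expected 9 tab-separated fields, got ",
         nfield[which(nfield != 9L)[1L]])
  }
  if (is.null(seqlengths)) {
    prag <- lines[startsWith(lines, "##sequence-region")]
    if (!length(prag)) {
      stop("no ##sequence-region pragmas and no seqlengths supplied")
    }
    parts <- strsplit(trimws(sub("^##sequence-region", "", prag)), "\\s+")
    seqlengths <- vapply(parts, function(p) as.integer(p[3L]), integer(1))
    names(seqlengths) <- vapply(parts, `[`, character(1), 1L)
  }
  si <- GenomeInfoDb::Seqinfo(names(seqlengths), seqlengths)
  if (!any(body)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = character(0), cds_start = integer(0), cds_end = integer(0)
    )
    return(gr)
  }
  feats <- rtracklayer::import(file, format = "gff3")
  type <- as.character(feats$type)
  genes <- feats[type == "gene"]
  if (any(is.na(genes$ID)) || any(!nzchar(genes$ID))) {
    stop("gene feature without an ID attribute")
  }
  # map every feature ID to its owning gene (depth <= 2: CDS -> mRNA -> gene)
  owner <- stats::setNames(genes$ID, genes$ID)
  mrna <- feats[type == "mRNA"]
  if (length(mrna)) {
    mp <- vapply(mrna$Parent, function(p) p[1L], character(1))
    owner[mrna$ID] <- ifelse(mp %in% names(owner), owner[mp], NA_character_)
  }
  cds <- feats[type == "CDS"]
  ann <- gene_annotation(
    GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(genes),
      IRanges::IRanges(BiocGenerics::start(genes), BiocGenerics::end(genes)),
      strand = BiocGenerics::strand(genes), seqinfo = si
    ),
    gene_id = genes$ID
  )
  if (length(cds)) {
    cp <- vapply(cds$Parent, function(p) p[1L], character(1))
    gene_of <- owner[cp]
    if (any(is.na(gene_of))) {
      stop("CDS feature with unresolvable Parent: ",
           utils::head(cp[is.na(gene_of)], 1))
    }
    cs <- tapply(BiocGenerics::start(cds), gene_of, min)
    ce <- tapply(BiocGenerics::end(cds), gene_of, max)
    idx <- match(names(cs), ann$gene_id)
    ann$cds_start[idx] <- as.integer(cs)
    ann$cds_end[idx] <- as.integer(ce)
  }
  validate_annotation(ann)
  ann
}

#' Write a gene annotation to GFF3
#'
#' Emits `##sequence-region` pragmas, one `gene` line per gene and one `CDS`
#' line per gene (the minimal coding span), so that
#' `read_gff3(write_gff3(a))` reproduces `a`.
#'
#' @param annotation annotation `GRanges`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(annotation, file) {
  validate_annotation(annotation)
  sl <- GenomeInfoDb::seqlengths(annotation)
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", names(sl), sl))
  chrom <- as.character(GenomeInfoDb::seqnames(annotation))
  strand <- as.character(BiocGenerics::strand(annotation))
  gene_lines <- sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        chrom, BiocGenerics::start(annotation),
                        BiocGenerics::end(annotation), strand,
                        annotation$gene_id)
  cds_lines <- sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                       chrom, annotation$cds_start, annotation$cds_end,
                       strand, annotation$gene_id, annotation$gene_id)
  writeLines(c(header, as.vector(rbind(gene_lines, cds_lines))), file)
  invisible(file)
}

#' Read scored peaks from a narrowPeak file
#'
#' narrowPeak is BED6+4: column 7 signal, column 8 -log10 p-value, column 9
#' -log10 q-value (FDR), column 10 summit offset from the interval start (-1
#' when unknown). Coordinates are converted from BED 0-based half-open to
#' the internal 1-based closed `GRanges` convention. A q-value of -1
#' (meaning "not computed") is rejected because the downstream consensus
#' filter reads that column; a summit of -1 becomes `NA`.
#'
#' @param file path to a narrowPeak file.
#' @return `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue` and `peak` (0-based summit offset or `NA`).
#' @export
read_narrowpeak <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(empty_peaks())
  }
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield < 10L)) {
    stop("narrowPeak line ", which(nfield < 10L)[1L],
         ": expected 10 columns, got ", nfield[nfield < 10L][1L])
  }
  peaks <- rtracklayer::import(
    file, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer")
  )
  if (any(BiocGenerics::width(peaks) < 1L)) {
    stop("peak with end <= start: ", peaks$name[BiocGenerics::width(peaks) < 1L][1L])
  }
  if (any(peaks$qValue < 0)) {
    stop("peak with missing q-value (-1) cannot be FDR-filtered: ",
         peaks$name[peaks$qValue < 0][1L])
  }
  peaks$peak[peaks$peak < 0L] <- NA_integer_
  bad <- !is.na(peaks$peak) & peaks$peak >= BiocGenerics::width(peaks)
  if (any(bad)) {
    stop("summit offset outside peak: ", peaks$name[bad][1L])
  }
  peaks
}

#' Write scored peaks to a narrowPeak file
#'
#' Peaks are written in deterministic (chromosome, start, end, name) order,
#' converting back to BED 0-based half-open coordinates; unknown summits are
#' written as -1. Two calls on the same input produce byte-identical files.
#'
#' @param peaks peak `GRanges` as returned by [read_narrowpeak()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_narrowpeak <- function(peaks, file) {
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  o <- order(chrom, BiocGenerics::start(peaks), BiocGenerics::end(peaks),
             peaks$name, method = "radix")
  p <- peaks[o]
  summit <- ifelse(is.na(p$peak), -1L, p$peak)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t%s\t%d",
                   as.character(GenomeInfoDb::seqnames(p)),
                   BiocGenerics::start(p) - 1L, BiocGenerics::end(p),
                   p$name, as.integer(p$score),
                   format_num(p$signalValue), format_num(p$pValue),
                   format_num(p$qValue), summit)
  writeLines(lines, file)
  invisible(file)
}

# fixed-notation numeric formatting so file output is locale/option independent
format_num <- function(x) {
  formatC(x, format = "fg", digits = 15, flag = "-", width = 1)
}

# empty peak GRanges with the narrowPeak metadata schema
empty_peaks <- function(seqinfo = NULL) {
  gr <- if (is.null(seqinfo)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(seqinfo = seqinfo)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), score = numeric(0), signalValue = numeric(0),
    pValue = numeric(0), qValue = numeric(0), peak = integer(0)
  )
  gr
}

#' Read a gene list
#'
#' One gene identifier per line; blank lines and `#` comments are ignored.
#'
#' @param file path to a plain-text gene list.
#' @return character vector of unique gene IDs in file order.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
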