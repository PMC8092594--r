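# Seeded synthetic genomes, replicate peak calls and reference gene sets.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: latent binding sites placed by a promoter/transcribed/downstream
# mixture around a set of true target genes, per-replicate edge jitter and
# score noise on the MACS2 -log10(q) scale, uniform background peaks, and
# artifact sites that recur in control replicates. Everything is a pure
# function of the parameter list (including its seed).

#' Simulation parameters
#'
#' Builds a validated parameter list for the synthetic-data generator. The
#' defaults describe a compact genome (3 chromosomes of 2 Mb, 300 genes, 60
#' true targets) assayed with 3 treatment and 3 control replicates --
#' deliberately small but structurally faithful: peak widths of 300 +/- 80
#' bp and confident calls around -log10(q) = 6 against a diffuse background
#' near 1.5 are typical of punctate transcription-factor ChIP-seq, and the
#' site-placement mixture (60% promoter / 10% transcribed / 30% downstream)
#' mirrors the promoter- and downstream-skewed binding the pipeline is
#' designed to detect.
#'
#' @param seed integer RNG seed; every simulated object derives from it.
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param n_genes,gene_length_mean,gene_length_sd gene count and transcribed
#'   length distribution (bp).
#' @param min_intergenic_bp minimum gap between adjacent genes. The default
#'   (6,500 bp) exceeds twice the upstream window, so the windows of
#'   adjacent genes never share a base regardless of strand orientation.
#' @param n_true_targets number of genes given a latent binding site.
#' @param n_treatment_reps,n_control_reps replicate counts.
#' @param promoter_weight,body_weight,downstream_weight mixture
#'   probabilities for latent-site zone placement; must sum to 1.
#' @param peak_width_mean,peak_width_sd peak width distribution (bp).
#' @param jitter_sd per-replicate Gaussian noise (bp) applied independently
#'   to each peak edge.
#' @param true_qscore_mean,background_qscore_mean mean -log10(q) of true and
#'   background peaks (sd 0.5, truncated at 0).
#' @param n_background_peaks_per_rep uniform background peaks added to every
#'   replicate, treatment and control alike.
#' @param n_artifact_sites sites that produce a confident peak in every
#'   replicate including controls (e.g. hyper-ChIPable regions).
#' @param ref_set_size,ref_overlap size of the simulated reference gene set
#'   and how many of its members are true targets.
#' @return A named list of class `sim_params`.
#' @export
simulation_params <- function(seed,
                              n_chroms = 3L,
                              chrom_length = 2000000L,
                              n_genes = 300L,
                              gene_length_mean = 2000,
                              gene_length_sd = 400,
                              min_intergenic_bp = 6500L,
                              n_true_targets = 60L,
                              n_treatment_reps = 3L,
                              n_control_reps = 3L,
                              promoter_weight = 0.6,
                              body_weight = 0.1,
                              downstream_weight = 0.3,
                              peak_width_mean = 300,
                              peak_width_sd = 80,
                              jitter_sd = 20,
                              true_qscore_mean = 6,
                              background_qscore_mean = 1.5,
                              n_background_peaks_per_rep = 100L,
                              n_artifact_sites = 10L,
                              ref_set_size = 80L,
                              ref_overlap = 40L) {
  p <- as.list(environment())
  p$seed <- as.integer(seed)
  ints <- c("n_chroms", "chrom_length", "n_genes", "min_intergenic_bp",
            "n_true_targets", "n_treatment_reps", "n_control_reps",
            "n_background_peaks_per_rep", "n_artifact_sites",
            "ref_set_size", "ref_overlap")
  for (k in ints) p[[k]] <- as.integer(p[[k]])
  w <- p$promoter_weight + p$body_weight + p$downstream_weight
  if (abs(w - 1) > 1e-9) stop("zone weights must sum to 1, got ", w)
  if (any(c(p$promoter_weight, p$body_weight, p$downstream_weight) < 0)) {
    stop("zone weights must be non-negative")
  }
  if (p$n_true_targets > p$n_genes) stop("n_true_targets exceeds n_genes")
  if (p$ref_overlap > min(p$ref_set_size, p$n_true_targets)) {
    stop("ref_overlap exceeds min(ref_set_size, n_true_targets)")
  }
  if (p$ref_set_size - p$ref_overlap > p$n_genes - p$n_true_targets) {
    stop("not enough non-target genes to fill the reference set")
  }
  if (p$jitter_sd < 0 || p$peak_width_sd < 0) stop("sds must be >= 0")
  structure(p, class = "sim_params")
}

#' Simulate a gene annotation
#'
#' Lays out non-overlapping genes (round-robin across chromosomes, random
#' strands, coding span equal to transcribed span) with intergenic gaps of
#' at least `min_intergenic_bp`; the slack left on each chromosome is
#' distributed randomly among the gaps so layouts differ across seeds.
#'
#' @param params a `sim_params` list (see [simulation_params()]).
#' @return An annotation `GRanges` (see [gene_annotation()]).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    n <- params$n_genes
    sl <- stats::setNames(rep(params$chrom_length, params$n_chroms),
                          sprintf("chr%d", seq_len(params$n_chroms)))
    si <- GenomeInfoDb::Seqinfo(names(sl), sl)
    if (n == 0L) {
      return(gene_annotation(GenomicRanges::GRanges(seqinfo = si),
                             gene_id = character(0)))
    }
    len <- pmax(300L, as.integer(round(stats::rnorm(
      n, params$gene_length_mean, params$gene_length_sd))))
    chrom_of <- rep(seq_len(params$n_chroms), length.out = n)
    starts <- integer(n)
    for (ci in seq_len(params$n_chroms)) {
      idx <- which(chrom_of == ci)
      k <- length(idx)
      if (!k) next
      # k genes need k+1 gaps of >= min_intergenic_bp
      slack <- params$chrom_length - sum(len[idx]) -
        (k + 1L) * params$min_intergenic_bp
      if (slack < 0L) {
        stop("cannot place ", k, " genes of total length ", sum(len[idx]),
             " on a ", params$chrom_length, " bp chromosome with ",
             params$min_intergenic_bp, " bp gaps")
      }
      # random split of the slack over the k+1 gaps
      cuts <- sort(stats::runif(k, 0, 1))
      extra <- floor(diff(c(0, cuts, 1)) * slack)
      gaps <- params$min_intergenic_bp + extra[seq_len(k)]
      starts[idx] <- cumsum(gaps) +
        c(0L, cumsum(len[idx])[-k]) + 1L  # 1-based starts
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_annotation(
      GenomicRanges::GRanges(
        names(sl)[chrom_of],
        IRanges::IRanges(starts, width = len),
        strand = strand, seqinfo = si
      ),
      gene_id = sprintf("g%04d", seq_len(n))
    )
  })
}

# draw a latent site position for one gene, given its zone.
# promoter: up to `up` bp 5' of the anchor start; downstream: up to `down`
# bp 3' of the anchor end; transcribed: inside the anchor span. 1-based.
draw_site <- function(start, end, strand, zone, up, down) {
  off <- switch(zone,
    promoter = -sample.int(up, 1L),
    transcribed = sample.int(end - start + 1L, 1L) - 1L,
    downstream = (end - start + 1L) - 1L + sample.int(down, 1L)
  )
  if (strand == "+") start + off else end - off
}

#' Simulate replicate peak calls with known ground truth
#'
#' Each true target gets one latent binding site drawn from the
#' promoter/transcribed/downstream mixture within its window. Every
#' treatment replicate receives a peak centred on each latent site with
#' independently jittered edges and a confident q-score; every replicate
#' (treatment and control) additionally receives uniform background peaks
#' with low q-scores; artifact sites yield confident peaks in all
#' replicates, so the control-exclusion filter has something to remove.
#'
#' @param annotation annotation from [simulate_genome()].
#' @param params the same `sim_params` list.
#' @return A list with elements `treatment` (list of peak `GRanges`, one per
#'   replicate), `control` (likewise) and `truth`, itself a list with
#'   `true_target_ids`, `latent_sites` (data.frame: gene_id, chrom,
#'   position, zone) and `artifact_positions` (data.frame: chrom, position).
#' @export
simulate_peaksets <- function(annotation, params) {
  stopifnot(inherits(params, "sim_params"))
  validate_annotation(annotation)
  withr::with_seed(params$seed + 1L, {
    sl <- GenomeInfoDb::seqlengths(annotation)
    si <- GenomeInfoDb::seqinfo(annotation)
    n_t <- params$n_true_targets
    target_ids <- sort(sample(annotation$gene_id, n_t))
    gi <- match(target_ids, annotation$gene_id)
    zones <- if (n_t) sample(c("promoter", "transcribed", "downstream"), n_t,
                             replace = TRUE,
                             prob = c(params$promoter_weight, params$body_weight,
                                      params$downstream_weight)) else character(0)
    pos <- integer(n_t)
    for (i in seq_len(n_t)) {
      g <- gi[i]
      pos[i] <- draw_site(annotation$cds_start[g], annotation$cds_end[g],
                          as.character(BiocGenerics::strand(annotation))[g],
                          zones[i], 3000L, 1500L)
    }
    site_chrom <- as.character(GenomeInfoDb::seqnames(annotation))[gi]
    latent <- data.frame(gene_id = target_ids, chrom = site_chrom,
                         position = pos, zone = zones,
                         stringsAsFactors = FALSE)

    art_chrom <- character(0); art_pos <- integer(0)
    if (params$n_artifact_sites > 0L) {
      art_chrom <- sample(names(sl), params$n_artifact_sites, replace = TRUE)
      art_pos <- as.integer(ceiling(stats::runif(params$n_artifact_sites) *
                                      sl[art_chrom]))
    }
    artifacts <- data.frame(chrom = art_chrom, position = art_pos,
                            stringsAsFactors = FALSE)

    draw_widths <- function(k) {
      pmax(50L, as.integer(round(stats::rnorm(
        k, params$peak_width_mean, params$peak_width_sd))))
    }
    # widths are a property of the site, so replicates coincide exactly
    # in the zero-jitter limit; only the edge jitter is per replicate
    latent_w <- draw_widths(nrow(latent))
    artifact_w <- draw_widths(nrow(artifacts))
    site_peaks <- function(chrom, centers, q_mean, label, w = NULL,
                           jitter = TRUE) {
      k <- length(centers)
      if (!k) return(empty_peaks(si))
      if (is.null(w)) w <- draw_widths(k)
      half <- w %/% 2L
      jl <- if (jitter) as.integer(round(stats::rnorm(k, 0, params$jitter_sd))) else 0L
      jr <- if (jitter) as.integer(round(stats::rnorm(k, 0, params$jitter_sd))) else 0L
      s <- centers - half + jl
      e <- centers + half + jr
      e <- pmax(e, s + 49L)                       # keep a minimal width
      s <- pmax(1L, s); e <- pmin(e, sl[chrom])
      q <- pmax(0, stats::rnorm(k, q_mean, 0.5))
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), seqinfo = si)
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = sprintf("%s_%03d", label, seq_len(k)), score = 0,
        signalValue = q, pValue = q + 1, qValue = q,
        peak = pmin(pmax(centers - s, 0L), e - s)
      )
      gr
    }
    background_peaks <- function(label) {
      k <- params$n_background_peaks_per_rep
      if (!k) return(empty_peaks(si))
      chrom <- sample(names(sl), k, replace = TRUE)
      centers <- as.integer(ceiling(stats::runif(k) * sl[chrom]))
      site_peaks(chrom, centers, params$background_qscore_mean,
                 paste0(label, "_bg"), jitter = FALSE)
    }
    one_rep <- function(label, with_true) {
      parts <- list()
      if (with_true) {
        parts <- c(parts, list(site_peaks(latent$chrom, latent$position,
                                          params$true_qscore_mean,
                                          paste0(label, "_site"), latent_w)))
      }
      if (nrow(artifacts)) {
        parts <- c(parts, list(site_peaks(artifacts$chrom, artifacts$position,
                                          params$true_qscore_mean,
                                          paste0(label, "_art"), artifact_w)))
      }
      parts <- c(parts, list(background_peaks(label)))
      do.call(c, parts)
    }
    treatment <- lapply(seq_len(params$n_treatment_reps), function(r) {
      one_rep(sprintf("t%d", r), with_true = TRUE)
    })
    names(treatment) <- sprintf("t%d", seq_len(params$n_treatment_reps))
    control <- lapply(seq_len(params$n_control_reps), function(r) {
      one_rep(sprintf("c%d", r), with_true = FALSE)
    })
    names(control) <- sprintf("c%d", seq_len(params$n_control_reps))
    list(treatment = treatment, control = control,
         truth = list(true_target_ids = target_ids, latent_sites = latent,
                      artifact_positions = artifacts))
  })
}

#' Simulate a reference gene set with controlled overlap
#'
#' Draws `ref_set_size` gene IDs of which exactly `ref_overlap` are true
#' targets and the remainder are non-targets, without replacement -- a
#' stand-in for an externally published target list used in overlap tests.
#'
#' @param truth the `truth` element of [simulate_peaksets()] output.
#' @param annotation the matching annotation.
#' @param params the same `sim_params` list.
#' @return Sorted character vector of gene IDs.
#' @export
simulate_reference_set <- function(truth, annotation, params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed + 2L, {
    targets <- truth$true_target_ids
    non_targets <- setdiff(annotation$gene_id, targets)
    if (params$ref_overlap > length(targets)) {
      stop("ref_overlap exceeds the number of true targets")
    }
    if (params$ref_set_size - params$ref_overlap > length(non_targets)) {
      stop("not enough non-target genes to fill the reference set")
    }
    sort(c(sample(targets, params$ref_overlap),
           sample(non_targets, params$ref_set_size - params$ref_overlap)))
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the annotation as GFF3, one narrowPeak file per replicate and the
#' ground truth as TSV, so a simulated run is indistinguishable on disk from
#' a real one.
#'
#' @param sim output of [simulate_peaksets()].
#' @param annotation the matching annotation.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(annotation = file.path(dir, "annotation.gff3"))
  write_gff3(annotation, paths$annotation)
  for (r in names(sim$treatment)) {
    p <- file.path(dir, sprintf("treatment_%s.narrowPeak", r))
    write_narrowpeak(sim$treatment[[r]], p)
    paths[[paste0("treatment_", r)]] <- p
  }
  for (r in names(sim$control)) {
    p <- file.path(dir, sprintf("control_%s.narrowPeak", r))
    write_narrowpeak(sim$control[[r]], p)
    paths[[paste0("control_", r)]] <- p
  }
  paths$truth <- file.path(dir, "truth_sites.tsv")
  utils::write.table(sim$truth$latent_sites, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
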