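# Simulator of single-cell amplicon-resequencing data with known truth.
# Emulates the observed regime of a childhood-leukemia panel: 128 single
# cells, 41 SNV + 36 SV assays, two clones descending from an ancestral
# population whose shared mutations are structural variants, with allelic
# dropout, false positives, doublet chambers, and poor-performing assays.

#' Simulation configuration
#'
#' Defaults mirror the observed regime of the study design this package
#' models: 128 cells, 41 SNV and 36 SV assays, two clones, 9.6\% doublet
#' chambers and 6.3\% poor-performing assays, allelic-dropout rate 0.1 and
#' false-positive rate 0.01 per cell-assay.
#'
#' @param seed RNG seed used by [simulate_truth()] / [simulate_observations()].
#' @param n_cells number of captured single cells.
#' @param n_snv,n_sv number of SNV and SV assays.
#' @param K_clones number of clones.
#' @param clone_proportions mixing proportions over clones (default equal).
#' @param mutations_per_edge optional integer vector of length `K_clones + 1`
#'   (ancestral edge first, then one private edge per clone); must sum to
#'   `n_snv + n_sv`. Default: with `ancestral_sv_only`, the ancestral edge
#'   carries 60\% of the SV assays and the rest split evenly across clones;
#'   otherwise all assays split evenly across edges.
#' @param ancestral_sv_only place only SV assays on the ancestral (root) edge,
#'   emulating an ancestral mutation cluster composed entirely of structural
#'   variants (default TRUE).
#' @param ado_rate per-cell per-present-assay false-negative (allelic
#'   dropout) probability.
#' @param fp_rate per-cell per-absent-assay false-positive probability.
#' @param doublet_rate probability a chamber holds two cells.
#' @param poor_assay_fraction fraction of assays that are poor performers.
#' @param poor_fail_prob per-cell probability that a poor assay yields no
#'   usable data.
#' @param depth_mean,depth_size negative-binomial depth model at SNV sites.
#' @param alt_vaf expected variant allele fraction when the variant is
#'   (effectively) present — 0.5 for a heterozygous somatic SNV.
#' @param error_vaf background alt-read rate when absent (sequencing error
#'   floor).
#' @param sv_reads_present_mean,sv_reads_absent_mean Poisson means of
#'   junction-matching read counts for present/absent SVs.
#' @param read_length simulated read length (nt).
#' @param n_background_reads non-matching filler reads per cell.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cells = 128L, n_snv = 41L, n_sv = 36L,
                       K_clones = 2L, clone_proportions = NULL,
                       mutations_per_edge = NULL, ancestral_sv_only = TRUE,
                       ado_rate = 0.1, fp_rate = 0.01,
                       doublet_rate = 0.096, poor_assay_fraction = 0.063,
                       poor_fail_prob = 0.8,
                       depth_mean = 100, depth_size = 5,
                       alt_vaf = 0.5, error_vaf = 0.002,
                       sv_reads_present_mean = 100, sv_reads_absent_mean = 1,
                       read_length = 150L, n_background_reads = 50L) {
  cfg <- as.list(environment())
  probs <- c(ado_rate, fp_rate, doublet_rate, poor_assay_fraction,
             poor_fail_prob, alt_vaf, error_vaf)
  if (any(probs < 0 | probs > 1)) {
    stop("rates/probabilities must be in [0, 1]", call. = FALSE)
  }
  if (K_clones < 1L) stop("K_clones must be >= 1", call. = FALSE)
  if (doublet_rate > 0 && K_clones < 2L) {
    stop("doublets require at least 2 clones", call. = FALSE)
  }
  if (is.null(cfg$clone_proportions)) {
    cfg$clone_proportions <- rep(1 / K_clones, K_clones)
  }
  if (abs(sum(cfg$clone_proportions) - 1) > 1e-8) {
    stop("clone_proportions must sum to 1", call. = FALSE)
  }
  if (!is.null(mutations_per_edge)) {
    if (length(mutations_per_edge) != K_clones + 1L) {
      stop("mutations_per_edge must have length K_clones + 1 ",
           "(ancestral edge first)", call. = FALSE)
    }
    if (sum(mutations_per_edge) != n_snv + n_sv) {
      stop("mutations_per_edge must sum to n_snv + n_sv = ", n_snv + n_sv,
           call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# random DNA strings
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# junction 30-mers, rejection-sampled so no junction occurs (either strand)
# inside another junction or its reverse complement
make_junctions <- function(n, len = 30L) {
  seqs <- character(0)
  while (length(seqs) < n) {
    cand <- random_dna(1L, len)
    pool <- c(seqs, revcomp(seqs))
    clash <- cand %in% pool || revcomp(cand) %in% pool
    if (!clash) seqs <- c(seqs, cand)
  }
  seqs
}

#' Simulate the ground-truth clonal structure
#'
#' Builds a clone tree rooted at the germline: one ancestral edge shared by
#' all clones and one private edge per clone (each mutation sits on exactly
#' one edge — infinite-sites). Cells are drawn from the clone proportions;
#' a doublet chamber holds an unordered pair of distinct clones and its
#' genotype is the union of the two clones' genotypes.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return object of class `sim_truth`: `assays` (assay table with class,
#'   edge assignment, junction sequences / SNV sites), `clone_genotypes`
#'   (K x J), `cells` (cell table with true labels and doublet flags),
#'   `cell_genotypes` (n x J), `poor_assays`, `config`.
#' @export
simulate_truth <- function(config = sim_config(), seed = NULL) {
  set.seed(seed %||% config$seed)
  K <- config$K_clones
  J <- config$n_snv + config$n_sv
  assay_id <- c(sprintf("SNV_%02d", seq_len(config$n_snv)),
                sprintf("SV_%02d", seq_len(config$n_sv)))
  assay_class <- rep(c("snv", "sv"), c(config$n_snv, config$n_sv))

  # edge assignment: edge 0 = ancestral (shared), edges 1..K = clone-private
  edge <- integer(J)
  if (is.null(config$mutations_per_edge)) {
    if (config$ancestral_sv_only && config$n_sv > 0L) {
      n_anc <- max(1L, round(0.6 * config$n_sv))
      sv_idx <- which(assay_class == "sv")
      anc <- sample(sv_idx, n_anc)
      rest <- setdiff(seq_len(J), anc)
    } else {
      n_anc <- floor(J / (K + 1L))
      anc <- sample(seq_len(J), n_anc)
      rest <- setdiff(seq_len(J), anc)
    }
    edge[anc] <- 0L
    edge[rest] <- sample(rep_len(seq_len(K), length(rest)))
  } else {
    sizes <- config$mutations_per_edge
    if (config$ancestral_sv_only) {
      sv_idx <- sample(which(assay_class == "sv"))
      if (sizes[1] > length(sv_idx)) {
        stop("ancestral_sv_only: ancestral edge size exceeds n_sv",
             call. = FALSE)
      }
      anc <- sv_idx[seq_len(sizes[1])]
    } else {
      anc <- sample(seq_len(J), sizes[1])
    }
    edge[anc] <- 0L
    rest <- sample(setdiff(seq_len(J), anc))
    edge[rest] <- rep(seq_len(K), times = sizes[-1])
  }

  # clone genotype: ancestral edge + own private edge
  clone_genotypes <- matrix(0L, K, J,
                            dimnames = list(paste0("clone", seq_len(K)),
                                            assay_id))
  for (k in seq_len(K)) clone_genotypes[k, edge %in% c(0L, k)] <- 1L

  # assay annotations
  chroms <- paste0("chr", sample(1:22, J, replace = TRUE))
  assays <- data.frame(
    assay_id = assay_id, class = assay_class, edge = edge,
    chrom = ifelse(assay_class == "snv", chroms, NA),
    pos = ifelse(assay_class == "snv",
                 sample.int(2e8, J, replace = TRUE), NA),
    ref = NA_character_, alt = NA_character_,
    junction_seq = NA_character_,
    sv_class = NA_character_,
    span_kb = NA_real_,
    stringsAsFactors = FALSE
  )
  bases <- c("A", "C", "G", "T")
  for (i in which(assay_class == "snv")) {
    rb <- sample(bases, 1L)
    assays$ref[i] <- rb
    assays$alt[i] <- sample(setdiff(bases, rb), 1L)
  }
  n_sv <- config$n_sv
  if (n_sv > 0L) {
    sv_rows <- which(assay_class == "sv")
    assays$junction_seq[sv_rows] <- make_junctions(n_sv)
    assays$sv_class[sv_rows] <-
      sample(c("deletion", "insertion", "inversion", "translocation"),
             n_sv, replace = TRUE, prob = c(0.8, 0.08, 0.03, 0.09))
    assays$span_kb[sv_rows] <- round(runif(n_sv, 0.1, 518.7), 1)
  }

  poor_assays <- sample(assay_id, round(config$poor_assay_fraction * J))

  # cells
  n <- config$n_cells
  is_doublet <- runif(n) < config$doublet_rate
  clone_a <- sample.int(K, n, replace = TRUE, prob = config$clone_proportions)
  clone_b <- rep(NA_integer_, n)
  for (i in which(is_doublet)) {
    clone_b[i] <- sample(setdiff(seq_len(K), clone_a[i]), 1L)
  }
  cell_genotypes <- clone_genotypes[clone_a, , drop = FALSE]
  for (i in which(is_doublet)) {
    cell_genotypes[i, ] <- pmax(cell_genotypes[i, ],
                                clone_genotypes[clone_b[i], ])
  }
  cell_id <- sprintf("cell_%03d", seq_len(n))
  rownames(cell_genotypes) <- cell_id
  cells <- data.frame(
    cell_id = cell_id, visually_single = TRUE,
    clone = ifelse(is_doublet, "doublet", paste0("clone", clone_a)),
    clone_a = clone_a, clone_b = clone_b, is_doublet = is_doublet,
    stringsAsFactors = FALSE
  )
  structure(list(assays = assays, clone_genotypes = clone_genotypes,
                 cells = cells, cell_genotypes = cell_genotypes,
                 poor_assays = poor_assays, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d cells (%d doublets), %d clones, %d SNV + %d SV assays (%d poor)\n",
    nrow(x$cells), sum(x$cells$is_doublet), x$config$K_clones,
    x$config$n_snv, x$config$n_sv, length(x$poor_assays)))
  invisible(x)
}

#' Simulate observed single-cell data from a ground truth
#'
#' Applies the error model to the true genotypes and draws read-count
#' evidence. Per cell, a present assay drops out with probability `ado_rate`
#' (allelic dropout at the genotype level, the way whole-genome-amplification
#' dropout manifests in amplicon data) and an absent assay is falsely
#' amplified with probability `fp_rate`. Poor assays yield no usable data
#' in a cell with probability `poor_fail_prob` (SNVs: no counts row; SVs:
#' background-level junction reads). SNV evidence: depth ~ NB(`depth_mean`,
#' `depth_size`), alt reads ~ Binomial(depth, `alt_vaf`) when effectively
#' present, Binomial(depth, `error_vaf`) otherwise. SV evidence: matching
#' reads ~ Poisson(`sv_reads_present_mean`) when present, else
#' Poisson(`sv_reads_absent_mean`).
#'
#' With `level = "reads"` per-cell reads are materialized: each matching read
#' embeds the junction 30-mer at a uniform offset in a `read_length`-mer
#' (reverse-complemented with probability 1/2, since raw reads are
#' unstranded), and background reads are rejection-sampled to contain no
#' junction on either strand.
#'
#' @param truth a `sim_truth`.
#' @param level `"counts"` (default) or `"reads"` (also generate FASTQ-ready
#'   read sequences; slower).
#' @param seed overrides `config$seed + 1`.
#' @return object of class `sim_data`: `snv_counts` (cell_id, assay_id,
#'   alt_count, depth), `junction_counts` (cell_id, assay_id, n_match_true),
#'   `coverage`, `cells`, `effective_genotypes` (post-error genotypes),
#'   `reads` (named list per cell, only with `level = "reads"`), `truth`.
#' @export
simulate_observations <- function(truth, level = c("counts", "reads"),
                                  seed = NULL) {
  level <- match.arg(level)
  config <- truth$config
  set.seed(seed %||% (config$seed + 1L))
  cells <- truth$cells
  assays <- truth$assays
  n <- nrow(cells)
  J <- nrow(assays)
  G <- truth$cell_genotypes

  # genotype-level error processes
  drop <- matrix(runif(n * J) < config$ado_rate, n, J) & G == 1L
  gain <- matrix(runif(n * J) < config$fp_rate, n, J) & G == 0L
  Geff <- G
  Geff[drop] <- 0L
  Geff[gain] <- 1L

  # poor assays fail per cell
  poor <- matrix(FALSE, n, J)
  pj <- which(assays$assay_id %in% truth$poor_assays)
  if (length(pj)) {
    poor[, pj] <- matrix(runif(n * length(pj)) < config$poor_fail_prob,
                         n, length(pj))
  }

  snv_j <- which(assays$class == "snv")
  sv_j <- which(assays$class == "sv")

  # SNV count tables (failed cell-assay pairs contribute no row)
  snv_rows <- expand.grid(i = seq_len(n), j = snv_j,
                          KEEP.OUT.ATTRS = FALSE)
  snv_rows <- snv_rows[!poor[cbind(snv_rows$i, snv_rows$j)], , drop = FALSE]
  depth <- rnbinom(nrow(snv_rows), size = config$depth_size,
                   mu = config$depth_mean)
  p_alt <- ifelse(Geff[cbind(snv_rows$i, snv_rows$j)] == 1L,
                  config$alt_vaf, config$error_vaf)
  alt <- rbinom(nrow(snv_rows), depth, p_alt)
  snv_counts <- data.frame(
    cell_id = cells$cell_id[snv_rows$i],
    assay_id = assays$assay_id[snv_rows$j],
    alt_count = alt, depth = depth, stringsAsFactors = FALSE
  )

  # SV junction-matching read counts
  sv_rows <- expand.grid(i = seq_len(n), j = sv_j, KEEP.OUT.ATTRS = FALSE)
  present <- Geff[cbind(sv_rows$i, sv_rows$j)] == 1L &
    !poor[cbind(sv_rows$i, sv_rows$j)]
  n_match <- rpois(nrow(sv_rows),
                   ifelse(present, config$sv_reads_present_mean,
                          config$sv_reads_absent_mean))
  junction_counts <- data.frame(
    cell_id = cells$cell_id[sv_rows$i],
    assay_id = assays$assay_id[sv_rows$j],
    n_match_true = n_match, stringsAsFactors = FALSE
  )

  reads <- NULL
  if (level == "reads") {
    junctions <- setNames(assays$junction_seq[sv_j], assays$assay_id[sv_j])
    reads <- lapply(seq_len(n), function(i) {
      rows <- which(sv_rows$i == i)
      counts <- setNames(n_match[rows], assays$assay_id[sv_rows$j[rows]])
      make_cell_reads(counts, junctions, config$read_length,
                      config$n_background_reads)
    })
    names(reads) <- cells$cell_id
  }

  structure(list(
    snv_counts = snv_counts,
    junction_counts = junction_counts,
    coverage = snv_counts[, c("cell_id", "assay_id", "depth")],
    cells = cells[, c("cell_id", "visually_single")],
    effective_genotypes = Geff,
    reads = reads,
    truth = truth
  ), class = "sim_data")
}

# reads for one cell: each junction embedded n_match times plus background
make_cell_reads <- function(counts, junctions, read_length,
                            n_background) {
  out <- character(0)
  jlen <- nchar(junctions[1])
  for (aid in names(counts)) {
    k <- counts[[aid]]
    if (k == 0L) next
    flank <- read_length - jlen
    off <- sample.int(flank + 1L, k, replace = TRUE) - 1L
    rd <- vapply(seq_len(k), function(r) {
      paste0(random_dna(1L, off[r]), junctions[[aid]],
             random_dna(1L, flank - off[r]))
    }, character(1))
    rc <- runif(k) < 0.5
    rd[rc] <- revcomp(rd[rc])
    out <- c(out, rd)
  }
  bg <- character(0)
  pool <- c(junctions, revcomp(junctions))
  while (length(bg) < n_background) {
    cand <- random_dna(n_background - length(bg), read_length)
    ok <- !vapply(cand, function(r) any(vapply(pool, grepl, logical(1),
                                               x = r, fixed = TRUE)),
                  logical(1))
    bg <- c(bg, cand[ok])
  }
  sample(c(out, bg))
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data: %d SNV count rows, %d junction-count rows, %d cells%s\n",
              nrow(x$snv_counts), nrow(x$junction_counts), nrow(x$cells),
              if (is.null(x$reads)) "" else " (with reads)"))
  invisible(x)
}

#' Extract the target manifests implied by a simulated truth
#'
#' @param truth a `sim_truth`.
#' @return list with `snv_sites` and `junctions` data.frames in the manifest
#'   formats expected by the genotyping stages.
#' @export
sim_manifests <- function(truth) {
  a <- truth$assays
  snv <- a[a$class == "snv", c("assay_id", "chrom", "pos", "ref", "alt")]
  sv <- a[a$class == "sv", c("assay_id", "sv_class", "junction_seq",
                             "span_kb")]
  rownames(snv) <- rownames(sv) <- NULL
  list(snv_sites = snv, junctions = sv)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Writes `manifests/snv_sites.tsv`, `manifests/junctions.tsv`,
#' `counts.tsv`, `coverage.tsv`, `cells.tsv`, per-cell FASTQ files under
#' `cells/` (gzipped; requires `level = "reads"` data), and the ground truth
#' under `truth/`.
#'
#' @param sim a `sim_data` (from [simulate_observations()]).
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  truth <- sim$truth
  dir.create(file.path(outdir, "manifests"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  m <- sim_manifests(truth)
  write_tsv(m$snv_sites, file.path(outdir, "manifests", "snv_sites.tsv"))
  write_tsv(m$junctions, file.path(outdir, "manifests", "junctions.tsv"))
  write_tsv(sim$snv_counts, file.path(outdir, "counts.tsv"))
  write_tsv(sim$coverage, file.path(outdir, "coverage.tsv"))
  write_tsv(sim$cells, file.path(outdir, "cells.tsv"))
  write_tsv(truth$cells, file.path(outdir, "truth", "cells.tsv"))
  write_tsv(cbind(data.frame(clone = rownames(truth$clone_genotypes)),
                  as.data.frame(truth$clone_genotypes)),
            file.path(outdir, "truth", "clone_genotypes.tsv"))
  write_tsv(truth$assays[, c("assay_id", "class", "edge")],
            file.path(outdir, "truth", "assay_edges.tsv"))
  if (!is.null(sim$reads)) {
    dir.create(file.path(outdir, "cells"), showWarnings = FALSE)
    for (cid in names(sim$reads)) {
      write_fastq(sim$reads[[cid]],
                  file.path(outdir, "cells", paste0(cid, ".fastq.gz")))
    }
  }
  invisible(outdir)
}

#' Apply the genotyping and QC stages to a simulated dataset in memory
#'
#' Runs the count-level pipeline on a `sim_data` object: SNV calls from the
#' count table, SV calls from the junction-matching read counts, cell QC,
#' and binary-matrix assembly — the same operations [run_pipeline()] performs
#' on files.
#'
#' @param sim a `sim_data` from [simulate_observations()].
#' @param min_reads,min_alt_reads,min_vaf,min_fraction,min_depth stage
#'   thresholds (pipeline defaults).
#' @return list: `gm` (a `genotype_matrix` over QC-passing cells), `qc`,
#'   `snv_calls`, `sv_calls`, `truth_labels` (true clone label per retained
#'   cell, `"doublet"` for doublet chambers).
#' @export
sim_genotype_matrix <- function(sim, min_reads = 40L, min_alt_reads = 3L,
                                min_vaf = 0.01, min_fraction = 0.80,
                                min_depth = 10L) {
  truth <- sim$truth
  m <- sim_manifests(truth)
  snv_calls <- do.call(rbind, lapply(sim$cells$cell_id, function(cid)
    genotype_snv_cell(sim$snv_counts[sim$snv_counts$cell_id == cid, ,
                                     drop = FALSE],
                      m$snv_sites, cell_id = cid,
                      min_alt_reads = min_alt_reads, min_vaf = min_vaf)))
  sv_calls <- data.frame(
    cell_id = sim$junction_counts$cell_id,
    assay_id = sim$junction_counts$assay_id,
    call = vapply(sim$junction_counts$n_match_true, call_sv_presence,
                  integer(1), min_reads = min_reads),
    stringsAsFactors = FALSE
  )
  qc <- qc_cells(sim$coverage, sim$cells, m$snv_sites$assay_id,
                 min_fraction = min_fraction, min_depth = min_depth)
  gm <- build_matrix(snv_calls, sv_calls, cell_ids = qc$cell_id[qc$pass],
                     assay_ids = truth$assays$assay_id,
                     assay_class = setNames(truth$assays$class,
                                            truth$assays$assay_id))
  truth_labels <- truth$cells$clone[match(rownames(gm$X),
                                          truth$cells$cell_id)]
  list(gm = gm, qc = qc, snv_calls = snv_calls, sv_calls = sv_calls,
       truth_labels = truth_labels)
}
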