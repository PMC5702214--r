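# End-to-end orchestration: SV genotyping -> SNV genotyping -> QC + matrix
# -> clonal inference -> tree, with a JSON run manifest recording the
# configuration, seed and per-stage output checksums.

#' Cluster cells and resolve the clonal structure of a genotype matrix
#'
#' Convenience wrapper over the clonal-inference stage: estimates the number
#' of cell clusters (unless `k` is given), fits the Bernoulli mixture, flags
#' doublet clusters, derives mutation clusters over the clone (non-doublet)
#' clusters, and reduces to clone consensus genotypes plus the minimal
#' spanning tree.
#'
#' @param gm a `genotype_matrix` (or plain 0/1 matrix).
#' @param k number of cell clusters, or `"auto"` (default) to estimate by
#'   hierarchical clustering + silhouette.
#' @param k_max,n_restarts,tol,max_iter,use_mask passed to [estimate_k()] /
#'   [bmix()].
#' @param doublet_tolerance passed to [flag_doublet_clusters()].
#' @param seed RNG seed for the EM restarts.
#' @param distance tree distance, see [build_mst()].
#' @return list: `fit` (a `bmix`), `K`, `doublet_clusters`, `clone_clusters`,
#'   `n_clones`, `mutation_clusters`, `nodes` (clone consensus genotypes),
#'   `tree` (a `clone_tree`), `cell_assignments` (data.frame).
#' @export
cluster_cells <- function(gm, k = "auto", k_max = 8L, n_restarts = 20L,
                          tol = 1e-6, max_iter = 500L, use_mask = FALSE,
                          doublet_tolerance = 0.15, seed = NULL,
                          distance = "hamming") {
  X <- if (inherits(gm, "genotype_matrix")) gm$X else as.matrix(gm)
  assay_class <- if (inherits(gm, "genotype_matrix")) gm$assay_class else NULL
  K <- if (identical(k, "auto")) estimate_k(X, k_max = k_max)$K else
    as.integer(k)
  fit <- bmix(gm, K, n_restarts = n_restarts, tol = tol,
              max_iter = max_iter, seed = seed, use_mask = use_mask)
  doublets <- flag_doublet_clusters(fit, tolerance = doublet_tolerance)
  clones <- setdiff(seq_len(K), doublets)
  mut <- derive_mutation_clusters(fit, exclude = doublets)
  nodes <- consensus_genotypes(fit, include = clones,
                               assay_class = assay_class)
  tree <- if (nrow(nodes$genotypes) >= 2L) build_mst(nodes, distance) else NULL
  role <- ifelse(seq_len(K) %in% doublets, "doublet", "clone")
  cell_assignments <- data.frame(
    cell_id = rownames(X) %||% sprintf("cell_%d", seq_len(nrow(X))),
    cluster = fit$cluster,
    role = role[fit$cluster],
    max_responsibility = apply(fit$gamma, 1L, max),
    stringsAsFactors = FALSE
  )
  list(fit = fit, K = K, doublet_clusters = doublets,
       clone_clusters = clones, n_clones = length(clones),
       mutation_clusters = mut, nodes = nodes, tree = tree,
       cell_assignments = cell_assignments)
}

#' Pipeline run configuration
#'
#' Thresholds default to the values the genotyping and QC stages were built
#' around: SV present above 40 exactly-matching reads; SNV present at a
#' minimum of 3 variant reads comprising more than 1\% of the position's
#' reads; cells retained at 80\% or more of SNV sites covered at 10X or more.
#'
#' @param fastq_dir directory of per-cell FASTQ files named `<cell_id>.fastq`
#'   or `<cell_id>.fastq.gz`.
#' @param junction_manifest,snv_manifest,snv_counts,coverage,cells input file
#'   paths (TSV; see the reader functions for the required columns).
#' @param outdir output directory.
#' @param min_reads,min_alt_reads,min_vaf,min_fraction,min_depth stage
#'   thresholds.
#' @param both_strands match SV junctions on both strands.
#' @param k `"auto"` or an integer number of cell clusters.
#' @param use_mask make the EM skip no-data entries instead of scoring them
#'   as 0.
#' @param distance tree distance metric.
#' @param seed RNG seed (mandatory for the stochastic clustering stage).
#' @return list of class `run_config`.
#' @export
run_config <- function(fastq_dir, junction_manifest, snv_manifest,
                       snv_counts, coverage, cells, outdir,
                       min_reads = 40L, min_alt_reads = 3L, min_vaf = 0.01,
                       min_fraction = 0.80, min_depth = 10L,
                       both_strands = TRUE, k = "auto", use_mask = FALSE,
                       distance = "hamming", seed = 1L) {
  cfg <- as.list(environment())
  if (min_reads < 0 || min_alt_reads < 0 || min_vaf < 0 ||
      min_fraction < 0 || min_fraction > 1 || min_depth < 0) {
    stop("threshold out of valid range", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes SV genotyping, SNV genotyping, cell QC + matrix assembly, clonal
#' inference and tree construction, writing each stage's outputs under
#' `config$outdir` together with a `run_manifest.json` recording the package
#' version, configuration, seed, and an md5 checksum of every output file.
#' Reruns with identical inputs, configuration and seed produce identical
#' checksums.
#'
#' @param config a [run_config()].
#' @return result bundle (invisibly): `sv_calls`, `snv_calls`, `qc`,
#'   `matrix` (a `genotype_matrix`), `poor_assays`, `clonal` (output of
#'   [cluster_cells()]), `manifest`, `outdir`.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  junctions <- run_stage("genotype-sv",
                         read_junction_manifest(config$junction_manifest))
  sv_calls <- run_stage("genotype-sv", {
    cells_meta <- read_tsv_checked(config$cells,
                                   c("cell_id", "visually_single"))
    fq <- file.path(config$fastq_dir,
                    paste0(cells_meta$cell_id, ".fastq.gz"))
    alt <- file.path(config$fastq_dir, paste0(cells_meta$cell_id, ".fastq"))
    fq[!file.exists(fq)] <- alt[!file.exists(fq)]
    missing <- !file.exists(fq)
    if (any(missing)) {
      stop("no FASTQ for cell(s): ",
           paste(cells_meta$cell_id[missing], collapse = ", "))
    }
    do.call(rbind, lapply(seq_along(fq), function(i)
      genotype_sv_cell(fq[i], junctions, cell_id = cells_meta$cell_id[i],
                       min_reads = config$min_reads,
                       both_strands = config$both_strands)))
  })
  write_tsv(sv_calls, file.path(outdir, "sv_calls.tsv"))

  snv_sites <- run_stage("genotype-snv", read_snv_manifest(config$snv_manifest))
  snv_calls <- run_stage("genotype-snv", {
    counts <- read_tsv_checked(config$snv_counts,
                               c("cell_id", "assay_id", "alt_count", "depth"))
    cells_meta <- read_tsv_checked(config$cells,
                                   c("cell_id", "visually_single"))
    do.call(rbind, lapply(cells_meta$cell_id, function(cid)
      genotype_snv_cell(counts[counts$cell_id == cid, , drop = FALSE],
                        snv_sites, cell_id = cid,
                        min_alt_reads = config$min_alt_reads,
                        min_vaf = config$min_vaf)))
  })
  write_tsv(snv_calls, file.path(outdir, "snv_calls.tsv"))

  qc <- run_stage("qc-matrix", {
    coverage <- read_tsv_checked(config$coverage,
                                 c("cell_id", "assay_id", "depth"))
    cells_meta <- read_tsv_checked(config$cells,
                                   c("cell_id", "visually_single"))
    qc_cells(coverage, cells_meta, snv_sites$assay_id,
             min_fraction = config$min_fraction,
             min_depth = config$min_depth)
  })
  write_tsv(qc, file.path(outdir, "qc.tsv"))
  gm <- run_stage("qc-matrix", {
    passing <- qc$cell_id[qc$pass]
    build_matrix(snv_calls, sv_calls, cell_ids = passing,
                 assay_ids = c(snv_sites$assay_id, junctions$assay_id),
                 assay_class = setNames(
                   rep(c("snv", "sv"),
                       c(nrow(snv_sites), nrow(junctions))),
                   c(snv_sites$assay_id, junctions$assay_id)))
  })
  write_tsv(cbind(data.frame(cell_id = rownames(gm$X)), as.data.frame(gm$X)),
            file.path(outdir, "matrix.tsv"))
  write_tsv(cbind(data.frame(cell_id = rownames(gm$mask)),
                  as.data.frame(gm$mask)),
            file.path(outdir, "mask.tsv"))
  poor <- flag_poor_assays(gm)

  clonal <- run_stage("cluster",
                      cluster_cells(gm, k = config$k,
                                    use_mask = config$use_mask,
                                    distance = config$distance,
                                    seed = config$seed))
  write_tsv(clonal$cell_assignments, file.path(outdir, "clusters.tsv"))
  write_tsv(cbind(data.frame(cluster = rownames(clonal$fit$theta)),
                  as.data.frame(clonal$fit$theta)),
            file.path(outdir, "theta.tsv"))
  write_tsv(clonal$mutation_clusters,
            file.path(outdir, "mutation_clusters.tsv"))
  jsonlite::write_json(
    list(pi = clonal$fit$pi, K = clonal$K,
         doublet_clusters = clonal$doublet_clusters,
         loglik_trace = clonal$fit$loglik_trace,
         seed = config$seed),
    file.path(outdir, "model.json"), auto_unbox = TRUE, digits = NA)

  run_stage("tree", {
    if (!is.null(clonal$tree)) {
      write_tsv(clonal$tree$edges, file.path(outdir, "tree_edges.tsv"))
      write_tree(clonal$tree, file.path(outdir, "tree.graphml"), "graphml")
      write_tree(clonal$tree, file.path(outdir, "tree.dot"), "dot")
    }
  })

  outputs <- list.files(outdir, full.names = TRUE, recursive = TRUE)
  outputs <- outputs[!grepl("run_manifest\\.json$", outputs)]
  manifest <- list(
    package = "clonotrace",
    version = as.character(packageVersion("clonotrace")),
    seed = config$seed,
    config = config[!vapply(config, is.function, logical(1))],
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sv_calls = sv_calls, snv_calls = snv_calls, qc = qc,
                 matrix = gm, poor_assays = poor, clonal = clonal,
                 manifest = manifest, outdir = outdir))
}
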