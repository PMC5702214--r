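# SNV genotyping from per-site read counts. Alignment and pileup counting are
# upstream, third-party steps; the bespoke content is the single-cell
# confirmation filter applied to the counts.

#' Call SNV presence from read counts at one site
#'
#' Present when at least `min_alt_reads` variant-supporting reads are seen
#' AND they comprise strictly more than `min_vaf` of all reads at the
#' position. The variant allele fraction denominator is the total depth at
#' the position, not ref+alt. Zero depth is an absent call. If the observed
#' alternate base is recorded it must equal the expected alternate base.
#'
#' @param alt_count variant-supporting reads (non-negative integer).
#' @param depth all reads at the position; must be `>= alt_count`.
#' @param min_alt_reads minimum variant reads, inclusive (default 3).
#' @param min_vaf variant allele fraction bound, strict (default 0.01).
#' @param observed_alt optional base actually observed; compared with
#'   `expected_alt` when both are given.
#' @param expected_alt the manifest's alternate base.
#' @return integer 0/1.
#' @examples
#' call_snv_presence(3, 100)  # 3 reads, 3% VAF -> present
#' call_snv_presence(3, 300)  # exactly 1% -> absent (bound is strict)
#' call_snv_presence(2, 10)   # 20% but only 2 reads -> absent
#' @export
call_snv_presence <- function(alt_count, depth, min_alt_reads = 3L,
                              min_vaf = 0.01, observed_alt = NULL,
                              expected_alt = NULL) {
  if (alt_count < 0 || depth < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (alt_count > depth) {
    stop("alt_count (", alt_count, ") exceeds depth (", depth, ")",
         call. = FALSE)
  }
  if (!is.null(observed_alt) && !is.null(expected_alt) &&
      !is.na(observed_alt) && toupper(observed_alt) != toupper(expected_alt)) {
    return(0L)
  }
  if (depth == 0L) return(0L)
  as.integer(alt_count >= min_alt_reads && alt_count / depth > min_vaf)
}

#' Check concordance of a single-cell variant with the bulk manifest
#'
#' A single-cell SNV observation is accepted only if its location and base
#' change agree exactly with the bulk-confirmed site: chromosome, 1-based
#' position, reference base and alternate base must all match.
#'
#' @param site list or one-row data.frame with `assay_id`, `chrom`, `pos`,
#'   `ref`, `alt` as observed in the cell.
#' @param manifest bulk SNV site manifest (see [read_snv_manifest()]).
#' @return logical: `TRUE` if accepted.
#' @export
check_bulk_concordance <- function(site, manifest) {
  row <- manifest[manifest$assay_id == site$assay_id, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("assay_id '", site$assay_id, "' not in bulk manifest", call. = FALSE)
  }
  identical(as.character(site$chrom), as.character(row$chrom)) &&
    as.integer(site$pos) == as.integer(row$pos) &&
    toupper(site$ref) == row$ref &&
    toupper(site$alt) == row$alt
}

#' Genotype every manifest SNV site in one cell
#'
#' Applies [call_snv_presence()] to each manifest site using the cell's
#' counts table. Sites with no counts row are absent and flagged `no_data`
#' (no usable data, distinct from a covered reference call).
#'
#' @param counts data.frame with columns `cell_id`, `assay_id`, `alt_count`,
#'   `depth` (and optionally `observed_alt`) for one cell.
#' @param manifest SNV site manifest.
#' @param cell_id identifier recorded in the output; defaults to the single
#'   cell id present in `counts`.
#' @param min_alt_reads,min_vaf thresholds, see [call_snv_presence()].
#' @return data.frame `cell_id`, `assay_id`, `call`, `flag` (one row per
#'   manifest site; flag is `""` or `no_data`).
#' @export
genotype_snv_cell <- function(counts, manifest, cell_id = NULL,
                              min_alt_reads = 3L, min_vaf = 0.01) {
  manifest <- validate_snv_sites(manifest)
  if (is.null(cell_id)) {
    cell_id <- if (nrow(counts)) as.character(counts$cell_id[1]) else "cell"
  }
  counts <- counts[counts$cell_id == cell_id, , drop = FALSE]
  if (anyDuplicated(counts$assay_id)) {
    stop("duplicate (cell, assay) rows in counts for cell '", cell_id, "'",
         call. = FALSE)
  }
  idx <- match(manifest$assay_id, counts$assay_id)
  call <- integer(nrow(manifest))
  flag <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    if (is.na(idx[i])) {
      flag[i] <- "no_data"
      next
    }
    r <- counts[idx[i], ]
    obs <- if ("observed_alt" %in% names(counts)) r$observed_alt else NULL
    call[i] <- call_snv_presence(r$alt_count, r$depth,
                                 min_alt_reads = min_alt_reads,
                                 min_vaf = min_vaf,
                                 observed_alt = obs,
                                 expected_alt = manifest$alt[i])
  }
  data.frame(cell_id = cell_id, assay_id = manifest$assay_id,
             call = call, flag = flag, stringsAsFactors = FALSE)
}
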