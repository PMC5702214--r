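# Cell quality control and assembly of the binary cell-by-mutation matrix.
# SNV and SV calls enter the same matrix as equivalent contributors to the
# clonal structure.

#' Quality-control one cell
#'
#' A cell is retained when it was visually confirmed to be a single cell and
#' at least `min_fraction` of the target SNV sites are covered at
#' `min_depth`X or greater (both bounds inclusive). Only SNV sites count
#' toward coverage; SV assays do not.
#'
#' @param site_depths named numeric vector of per-SNV-site depths for the
#'   cell; sites absent from the vector count as depth 0.
#' @param snv_assay_ids character vector of all target SNV assay ids (the
#'   QC denominator).
#' @param visually_single was the chamber visually confirmed to contain one
#'   cell?
#' @param min_fraction minimum covered fraction (default 0.80, inclusive).
#' @param min_depth minimum depth for a site to count as covered (default 10,
#'   inclusive).
#' @return list with `pass` (logical) and `fraction_covered`.
#' @export
qc_cell <- function(site_depths, snv_assay_ids, visually_single = TRUE,
                    min_fraction = 0.80, min_depth = 10L) {
  if (length(snv_assay_ids) == 0L) {
    stop("empty SNV manifest: QC fraction undefined", call. = FALSE)
  }
  if (any(site_depths < 0)) stop("negative depth", call. = FALSE)
  d <- site_depths[match(snv_assay_ids, names(site_depths))]
  d[is.na(d)] <- 0
  frac <- sum(d >= min_depth) / length(snv_assay_ids)
  list(pass = isTRUE(visually_single) && frac >= min_fraction,
       fraction_covered = frac)
}

#' Apply cell QC to a cohort
#'
#' @param coverage data.frame `cell_id`, `assay_id`, `depth` with per-cell
#'   depths at SNV sites.
#' @param cells data.frame `cell_id`, `visually_single`.
#' @param snv_assay_ids all target SNV assay ids.
#' @inheritParams qc_cell
#' @return data.frame `cell_id`, `visually_single`, `fraction_covered`,
#'   `pass`.
#' @export
qc_cells <- function(coverage, cells, snv_assay_ids,
                     min_fraction = 0.80, min_depth = 10L) {
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cid <- cells$cell_id[i]
    cov <- coverage[coverage$cell_id == cid, , drop = FALSE]
    q <- qc_cell(setNames(cov$depth, cov$assay_id), snv_assay_ids,
                 visually_single = cells$visually_single[i],
                 min_fraction = min_fraction, min_depth = min_depth)
    data.frame(cell_id = cid, visually_single = cells$visually_single[i],
               fraction_covered = q$fraction_covered, pass = q$pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Assemble the binary cell-by-mutation matrix
#'
#' Packs per-cell SNV and SV calls into one 0/1 matrix with cells as rows and
#' assays as columns, in the given assay (manifest) order. A (cell, assay)
#' pair with no call, or an SNV call flagged `no_data`, becomes 0 in the
#' matrix with the companion mask set to 1; the matrix itself has no missing
#' state, matching how the calls are used downstream, while the mask lets the
#' mixture model optionally ignore no-data entries.
#'
#' @param snv_calls,sv_calls data.frames with `cell_id`, `assay_id`, `call`
#'   (0/1) and, for SNVs, optionally `flag`. Either may be NULL.
#' @param cell_ids QC-passing cells to include, in row order.
#' @param assay_ids column order; defaults to SNV assays then SV assays in
#'   first-appearance order.
#' @param assay_class optional named vector mapping assay_id to
#'   `"snv"`/`"sv"`; derived from which table an assay came from by default.
#' @return object of class `genotype_matrix`: list with `X` (0/1 matrix),
#'   `mask` (1 = no usable data), `assay_class`.
#' @export
build_matrix <- function(snv_calls = NULL, sv_calls = NULL, cell_ids,
                         assay_ids = NULL, assay_class = NULL) {
  if (length(cell_ids) == 0L) {
    stop("no QC-passing cells: cannot build a genotype matrix", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids", call. = FALSE)
  tag <- function(df, cls) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$.class <- cls
    if (!"flag" %in% names(df)) df$flag <- ""
    df[, c("cell_id", "assay_id", "call", "flag", ".class")]
  }
  calls <- rbind(tag(snv_calls, "snv"), tag(sv_calls, "sv"))
  if (is.null(calls)) stop("no calls supplied", call. = FALSE)
  calls <- calls[calls$cell_id %in% cell_ids, , drop = FALSE]
  key <- paste(calls$cell_id, calls$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    agree <- all(vapply(unique(dup), function(k)
      length(unique(calls$call[key == k])) == 1L, logical(1)))
    if (!agree) {
      stop("conflicting duplicate calls for the same (cell, assay) pair",
           call. = FALSE)
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  if (is.null(assay_ids)) {
    assay_ids <- c(unique(calls$assay_id[calls$.class == "snv"]),
                   unique(calls$assay_id[calls$.class == "sv"]))
  }
  if (anyDuplicated(assay_ids)) stop("duplicate assay_ids", call. = FALSE)
  if (is.null(assay_class)) {
    assay_class <- setNames(calls$.class[match(assay_ids, calls$assay_id)],
                            assay_ids)
  }
  X <- matrix(0L, nrow = length(cell_ids), ncol = length(assay_ids),
              dimnames = list(cell_ids, assay_ids))
  mask <- matrix(1L, nrow = length(cell_ids), ncol = length(assay_ids),
                 dimnames = list(cell_ids, assay_ids))
  ri <- match(calls$cell_id, cell_ids)
  ci <- match(calls$assay_id, assay_ids)
  keep <- !is.na(ci)
  idx <- cbind(ri[keep], ci[keep])
  X[idx] <- as.integer(calls$call[keep])
  mask[idx] <- as.integer(calls$flag[keep] == "no_data")
  X[mask == 1L] <- 0L
  structure(list(X = X, mask = mask, assay_class = assay_class),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d cells x %d assays (%d SNV, %d SV); %.1f%% entries masked (no data)\n",
              nrow(x$X), ncol(x$X),
              sum(x$assay_class == "snv"), sum(x$assay_class == "sv"),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$X

#' @export
dim.genotype_matrix <- function(x) dim(x$X)

#' Convert a genotype matrix back to long-form call records
#'
#' Inverse of [build_matrix()] on non-masked entries: masked entries become
#' `no_data` rows so that rebuilding the matrix round-trips exactly.
#'
#' @param gm a `genotype_matrix`.
#' @return data.frame `cell_id`, `assay_id`, `call`, `flag`.
#' @export
matrix_to_calls <- function(gm) {
  df <- expand.grid(cell_id = rownames(gm$X), assay_id = colnames(gm$X),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$call <- as.integer(gm$X[cbind(df$cell_id, df$assay_id)])
  df$flag <- ifelse(gm$mask[cbind(df$cell_id, df$assay_id)] == 1L,
                    "no_data", "")
  df
}

#' Flag assays with too much missing data
#'
#' A complement to finding poor assays post hoc as an all-absent mutation
#' cluster (see [derive_mutation_clusters()]): assays whose no-data fraction
#' across cells exceeds `max_missing_fraction` (strictly) can be excluded
#' before clustering.
#'
#' @param gm a `genotype_matrix`.
#' @param max_missing_fraction flag assays with mask fraction strictly above
#'   this (default 0.2).
#' @return character vector of flagged assay ids (possibly empty).
#' @export
flag_poor_assays <- function(gm, max_missing_fraction = 0.2) {
  if (nrow(gm$X) == 0L) stop("empty matrix", call. = FALSE)
  frac <- colMeans(gm$mask)
  colnames(gm$X)[frac > max_missing_fraction]
}
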