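# readers and writers for the formats the pipeline exchanges:
# FASTQ (via Biostrings, gzip transparent), header-validated TSV,
# target manifests, and a minimal per-cell VCF

#' Read a FASTQ file into a character vector of read sequences
#'
#' Plain or gzip-compressed FASTQ. Qualities are discarded: genotyping here
#' matches sequence only.
#'
#' @param path path to a `.fastq` or `.fastq.gz` file.
#' @return character vector of uppercase read sequences (possibly empty).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path, call. = FALSE)
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  toupper(as.character(reads, use.names = FALSE))
}

#' Write reads to a FASTQ file
#'
#' @param reads character vector of read sequences.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param ids optional read identifiers (defaults to `read_1..n`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  n <- length(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n > 0L) {
    rec <- rbind(paste0("@", ids), reads, "+",
                 vapply(nchar(reads), function(k)
                   strrep("I", k), character(1)))
    writeLines(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a TSV with required header columns
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an SV breakpoint-junction manifest
#'
#' The manifest lists one row per bulk-confirmed structural variant with the
#' novel junction sequence spanning its breakpoint. Junctions are uppercase
#' DNA of a fixed length (30 nt by default, the window used for exact-match
#' genotyping).
#'
#' @param path TSV with columns `assay_id`, `sv_class`, `junction_seq` and
#'   optionally `span_kb`.
#' @param junction_len required junction length in nucleotides (default 30);
#'   set to `NA` to accept any positive length.
#' @return data.frame with validated, uppercased junction sequences.
#' @export
read_junction_manifest <- function(path, junction_len = 30L) {
  df <- read_tsv_checked(path, c("assay_id", "sv_class", "junction_seq"))
  validate_junctions(df, junction_len)
}

#' @rdname read_junction_manifest
#' @param manifest data.frame with the manifest columns (for programmatic use).
#' @export
validate_junctions <- function(manifest, junction_len = 30L) {
  manifest$junction_seq <- toupper(manifest$junction_seq)
  if (anyDuplicated(manifest$assay_id)) {
    stop("duplicate assay_id in junction manifest: ",
         paste(unique(manifest$assay_id[duplicated(manifest$assay_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !is_dna(manifest$junction_seq) | nchar(manifest$junction_seq) == 0L
  if (any(bad)) {
    stop("junction_seq contains non-ACGT symbols for assay(s): ",
         paste(manifest$assay_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.na(junction_len)) {
    wrong <- nchar(manifest$junction_seq) != junction_len
    if (any(wrong)) {
      stop("junction_seq must be exactly ", junction_len,
           " nt (see `junction_len`); offending assay(s): ",
           paste(manifest$assay_id[wrong], collapse = ", "), call. = FALSE)
    }
  }
  ok_class <- c("deletion", "insertion", "inversion", "translocation")
  if (!all(manifest$sv_class %in% ok_class)) {
    stop("sv_class must be one of: ", paste(ok_class, collapse = ", "),
         call. = FALSE)
  }
  manifest
}

#' Read and validate an SNV site manifest
#'
#' One row per bulk-confirmed SNV: 1-based position, reference and alternate
#' base (VCF coordinate convention).
#'
#' @param path TSV with columns `assay_id`, `chrom`, `pos`, `ref`, `alt`.
#' @return validated data.frame.
#' @export
read_snv_manifest <- function(path) {
  df <- read_tsv_checked(path, c("assay_id", "chrom", "pos", "ref", "alt"))
  validate_snv_sites(df)
}

#' @rdname read_snv_manifest
#' @param manifest data.frame with the manifest columns.
#' @export
validate_snv_sites <- function(manifest) {
  manifest$ref <- toupper(manifest$ref)
  manifest$alt <- toupper(manifest$alt)
  if (anyDuplicated(manifest$assay_id)) {
    stop("duplicate assay_id in SNV manifest", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  if (!all(manifest$ref %in% bases) || !all(manifest$alt %in% bases)) {
    stop("ref/alt must be single bases in {A,C,G,T}", call. = FALSE)
  }
  if (any(manifest$ref == manifest$alt)) {
    stop("ref and alt must differ at every site", call. = FALSE)
  }
  if (any(manifest$pos < 1)) stop("pos must be >= 1 (1-based)", call. = FALSE)
  manifest
}

#' Write per-cell SNV genotype calls as a minimal VCF 4.2
#'
#' One sample column per cell, GT of `0/1` for present and `0/0` for absent;
#' sites with no usable data are `./.`.
#'
#' @param calls data.frame with columns `cell_id`, `assay_id`, `call`
#'   (0/1) and optionally `flag` (`no_data` marks missing genotypes).
#' @param sites SNV site manifest (`assay_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sites, path) {
  cells <- sort(unique(calls$cell_id))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  gt <- matrix("./.", nrow = nrow(sites), ncol = length(cells),
               dimnames = list(sites$assay_id, cells))
  for (i in seq_len(nrow(calls))) {
    aid <- calls$assay_id[i]
    if (!aid %in% rownames(gt)) next
    flag <- if ("flag" %in% names(calls)) calls$flag[i] else ""
    gt[aid, as.character(calls$cell_id[i])] <-
      if (identical(flag, "no_data")) "./." else
        if (calls$call[i] == 1) "0/1" else "0/0"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=clonotrace_%s", as.character(packageVersion("clonotrace"))),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cells), collapse = "\t")
  ), con)
  body <- cbind(sites$chrom, sites$pos, sites$assay_id, sites$ref, sites$alt,
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
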