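# SV genotyping: exact matching of breakpoint junction sequences in raw reads.
# A structural variant creates a novel junction sequence where two rearranged
# segments join; a fixed-length window (30 nt) spanning that junction occurs
# in a read if and only if the read crosses the breakpoint, so counting reads
# that contain the window exactly genotypes the SV without alignment.

#' Count reads exactly matching a breakpoint junction sequence
#'
#' A read counts if it contains `junction_seq` as an exact substring (no
#' mismatches, no indels); with `both_strands = TRUE` (default) a read also
#' counts if it contains the reverse complement, since raw reads are
#' unstranded. Each read counts at most once, even with multiple occurrences
#' or hits on both strands. Reads containing ambiguous bases simply never
#' match. Duplicate reads are all counted: amplicon data is expected to be
#' heavily duplicated.
#'
#' @param reads character vector of read sequences (any lengths, may be empty).
#' @param junction_seq uppercase DNA string (A/C/G/T only).
#' @param both_strands also match the reverse complement of the junction.
#' @return list with `n_match` (reads containing the junction) and
#'   `n_reads_scanned` (total reads examined); `n_match <= n_reads_scanned`.
#' @examples
#' j <- strrep("ACGT", 8)  # toy junction
#' count_junction_reads(c(paste0("TT", j, "AA"), "AAAA"), j)
#' @export
count_junction_reads <- function(reads, junction_seq, both_strands = TRUE) {
  junction_seq <- toupper(junction_seq)
  if (!is_dna(junction_seq) || nchar(junction_seq) == 0L) {
    stop("junction sequence contains non-ACGT symbols", call. = FALSE)
  }
  reads <- toupper(reads)
  hit <- grepl(junction_seq, reads, fixed = TRUE)
  if (both_strands) {
    hit <- hit | grepl(revcomp(junction_seq), reads, fixed = TRUE)
  }
  list(n_match = sum(hit), n_reads_scanned = length(reads))
}

#' Call structural-variant presence from a junction read count
#'
#' Present when strictly more than `min_reads` reads match the junction
#' exactly. The default of 40 was chosen upstream to exclude false positives
#' from cross-contamination or index hopping, so exactly 40 matching reads is
#' an absent call.
#'
#' @param n_match number of exactly-matching reads (or the list returned by
#'   [count_junction_reads()]).
#' @param min_reads threshold; call is present iff `n_match > min_reads`.
#' @return integer 0/1.
#' @export
call_sv_presence <- function(n_match, min_reads = 40L) {
  if (is.list(n_match)) n_match <- n_match$n_match
  if (min_reads < 0) stop("min_reads must be non-negative", call. = FALSE)
  if (n_match < 0) stop("n_match must be non-negative", call. = FALSE)
  as.integer(n_match > min_reads)
}

#' Genotype every SV junction in one cell's reads
#'
#' Scans a cell's raw reads (a FASTQ file or an in-memory read vector) for
#' each junction in the manifest and applies the presence threshold.
#' Deterministic for fixed input.
#'
#' @param reads path to a FASTQ (plain or gzipped) or a character vector of
#'   read sequences.
#' @param manifest junction manifest data.frame (see
#'   [read_junction_manifest()]).
#' @param cell_id identifier recorded in the output.
#' @param min_reads presence threshold, see [call_sv_presence()].
#' @param both_strands see [count_junction_reads()].
#' @param junction_len expected junction length for validation (NA = any).
#' @return data.frame with one row per junction: `cell_id`, `assay_id`,
#'   `n_match`, `n_reads_scanned`, `call`.
#' @export
genotype_sv_cell <- function(reads, manifest, cell_id = "cell",
                             min_reads = 40L, both_strands = TRUE,
                             junction_len = 30L) {
  if (is.character(reads) && length(reads) == 1L &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- read_fastq(reads)
  }
  if (nrow(manifest) == 0L) stop("empty junction manifest", call. = FALSE)
  manifest <- validate_junctions(manifest, junction_len)
  counts <- lapply(manifest$junction_seq, function(j)
    count_junction_reads(reads, j, both_strands = both_strands))
  n_match <- vapply(counts, `[[`, integer(1), "n_match")
  data.frame(
    cell_id = cell_id,
    assay_id = manifest$assay_id,
    n_match = n_match,
    n_reads_scanned = length(reads),
    call = vapply(n_match, call_sv_presence, integer(1),
                  min_reads = min_reads),
    stringsAsFactors = FALSE
  )
}
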