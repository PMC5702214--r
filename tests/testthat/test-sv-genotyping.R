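test_that("junction counting matches a naive per-read substring oracle", {
  set.seed(101)
  for (rep in 1:25) {
    j <- rand_seq(30)
    n_with <- sample(0:60, 1)
    n_without <- sample(0:60, 1)
    reads <- random_reads(n_with, n_without, j)
    # reverse-complement a random subset: counts must be strand-insensitive
    rc_idx <- runif(length(reads)) < 0.5
    reads[rc_idx] <- revcomp(reads[rc_idx])
    got <- count_junction_reads(reads, j, both_strands = TRUE)
    expect_identical(got$n_match, n_with)
    expect_identical(got$n_match, oracle_count_junction(reads, j, TRUE))
    expect_identical(got$n_reads_scanned, length(reads))
    fwd <- count_junction_reads(reads, j, both_strands = FALSE)
    expect_identical(fwd$n_match, oracle_count_junction(reads, j, FALSE))
    expect_lte(fwd$n_match, got$n_match)
  }
})

test_that("empty input, multiple occurrences, and ambiguous bases behave", {
  j <- rand_seq(30)
  expect_identical(count_junction_reads(character(0), j)$n_match, 0L)
  # two occurrences in one read count once
  expect_identical(
    count_junction_reads(paste0(j, "ACGT", j), j)$n_match, 1L)
  # a read carrying only the reverse complement counts iff both_strands
  r <- paste0("AAAA", revcomp(j), "TTTT")
  expect_identical(count_junction_reads(r, j, both_strands = TRUE)$n_match, 1L)
  expect_identical(count_junction_reads(r, j, both_strands = FALSE)$n_match, 0L)
  # an N inside the junction window prevents an exact match
  broken <- paste0("AA", sub("^(.{10}).", "\\1N", j), "TT")
  expect_identical(count_junction_reads(broken, j)$n_match, 0L)
  expect_error(count_junction_reads("ACGT", "ACGTN"), "non-ACGT")
})

test_that("adding matching reads never decreases the count; non-matching never changes it", {
  set.seed(102)
  j <- rand_seq(30)
  reads <- random_reads(5, 5, j)
  base <- count_junction_reads(reads, j)$n_match
  with_hit <- count_junction_reads(c(reads, paste0("GG", j, "CC")), j)$n_match
  expect_identical(with_hit, base + 1L)
  bg <- random_reads(0, 1, j)
  expect_identical(count_junction_reads(c(reads, bg), j)$n_match, base)
})

test_that("presence call is strictly greater-than the read threshold", {
  expect_identical(call_sv_presence(41, min_reads = 40), 1L)
  expect_identical(call_sv_presence(40, min_reads = 40), 0L)
  expect_identical(call_sv_presence(0), 0L)
  # the flip happens exactly between min_reads and min_reads + 1
  for (thr in c(0L, 3L, 40L)) {
    expect_identical(call_sv_presence(thr, min_reads = thr), 0L)
    expect_identical(call_sv_presence(thr + 1L, min_reads = thr), 1L)
  }
  expect_error(call_sv_presence(5, min_reads = -1), "non-negative")
})

test_that("per-cell SV genotyping over a FASTQ is correct and deterministic", {
  set.seed(103)
  jA <- rand_seq(30); jB <- rand_seq(30)
  manifest <- data.frame(assay_id = c("SV_A", "SV_B"),
                         sv_class = c("deletion", "translocation"),
                         junction_seq = c(jA, jB),
                         stringsAsFactors = FALSE)
  reads <- c(random_reads(100, 20, jA), random_reads(5, 0, jB))
  fq <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fq)
  calls <- genotype_sv_cell(fq, manifest, cell_id = "c1", min_reads = 40)
  expect_identical(calls$call[calls$assay_id == "SV_A"], 1L)
  expect_identical(calls$call[calls$assay_id == "SV_B"], 0L)
  expect_identical(calls$n_match[calls$assay_id == "SV_A"], 100L)
  expect_identical(calls$n_match[calls$assay_id == "SV_B"], 5L)
  expect_identical(calls$n_reads_scanned, rep(length(reads), 2L))
  # same file scanned twice: identical result
  expect_identical(calls, genotype_sv_cell(fq, manifest, cell_id = "c1",
                                           min_reads = 40))
  # empty FASTQ: everything absent with zero counts
  fq0 <- tempfile(fileext = ".fastq")
  write_fastq(character(0), fq0)
  calls0 <- genotype_sv_cell(fq0, manifest, cell_id = "c1")
  expect_true(all(calls0$n_match == 0L))
  expect_true(all(calls0$call == 0L))
})

test_that("manifest validation enforces length, alphabet and uniqueness", {
  bad_len <- data.frame(assay_id = "x", sv_class = "deletion",
                        junction_seq = "ACGT")
  expect_error(validate_junctions(bad_len), "exactly 30")
  expect_silent(validate_junctions(bad_len, junction_len = 4L))
  expect_silent(validate_junctions(bad_len, junction_len = NA))
  dup <- data.frame(assay_id = c("x", "x"), sv_class = "deletion",
                    junction_seq = c(rand_seq(30), rand_seq(30)))
  expect_error(validate_junctions(dup), "duplicate")
  bad_chr <- data.frame(assay_id = "x", sv_class = "deletion",
                        junction_seq = paste0(rand_seq(29), "N"))
  expect_error(validate_junctions(bad_chr), "non-ACGT")
})
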