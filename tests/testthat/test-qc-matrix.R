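test_that("cell QC applies the coverage rule inclusively on a 41-site panel", {
  sites <- sprintf("s%02d", 1:41)
  depths33 <- setNames(c(rep(10, 33), rep(9, 8)), sites)  # 33/41 = 0.805
  q <- qc_cell(depths33, sites)
  expect_true(q$pass)
  expect_equal(q$fraction_covered, 33 / 41)
  depths32 <- setNames(c(rep(10, 32), rep(9, 9)), sites)  # 32/41 = 0.780
  expect_false(qc_cell(depths32, sites)$pass)
  # a visually doubtful chamber fails regardless of coverage
  full <- setNames(rep(1000, 41), sites)
  expect_false(qc_cell(full, sites, visually_single = FALSE)$pass)
  # sites missing from the coverage table count as depth 0
  expect_equal(qc_cell(full[1:10], sites)$fraction_covered, 10 / 41)
})

test_that("QC is monotone in coverage depth", {
  set.seed(301)
  sites <- sprintf("s%02d", 1:20)
  for (rep in 1:10) {
    d <- setNames(sample(0:20, 20, replace = TRUE), sites)
    before <- qc_cell(d, sites)$pass
    after <- qc_cell(d + sample(0:5, 20, replace = TRUE), sites)$pass
    expect_true(after >= before)
  }
})

test_that("matrix assembly packs calls, masks missing data, keeps column order", {
  snv <- data.frame(cell_id = rep(c("c1", "c2", "c3"), each = 2),
                    assay_id = rep(c("s1", "s2"), 3),
                    call = c(1L, 0L, 0L, 1L, 1L, 1L),
                    flag = c("", "", "", "no_data", "", ""),
                    stringsAsFactors = FALSE)
  sv <- data.frame(cell_id = c("c1", "c1", "c2", "c2", "c3"),
                   assay_id = c("v1", "v2", "v1", "v2", "v1"),
                   call = c(1L, 1L, 0L, 1L, 0L),
                   stringsAsFactors = FALSE)  # c3 x v2 missing entirely
  gm <- build_matrix(snv, sv, cell_ids = c("c1", "c2", "c3"))
  expect_identical(dim(gm$X), c(3L, 4L))
  expect_identical(colnames(gm$X), c("s1", "s2", "v1", "v2"))
  expect_identical(gm$X["c1", ], c(s1 = 1L, s2 = 0L, v1 = 1L, v2 = 1L))
  # a no_data SNV call is 0 in X with mask 1
  expect_identical(gm$X["c2", "s2"], 0L)
  expect_identical(gm$mask["c2", "s2"], 1L)
  # an entirely absent (cell, assay) pair is 0 with mask 1
  expect_identical(gm$X["c3", "v2"], 0L)
  expect_identical(gm$mask["c3", "v2"], 1L)
  expect_identical(sum(gm$mask), 2L)
  expect_identical(unname(gm$assay_class),
                   c("snv", "snv", "sv", "sv"))
})

test_that("matrix <-> call records round-trips exactly", {
  set.seed(302)
  X <- block_matrix(4, 6, noise = 0.2)
  snv <- data.frame(cell_id = rep(rownames(X), ncol(X)),
                    assay_id = rep(colnames(X), each = nrow(X)),
                    call = as.integer(X),
                    flag = sample(c("", "no_data"), length(X),
                                  replace = TRUE, prob = c(0.9, 0.1)),
                    stringsAsFactors = FALSE)
  gm <- build_matrix(snv_calls = snv, cell_ids = rownames(X),
                     assay_ids = colnames(X))
  back <- matrix_to_calls(gm)
  gm2 <- build_matrix(snv_calls = back, cell_ids = rownames(X),
                      assay_ids = colnames(X))
  expect_identical(gm$X, gm2$X)
  expect_identical(gm$mask, gm2$mask)
})

test_that("degenerate matrix inputs error clearly", {
  sv <- data.frame(cell_id = "c1", assay_id = "v1", call = 1L)
  expect_error(build_matrix(sv_calls = sv, cell_ids = character(0)),
               "no QC-passing cells")
  conflict <- rbind(sv, data.frame(cell_id = "c1", assay_id = "v1",
                                   call = 0L))
  expect_error(build_matrix(sv_calls = conflict, cell_ids = "c1"),
               "conflicting duplicate")
  # agreeing duplicates are tolerated
  agree <- rbind(sv, sv)
  expect_silent(gm <- build_matrix(sv_calls = agree, cell_ids = "c1"))
  expect_identical(gm$X[1, 1], 1L)
})

test_that("poor-assay flagging uses a strict missingness threshold", {
  mask <- matrix(0L, 10, 3, dimnames = list(sprintf("c%d", 1:10),
                                            c("a1", "a2", "a3")))
  mask[1:3, 2] <- 1L  # 30% missing
  mask[1:2, 3] <- 1L  # exactly 20% missing
  gm <- structure(list(X = mask * 0L, mask = mask,
                       assay_class = c(a1 = "snv", a2 = "snv", a3 = "sv")),
                  class = "genotype_matrix")
  expect_identical(flag_poor_assays(gm, 0.2), "a2")
  expect_identical(flag_poor_assays(gm, 1.0), character(0))
  expect_identical(flag_poor_assays(gm, 0.0), c("a2", "a3"))
})
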