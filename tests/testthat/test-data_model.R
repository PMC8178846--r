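test_that("expression read/write round-trips and validates", {
  dir <- withr::local_tempdir()
  vals <- matrix(round(rnorm(12), 6), 3, 4,
                 dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  em <- expr_matrix(vals, data.frame(sample_id = paste0("s", 1:4),
                                     group = c("PT", "PT", "RL", "RL"),
                                     model_id = "m1"))
  expect_identical(dim(em$values), c(3L, 4L))
  f1 <- file.path(dir, "e.tsv"); f2 <- file.path(dir, "a.tsv")
  write_expression(em, f1, f2)
  back <- read_expression(f1, f2)
  expect_equal(back$values, em$values)
  expect_equal(back$annotations$group, em$annotations$group)

  # non-numeric cell names gene and sample
  bad <- readLines(f1)
  bad[2] <- sub("\t[^\t]*$", "\txx", bad[2])
  writeLines(bad, f1)
  expect_error(read_expression(f1, f2), "'A'.*'s4'")
})

test_that("duplicate gene rows collapse by mean, order-independently", {
  dir <- withr::local_tempdir()
  anno <- file.path(dir, "a.tsv")
  write.table(data.frame(sample_id = c("s1", "s2"), cohort_id = "c1"),
              anno, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c("gene_id\ts1\ts2", "A\t2\t2", "B\t5\t7", "A\t4\t4")
  f <- file.path(dir, "e.tsv")
  writeLines(lines, f)
  expect_warning(em <- read_expression(f, anno), "duplicat")
  expect_equal(em$values["A", ], c(s1 = 3, s2 = 3))
  # permuted rows give identical per-gene values
  writeLines(lines[c(1, 4, 3, 2)], f)
  expect_warning(em2 <- read_expression(f, anno), "duplicat")
  g <- sort(rownames(em$values))
  expect_equal(em$values[g, ], em2$values[g, ])
})

test_that("samples without annotation are rejected by name", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id\ts1\tsX", "A\t1\t2"), file.path(dir, "e.tsv"))
  write.table(data.frame(sample_id = "s1", cohort_id = "c1"),
              file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_expression(file.path(dir, "e.tsv"),
                               file.path(dir, "a.tsv")), "sX")
})

test_that("GMT parsing, weights, and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s.gmt")
  writeLines(c("sig1\tdesc\tG1\tG2:-1",
               "sig3\tother\tG9:0.25\tG8\tG7:-2.5"), f)
  sigs <- read_signature_gmt(f)
  expect_named(sigs, c("sig1", "sig3"))
  expect_equal(sigs$sig1$gene_id, c("G1", "G2"))
  expect_equal(sigs$sig1$weight, c(1, -1))
  expect_equal(sigs$sig3$weight, c(0.25, 1, -2.5))

  writeLines("sig2\tdesc", f)
  expect_error(read_signature_gmt(f), "no genes")
  writeLines("sig2\tdesc\tG1:abc", f)
  expect_error(read_signature_gmt(f), "non-numeric weight")

  f2 <- file.path(dir, "out.gmt")
  write_signature_gmt(sigs, f2)
  back <- read_signature_gmt(f2)
  expect_equal(back$sig3$gene_id, sigs$sig3$gene_id)
  expect_equal(back$sig3$weight, sigs$sig3$weight)
  expect_equal(names(back), names(sigs))
})

test_that("harmonize restricts signatures per cohort with coverage", {
  sig <- gene_signature(c("A", "B", "C"), c(1, -1, 1))
  coh1 <- make_expr(matrix(rnorm(8), 4, 2), genes = c("A", "C", "D", "E"))
  coh2 <- make_expr(matrix(rnorm(6), 3, 2), genes = c("A", "B", "C"))
  coh3 <- make_expr(matrix(rnorm(4), 2, 2), genes = c("X", "Y"))
  h <- harmonize(list(k1 = coh1, k2 = coh2), sig)
  expect_equal(h$k1$signature$gene_id, c("A", "C"))
  expect_equal(h$k1$signature$weight, c(1, 1))
  expect_equal(h$k1$coverage, 2 / 3)
  expect_equal(h$k2$signature$gene_id, sig$gene_id)  # identity
  expect_equal(h$k2$coverage, 1)
  expect_error(harmonize(list(k3 = coh3), sig), "k3")
})

test_that("cohort_survival and clinical round-trip enforce invariants", {
  dir <- withr::local_tempdir()
  cs <- cohort_survival(paste0("p", 1:3), c(10, 0, 55.5), c(1, 0, 1),
                        endpoint = "DMFS", cohort_id = "GSEx")
  f <- file.path(dir, "clin.tsv")
  write_clinical(cs, f)
  back <- read_clinical(f)
  expect_equal(as.data.frame(back), as.data.frame(cs))
  expect_error(cohort_survival("p1", -1, 1), ">= 0")
  expect_error(cohort_survival(c("p1", "p2"), c(1, 2), c(0, 2)), "0/1")
  expect_error(cohort_survival(c("p1", "p2"), c(1, 2), c(0, 1),
                               endpoint = c("RFS", "DSS")), "one endpoint")
})
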