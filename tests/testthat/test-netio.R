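test_that("interaction reading normalizes scores, collapses duplicates and drops self-loops", {
  f <- write_lines_tmp(c("TLR3\tTICAM1\t900",
                         "A\tB\t500",
                         "B\tA\t700",
                         "A\tA\t800"))
  expect_message(rec <- read_interactions(f), "self-loop")
  expect_equal(nrow(rec), 2)
  tlr3 <- rec[rec$gene_a == "TICAM1" | rec$gene_b == "TICAM1", ]
  expect_equal(sort(c(tlr3$gene_a, tlr3$gene_b)), c("TICAM1", "TLR3"))
  expect_equal(tlr3$score, 0.9)
  ab <- rec[rec$gene_a == "A", ]
  expect_equal(ab$gene_b, "B")
  expect_equal(ab$score, 0.7)  # duplicate collapse keeps the max
  expect_equal(attr(rec, "self_loops_dropped"), 1L)
})

test_that("interaction reading accepts a header, custom scales and mixed case", {
  f <- write_lines_tmp(c("gene_a\tgene_b\tscore",
                         "# comment",
                         "tlr3\tticam1\t0.9"))
  rec <- read_interactions(f, score_scale = 1)
  expect_equal(rec$gene_a, "TICAM1")
  expect_equal(rec$gene_b, "TLR3")
  expect_equal(rec$score, 0.9)
})

test_that("interaction reading reports malformed rows and bad scores by line number", {
  f <- write_lines_tmp(c("A\tB\t900", "C\tD"))
  expect_error(read_interactions(f), "line 2")
  f <- write_lines_tmp(c("A\tB\t900", "C\tD\t0"))
  expect_error(read_interactions(f), "line 2.*\\(0, 1000\\]")
  f <- write_lines_tmp(c("A\tB\t1500"))
  expect_error(read_interactions(f), "line 1")
  f <- write_lines_tmp(c("A\tB\tscorey"))
  expect_error(read_interactions(f), "line 1")
  expect_error(read_interactions(tempfile()), "not found")
})

test_that("duplicate-pair collapse is order-independent", {
  withr::with_seed(11, {
    base <- data.frame(
      gene_a = sample(LETTERS[1:6], 30, replace = TRUE),
      gene_b = sample(LETTERS[1:6], 30, replace = TRUE),
      score = sample(seq(100, 900, by = 50), 30, replace = TRUE)
    )
    base <- base[base$gene_a != base$gene_b, ]
    lines <- sprintf("%s\t%s\t%d", base$gene_a, base$gene_b, base$score)
    ref <- read_interactions(write_lines_tmp(lines))
    for (k in 1:5) {
      shuf <- read_interactions(write_lines_tmp(sample(lines)))
      expect_identical(shuf, ref, ignore_attr = TRUE)
    }
  })
})

test_that("alias tables support alias and full-name lookup with conflicts rejected", {
  f <- write_lines_tmp(c(
    "alias\tcanonical\tfull_name",
    "TLR3\tTLR3\tToll-like receptor 3",
    "TRIF\tTICAM1\tTIR domain containing adaptor molecule 1",
    "TICAM1\tTICAM1\tTIR domain containing adaptor molecule 1"
  ))
  am <- read_aliases(f)
  expect_equal(resolve_alias(am, "TRIF"), "TICAM1")
  expect_equal(resolve_alias(am, "Trif"), "TICAM1")  # case-normalized fallback
  expect_equal(resolve_alias(am, "TLR3"), "TLR3")
  expect_equal(gene_full_name(am, "TLR3"), "Toll-like receptor 3")
  expect_true(is.na(resolve_alias(am, "NOSUCHGENE")))
  expect_equal(gene_full_name(am, "NOSUCHGENE"), "")

  bad <- write_lines_tmp(c("TRIF\tTICAM1\tx", "TRIF\tTLR3\ty"))
  expect_error(read_aliases(bad), "conflicting alias 'TRIF'.*TICAM1, TLR3")
})

test_that("variant tables round-trip through write and read exactly", {
  v <- data.frame(
    gene = c("TICAM1", "TBK1", "UNC93B1"),
    effect = c("missense", "nonsense", "splice"),
    freq_db1 = c(0.0012345678901, 0, 0.5),
    freq_db2 = c(0.25, 1e-9, 0),
    cohort_freq = c(0, 0.006, 0.0061),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".tsv")
  write_table(v, f)
  expect_identical(read_variants(f), v)
})

test_that("variant reading rejects unknown effect tokens and treats missing frequency as zero", {
  f <- write_lines_tmp(c("G1\tmissense\t0.001\t\t",
                         "G2\tSYNONYMOUS\t0\t0\t0"))
  v <- read_variants(f)
  expect_equal(v$freq_db2, c(0, 0))
  expect_equal(v$cohort_freq, c(0, 0))
  expect_equal(v$effect, c("missense", "synonymous"))

  bad <- write_lines_tmp("G1\tgarbled\t0\t0\t0")
  expect_error(read_variants(bad), "unknown effect class 'garbled'")
  oob <- write_lines_tmp("G1\tmissense\t1.5\t0\t0")
  expect_error(read_variants(oob), "\\[0, 1\\]")
})

test_that("gene lists read one upper-cased symbol per line; empty files are empty lists", {
  f <- write_lines_tmp(c("tlr3", "", "# comment", " TICAM1 "))
  expect_equal(read_gene_list(f), c("TLR3", "TICAM1"))
  empty <- write_lines_tmp(character(0))
  expect_equal(read_gene_list(empty), character(0))
})

test_that("connectome export carries the ten annotation categories", {
  cx <- build_connectome(toy_network(), "A")
  f <- tempfile(fileext = ".tsv")
  write_table(connectome_table(cx), f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_true(all(c("distance", "rank", "p_value", "brp", "ratio_median",
                    "ratio_mean", "sphere", "route", "degrees",
                    "full_name") %in% header))
})
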