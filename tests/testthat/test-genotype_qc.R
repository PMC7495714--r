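tree <- default_tree()

test_that("call acceptance applies the strict intensity-over-baseline rule", {
  mk <- function(intensity, baseline, allele = "A")
    list(allele = allele, intensity = intensity, baseline = baseline)
  expect_true(accept_call(mk(12, 3)))    # delta 9
  expect_false(accept_call(mk(7, 3)))    # delta 4: noise
  expect_false(accept_call(mk(8, 3)))    # delta exactly 5: still noise
  expect_false(accept_call(mk(12, 3, allele = "N")))
  expect_false(accept_call(mk(12, 3, allele = NA)))
  expect_true(accept_call(mk(8, 3), min_delta = 4))
})

test_that("sample call rate uses the panel denominator with a strict cut", {
  calls38 <- perfect_calls("H", tree, drop_positions = tree$panel[1])
  s38 <- qc_sample(calls38, tree$panel)
  expect_equal(s38$call_rate, 38 / 39)
  expect_true(s38$passed_qc)

  calls37 <- perfect_calls("H", tree, drop_positions = tree$panel[1:2])
  s37 <- qc_sample(calls37, tree$panel)
  expect_equal(s37$call_rate, 37 / 39)
  expect_false(s37$passed_qc)

  s0 <- qc_sample(perfect_calls("H", tree)[0, ], tree$panel)
  expect_equal(s0$call_rate, 0)
  expect_false(s0$passed_qc)
})

test_that("ambiguous inputs are rejected", {
  calls <- perfect_calls("H", tree)
  mixed <- rbind(calls, transform(calls[1, ], sample_id = "s2"))
  expect_error(qc_sample(mixed, tree$panel), "more than one sample")
  dup <- rbind(calls, calls[1, ])
  expect_error(qc_sample(dup, tree$panel), "duplicate call")
  off <- transform(calls, position = position + 1L)
  expect_error(qc_sample(off, tree$panel), "outside the declared panel")
})

test_that("QC is monotone in its thresholds and call-order invariant", {
  set.seed(404)
  calls <- perfect_calls("J1", tree)
  calls$intensity <- runif(39, 4, 14)
  deltas <- c(0, 2, 5, 8, 11)
  accepted <- lapply(deltas, function(d) sum(accept_call(calls, d)))
  expect_true(all(diff(unlist(accepted)) <= 0))

  rates <- c(0.5, 0.8, 0.95, 0.99)
  passed <- vapply(rates, function(r)
    qc_sample(calls, tree$panel, rate_threshold = r)$passed_qc, logical(1))
  expect_true(all(diff(passed) <= 0))

  shuffled <- calls[sample(nrow(calls)), ]
  a <- qc_sample(calls, tree$panel)
  b <- qc_sample(shuffled, tree$panel)
  expect_identical(a$calls[order(as.integer(names(a$calls)))],
                   b$calls[order(as.integer(names(b$calls)))])
  expect_identical(a$call_rate, b$call_rate)
})

test_that("cohort-level QC agrees with per-sample QC", {
  raw <- rbind(perfect_calls("H4", tree, sample_id = "a"),
               perfect_calls("K", tree, sample_id = "b",
                             drop_positions = tree$panel[1:3]))
  qc <- qc_cohort(raw, tree$panel)
  expect_identical(qc$qc_table$passed_qc, c(TRUE, FALSE))
  single <- qc_sample(raw[raw$sample_id == "a", ], tree$panel)
  expect_identical(qc$samples[["a"]]$calls, single$calls)
  expect_identical(rownames(qc$genotypes), "a")
  expect_false(anyNA(qc$genotypes["a", ]))
})

test_that("genotype TSV round-trips through the reader", {
  raw <- perfect_calls("U5", tree)
  f <- tempfile(fileext = ".tsv")
  write.table(raw, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_genotype_tsv(f)
  expect_equal(back$position, raw$position)
  expect_equal(back$allele, raw$allele)
  expect_error(read_genotype_tsv({
    f2 <- tempfile(fileext = ".tsv")
    write.table(raw[, 1:3], f2, sep = "\t", row.names = FALSE)
    f2
  }), "lacks columns")
})

test_that("a single-sample VCF maps onto the panel with auto-accepted calls", {
  skip_if_not_installed("vcfR")
  # sample carrying the J1 path as ALT calls relative to an rCRS-like
  # reference (rCRS sits inside H: H-path loci have the derived base as REF)
  path <- defining_path(tree, "J1")
  info <- mthaplotau:::panel_alleles(tree)
  body <- vapply(seq_len(nrow(path)), function(i) {
    pos <- path$position[i]
    ref <- info$reference[info$position == pos]
    sprintf("MT\t%d\t.\t%s\t%s\t99\tPASS\t.\tGT\t1", pos, ref,
            path$derived[i])
  }, character(1))
  # H-path loci off the J1 path: the sample carries the ancestral base,
  # which is ALT relative to the rCRS-like reference
  hpath <- defining_path(tree, "H")
  hpath <- hpath[!hpath$position %in% path$position, , drop = FALSE]
  body2 <- vapply(seq_len(nrow(hpath)), function(i) {
    pos <- hpath$position[i]
    sprintf("MT\t%d\t.\t%s\t%s\t99\tPASS\t.\tGT\t1", pos,
            hpath$derived[i], hpath$ancestral[i])
  }, character(1))
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=MT,length=16569>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
           body, body2)
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  calls <- read_genotype_vcf(f, tree)
  expect_equal(nrow(calls), 39L)
  s <- qc_sample(calls, tree$panel)
  expect_true(s$passed_qc)  # intensity-free calls are auto-accepted
  asg <- assign_haplogroup(s, tree)
  expect_identical(asg$haplogroup, "J1")
})
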