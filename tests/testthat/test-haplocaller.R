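tree <- default_tree()

test_that("path matching requires every derived allele to be present", {
  s <- perfect_sample("J1", tree)
  expect_true(match_node(s, tree, tree$root))  # empty path, vacuous
  expect_true(match_node(s, tree, "J1"))
  expect_true(match_node(s, tree, "J"))        # prefix
  expect_false(match_node(s, tree, "J1d"))
  expect_false(match_node(s, tree, "K"))

  # a no-call at an H-path SNP is not "present": descent is blocked
  h_snp <- defining_path(tree, "H")$position[4]
  s_miss <- perfect_sample("H", tree, drop_positions = h_snp)
  expect_false(match_node(s_miss, tree, "H"))
  expect_true(match_node(s_miss, tree, "HV"))
  expect_error(match_node(s, tree, "nope"), "unknown haplogroup")
})

test_that("match_node of a child implies match_node of its parent", {
  for (nm in names(tree$nodes)) {
    s <- perfect_sample(nm, tree)
    parent <- tree$nodes[[nm]]$parent
    if (!is.na(parent) && match_node(s, tree, nm))
      expect_true(match_node(s, tree, parent))
  }
})

test_that("sequential descent assigns the deepest conflict-free node", {
  a <- assign_haplogroup(perfect_sample("H4", tree), tree)
  expect_identical(a$status, "assigned")
  expect_identical(a$haplogroup, "H4")
  expect_length(a$off_path_derived, 0L)
  expect_length(a$missing_on_path, 0L)

  # derived on the J1 path plus a K-defining derived allele: conflict
  k_snp <- tree$nodes[["K"]]$snps$position[1]
  con <- assign_haplogroup(
    perfect_sample("J1", tree, extra_derived = k_snp), tree)
  expect_identical(con$status, "conflict")
  expect_true(k_snp %in% con$off_path_derived)

  # zero derived alleles: root-only match, unassigned
  root_s <- perfect_sample(tree$root, tree)
  expect_identical(assign_haplogroup(root_s, tree)$status, "unassigned")

  # failed-QC samples are not called
  bad <- qc_sample(perfect_calls("H", tree,
                                 drop_positions = tree$panel[1:5]),
                   tree$panel)
  expect_identical(assign_haplogroup(bad, tree)$status, "failed_qc")
})

test_that("a blocked branch falls back to the deepest called ancestor", {
  h1_snp <- tree$nodes[["H1"]]$snps$position[1]
  s <- perfect_sample("H1", tree, drop_positions = h1_snp)
  a <- assign_haplogroup(s, tree)
  expect_identical(a$haplogroup, "H")
})

test_that("every tree node is recovered from its own perfect data", {
  for (nm in names(tree$nodes)) {
    a <- assign_haplogroup(perfect_sample(nm, tree), tree)
    if (nm == tree$root) expect_identical(a$status, "unassigned")
    else expect_identical(a$haplogroup, nm)
  }
})

test_that("the caller agrees with a brute-force oracle on noisy samples", {
  cfg <- sim_config(seed = 5)
  set.seed(5)
  n <- 1000
  haps <- sample(names(tree$nodes), n, replace = TRUE)
  raw <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_genotypes(haps[i], tree, cfg,
                       seed = mthaplotau:::subject_seed(5, i),
                       sample_id = sprintf("o%04d", i))
  }))
  qc <- qc_cohort(raw, tree$panel)
  vec <- call_haplogroups(qc$genotypes, tree, qc$qc_table)
  for (id in vec$sample_id) {
    o <- oracle_assign(qc$samples[[id]], tree)
    row <- vec[vec$sample_id == id, ]
    expect_identical(row$status, o$status)
    if (o$status == "assigned")
      expect_identical(row$haplogroup, o$haplogroup)
    # and the scalar API agrees with the vectorised one
    s <- assign_haplogroup(qc$samples[[id]], tree)
    expect_identical(s$status, row$status)
  }
})

test_that("assignment is deterministic under node reordering", {
  s <- perfect_sample("T2", tree)
  rev_doc <- yaml::yaml.load(serialize_tree(tree))
  rev_doc$nodes <- rev(rev_doc$nodes)
  rev_tree <- load_tree(rev_doc)
  expect_identical(assign_haplogroup(s, tree)$haplogroup,
                   assign_haplogroup(s, rev_tree)$haplogroup)
})

test_that("super-haplogroup mapping pools U/K and J/T lineages", {
  expect_identical(to_super_haplogroup("U5", tree), "UK")
  expect_identical(to_super_haplogroup("K", tree), "UK")
  expect_identical(to_super_haplogroup("J1", tree), "JT")
  expect_identical(to_super_haplogroup("T2", tree), "JT")
  expect_identical(to_super_haplogroup("H4", tree), "H4")  # identity-mapped

  empty_map_tree <- tree
  empty_map_tree$super_map <- character(0)
  expect_true(is.na(to_super_haplogroup("H4", empty_map_tree)))

  # nearest mapped ancestor when the node itself is unmapped
  partial <- tree
  partial$super_map <- c(U = "UK")
  expect_identical(to_super_haplogroup("U5", partial), "UK")

  un <- mthaplotau:::new_assignment("x", NA_character_, "conflict")
  expect_true(is.na(to_super_haplogroup(un, tree)))
})

test_that("the European filter keeps flagged clades and removes the rest", {
  doc <- yaml::yaml.load(serialize_tree(tree))
  for (i in seq_along(doc$nodes))
    if (doc$nodes[[i]]$name == "X") doc$nodes[[i]]$european <- FALSE
  mixed_tree <- load_tree(doc)

  raw <- rbind(perfect_calls("H1", tree, sample_id = "euro"),
               perfect_calls("X", tree, sample_id = "nonmatch"),
               perfect_calls("J1", tree, sample_id = "confl",
                             extra_derived = tree$nodes[["K"]]$snps$position[1]),
               perfect_calls("N", tree, sample_id = "rootonly"))
  qc <- qc_cohort(raw, mixed_tree$panel)
  asg <- call_haplogroups(qc$genotypes, mixed_tree, qc$qc_table)
  part <- filter_european(asg, mixed_tree)

  expect_identical(part$kept$sample_id, "euro")
  expect_identical(part$kept$haplogroup, "H1")
  expect_identical(part$kept$super_haplogroup, "H1")
  removed <- setNames(part$removed$removal_reason, part$removed$sample_id)
  expect_identical(removed[["nonmatch"]], "non_european")
  expect_identical(removed[["confl"]], "conflict")
  expect_identical(removed[["rootonly"]], "unassigned")
  expect_setequal(c(part$kept$sample_id, part$removed$sample_id),
                  unique(raw$sample_id))
})
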