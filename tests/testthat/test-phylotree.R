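tree <- default_tree()

test_that("the shipped tree document loads with the full 39-locus panel", {
  expect_s3_class(tree, "haplo_tree")
  expect_length(tree$panel, 39L)
  expect_identical(tree$root, "N")
  # every defining SNP belongs to the panel, positions unique across it
  all_snps <- do.call(rbind, lapply(tree$nodes, function(n) n$snps))
  expect_true(all(all_snps$position %in% tree$panel))
  expect_false(anyDuplicated(all_snps$position) > 0)
  expect_true(all(all_snps$position >= 1 & all_snps$position <= 16569))
  expect_true(all(all_snps$ancestral != all_snps$derived))
})

test_that("a degenerate single-node tree is valid with an empty panel", {
  t1 <- load_tree(list(name = "mini", root = "N",
                       nodes = list(list(name = "N", parent = NULL,
                                         european = TRUE, snps = list()))))
  expect_length(t1$panel, 0L)
  expect_identical(defining_path(t1, "N"),
                   defining_path(t1, t1$root))
  expect_equal(nrow(defining_path(t1, "N")), 0L)
})

test_that("malformed documents are rejected with named violations", {
  self_parent <- list(root = "A", nodes = list(
    list(name = "A", parent = "A", european = TRUE, snps = list())))
  expect_error(load_tree(self_parent), "cycle")

  dup <- list(root = "A", nodes = list(
    list(name = "A", parent = NULL, european = TRUE, snps = list()),
    list(name = "A", parent = NULL, european = TRUE, snps = list())))
  expect_error(load_tree(dup), "duplicate node name: A")

  dangling <- list(root = "A", nodes = list(
    list(name = "A", parent = NULL, european = TRUE, snps = list()),
    list(name = "B", parent = "Z", european = TRUE, snps = list())))
  expect_error(load_tree(dangling), "dangling parent 'Z'")

  off_panel <- list(root = "A", panel = list(5L), nodes = list(
    list(name = "A", parent = NULL, european = TRUE, snps = list()),
    list(name = "B", parent = "A", european = TRUE,
         snps = list(list(position = 7L, ancestral = "A", derived = "G")))))
  expect_error(load_tree(off_panel), "outside the declared panel")
})

test_that("defining paths end at the published defining variants", {
  expect_equal(nrow(defining_path(tree, tree$root)), 0L)

  h4 <- defining_path(tree, "H4")
  expect_identical(h4$rsid[nrow(h4)], "rs41419549")
  expect_identical(h4$derived[nrow(h4)], "C")
  expect_identical(h4$node[nrow(h4)], "H4")

  hv0a <- defining_path(tree, "HV0a")
  expect_true("rs35788393" %in% hv0a$rsid)
  expect_true("rs193302980" %in% hv0a$rsid)  # HV branch is on the path
  expect_error(defining_path(tree, "Z9"), "unknown haplogroup")
})

test_that("defining paths have the prefix property over the whole tree", {
  for (nm in names(tree$nodes)) {
    parent <- tree$nodes[[nm]]$parent
    if (is.na(parent)) next
    child_path <- defining_path(tree, nm)
    parent_path <- defining_path(tree, parent)
    own <- tree$nodes[[nm]]$snps
    expect_equal(child_path$position,
                 c(parent_path$position, own$position))
  }
})

test_that("disjoint_clades matches the sibling definition and is symmetric", {
  toy <- toy_tree()
  expect_identical(disjoint_clades(toy, toy$root), character(0))
  expect_identical(disjoint_clades(toy, "A"), "B")
  expect_identical(disjoint_clades(tree, tree$root), character(0))
  expect_true("K" %in% disjoint_clades(tree, "J1"))
  expect_false("J" %in% disjoint_clades(tree, "J1"))   # ancestor
  expect_false("J1d" %in% disjoint_clades(tree, "J1")) # descendant
  # exhaustive symmetry over the shipped tree
  for (a in names(tree$nodes))
    for (b in disjoint_clades(tree, a))
      expect_true(a %in% disjoint_clades(tree, b))
  expect_error(disjoint_clades(tree, "nope"), "unknown haplogroup")
})

test_that("serialisation round-trips to an identical tree", {
  txt <- serialize_tree(tree)
  back <- load_tree(yaml::yaml.load(txt))
  expect_identical(back$panel, tree$panel)
  expect_identical(names(back$nodes), names(tree$nodes))
  expect_identical(back$super_map, tree$super_map)
  for (nm in names(tree$nodes))
    expect_identical(back$nodes[[nm]], tree$nodes[[nm]])
  js <- tree_to_json(tree)
  expect_identical(jsonlite::fromJSON(js)$root, "N")
})
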