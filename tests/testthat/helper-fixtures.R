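# Shared fixtures: tiny trees, perfect-data samples and an independent
# brute-force assignment oracle.

# a 3-node tree root -> {A, B}, one defining SNP each
toy_tree <- function() {
  load_tree(list(
    name = "toy", root = "ROOT", panel = list(100L, 200L),
    nodes = list(
      list(name = "ROOT", parent = NULL, european = TRUE, snps = list()),
      list(name = "A", parent = "ROOT", european = TRUE,
           snps = list(list(position = 100L, ancestral = "A",
                            derived = "G"))),
      list(name = "B", parent = "ROOT", european = TRUE,
           snps = list(list(position = 200L, ancestral = "C",
                            derived = "T"))))))
}

# raw calls for a sample carrying exactly the defining path of `haplogroup`
# (derived on path, ancestral elsewhere), clean intensities
perfect_calls <- function(haplogroup, tree, sample_id = "s1",
                          drop_positions = integer(0),
                          extra_derived = integer(0)) {
  info <- mthaplotau:::panel_alleles(tree)
  path <- defining_path(tree, haplogroup)
  allele <- ifelse(info$position %in% c(path$position, extra_derived),
                   info$derived, info$ancestral)
  allele[info$position %in% drop_positions] <- "N"
  data.frame(sample_id = sample_id, position = info$position,
             allele = allele, intensity = 12, baseline = 3,
             stringsAsFactors = FALSE)
}

perfect_sample <- function(haplogroup, tree, ...) {
  qc_sample(perfect_calls(haplogroup, tree, ...), tree$panel)
}

# independent assignment oracle: enumerate ALL nodes with match_node
# semantics re-implemented from the defining-path definition, take the
# argmax depth, then scan every disjoint clade's defining SNPs directly.
oracle_assign <- function(sample, tree) {
  if (!isTRUE(sample$passed_qc)) return(list(haplogroup = NA, status = "failed_qc"))
  depths <- sapply(names(tree$nodes), function(nm) {
    path <- defining_path(tree, nm)
    if (nrow(path) == 0) return(0L)
    got <- sample$calls[as.character(path$position)]
    if (all(!is.na(got) & got == path$derived)) nrow(path) else -1L
  })
  # depth here counted in tree edges, recomputed independently
  edge_depth <- sapply(names(tree$nodes), function(nm)
    length(mthaplotau:::ancestors_of(tree, nm)))
  ok <- names(depths)[depths >= 0]
  cand <- ok[which.max(edge_depth[ok])]
  if (sum(edge_depth[ok] == max(edge_depth[ok])) > 1L)
    return(list(haplogroup = NA, status = "conflict"))
  conflict <- FALSE
  for (nm in disjoint_clades(tree, cand)) {
    snps <- tree$nodes[[nm]]$snps
    for (k in seq_len(nrow(snps))) {
      got <- sample$calls[as.character(snps$position[k])]
      if (!is.na(got) && got == snps$derived[k]) conflict <- TRUE
    }
  }
  if (conflict) return(list(haplogroup = NA, status = "conflict"))
  if (cand == tree$root) return(list(haplogroup = NA, status = "unassigned"))
  list(haplogroup = cand, status = "assigned")
}
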