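# -- Haplogroup assignment -----------------------------------------------
#
# Sequential-descent rule: a sample belongs to a haplogroup when the
# derived allele is present at every defining SNP from the root down to
# that node; the assignment is the deepest such node.  A derived call at a
# defining SNP of a phylogenetically disjoint clade contradicts the
# assignment and yields a conflict.  A no-call at a path SNP blocks
# descent through that branch (a missing call is not "present"): the
# sample may still be assigned a shallower ancestor.

ASSIGN_STATUSES <- c("assigned", "unassigned", "conflict", "non_european",
                     "failed_qc")

#' Does a sample match a haplogroup's full defining path?
#'
#' `TRUE` iff every SNP on [defining_path()] of the node has an accepted
#' call equal to its required derived allele.  The root's empty path
#' matches vacuously.
#'
#' @param sample A `sample_genotypes` (from [qc_sample()]).
#' @param tree A `haplo_tree`.
#' @param node Haplogroup name.
#' @return Logical scalar.
#' @export
match_node <- function(sample, tree, node) {
  path <- defining_path(tree, node)
  if (!nrow(path)) return(TRUE)
  got <- sample$calls[as.character(path$position)]
  all(!is.na(got) & got == path$derived)
}

#' Assign one sample to a haplogroup
#'
#' Finds the deepest node whose full defining path is present in the
#' sample's accepted calls, then applies the clade-exclusion check: if any
#' accepted call carries the derived allele of a defining SNP belonging to
#' a clade disjoint from the candidate, the assignment is a `conflict`.  A
#' candidate equal to the root (no informative derived alleles) is
#' `unassigned`.  Samples that failed QC are returned as `failed_qc`
#' without a call attempt.
#'
#' @inheritParams match_node
#' @return A list of class `haplo_assignment` with fields `sample_id`,
#'   `haplogroup` (or `NA`), `status`, `matched_snps` (data frame
#'   position/allele), `off_path_derived` (positions derived in disjoint
#'   clades), `missing_on_path`.
#' @export
assign_haplogroup <- function(sample, tree) {
  if (!isTRUE(sample$passed_qc))
    return(new_assignment(sample$sample_id, NA_character_, "failed_qc"))

  matches <- names(tree$nodes)[vapply(names(tree$nodes), function(nm)
    match_node(sample, tree, nm), logical(1))]
  depths <- tree$depth[matches]
  deepest <- matches[depths == max(depths)]

  if (length(deepest) > 1L) {
    # two sibling candidates fully matched: contradictory data
    off <- unlist(lapply(deepest, function(nm)
      tree$nodes[[nm]]$snps$position))
    return(new_assignment(sample$sample_id, NA_character_, "conflict",
                          off_path_derived = sort(unique(off))))
  }
  candidate <- deepest

  off <- off_path_derived_positions(sample$calls, tree, candidate)
  if (length(off))
    return(new_assignment(sample$sample_id, NA_character_, "conflict",
                          off_path_derived = off))
  if (candidate == tree$root)
    return(new_assignment(sample$sample_id, NA_character_, "unassigned"))

  path <- defining_path(tree, candidate)
  got <- sample$calls[as.character(path$position)]
  new_assignment(sample$sample_id, candidate, "assigned",
                 matched_snps = data.frame(position = path$position,
                                           allele = unname(got),
                                           stringsAsFactors = FALSE),
                 missing_on_path = path$position[is.na(got)])
}

new_assignment <- function(sample_id, haplogroup, status,
                           matched_snps = data.frame(position = integer(0),
                                                     allele = character(0)),
                           off_path_derived = integer(0),
                           missing_on_path = integer(0)) {
  structure(list(sample_id = sample_id, haplogroup = haplogroup,
                 status = status, matched_snps = matched_snps,
                 off_path_derived = as.integer(off_path_derived),
                 missing_on_path = as.integer(missing_on_path)),
            class = "haplo_assignment")
}

# accepted calls carrying the derived allele of a defining SNP of any
# clade disjoint from `candidate`
off_path_derived_positions <- function(calls, tree, candidate) {
  disjoint <- disjoint_clades(tree, candidate)
  if (!length(disjoint)) return(integer(0))
  bad <- do.call(rbind, lapply(disjoint, function(nm) tree$nodes[[nm]]$snps))
  if (!nrow(bad)) return(integer(0))
  got <- calls[as.character(bad$position)]
  sort(unique(bad$position[!is.na(got) & got == bad$derived]))
}

#' Assign haplogroups to a whole cohort
#'
#' Vectorised cohort-level caller over a genotype matrix (samples x panel
#' positions, accepted alleles with `NA` for missing), agreeing call-for-
#' call with [assign_haplogroup()].  Samples in `qc_table` that failed QC
#' are reported as `failed_qc`.
#'
#' @param genotypes Character matrix from [qc_cohort()].
#' @param tree A `haplo_tree`.
#' @param qc_table Optional QC table from [qc_cohort()]; failed samples are
#'   appended with status `failed_qc`.
#' @return Data frame with columns `sample_id`, `haplogroup`, `status`,
#'   `matched_snps`, `off_path_derived`, `missing_on_path` (the last three
#'   semicolon-joined `position:allele` / position lists).
#' @export
call_haplogroups <- function(genotypes, tree, qc_table = NULL) {
  nms <- names(tree$nodes)
  n <- nrow(genotypes)
  pos_chr <- colnames(genotypes)
  if (n == 0L) {
    out <- data.frame(sample_id = character(0), haplogroup = character(0),
                      status = character(0), matched_snps = character(0),
                      off_path_derived = character(0),
                      missing_on_path = character(0),
                      stringsAsFactors = FALSE)
    if (!is.null(qc_table) && any(!qc_table$passed_qc))
      out <- rbind(out, data.frame(
        sample_id = qc_table$sample_id[!qc_table$passed_qc],
        haplogroup = NA_character_, status = "failed_qc",
        matched_snps = "", off_path_derived = "", missing_on_path = "",
        stringsAsFactors = FALSE))
    return(out)
  }

  match_mat <- matrix(FALSE, nrow = n, ncol = length(nms),
                      dimnames = list(rownames(genotypes), nms))
  for (nm in nms) {
    path <- defining_path(tree, nm)
    if (!nrow(path)) { match_mat[, nm] <- TRUE; next }
    cols <- match(as.character(path$position), pos_chr)
    sub <- genotypes[, cols, drop = FALSE]
    hit <- sweep(sub, 2L, path$derived, function(a, b) !is.na(a) & a == b)
    match_mat[, nm] <- rowSums(hit) == nrow(path)
  }

  depth_row <- matrix(tree$depth[nms], nrow = n, ncol = length(nms),
                      byrow = TRUE)
  depth_row[!match_mat] <- -1L
  max_depth <- apply(depth_row, 1L, max)
  n_at_max <- rowSums(depth_row == max_depth)
  cand_idx <- max.col(depth_row, ties.method = "first")
  candidate <- nms[cand_idx]

  haplogroup <- rep(NA_character_, n)
  status <- rep("unassigned", n)
  off_str <- character(n); matched_str <- character(n)

  for (cand in unique(candidate)) {
    rows <- which(candidate == cand & n_at_max == 1L)
    if (!length(rows)) next
    disjoint <- disjoint_clades(tree, cand)
    bad <- if (length(disjoint))
      do.call(rbind, lapply(disjoint, function(nm) tree$nodes[[nm]]$snps))
    else empty_snps()
    if (nrow(bad)) {
      cols <- match(as.character(bad$position), pos_chr)
      sub <- genotypes[rows, cols, drop = FALSE]
      hit <- sweep(sub, 2L, bad$derived, function(a, b) !is.na(a) & a == b)
      conf <- rowSums(hit) > 0L
      if (any(conf)) {
        cr <- rows[conf]
        status[cr] <- "conflict"
        off_str[cr] <- apply(hit[conf, , drop = FALSE], 1L, function(h)
          paste(sort(bad$position[h]), collapse = ";"))
      }
      rows <- rows[!conf]
    }
    if (!length(rows)) next
    if (cand == tree$root) { status[rows] <- "unassigned"; next }
    status[rows] <- "assigned"
    haplogroup[rows] <- cand
    path <- defining_path(tree, cand)
    matched_str[rows] <- paste(path$position, path$derived, sep = ":",
                               collapse = ";")
  }
  ties <- which(n_at_max > 1L)
  if (length(ties)) {
    status[ties] <- "conflict"
    off_str[ties] <- vapply(ties, function(i) {
      at_max <- nms[depth_row[i, ] == max_depth[i]]
      paste(sort(unique(unlist(lapply(at_max, function(nm)
        tree$nodes[[nm]]$snps$position)))), collapse = ";")
    }, character(1))
  }

  out <- data.frame(sample_id = rownames(genotypes), haplogroup = haplogroup,
                    status = status, matched_snps = matched_str,
                    off_path_derived = off_str,
                    missing_on_path = "", stringsAsFactors = FALSE)
  if (!is.null(qc_table)) {
    failed <- qc_table$sample_id[!qc_table$passed_qc]
    if (length(failed))
      out <- rbind(out, data.frame(sample_id = failed,
                                   haplogroup = NA_character_,
                                   status = "failed_qc", matched_snps = "",
                                   off_path_derived = "",
                                   missing_on_path = "",
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Map an assignment to its super-haplogroup
#'
#' Looks up the assigned haplogroup in the tree's super-haplogroup map,
#' falling back to the nearest mapped ancestor.  Non-assigned inputs and
#' unmapped haplogroups yield `NA`.
#'
#' @param assignment A `haplo_assignment`, or a haplogroup name.
#' @param tree A `haplo_tree`.
#' @return Super-haplogroup label or `NA_character_`.
#' @export
to_super_haplogroup <- function(assignment, tree) {
  hap <- if (is.character(assignment)) assignment
         else if (identical(assignment$status, "assigned")) assignment$haplogroup
         else NA_character_
  if (is.na(hap)) return(NA_character_)
  cur <- hap
  while (!is.na(cur)) {
    if (cur %in% names(tree$super_map))
      return(unname(tree$super_map[[cur]]))
    cur <- tree$nodes[[cur]]$parent
  }
  NA_character_
}

#' Partition assignments into European-kept and removed
#'
#' Keeps assignments whose node (or an ancestor) is flagged European in
#' the tree; everything else -- non-European assignments, conflicts,
#' unassigned and QC-failed samples -- is removed with a reason, and kept
#' rows gain a `super_haplogroup` column.
#'
#' @param assignments Data frame from [call_haplogroups()].
#' @param tree A `haplo_tree`.
#' @return List with `kept` and `removed` data frames; `removed` carries a
#'   `removal_reason` column.
#' @export
filter_european <- function(assignments, tree) {
  # effective flag: the node's own when stated, else inherited from the
  # nearest ancestor that states one
  is_euro <- function(hap) {
    cur <- hap
    while (!is.na(cur)) {
      flag <- tree$nodes[[cur]]$european
      if (!is.na(flag)) return(flag)
      cur <- tree$nodes[[cur]]$parent
    }
    FALSE
  }
  assigned <- assignments$status == "assigned"
  euro <- rep(FALSE, nrow(assignments))
  euro[assigned] <- vapply(assignments$haplogroup[assigned], is_euro,
                           logical(1))
  keep <- assigned & euro
  kept <- assignments[keep, , drop = FALSE]
  if (nrow(kept))
    kept$super_haplogroup <- vapply(kept$haplogroup, to_super_haplogroup,
                                    character(1), tree = tree)
  removed <- assignments[!keep, , drop = FALSE]
  removed$removal_reason <- ifelse(
    removed$status == "assigned", "non_european", removed$status)
  if (nrow(removed))
    removed$status[removed$status == "assigned"] <- "non_european"
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' @export
print.haplo_assignment <- function(x, ...) {
  cat("sample ", x$sample_id, ": ", x$status,
      if (!is.na(x$haplogroup)) paste0(" (", x$haplogroup, ")") else "",
      "\n", sep = "")
  invisible(x)
}
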