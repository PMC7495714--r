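#' @keywords internal
"_PACKAGE"

# -- Haplogroup phylogeny ------------------------------------------------
#
# A haplo_tree is a rooted tree of haplogroup nodes.  Each node carries the
# defining SNPs of the branch leading to it: rCRS position, ancestral and
# derived allele, optional rsID and gene/region label.  The panel is the
# full set of assayed loci; every defining SNP must belong to it.

MT_GENOME_LENGTH <- 16569L

#' Load and validate a haplogroup tree document
#'
#' Reads a YAML tree document describing a rooted mtDNA haplogroup
#' phylogeny: one record per node with its parent, a `european` flag and
#' the branch-defining SNPs (rCRS position, ancestral allele, derived
#' allele, optional `rsid` and `locus_label`), plus the declared typing
#' panel and an optional haplogroup-to-super-haplogroup map.  The document
#' is validated structurally before use; all violations are reported
#' together.
#'
#' @param path Path to a YAML tree document, or a list already parsed from
#'   one (useful for constructing small trees in code).
#' @return An object of class `haplo_tree`: a list with elements `nodes`
#'   (name-keyed list of node records), `root`, `panel` (integer vector of
#'   rCRS positions), `super_map` (named character vector) and `name`.
#' @examples
#' tree <- load_tree(system.file("extdata", "phylotree_european.yaml",
#'                               package = "mthaplotau"))
#' length(tree$panel)  # 39 assayed loci
#' @export
load_tree <- function(path) {
  doc <- if (is.character(path)) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("tree document parse error: ",
                                      conditionMessage(e), call. = FALSE))
  } else if (is.list(path)) {
    path
  } else {
    stop("`path` must be a file path or a parsed document list", call. = FALSE)
  }
  if (is.null(doc$nodes) || length(doc$nodes) == 0L)
    stop("tree document parse error: no nodes", call. = FALSE)

  problems <- character(0)
  nms <- vapply(doc$nodes, function(n) as.character(n$name %||% NA_character_),
                character(1))
  if (anyNA(nms)) problems <- c(problems, "node without a name")
  dup <- nms[duplicated(nms)]
  if (length(dup))
    problems <- c(problems, paste0("duplicate node name: ", unique(dup)))

  nodes <- list()
  for (n in doc$nodes) {
    snps <- normalize_snps(n$snps, n$name)
    if (is.character(snps)) { problems <- c(problems, snps); snps <- empty_snps() }
    nodes[[as.character(n$name)]] <- list(
      name = as.character(n$name),
      parent = if (is.null(n$parent) || is.na(n$parent %||% NA)) NA_character_
               else as.character(n$parent),
      european = if (is.null(n$european) || is.na(n$european)) NA
                 else isTRUE(n$european),
      snps = snps)
  }

  roots <- nms[vapply(nodes, function(n) is.na(n$parent), logical(1))]
  root <- as.character(doc$root %||% roots[1])
  if (length(roots) != 1L)
    problems <- c(problems, paste0("tree must have exactly one root, found ",
                                   length(roots)))
  if (!root %in% nms)
    problems <- c(problems, paste0("declared root '", root, "' is not a node"))

  # dangling parents and cycles
  for (nm in names(nodes)) {
    p <- nodes[[nm]]$parent
    if (!is.na(p) && !p %in% nms)
      problems <- c(problems, paste0("node '", nm, "' has dangling parent '",
                                     p, "'"))
  }
  for (nm in names(nodes)) {
    seen <- character(0); cur <- nm
    repeat {
      p <- nodes[[cur]]$parent
      if (is.null(p) || is.na(p) || !p %in% nms) break
      if (p %in% c(seen, cur)) {
        problems <- c(problems, paste0("cycle involving node '", nm, "'"))
        break
      }
      seen <- c(seen, cur); cur <- p
    }
  }

  panel <- sort(unique(as.integer(unlist(doc$panel))))
  all_snps <- do.call(rbind, lapply(nodes, function(n) n$snps))
  if (is.null(doc$panel)) panel <- sort(unique(all_snps$position))
  if (nrow(all_snps)) {
    bad <- all_snps$position[!all_snps$position %in% panel]
    if (length(bad))
      problems <- c(problems,
                    paste0("defining SNP at position ", bad,
                           " is outside the declared panel"))
    if (anyDuplicated(all_snps$position))
      problems <- c(problems, paste0(
        "panel position used by more than one branch: ",
        paste(unique(all_snps$position[duplicated(all_snps$position)]),
              collapse = ", ")))
    out_of_range <- all_snps$position < 1L | all_snps$position > MT_GENOME_LENGTH
    if (any(out_of_range))
      problems <- c(problems, paste0("position outside rCRS range: ",
                                     all_snps$position[out_of_range]))
    same <- all_snps$ancestral == all_snps$derived
    if (any(same))
      problems <- c(problems, paste0("ancestral equals derived at position ",
                                     all_snps$position[same]))
  }

  super_map <- unlist(doc$super_map %||% list())
  if (length(super_map)) {
    unknown <- names(super_map)[!names(super_map) %in% nms]
    if (length(unknown))
      problems <- c(problems, paste0("super_map entry for unknown node '",
                                     unknown, "'"))
  }

  if (length(problems))
    stop("tree validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  tree <- structure(list(name = as.character(doc$name %||% "haplo_tree"),
                         nodes = nodes, root = root, panel = panel,
                         super_map = super_map),
                    class = "haplo_tree")
  tree$depth <- node_depths(tree)
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_snps <- function() {
  data.frame(position = integer(0), ancestral = character(0),
             derived = character(0), rsid = character(0),
             locus_label = character(0), stringsAsFactors = FALSE)
}

normalize_snps <- function(snps, node_name) {
  if (is.null(snps) || length(snps) == 0L) return(empty_snps())
  rows <- lapply(snps, function(s) {
    if (is.null(s$position) || is.null(s$ancestral) || is.null(s$derived))
      return(NULL)
    data.frame(position = as.integer(s$position),
               ancestral = toupper(as.character(s$ancestral)),
               derived = toupper(as.character(s$derived)),
               rsid = as.character(s$rsid %||% NA_character_),
               locus_label = as.character(s$locus_label %||% NA_character_),
               stringsAsFactors = FALSE)
  })
  if (any(vapply(rows, is.null, logical(1))))
    return(paste0("malformed SNP record in node '", node_name, "'"))
  do.call(rbind, rows)
}

node_depths <- function(tree) {
  d <- integer(length(tree$nodes)); names(d) <- names(tree$nodes)
  for (nm in names(tree$nodes)) {
    depth <- 0L; cur <- nm
    while (!is.na(tree$nodes[[cur]]$parent)) {
      depth <- depth + 1L; cur <- tree$nodes[[cur]]$parent
    }
    d[nm] <- depth
  }
  d
}

#' The shipped European haplogroup tree
#'
#' Loads the package's default 39-locus European mtDNA phylogeny document.
#' The result is memoised for the session.
#'
#' @return A `haplo_tree`.
#' @export
default_tree <- function() {
  if (is.null(.tree_cache$tree))
    .tree_cache$tree <- load_tree(system.file("extdata",
                                              "phylotree_european.yaml",
                                              package = "mthaplotau"))
  .tree_cache$tree
}
.tree_cache <- new.env(parent = emptyenv())

stop_unknown_node <- function(tree, haplogroup) {
  if (!haplogroup %in% names(tree$nodes))
    stop("unknown haplogroup '", haplogroup, "'", call. = FALSE)
}

#' Defining SNP path from the root to a haplogroup
#'
#' Concatenates the branch-defining SNPs from the root down to the named
#' node, in root-to-leaf order.  A sample belongs to the haplogroup only if
#' it carries the derived allele at every locus on this path.
#'
#' @param tree A `haplo_tree`.
#' @param haplogroup Node name.
#' @return A data frame with columns `position`, `ancestral`, `derived`,
#'   `rsid`, `locus_label`, `node`; zero rows for the root.
#' @export
defining_path <- function(tree, haplogroup) {
  stop_unknown_node(tree, haplogroup)
  chain <- character(0); cur <- haplogroup
  repeat {
    chain <- c(cur, chain)
    p <- tree$nodes[[cur]]$parent
    if (is.na(p)) break
    cur <- p
  }
  rows <- lapply(chain, function(nm) {
    s <- tree$nodes[[nm]]$snps
    if (nrow(s)) cbind(s, node = nm, stringsAsFactors = FALSE)
    else cbind(empty_snps(), node = character(0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ancestors_of <- function(tree, haplogroup) {
  out <- character(0); cur <- tree$nodes[[haplogroup]]$parent
  while (!is.na(cur)) { out <- c(out, cur); cur <- tree$nodes[[cur]]$parent }
  out
}

descendants_of <- function(tree, haplogroup) {
  parents <- vapply(tree$nodes, function(n) n$parent, character(1))
  out <- character(0); frontier <- haplogroup
  while (length(frontier)) {
    kids <- names(parents)[!is.na(parents) & parents %in% frontier]
    out <- c(out, kids); frontier <- kids
  }
  out
}

#' Clades phylogenetically disjoint from a haplogroup
#'
#' Returns every node that is neither an ancestor nor a descendant of the
#' named haplogroup (nor the node itself).  A derived call at a defining
#' SNP of a disjoint clade contradicts an assignment to the haplogroup.
#'
#' @inheritParams defining_path
#' @return Character vector of node names (possibly empty).
#' @export
disjoint_clades <- function(tree, haplogroup) {
  stop_unknown_node(tree, haplogroup)
  related <- c(haplogroup, ancestors_of(tree, haplogroup),
               descendants_of(tree, haplogroup))
  setdiff(names(tree$nodes), related)
}

#' Serialise a tree back to a YAML document
#'
#' @param tree A `haplo_tree`.
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML text (invisibly when written to a file).
#' @export
serialize_tree <- function(tree, path = NULL) {
  doc <- list(
    name = tree$name, root = tree$root,
    panel = as.list(as.integer(tree$panel)),
    nodes = lapply(unname(tree$nodes), function(n) {
      snps <- lapply(seq_len(nrow(n$snps)), function(i) {
        s <- as.list(n$snps[i, c("position", "ancestral", "derived",
                                 "rsid", "locus_label")])
        s$position <- as.integer(s$position)
        s[!vapply(s, function(x) is.na(x), logical(1))]
      })
      list(name = n$name,
           parent = if (is.na(n$parent)) NULL else n$parent,
           european = n$european, snps = snps)
    }),
    super_map = as.list(tree$super_map))
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Export a tree as JSON
#'
#' @inheritParams serialize_tree
#' @return A JSON string (class `json`).
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(list(
    name = tree$name, root = tree$root, panel = tree$panel,
    nodes = lapply(unname(tree$nodes), function(n)
      list(name = n$name, parent = n$parent, european = n$european,
           snps = n$snps)),
    super_map = as.list(tree$super_map)), auto_unbox = TRUE, na = "null")
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("mtDNA haplogroup tree '", x$name, "': ", length(x$nodes),
      " nodes, panel of ", length(x$panel), " loci, root '", x$root,
      "'\n", sep = "")
  invisible(x)
}
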