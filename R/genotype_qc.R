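# -- Genotype quality control --------------------------------------------
#
# Raw panel calls carry a signal intensity and a baseline intensity; a call
# is accepted only when its allele is a real base and its intensity exceeds
# the baseline by more than `min_delta` (smaller excursions are treated as
# instrument noise).  Samples are accepted when their call rate over the
# full declared panel is strictly above `rate_threshold`.

NO_CALL <- "N"

#' Accept or reject a single raw genotype call
#'
#' A call is accepted iff the called allele is not the no-call marker
#' (`"N"`, empty, or `NA`) and the signal intensity exceeds the baseline
#' intensity by strictly more than `min_delta`; an excess of exactly
#' `min_delta` or less is rejected as noise.
#'
#' @param call A list or one-row data frame with fields `allele`,
#'   `intensity`, `baseline`.  Vectorised: a data frame of many calls
#'   yields a logical vector.
#' @param min_delta Minimum required intensity excess over baseline
#'   (arbitrary units; default 5).
#' @return Logical: `TRUE` for accepted calls.
#' @export
accept_call <- function(call, min_delta = 5) {
  allele <- toupper(as.character(call$allele))
  no_call <- is.na(allele) | allele == NO_CALL | allele == ""
  delta <- as.numeric(call$intensity) - as.numeric(call$baseline)
  !no_call & !is.na(delta) & delta > min_delta
}

#' Quality-control the calls of one sample
#'
#' Applies per-call acceptance ([accept_call()]) and the sample-level call
#' rate rule: the call rate is the number of accepted calls divided by the
#' full panel size (not the number of attempted calls), and the sample
#' passes iff the rate is strictly greater than `rate_threshold`.
#'
#' @param calls Data frame of raw calls for one sample, with columns
#'   `sample_id`, `position`, `allele`, `intensity`, `baseline`.
#' @param panel Integer vector of panel positions (the denominator).
#' @param rate_threshold Minimum call rate, strict (default 0.95).
#' @param min_delta Passed to [accept_call()].
#' @return An object of class `sample_genotypes`: list with `sample_id`,
#'   `calls` (named character vector, position -> accepted allele),
#'   `call_rate`, `passed_qc`.
#' @export
qc_sample <- function(calls, panel, rate_threshold = 0.95, min_delta = 5) {
  ids <- unique(as.character(calls$sample_id))
  if (length(ids) > 1L)
    stop("calls belong to more than one sample: ",
         paste(ids, collapse = ", "), call. = FALSE)
  pos <- as.integer(calls$position)
  if (length(pos) && !all(pos %in% panel))
    stop("call at position ", paste(setdiff(pos, panel), collapse = ", "),
         " outside the declared panel", call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicate call for position ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "),
         " in sample ", ids, call. = FALSE)
  ok <- if (nrow(calls)) accept_call(calls, min_delta) else logical(0)
  accepted <- stats::setNames(toupper(as.character(calls$allele[ok])),
                              as.character(pos[ok]))
  rate <- length(accepted) / length(panel)
  structure(list(sample_id = if (length(ids)) ids else NA_character_,
                 calls = accepted, call_rate = rate,
                 passed_qc = rate > rate_threshold),
            class = "sample_genotypes")
}

#' Quality-control a whole cohort of raw calls
#'
#' Vectorised equivalent of applying [qc_sample()] to every sample in a
#' long-format call table.
#'
#' @param raw Data frame with columns `sample_id`, `position`, `allele`,
#'   `intensity`, `baseline`.
#' @inheritParams qc_sample
#' @return A list with `samples` (list of `sample_genotypes`), `qc_table`
#'   (data frame sample_id, call_rate, passed_qc) and `genotypes` (samples
#'   x panel character matrix of accepted alleles, `NA` where missing;
#'   QC-passing samples only).
#' @export
qc_cohort <- function(raw, panel, rate_threshold = 0.95, min_delta = 5) {
  raw$sample_id <- as.character(raw$sample_id)
  raw$position <- as.integer(raw$position)
  if (!all(raw$position %in% panel))
    stop("calls at positions outside the declared panel", call. = FALSE)
  key <- paste(raw$sample_id, raw$position)
  if (anyDuplicated(key))
    stop("duplicate (sample, position) calls", call. = FALSE)
  ok <- accept_call(raw, min_delta)
  ids <- sort(unique(raw$sample_id))
  n_acc <- table(factor(raw$sample_id[ok], levels = ids))
  rate <- as.numeric(n_acc) / length(panel)
  passed <- rate > rate_threshold
  qc_table <- data.frame(sample_id = ids, call_rate = rate,
                         passed_qc = passed, stringsAsFactors = FALSE)

  geno <- matrix(NA_character_, nrow = sum(passed), ncol = length(panel),
                 dimnames = list(ids[passed], as.character(panel)))
  keep <- ok & raw$sample_id %in% ids[passed]
  if (any(keep))
    geno[cbind(raw$sample_id[keep], as.character(raw$position[keep]))] <-
      toupper(as.character(raw$allele[keep]))

  samples <- lapply(ids, function(id) {
    sel <- ok & raw$sample_id == id
    structure(list(sample_id = id,
                   calls = stats::setNames(
                     toupper(as.character(raw$allele[sel])),
                     as.character(raw$position[sel])),
                   call_rate = rate[match(id, ids)],
                   passed_qc = passed[match(id, ids)]),
              class = "sample_genotypes")
  })
  names(samples) <- ids
  list(samples = samples, qc_table = qc_table, genotypes = geno)
}

#' Read a long-format genotype call table
#'
#' @param path TSV with columns `sample_id`, `position`, `allele`,
#'   `intensity`, `baseline` (blank or `N` allele = no call).
#' @return Data frame of raw calls.
#' @export
read_genotype_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character"))
  need <- c("sample_id", "position", "allele", "intensity", "baseline")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("genotype table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw$allele[is.na(raw$allele) | raw$allele == ""] <- NO_CALL
  raw
}

#' Read panel genotypes from a single-sample mtDNA VCF
#'
#' Maps VCF records on the mitochondrial contig onto the panel loci.  VCFs
#' carry no assay intensities, so every mapped call is auto-accepted: it is
#' given an intensity comfortably above baseline so that downstream QC
#' treats it as a valid call.  Panel positions with no VCF record are
#' emitted as reference (ancestral-coordinate) calls of the rCRS base given
#' in the tree document when derivable, otherwise as no-calls.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param tree A `haplo_tree` supplying the panel and per-locus alleles.
#' @param sample_id Sample identifier to attach (default: VCF sample name).
#' @param assume_reference When `TRUE` (default), panel loci absent from
#'   the VCF are treated as homoplasmic reference calls (the locus allele
#'   that matches rCRS); when `FALSE` they become no-calls.
#' @return Data frame of raw calls suitable for [qc_sample()].
#' @export
read_genotype_vcf <- function(path, tree, sample_id = NULL,
                              assume_reference = TRUE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id))
    sample_id <- if (ncol(v@gt) >= 2L) colnames(v@gt)[2L] else "vcf_sample"

  panel_info <- panel_alleles(tree)
  pos <- as.integer(fix$POS)
  allele <- rep(NO_CALL, length(tree$panel))
  names(allele) <- as.character(tree$panel)
  if (assume_reference) {
    # rCRS base at each panel locus: the allele the reference genome carries
    allele[] <- panel_info$reference
  }
  hit <- pos %in% tree$panel
  for (i in which(hit)) {
    gt <- if (ncol(v@gt) >= 2L) sub(":.*", "", v@gt[i, 2L]) else "1"
    alt <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    idx <- suppressWarnings(as.integer(sub("[/|].*", "", gt)))
    if (is.na(idx)) { allele[as.character(pos[i])] <- NO_CALL; next }
    called <- if (idx == 0L) fix$REF[i] else alt[idx]
    allele[as.character(pos[i])] <- toupper(called)
  }
  data.frame(sample_id = sample_id, position = as.integer(names(allele)),
             allele = unname(allele), intensity = 100, baseline = 0,
             stringsAsFactors = FALSE)
}

# For each panel locus: ancestral and derived allele, and the rCRS
# reference base (rCRS sits inside haplogroup H, so loci on the root->H
# path carry the derived allele in the reference, all others the
# ancestral).
panel_alleles <- function(tree) {
  all_snps <- do.call(rbind, lapply(tree$nodes, function(n) n$snps))
  ord <- match(tree$panel, all_snps$position)
  anc <- all_snps$ancestral[ord]
  der <- all_snps$derived[ord]
  ref <- anc
  if ("H" %in% names(tree$nodes)) {
    h_path <- defining_path(tree, "H")
    on_h <- tree$panel %in% h_path$position
    ref[on_h] <- der[on_h]
  }
  data.frame(position = tree$panel, ancestral = anc, derived = der,
             reference = ref, stringsAsFactors = FALSE)
}

#' @export
print.sample_genotypes <- function(x, ...) {
  cat("sample ", x$sample_id, ": ", length(x$calls), " accepted calls, ",
      "call rate ", sprintf("%.3f", x$call_rate), ", QC ",
      if (x$passed_qc) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}
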