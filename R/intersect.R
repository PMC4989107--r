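# Intersection of the constraint-LRT verdicts with external SIFT-like and
# PolyPhen2-like prediction tables, the consensus definition of
# "deleterious" (nonsynonymous AND called deleterious by all three methods),
# and the per-sample summary tables built from it.

PRED_METHODS <- c("sift", "polyphen", "lrt")
NONSYN_CLASSES <- c("missense", "nonsense", "stop_loss")

#' Read an external prediction table
#'
#' Tab-separated with header columns `variant_id` (chrom:pos:ref:alt key)
#' and `verdict` ("deleterious" / "tolerated").
#'
#' @param path TSV file.
#' @param method Method label, one of "sift", "polyphen", "lrt".
#' @return data.frame `variant_id`, `method`, `verdict`.
#' @export
read_predictions <- function(path, method) {
  method <- match.arg(method, PRED_METHODS)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "verdict") %in% names(d)))
    stop("read_predictions: need columns variant_id, verdict")
  data.frame(variant_id = d$variant_id, method = method,
             verdict = d$verdict, stringsAsFactors = FALSE)
}

#' Consensus deleterious call across prediction methods
#'
#' A variant is consensus-deleterious iff its effect is nonsynonymous AND
#' all three methods (SIFT-like, PolyPhen2-like, constraint LRT) report a
#' verdict AND all three say deleterious. Variants with any missing method
#' are placed in a separate "untestable" stratum rather than being counted
#' as tolerated. The number of agreeing methods (0..3) is also reported, for
#' frequency spectra stratified by prediction agreement.
#'
#' @param predictions data.frame `variant_id`, `method`, `verdict` (long
#'   form; at most one row per variant x method).
#' @param classes Named character vector: effect class per variant id.
#' @return data.frame with one row per variant: `variant_id`, `class`,
#'   `n_methods`, `n_agree` (methods saying deleterious), `consensus`
#'   ("deleterious", "tolerated" or "untestable"), `inconsistent` (TRUE for
#'   non-nonsynonymous variants carrying deleterious verdicts).
#' @export
consensus_call <- function(predictions, classes) {
  if (anyDuplicated(predictions[, c("variant_id", "method")]))
    stop("consensus_call: duplicate (variant, method) rows")
  ids <- unique(predictions$variant_id)
  rows <- lapply(ids, function(id) {
    p <- predictions[predictions$variant_id == id, , drop = FALSE]
    p <- p[p$verdict %in% c("deleterious", "tolerated"), , drop = FALSE]
    cls <- if (id %in% names(classes)) classes[[id]] else NA_character_
    nonsyn <- !is.na(cls) && cls %in% NONSYN_CLASSES
    n_methods <- nrow(p)
    n_agree <- sum(p$verdict == "deleterious")
    inconsistent <- !nonsyn && n_agree > 0
    consensus <- if (n_methods < length(PRED_METHODS)) "untestable"
      else if (nonsyn && n_agree == length(PRED_METHODS)) "deleterious"
      else "tolerated"
    data.frame(variant_id = id, class = cls, n_methods = n_methods,
               n_agree = n_agree, consensus = consensus,
               inconsistent = inconsistent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-accession counts of derived alleles by class
#'
#' For each accession, counts polarized variants whose derived allele the
#' accession carries, stratified by effect class, plus the
#' consensus-deleterious count.
#'
#' @param vt A [variant_table()].
#' @param polarization Result of [polarize_variants()].
#' @param classes Named character vector: effect class per variant id.
#' @param consensus data.frame from [consensus_call()].
#' @return data.frame: one row per accession with columns `sample`,
#'   `noncoding`, `synonymous`, `missense`, `nonsense`, `deleterious`.
#' @export
per_sample_counts <- function(vt, polarization, classes, consensus) {
  samples <- vt$sample_ids
  del_ids <- consensus$variant_id[consensus$consensus == "deleterious"]
  cols <- c("noncoding", "synonymous", "missense", "nonsense", "deleterious")
  m <- matrix(0L, length(samples), length(cols),
              dimnames = list(samples, cols))
  pol <- polarization$polarized
  for (i in seq_len(nrow(pol))) {
    id <- pol$variant_id[i]
    cl <- if (id %in% names(classes)) classes[[id]] else NA_character_
    carriers <- polarization$carriers[[id]]
    if (is.null(carriers) || length(carriers) == 0) next
    if (!all(carriers %in% samples))
      stop("per_sample_counts: accession absent from VCF: ",
           paste(setdiff(carriers, samples), collapse = ", "))
    if (!is.na(cl)) {
      col <- if (cl == "stop_loss") "nonsense" else cl
      if (col %in% cols) m[carriers, col] <- m[carriers, col] + 1L
    }
    if (id %in% del_ids) m[carriers, "deleterious"] <-
        m[carriers, "deleterious"] + 1L
  }
  data.frame(sample = samples, m, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Proportion of nonsynonymous variants called deleterious
#'
#' Reported per method and for the three-way intersection, under both
#' denominator conventions: `shared` (all nonsynonymous variants with all
#' three verdicts present) and `per_method` (each method's own testable
#' set).
#'
#' @param predictions Long-form prediction table.
#' @param classes Named character vector: effect class per variant id.
#' @return List with `shared` and `per_method`, each a named numeric vector
#'   over sift/polyphen/lrt/consensus.
#' @export
proportion_deleterious <- function(predictions, classes) {
  cons <- consensus_call(predictions, classes)
  nonsyn <- cons[!is.na(cons$class) & cons$class %in% NONSYN_CLASSES, ,
                 drop = FALSE]
  if (nrow(nonsyn) == 0) stop("proportion_deleterious: no nonsynonymous variants")
  testable <- nonsyn[nonsyn$consensus != "untestable", , drop = FALSE]
  by_method <- function(ids) {
    vapply(PRED_METHODS, function(mth) {
      p <- predictions[predictions$method == mth &
                         predictions$variant_id %in% ids &
                         predictions$verdict %in% c("deleterious", "tolerated"), ,
                       drop = FALSE]
      if (nrow(p) == 0) return(NA_real_)
      mean(p$verdict == "deleterious")
    }, numeric(1))
  }
  shared <- c(by_method(testable$variant_id),
              consensus = if (nrow(testable) > 0)
                mean(testable$consensus == "deleterious") else NA_real_)
  per_method <- c(by_method(nonsyn$variant_id),
                  consensus = if (nrow(testable) > 0)
                    mean(testable$consensus == "deleterious") else NA_real_)
  list(shared = shared, per_method = per_method)
}

#' Deleterious fraction of a panel of known causative variants
#'
#' @param panel Character vector of variant ids (e.g. known
#'   phenotype-altering SNPs).
#' @param consensus data.frame from [consensus_call()].
#' @return List with `fraction` (of resolvable panel variants called
#'   consensus-deleterious) and `detail` (per-variant breakdown).
#' @export
causative_panel_report <- function(panel, consensus) {
  if (length(panel) == 0) stop("causative_panel_report: empty panel")
  hit <- consensus[consensus$variant_id %in% panel, , drop = FALSE]
  unresolved <- setdiff(panel, consensus$variant_id)
  if (length(unresolved) > 0)
    ds_log("causative_panel_report: %d panel variant(s) unresolved",
           length(unresolved))
  if (nrow(hit) == 0) stop("causative_panel_report: no panel variants resolvable")
  list(fraction = mean(hit$consensus == "deleterious"), detail = hit,
       unresolved = unresolved)
}
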