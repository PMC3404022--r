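#' Call states
#'
#' Integer codes for the four per-cell call states of a [genotype_matrix()].
#' Haploid Y calls are ANCESTRAL or DERIVED when observed; MISSING when no
#' reads support the site (or the site was dropped); AMBIGUOUS when reads
#' support both alleles, the haploid analogue of a heterozygous-looking call.
#'
#' @format Named integer vector of length 4.
#' @export
CALL_STATES <- c(ANCESTRAL = 0L, DERIVED = 1L, MISSING = 2L, AMBIGUOUS = 3L)

#' @rdname CALL_STATES
#' @param code integer vector of call-state codes.
#' @return `call_state_label()`: character vector of state names.
#' @export
call_state_label <- function(code) {
  names(CALL_STATES)[match(code, CALL_STATES)]
}

#' Construct a genotype matrix
#'
#' The central container of the pipeline: an integer matrix of call states
#' (see [CALL_STATES]) with samples as rows and variants as columns, plus the
#' variant table and sample metadata.
#'
#' @param calls integer matrix, samples x variants, values in `CALL_STATES`;
#'   rownames are sample ids, colnames are variant ids.
#' @param variants data.frame with one row per column of `calls`: columns
#'   `id`, `contig`, `position` (1-based), `ancestral`, `derived`, `name`
#'   (optional marker name, NA allowed), `known` (logical), `rs_id`.
#' @param samples data.frame with one row per row of `calls`: columns
#'   `sample_id`, `population` (NA allowed).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  stopifnot(is.matrix(calls), is.integer(calls))
  if (nrow(calls) != nrow(samples))
    stop("genotype_matrix: sample dimension mismatch")
  if (ncol(calls) != nrow(variants))
    stop("genotype_matrix: variant dimension mismatch")
  if (anyDuplicated(samples$sample_id))
    stop("genotype_matrix: duplicate sample ids")
  if (anyDuplicated(variants$id))
    stop("genotype_matrix: duplicate variant ids")
  if (!all(calls %in% CALL_STATES))
    stop("genotype_matrix: cell values outside the call-state codes")
  bad <- variants$ancestral == variants$derived
  if (any(bad))
    stop("genotype_matrix: ancestral == derived for ", sum(bad), " variant(s)")
  if (any(variants$position < 1))
    stop("genotype_matrix: positions must be >= 1")
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(factor(call_state_label(x$calls), levels = names(CALL_STATES)))
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Look up a variant column index by name or id
#'
#' Marker names (e.g. "DF27") take precedence over raw variant ids.
#'
#' @param gm a [genotype_matrix()].
#' @param name marker name or variant id.
#' @return integer column index.
#' @export
variant_index <- function(gm, name) {
  i <- which(!is.na(gm$variants$name) & gm$variants$name == name)
  if (length(i) == 0) i <- which(gm$variants$id == name)
  if (length(i) == 0)
    stop("variant '", name, "' not found in the genotype matrix")
  if (length(i) > 1)
    stop("variant name '", name, "' is not unique in the genotype matrix")
  i
}

#' Attach population labels from a sample metadata table
#'
#' @param gm a [genotype_matrix()].
#' @param meta data.frame with columns `sample_id`, `population` (as read by
#'   [read_sample_metadata()]).
#' @return the genotype matrix with populations filled in.
#' @export
set_sample_metadata <- function(gm, meta) {
  stopifnot(all(c("sample_id", "population") %in% names(meta)))
  idx <- match(gm$samples$sample_id, meta$sample_id)
  gm$samples$population <- meta$population[idx]
  gm
}
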