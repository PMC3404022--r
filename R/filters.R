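#' Screen samples at the anchor marker
#'
#' Splits the cohort by call state at the anchor SNP: DERIVED samples are
#' cases, ANCESTRAL samples are controls, MISSING/AMBIGUOUS samples are
#' excluded (reported, but they take no further part in filtering).
#'
#' @param gm a [genotype_matrix()].
#' @param anchor_name marker name or variant id of the anchor.
#' @return A `screen_result`: list with `anchor_id`, `anchor_index`,
#'   `cases`, `controls`, `excluded` (character vectors of sample ids).
#' @export
screen_samples <- function(gm, anchor_name) {
  i <- variant_index(gm, anchor_name)
  st <- gm$calls[, i]
  res <- structure(list(
    anchor_id = gm$variants$id[i],
    anchor_name = anchor_name,
    anchor_index = i,
    cases = rownames(gm$calls)[st == CALL_STATES[["DERIVED"]]],
    controls = rownames(gm$calls)[st == CALL_STATES[["ANCESTRAL"]]],
    excluded = rownames(gm$calls)[st %in% CALL_STATES[c("MISSING",
                                                        "AMBIGUOUS")]]),
    class = "screen_result")
  if (length(res$controls) == 0)
    warning("screen_samples: no controls at the anchor; ",
            "the control-ancestral filter (F1) is vacuous")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result at %s (%s): %d cases, %d controls, %d excluded\n",
              x$anchor_name, x$anchor_id, length(x$cases),
              length(x$controls), length(x$excluded)))
  invisible(x)
}

#' Re-orient ancestral alleles by control majority
#'
#' When ancestral states cannot be trusted from the VCF (no INFO ANC, or an
#' unreliable reference), the majority observed allele among controls
#' defines the ancestral state per site. Sites where the majority is the
#' derived allele are flipped (states, alleles and read depths); ties are
#' flagged unusable. Sites with no observed control calls are left as read.
#'
#' @param gm a [genotype_matrix()].
#' @param screen a `screen_result`.
#' @return list with `gm` (re-oriented matrix) and `unusable` (variant ids
#'   with a control-majority tie).
#' @export
orient_by_controls <- function(gm, screen) {
  ctrl <- gm$calls[screen$controls, , drop = FALSE]
  n_anc <- colSums(ctrl == CALL_STATES[["ANCESTRAL"]])
  n_der <- colSums(ctrl == CALL_STATES[["DERIVED"]])
  tie <- n_anc == n_der & n_anc > 0
  flip <- n_der > n_anc
  if (any(flip)) {
    cols <- which(flip)
    a <- gm$calls[, cols, drop = FALSE]
    a[a == CALL_STATES[["ANCESTRAL"]]] <- 99L
    a[a == CALL_STATES[["DERIVED"]]] <- CALL_STATES[["ANCESTRAL"]]
    a[a == 99L] <- CALL_STATES[["DERIVED"]]
    gm$calls[, cols] <- a
    tmp <- gm$variants$ancestral[cols]
    gm$variants$ancestral[cols] <- gm$variants$derived[cols]
    gm$variants$derived[cols] <- tmp
    ad <- attr(gm, "ad")
    if (!is.null(ad)) {
      tmpm <- ad$anc[, cols, drop = FALSE]
      ad$anc[, cols] <- ad$der[, cols, drop = FALSE]
      ad$der[, cols] <- tmpm
      attr(gm, "ad") <- ad
    }
  }
  list(gm = gm, unusable = gm$variants$id[tie])
}

# observed-call helper matrices over a sample subset
.obs_matrices <- function(gm, sample_ids) {
  S <- gm$calls[sample_ids, , drop = FALSE]
  list(der = S == CALL_STATES[["DERIVED"]],
       anc = S == CALL_STATES[["ANCESTRAL"]],
       amb = S == CALL_STATES[["AMBIGUOUS"]])
}

#' Filter F1: all observed controls ancestral
#'
#' A variant fails when at least one control has an observed DERIVED call.
#' MISSING/AMBIGUOUS controls are uninformative; a variant with zero
#' observed control calls passes vacuously but is annotated.
#'
#' @param gm a [genotype_matrix()].
#' @param screen a `screen_result`.
#' @return Named logical vector (TRUE = pass), with attributes
#'   `n_observed_controls`, `n_derived_controls` and `no_informative_controls`.
#' @export
filter_control_ancestral <- function(gm, screen) {
  m <- .obs_matrices(gm, screen$controls)
  n_der <- colSums(m$der)
  n_obs <- colSums(m$der | m$anc)
  pass <- n_der == 0
  names(pass) <- gm$variants$id
  attr(pass, "n_observed_controls") <- n_obs
  attr(pass, "n_derived_controls") <- n_der
  attr(pass, "no_informative_controls") <- n_obs == 0
  pass
}

#' Filter F2: at least two derived cases
#'
#' A variant fails when at most one case sample has an observed DERIVED
#' call (singletons carry no clade information and are not catalogued).
#' AMBIGUOUS calls never count toward the threshold.
#'
#' @inheritParams filter_control_ancestral
#' @return Named logical vector (TRUE = pass) with attribute
#'   `n_derived_cases`.
#' @export
filter_non_singleton <- function(gm, screen) {
  m <- .obs_matrices(gm, screen$cases)
  n_der <- colSums(m$der)
  pass <- n_der >= 2
  names(pass) <- gm$variants$id
  attr(pass, "n_derived_cases") <- n_der
  pass
}

#' Filter F3: no heterozygous-looking calls
#'
#' A variant fails when the number of AMBIGUOUS calls among cases plus
#' controls exceeds `max_ambiguous` (default 0, the strict rule: any
#' heterozygous-looking call disqualifies the site on a haploid chromosome).
#'
#' @inheritParams filter_control_ancestral
#' @param max_ambiguous maximum tolerated AMBIGUOUS calls.
#' @return Named logical vector (TRUE = pass) with attribute `n_ambiguous`.
#' @export
filter_ambiguous <- function(gm, screen, max_ambiguous = 0L) {
  used <- c(screen$cases, screen$controls)
  n_amb <- colSums(gm$calls[used, , drop = FALSE] ==
                     CALL_STATES[["AMBIGUOUS"]])
  pass <- n_amb <= max_ambiguous
  names(pass) <- gm$variants$id
  attr(pass, "n_ambiguous") <- n_amb
  pass
}

#' Rooted pairwise compatibility of two variants
#'
#' With ancestral state known, two variants can lie on one tree iff their
#' derived-carrier sets, restricted to jointly observed samples, are nested
#' or disjoint. Equivalently the pair is *in*compatible iff all three
#' carrier patterns (1,0), (0,1) and (1,1) occur among jointly observed
#' samples (the rooted three-gamete condition).
#'
#' @param v1_derived_cases,v2_derived_cases character vectors of case
#'   samples with observed derived calls.
#' @param jointly_observed case samples with observed (ANCESTRAL or
#'   DERIVED) calls at both variants.
#' @return TRUE when compatible.
#' @export
compatible <- function(v1_derived_cases, v2_derived_cases, jointly_observed) {
  d1 <- intersect(v1_derived_cases, jointly_observed)
  d2 <- intersect(v2_derived_cases, jointly_observed)
  p11 <- length(intersect(d1, d2)) > 0
  p10 <- length(setdiff(d1, d2)) > 0
  p01 <- length(setdiff(d2, d1)) > 0
  !(p11 && p10 && p01)
}

# pattern-level incompatibility over case samples; returns for a set of
# variant columns: pattern index per variant and the u x u incompatibility
# matrix
.pattern_conflicts <- function(gm, cases, ids) {
  S <- gm$calls[cases, ids, drop = FALSE]
  D <- S == CALL_STATES[["DERIVED"]]
  A <- S == CALL_STATES[["ANCESTRAL"]]
  key <- apply(D + 2L * A, 2, paste, collapse = "")
  pat <- match(key, unique(key))
  first <- match(seq_along(unique(key)), pat)
  Du <- D[, first, drop = FALSE] * 1
  Au <- A[, first, drop = FALSE] * 1
  n11 <- crossprod(Du, Du)
  n10 <- crossprod(Du, Au)
  incomp <- (n11 > 0) & (n10 > 0) & (t(n10) > 0)
  diag(incomp) <- FALSE
  list(pat = pat, incomp = incomp)
}

#' Filter F4: phylogenetic consistency
#'
#' Builds the pairwise incompatibility graph over the surviving variants
#' (rooted three-gamete test on case samples) and greedily removes the
#' variant with the highest conflict degree until the graph is
#' conflict-free. Ties are broken by fewer observed derived cases, then by
#' higher genomic position, so the outcome is independent of input order.
#' Incompatible sites are the signature of duplicated or recombining
#' regions, where a pseudo-variant recurs on unrelated branches.
#'
#' @inheritParams filter_control_ancestral
#' @param survivors variant ids that passed F1-F3.
#' @return list with `pass` (named logical over `survivors`), `edges`
#'   (data.frame `v1`, `v2`: the initial incompatibility graph) and
#'   `partners` (named list: removed variant -> conflicting variant ids at
#'   removal time).
#' @export
filter_consistent <- function(gm, screen, survivors) {
  survivors <- survivors[order(gm$variants$position[
    match(survivors, gm$variants$id)])]
  pass <- stats::setNames(rep(TRUE, length(survivors)), survivors)
  empty <- list(pass = pass,
                edges = data.frame(v1 = character(0), v2 = character(0),
                                   stringsAsFactors = FALSE),
                partners = list())
  if (length(survivors) < 2) return(empty)

  pc <- .pattern_conflicts(gm, screen$cases, survivors)
  pat <- pc$pat
  incomp <- pc$incomp
  if (!any(incomp)) return(empty)

  # variant-level edge list of the initial graph
  ii <- which(incomp & upper.tri(incomp), arr.ind = TRUE)
  edges <- do.call(rbind, lapply(seq_len(nrow(ii)), function(r) {
    va <- survivors[pat == ii[r, 1]]
    vb <- survivors[pat == ii[r, 2]]
    expand.grid(v1 = va, v2 = vb, stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$v1, edges$v2), , drop = FALSE]
  rownames(edges) <- NULL

  n_der <- colSums(gm$calls[screen$cases, survivors, drop = FALSE] ==
                     CALL_STATES[["DERIVED"]])
  posn <- gm$variants$position[match(survivors, gm$variants$id)]
  alive <- rep(TRUE, length(survivors))
  partners <- list()
  repeat {
    n_alive_pat <- tabulate(pat[alive], nbins = nrow(incomp))
    deg <- as.vector(incomp %*% n_alive_pat)[pat]
    deg[!alive] <- -1
    if (max(deg) <= 0) break
    pick <- order(-deg, n_der, -posn)[1]
    conflict_pats <- which(incomp[pat[pick], ])
    partners[[survivors[pick]]] <-
      survivors[alive & pat %in% conflict_pats]
    alive[pick] <- FALSE
  }
  pass[] <- alive
  list(pass = pass, edges = edges, partners = partners)
}

#' Annotate novelty against a known-variant list
#'
#' A variant is known iff its (contig, position, derived allele) key is in
#' the list; its name is taken from the list when known.
#'
#' @param variants variant table of a [genotype_matrix()].
#' @param known_list a [read_known_list()] table (or NULL: all novel).
#' @return the variant table with `known` and `name` filled in.
#' @export
annotate_novelty <- function(variants, known_list) {
  variants$known <- FALSE
  if (!is.null(known_list) && nrow(known_list) > 0) {
    key <- paste(variants$contig, variants$position, variants$derived,
                 sep = ":")
    lkey <- paste(known_list$contig, known_list$position, known_list$derived,
                  sep = ":")
    m <- match(key, lkey)
    hit <- !is.na(m)
    variants$known[hit] <- TRUE
    variants$name[hit] <- known_list$name[m[hit]]
  }
  variants
}

#' Run the full filter cascade
#'
#' Applies the stages in fixed order with first-fail attribution:
#' orientation (optional control-majority, tie = UNUSABLE), F1
#' control-ancestral, F2 non-singleton, F3 no-ambiguous, F4 phylogenetic
#' consistency. The anchor variant itself runs through the cascade like any
#' other site (it is derived in every case and ancestral in every control
#' by construction of the screen, so it is retained and later labels the
#' root).
#'
#' @param gm a [genotype_matrix()].
#' @param screen a `screen_result` from [screen_samples()].
#' @param max_ambiguous F3 threshold (default 0).
#' @param known_list optional [read_known_list()] table for novelty
#'   annotation.
#' @param orientation `"as-read"` (trust the matrix orientation) or
#'   `"control-majority"` (re-derive ancestral states from controls, see
#'   [orient_by_controls()]).
#' @return A `filter_report`: list with `table` (one row per variant:
#'   outcome, counts, conflict partners, annotation), `edges` (the F4
#'   incompatibility graph), `retained` (ids), and `gm` (the possibly
#'   re-oriented, novelty-annotated matrix).
#' @export
run_filters <- function(gm, screen, max_ambiguous = 0L, known_list = NULL,
                        orientation = c("as-read", "control-majority")) {
  orientation <- match.arg(orientation)
  unusable <- character(0)
  if (orientation == "control-majority") {
    o <- orient_by_controls(gm, screen)
    gm <- o$gm
    unusable <- o$unusable
  }
  gm$variants <- annotate_novelty(gm$variants, known_list)

  f1 <- filter_control_ancestral(gm, screen)
  f2 <- filter_non_singleton(gm, screen)
  f3 <- filter_ambiguous(gm, screen, max_ambiguous)

  ids <- gm$variants$id
  outcome <- rep("RETAINED", length(ids))
  outcome[!f3] <- "FAIL_AMBIGUOUS"
  outcome[!f2] <- "FAIL_SINGLETON"
  outcome[!f1] <- "FAIL_CONTROL_DERIVED"
  outcome[ids %in% unusable] <- "UNUSABLE"

  survivors <- ids[outcome == "RETAINED"]
  f4 <- filter_consistent(gm, screen, survivors)
  removed <- names(f4$pass)[!f4$pass]
  outcome[ids %in% removed] <- "FAIL_INCONSISTENT"

  annotation <- rep("", length(ids))
  annotation[attr(f1, "no_informative_controls")] <- "no informative controls"
  obs_case <- matrix(gm$calls[screen$cases, , drop = FALSE] %in%
                       CALL_STATES[c("ANCESTRAL", "DERIVED")],
                     nrow = length(screen$cases))
  n_obs_cases <- colSums(obs_case)
  all_derived <- attr(f2, "n_derived_cases") +
    attr(f1, "n_derived_controls") ==
    n_obs_cases + attr(f1, "n_observed_controls") &
    n_obs_cases + attr(f1, "n_observed_controls") > 0
  annotation[all_derived & annotation == ""] <-
    "all observed samples derived (possible reference artefact)"

  partners_str <- vapply(ids, function(v) {
    p <- f4$partners[[v]]
    if (is.null(p)) "" else paste(p, collapse = ",")
  }, character(1))

  tab <- data.frame(
    id = ids,
    outcome = outcome,
    n_derived_cases = unname(attr(f2, "n_derived_cases")),
    n_observed_controls = unname(attr(f1, "n_observed_controls")),
    n_derived_controls = unname(attr(f1, "n_derived_controls")),
    n_ambiguous = unname(attr(f3, "n_ambiguous")),
    conflict_partners = unname(partners_str),
    block = "",
    annotation = annotation,
    stringsAsFactors = FALSE)
  structure(list(table = tab, edges = f4$edges,
                 retained = ids[outcome == "RETAINED"], gm = gm),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  tab <- table(x$table$outcome)
  cat("filter_report:", nrow(x$table), "variants\n")
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}
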