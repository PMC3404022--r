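#' Per-clade summary table
#'
#' One row per tree node: block label, directly attached samples, subtree
#' totals, per-population subtree counts and percentages (one decimal,
#' round half away from zero, the convention used when reporting clade
#' composition), and the number of novel vs known member variants.
#'
#' @param tree a `clade_tree`.
#' @param placements output of [place_samples()].
#' @param sample_meta data.frame `sample_id`, `population`.
#' @param variants novelty-annotated variant table (the `gm$variants` of the
#'   filter report), or NULL to skip novelty counts.
#' @return A `clade_summary` data.frame; percentage columns are numeric with
#'   NA for empty subtrees (rendered as an em dash on write).
#' @export
summarize_clades <- function(tree, placements, sample_meta, variants = NULL) {
  if (!all(placements$sample_id %in% tree$case_samples))
    stop("summarize_clades: placements contain unknown sample(s): ",
         paste(setdiff(placements$sample_id, tree$case_samples),
               collapse = ", "))
  pops <- sort(unique(sample_meta$population[
    sample_meta$sample_id %in% tree$case_samples]))
  pop_of <- stats::setNames(sample_meta$population, sample_meta$sample_id)
  rows <- lapply(tree$nodes$id, function(n) {
    sub <- .subtree_samples(tree, n)
    att <- tree$samples_at[[n]]
    bl <- tree$node_blocks[[n]]
    vids <- unlist(lapply(bl, `[[`, "variants"))
    n_known <- n_novel <- 0L
    if (!is.null(variants) && length(vids) > 0) {
      kn <- variants$known[match(vids, variants$id)]
      n_known <- sum(kn %in% TRUE)
      n_novel <- sum(kn %in% FALSE)
    }
    row <- data.frame(node_id = n,
                      label = tree$nodes$label[tree$nodes$id == n],
                      n_attached = length(att), n_subtree = length(sub),
                      n_novel = n_novel, n_known = n_known,
                      stringsAsFactors = FALSE)
    for (p in pops) {
      cnt <- sum(pop_of[sub] %in% p)
      row[[paste0("n_", p)]] <- cnt
      row[[paste0("pct_", p)]] <- if (length(sub) == 0) NA_real_ else
        round_half_away(100 * cnt / length(sub), 1)
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clade_summary", "data.frame")
  out
}

#' Write a clade summary as TSV
#'
#' Undefined percentages (empty subtrees) are rendered as an em dash.
#'
#' @param summary a `clade_summary`.
#' @param path output TSV.
#' @return (invisibly) `path`.
#' @export
write_clade_summary <- function(summary, path) {
  out <- as.data.frame(summary)
  for (col in grep("^pct_", names(out), value = TRUE)) {
    v <- sprintf("%.1f", out[[col]])
    v[is.na(out[[col]])] <- "—"
    out[[col]] <- v
  }
  write_tsv(out, path)
}
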