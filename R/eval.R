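#' Score a pipeline run against simulated ground truth
#'
#' Computes the recovery metrics the synthetic generator exists to measure:
#' exact retention of branch variants, correct rejection classes, rooted
#' Robinson-Foulds distance to the true tree, tip-placement accuracy, the
#' fraction of retained branch variants assigned to their true branch (the
#' observed block derived set must equal the branch's true case carriers),
#' and control contamination (erroneous derived control calls, and the
#' branch variants they knock out at F1).
#'
#' @param filter_report a `filter_report` from [run_filters()].
#' @param tree the `clade_tree` built from its retained variants.
#' @param truth the `sim_truth`.
#' @param gm the simulated [genotype_matrix()].
#' @param screen the `screen_result`.
#' @return list of metrics (see details above).
#' @export
evaluate_against_truth <- function(filter_report, tree, truth, gm, screen) {
  tab <- filter_report$table
  branch_ids <- unlist(truth$branch_variants, use.names = FALSE)
  singleton_ids <- names(truth$singleton_variants)
  artefact_ids <- names(truth$artefact_variants)

  retained <- setdiff(filter_report$retained, truth$anchor_id)
  fail_singleton <- tab$id[tab$outcome == "FAIL_SINGLETON"]
  fail_inconsistent <- tab$id[tab$outcome == "FAIL_INCONSISTENT"]

  # block assignment: retained branch variants whose observed block equals
  # the true carrier set of their branch
  blk_of <- new.env(parent = emptyenv())
  for (n in tree$nodes$id) {
    for (b in tree$node_blocks[[n]]) {
      for (v in b$variants) assign(v, b, envir = blk_of)
    }
  }
  correct <- vapply(intersect(branch_ids, retained), function(v) {
    b <- get0(v, envir = blk_of)
    if (is.null(b)) return(FALSE)
    setequal(b$derived_cases, intersect(truth_carriers(truth, v),
                                        screen$cases))
  }, logical(1))

  # tip placement: sample's terminal subtree set equals its true node's
  # subtree set (root compared as root)
  true_key <- vapply(truth$case_samples, function(s) {
    node <- truth$sample_tip[[s]]
    if (node == 0L) return("ROOT")
    nodes <- subtree_nodes(truth$tree, node)
    paste(sort(names(truth$sample_tip)[truth$sample_tip %in% nodes]),
          collapse = ",")
  }, character(1))
  placed_cases <- intersect(truth$case_samples, names(tree$sample_node))
  recon_key <- vapply(placed_cases, function(s) {
    n <- tree$sample_node[[s]]
    if (n == 1L) return("ROOT")
    paste(.subtree_samples(tree, n), collapse = ",")
  }, character(1))
  placement_ok <- recon_key == true_key[placed_cases]

  # control contamination measured from the matrix
  ctrl_der <- gm$calls[intersect(truth$control_samples,
                                 rownames(gm$calls)), , drop = FALSE] ==
    CALL_STATES[["DERIVED"]]
  contaminated_calls <- sum(ctrl_der)
  branch_lost_f1 <- sum(tab$outcome[match(branch_ids, tab$id)] ==
                          "FAIL_CONTROL_DERIVED", na.rm = TRUE)

  list(
    retained_equals_branch = setequal(retained, branch_ids),
    n_retained = length(retained),
    n_branch_true = length(branch_ids),
    singleton_match = setequal(fail_singleton, singleton_ids),
    artefact_match = setequal(fail_inconsistent, artefact_ids),
    rf = rf_distance(tree, truth),
    placement_accuracy = mean(placement_ok),
    n_cases_placed = length(placed_cases),
    branch_assignment_fraction =
      if (length(correct) == 0) NA_real_ else mean(correct),
    control_contaminated_calls = contaminated_calls,
    branch_variants_lost_to_f1 = branch_lost_f1)
}
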