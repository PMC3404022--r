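#' Collapse retained variants into equivalent-marker blocks
#'
#' Two variants are phylogenetically equivalent when their observed derived
#' case-sample sets are identical: they mark the same branch and are
#' indistinguishable. Each block is labelled with its member marker names
#' (falling back to variant ids) in alphanumeric order, the convention used
#' when equivalent markers are listed on a branch. Block pairs whose derived
#' sets differ only through missing data are flagged
#' "possibly equivalent (missing data)".
#'
#' @param gm a [genotype_matrix()].
#' @param retained_variants variant ids that survived the filter cascade.
#' @param screen a `screen_result` (defines the case cohort).
#' @return A `marker_blocks` list; each element has `variants`, `names`,
#'   `derived_cases`, `anc_observed` (cases with an observed ancestral call
#'   at >= 1 member and no derived call) and `label`. Attribute
#'   `possibly_equivalent` holds the flagged block-label pairs.
#' @export
equivalence_blocks <- function(gm, retained_variants, screen) {
  cases <- screen$cases
  if (length(retained_variants) == 0)
    return(structure(list(), class = "marker_blocks"))
  S <- gm$calls[cases, retained_variants, drop = FALSE]
  D <- S == CALL_STATES[["DERIVED"]]
  key <- apply(D, 2, paste, collapse = "")
  disp <- ifelse(is.na(gm$variants$name), gm$variants$id,
                 gm$variants$name)[match(retained_variants, gm$variants$id)]
  blocks <- lapply(unique(key), function(k) {
    members <- retained_variants[key == k]
    dc <- cases[D[, match(members[1], retained_variants)]]
    if (length(dc) == 0)
      stop("equivalence_blocks: block with empty derived case set (",
           paste(members, collapse = ","), ")")
    A <- S[, key == k, drop = FALSE] == CALL_STATES[["ANCESTRAL"]]
    anc_obs <- setdiff(cases[rowSums(A) > 0], dc)
    nm <- natural_sort(disp[key == k])
    list(variants = members, names = nm, derived_cases = dc,
         anc_observed = anc_obs, label = paste(nm, collapse = ", "))
  })
  # flag near-equivalence: D_i strictly inside D_j, the difference never
  # observed ancestral at i's members
  flags <- list()
  if (length(blocks) > 1) {
    for (i in seq_along(blocks)) {
      for (j in seq_along(blocks)) {
        if (i == j) next
        di <- blocks[[i]]$derived_cases
        dj <- blocks[[j]]$derived_cases
        if (length(di) < length(dj) && all(di %in% dj) &&
            !any(setdiff(dj, di) %in% blocks[[i]]$anc_observed)) {
          flags[[length(flags) + 1L]] <-
            c(blocks[[i]]$label, blocks[[j]]$label)
        }
      }
    }
  }
  structure(blocks, class = "marker_blocks", possibly_equivalent = flags)
}

# all three rooted gamete patterns present between two blocks?
.blocks_conflict <- function(b1, b2) {
  p11 <- length(intersect(b1$derived_cases, b2$derived_cases)) > 0
  p10 <- length(intersect(b1$derived_cases, b2$anc_observed)) > 0
  p01 <- length(intersect(b2$derived_cases, b1$anc_observed)) > 0
  p11 && p10 && p01
}

#' Build the rooted clade tree from marker blocks
#'
#' Blocks are inserted in decreasing derived-set size (ties by label) under
#' the deepest node whose derived set contains them; with complete data this
#' is exact laminar-family insertion, and with missing data a block descends
#' under a candidate only when no jointly observed call contradicts the
#' nesting. Blocks whose derived set equals the full case cohort label the
#' root (the anchor clade). Each case sample then attaches to its most
#' derived containing node. The resulting node family is checked for
#' generalized laminarity (pairwise rooted compatibility) as a hard
#' postcondition; a violation means the consistency filter's contract was
#' broken upstream.
#'
#' @param blocks a `marker_blocks` list from [equivalence_blocks()] (plain
#'   lists with `derived_cases` and `label` also work; `anc_observed`
#'   defaults to the strict complement of the derived set).
#' @param case_samples character vector: the full case cohort.
#' @param gm optional [genotype_matrix()]; used to weigh conflicting
#'   placement evidence when attaching samples under noise.
#' @return A `clade_tree`: list with `nodes` (data.frame `id`, `parent`,
#'   `label`), `node_blocks` (list of blocks per node; root may hold the
#'   anchor block), `samples_at` (attached samples per node),
#'   `sample_node` (named integer: sample -> node id) and `case_samples`.
#' @export
build_tree <- function(blocks, case_samples, gm = NULL) {
  blocks <- lapply(blocks, function(b) {
    if (is.null(b$anc_observed))
      b$anc_observed <- setdiff(case_samples, b$derived_cases)
    if (is.null(b$names)) b$names <- b$label
    b
  })
  sizes <- vapply(blocks, function(b) length(b$derived_cases), integer(1))
  labels <- vapply(blocks, function(b) b$label, character(1))
  ord <- order(-sizes, natural_order(labels))
  blocks <- blocks[ord]

  root_block <- list(variants = character(0), names = character(0),
                     derived_cases = case_samples, anc_observed = character(0),
                     label = "root")
  nodes <- data.frame(id = 1L, parent = NA_integer_, label = "root",
                      stringsAsFactors = FALSE)
  node_blocks <- list(list())   # node 1 = root; may absorb full-set blocks

  node_set <- function(n) {
    bl <- node_blocks[[n]]
    if (n == 1L || length(bl) == 0) {
      if (n == 1L) return(root_block)
      stop("build_tree: non-root node without a block")
    }
    bl[[1]]
  }

  for (b in blocks) {
    if (setequal(b$derived_cases, case_samples)) {
      # anchor-equivalent markers label the root
      node_blocks[[1]] <- c(node_blocks[[1]], list(b))
      root_names <- natural_sort(unlist(lapply(node_blocks[[1]],
                                               `[[`, "names")))
      nodes$label[1] <- paste(root_names, collapse = ", ")
      next
    }
    cur <- 1L
    repeat {
      kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == cur]
      cand <- kids[vapply(kids, function(k) {
        ks <- node_set(k)
        length(intersect(b$derived_cases, ks$derived_cases)) > 0 &&
          !any(b$derived_cases %in% ks$anc_observed)
      }, logical(1))]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        ov <- vapply(cand, function(k)
          length(intersect(b$derived_cases,
                           node_set(k)$derived_cases)), integer(1))
        cand <- cand[order(-ov, natural_order(nodes$label[cand]))][1]
      }
      cur <- cand[1]
    }
    nid <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = nid, parent = cur, label = b$label,
                                     stringsAsFactors = FALSE))
    node_blocks[[nid]] <- list(b)
  }

  # attach each sample to its most derived containing node: the deepest
  # node whose block has the sample observed derived. A sample missing at a
  # parent block but derived below it still descends (passage is implied by
  # laminarity and reported as a diagnostic by place_samples).
  is_ancestor <- function(a, b) {   # is a a strict ancestor of b?
    p <- nodes$parent[nodes$id == b]
    while (!is.na(p)) {
      if (p == a) return(TRUE)
      p <- nodes$parent[nodes$id == p]
    }
    FALSE
  }
  sample_node <- stats::setNames(rep(1L, length(case_samples)), case_samples)
  placement_conflicts <- list()
  member_evidence <- function(s, b) {
    if (is.null(gm)) return(length(b$variants))
    sum(gm$calls[s, b$variants] == CALL_STATES[["DERIVED"]])
  }
  nonroot <- nodes$id[nodes$id != 1L]
  for (s in case_samples) {
    cand <- nonroot[vapply(nonroot, function(n)
      s %in% node_set(n)$derived_cases, logical(1))]
    if (length(cand) > 1) {
      # keep only the deepest of each containment chain
      keep <- vapply(cand, function(a)
        !any(vapply(cand, function(b) a != b && is_ancestor(a, b),
                    logical(1))), logical(1))
      cand <- cand[keep]
    }
    if (length(cand) > 1) {
      placement_conflicts[[s]] <- nodes$label[match(cand, nodes$id)]
      ev <- vapply(cand, function(k) member_evidence(s, node_set(k)),
                   numeric(1))
      cand <- cand[order(-ev, natural_order(nodes$label[match(cand,
                                                              nodes$id)]))]
    }
    sample_node[s] <- if (length(cand) == 0) 1L else cand[1]
  }
  samples_at <- lapply(nodes$id, function(n)
    sort(names(sample_node)[sample_node == n]))

  tree <- structure(list(nodes = nodes, node_blocks = node_blocks,
                         samples_at = samples_at, sample_node = sample_node,
                         case_samples = case_samples,
                         placement_conflicts = placement_conflicts),
                    class = "clade_tree")
  assert_tree_consistent(tree)
  tree
}

#' Generalized laminarity assertion
#'
#' Hard postcondition of [build_tree()]: every pair of non-root nodes must
#' be rooted-compatible on observed calls (no pair shows all three gamete
#' patterns). With complete data this is exactly strict laminarity of the
#' derived-set family.
#'
#' @param tree a `clade_tree`.
#' @return TRUE invisibly; stops with an internal-consistency error
#'   otherwise.
#' @export
assert_tree_consistent <- function(tree) {
  ids <- tree$nodes$id[tree$nodes$id != 1L]
  if (length(ids) < 2) return(invisible(TRUE))
  get_block <- function(n) tree$node_blocks[[n]][[1]]
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      if (.blocks_conflict(get_block(ids[i]), get_block(ids[j])))
        stop("internal-consistency error: blocks '",
             tree$nodes$label[ids[i]], "' and '", tree$nodes$label[ids[j]],
             "' are incompatible (F4 contract violated)")
    }
  }
  invisible(TRUE)
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("clade_tree: %d nodes (incl. root), %d case samples\n",
              nrow(x$nodes), length(x$case_samples)))
  invisible(x)
}

# case samples in the subtree of each node (attached there or below)
.subtree_samples <- function(tree, node) {
  kids <- tree$nodes$id[!is.na(tree$nodes$parent) &
                          tree$nodes$parent == node]
  out <- tree$samples_at[[node]]
  for (k in kids) out <- c(out, .subtree_samples(tree, k))
  sort(out)
}

#' Clade sample-set family of a tree
#'
#' The set of subtree case-sample sets over non-root nodes, each encoded as
#' a sorted comma-joined key. Two rooted trees on the same cohort are
#' topologically identical iff their families are equal; the symmetric
#' difference is the rooted Robinson-Foulds distance ([rf_distance()]).
#'
#' @param x a `clade_tree` or `sim_truth`.
#' @return character vector of clade keys.
#' @export
clade_family <- function(x) {
  if (inherits(x, "clade_tree")) {
    ids <- x$nodes$id[x$nodes$id != 1L]
    keys <- vapply(ids, function(n)
      paste(.subtree_samples(x, n), collapse = ","), character(1))
  } else if (inherits(x, "sim_truth")) {
    tip <- x$sample_tip
    keys <- vapply(seq_len(x$tree$n_clades), function(b) {
      nodes <- subtree_nodes(x$tree, b)
      paste(sort(names(tip)[tip %in% nodes]), collapse = ",")
    }, character(1))
  } else stop("clade_family: unsupported object")
  unique(keys[keys != ""])
}

#' Rooted Robinson-Foulds distance
#'
#' Symmetric difference of the two clade families (see [clade_family()]).
#'
#' @param a,b `clade_tree`/`sim_truth` objects or clade-key vectors.
#' @return non-negative integer; 0 iff identical rooted topologies.
#' @export
rf_distance <- function(a, b) {
  fa <- if (is.character(a)) a else clade_family(a)
  fb <- if (is.character(b)) b else clade_family(b)
  length(setdiff(fa, fb)) + length(setdiff(fb, fa))
}

#' Reconcile the data-derived tree against a scaffold of named markers
#'
#' For each scaffold marker found in the tree: CONFIRMED when its tree
#' parent's block (or its own block) contains its scaffold parent or an
#' ancestor of it; otherwise REPOSITIONED, keeping the data-derived
#' placement (data wins) and reporting both. Scaffold markers absent from
#' the data are UNPLACED.
#'
#' @param tree a `clade_tree`.
#' @param scaffold a [read_scaffold()] table.
#' @return A `reconciliation_report` data.frame: `marker`, `status`,
#'   `old_parent`, `new_parent`, `node_id`.
#' @export
reconcile_scaffold <- function(tree, scaffold) {
  if (!inherits(scaffold, "scaffold_tree"))
    stop("reconcile_scaffold: scaffold is not a scaffold_tree ",
         "(read it with read_scaffold)")
  root_marker <- scaffold$marker_name[scaffold$parent_name == ""]
  node_names <- lapply(tree$nodes$id, function(n) {
    bl <- tree$node_blocks[[n]]
    if (length(bl) == 0) character(0) else unlist(lapply(bl, `[[`, "names"))
  })
  find_node <- function(marker) {
    hit <- which(vapply(node_names, function(nm) marker %in% nm, logical(1)))
    if (length(hit) == 0) NA_integer_ else tree$nodes$id[hit[1]]
  }
  scaffold_ancestors <- function(m) {
    out <- character(0)
    cur <- scaffold$parent_name[scaffold$marker_name == m]
    while (length(cur) == 1 && cur != "") {
      out <- c(out, cur)
      cur <- scaffold$parent_name[scaffold$marker_name == cur]
    }
    out
  }
  markers <- scaffold$marker_name[scaffold$parent_name != ""]
  rows <- lapply(markers, function(m) {
    old_parent <- scaffold$parent_name[scaffold$marker_name == m]
    n <- find_node(m)
    if (is.na(n))
      return(data.frame(marker = m, status = "UNPLACED",
                        old_parent = old_parent, new_parent = "",
                        node_id = NA_integer_, stringsAsFactors = FALSE))
    anc_ok <- c(old_parent, scaffold_ancestors(old_parent))
    parent_id <- tree$nodes$parent[tree$nodes$id == n]
    pnames <- node_names[[which(tree$nodes$id == parent_id)]]
    own <- setdiff(node_names[[which(tree$nodes$id == n)]], m)
    confirmed <- any(anc_ok %in% c(pnames, own)) ||
      (parent_id == 1L && root_marker %in% anc_ok)
    data.frame(marker = m,
               status = if (confirmed) "CONFIRMED" else "REPOSITIONED",
               old_parent = old_parent,
               new_parent = tree$nodes$label[tree$nodes$id == parent_id],
               node_id = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reconciliation_report", "data.frame")
  out
}

#' Place samples on the tree with diagnostics
#'
#' Reports each case sample's terminal node and its marker-block path from
#' the root. For every node on the path (and every child block at the path
#' boundary) where the sample's calls are all MISSING or AMBIGUOUS, an
#' "undetermined at <block>" diagnostic is emitted: passage through an
#' undetermined node is implied by laminarity, never imputed into the
#' matrix.
#'
#' @param tree a `clade_tree` built with the matching matrix.
#' @param gm the [genotype_matrix()].
#' @return data.frame: `sample_id`, `node_id`, `terminal_label`, `path`
#'   (labels joined by `" > "`, `"root"` alone for root-attached samples),
#'   `n_undetermined`, `diagnostics` (`"; "`-joined).
#' @export
place_samples <- function(tree, gm) {
  path_to_root <- function(n) {
    out <- integer(0)
    while (!is.na(n)) {
      out <- c(n, out)
      n <- tree$nodes$parent[tree$nodes$id == n]
    }
    out
  }
  undetermined_at <- function(s, node) {
    bl <- tree$node_blocks[[node]]
    if (length(bl) == 0) return(FALSE)
    v <- unlist(lapply(bl, `[[`, "variants"))
    v <- v[v %in% colnames(gm$calls)]
    if (length(v) == 0) return(FALSE)
    all(gm$calls[s, v] %in% CALL_STATES[c("MISSING", "AMBIGUOUS")])
  }
  rows <- lapply(names(tree$sample_node), function(s) {
    term <- tree$sample_node[[s]]
    p <- path_to_root(term)
    labs <- tree$nodes$label[match(p, tree$nodes$id)]
    diags <- character(0)
    for (n in p) {
      if (n == 1L) next
      if (undetermined_at(s, n))
        diags <- c(diags, paste0("undetermined at ",
                                 tree$nodes$label[tree$nodes$id == n],
                                 " (passage inferred)"))
    }
    kids <- tree$nodes$id[!is.na(tree$nodes$parent) &
                            tree$nodes$parent == term]
    for (k in kids) {
      if (undetermined_at(s, k))
        diags <- c(diags, paste0("undetermined at ",
                                 tree$nodes$label[tree$nodes$id == k]))
    }
    if (!is.null(tree$placement_conflicts[[s]]))
      diags <- c(diags, paste0("conflicting placement evidence: ",
                               paste(tree$placement_conflicts[[s]],
                                     collapse = " vs ")))
    data.frame(sample_id = s, node_id = term,
               terminal_label = labs[length(labs)],
               path = paste(labs, collapse = " > "),
               n_undetermined = length(grep("^undetermined", diags)),
               diagnostics = paste(diags, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# newick-safe labels: equivalent markers joined by "/", no reserved chars
.newick_label <- function(x) {
  x <- gsub(", ", "/", x, fixed = TRUE)
  gsub("[][ ,;:()']", "_", x)
}

#' Export the clade tree as Newick
#'
#' Internal node labels are the block labels (equivalent markers joined by
#' `/`); attached samples become leaves. A node with neither samples nor
#' children is written as a leaf carrying its block label.
#'
#' @param tree a `clade_tree`.
#' @param path output file.
#' @return (invisibly) the Newick string.
#' @export
export_newick <- function(tree, path) {
  rec <- function(n) {
    kids <- tree$nodes$id[!is.na(tree$nodes$parent) &
                            tree$nodes$parent == n]
    kids <- kids[natural_order(tree$nodes$label[match(kids, tree$nodes$id)])]
    samp <- sort(tree$samples_at[[n]])
    label <- .newick_label(tree$nodes$label[tree$nodes$id == n])
    parts <- c(samp, vapply(kids, rec, character(1)))
    if (length(parts) == 0) return(label)
    paste0("(", paste(parts, collapse = ","), ")", label)
  }
  nwk <- paste0(rec(1L), ";")
  writeLines(nwk, path)
  invisible(nwk)
}
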