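#' Simulation configuration
#'
#' Parameters of the synthetic low-coverage Y-chromosome call generator. The
#' defaults describe the regime the pipeline targets: a modest case cohort
#' screened at an anchor marker against a control cohort, genotyped at 2-4x
#' coverage where missing calls and spurious heterozygous-looking calls are
#' routine.
#'
#' @param n_case_samples number of case samples (derived at the anchor).
#'   Must be at least `2 * n_clades` so that every clade is recoverable
#'   (each clade node receives at least two directly attached cases).
#' @param n_control_samples number of control samples (ancestral at the
#'   anchor); may be 0.
#' @param n_clades number of clade nodes below the anchor root.
#' @param variants_per_branch branch-private variants placed on each clade
#'   branch (a fixed count, so noiseless block sizes are exact).
#' @param singleton_count variants assigned to exactly one case sample each.
#' @param recurrent_count duplicated-region artefact variants, each assigned
#'   to two branches with disjoint subtrees (requires `n_clades >= 3`).
#' @param mean_coverage mean reads per site (Poisson), default 3.0 to match
#'   the 2-4x low-coverage regime.
#' @param per_read_error probability a read reports the wrong allele.
#' @param missing_rate probability a genotyped site is dropped outright.
#' @param ambiguity_threshold_reads a call is AMBIGUOUS when both alleles
#'   have at least this many supporting reads (default 2).
#' @param populations named numeric vector of population sampling weights;
#'   labels are reporting-only and never influence inference.
#' @param anchor_name marker name given to the anchor variant.
#' @param seed integer seed; fully determines all output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_case_samples = 30L,
                       n_control_samples = 20L,
                       n_clades = 8L,
                       variants_per_branch = 3L,
                       singleton_count = 5L,
                       recurrent_count = 2L,
                       mean_coverage = 3.0,
                       per_read_error = 0.02,
                       missing_rate = 0.05,
                       ambiguity_threshold_reads = 2L,
                       populations = c(GBR = 0.35, CEU = 0.30,
                                       IBS = 0.20, TSI = 0.15),
                       anchor_name = "L11",
                       seed = 1L) {
  cfg <- list(n_case_samples = as.integer(n_case_samples),
              n_control_samples = as.integer(n_control_samples),
              n_clades = as.integer(n_clades),
              variants_per_branch = as.integer(variants_per_branch),
              singleton_count = as.integer(singleton_count),
              recurrent_count = as.integer(recurrent_count),
              mean_coverage = as.numeric(mean_coverage),
              per_read_error = as.numeric(per_read_error),
              missing_rate = as.numeric(missing_rate),
              ambiguity_threshold_reads = as.integer(ambiguity_threshold_reads),
              populations = populations,
              anchor_name = as.character(anchor_name),
              seed = as.integer(seed))
  counts <- c("n_case_samples", "n_control_samples", "n_clades",
              "variants_per_branch", "singleton_count", "recurrent_count",
              "ambiguity_threshold_reads")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config: ", f, " must be a non-negative count")
  for (f in c("per_read_error", "missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must be a probability in [0, 1]")
  if (cfg$mean_coverage <= 0) stop("sim_config: mean_coverage must be > 0")
  if (cfg$n_clades < 1) stop("sim_config: n_clades must be >= 1")
  if (cfg$n_case_samples < 2L * cfg$n_clades)
    stop("sim_config: n_case_samples must be >= 2 * n_clades ",
         "(each clade needs two private case samples to be recoverable)")
  if (cfg$recurrent_count > 0 && cfg$n_clades < 3)
    stop("sim_config: recurrent artefacts need n_clades >= 3 ",
         "(a branch with a non-root parent plus a disjoint branch)")
  if (is.null(names(cfg$populations)) || any(cfg$populations < 0) ||
      sum(cfg$populations) <= 0)
    stop("sim_config: populations must be a named vector of ",
         "non-negative weights")
  cfg$populations <- cfg$populations / sum(cfg$populations)
  structure(cfg, class = "sim_config")
}

#' Simulate a rooted clade tree
#'
#' Generates the nested subclade structure below an anchor root. Node 0 is
#' the root (the anchor clade); nodes `1..n_clades` are clade nodes. To
#' guarantee that recurrent artefacts are always constructible (a branch
#' with a non-root parent plus a branch disjoint from that parent's
#' subtree), the first two clades attach to the root and the third attaches
#' below clade 1; the rest attach uniformly at random.
#'
#' @param n_clades number of clade nodes (>= 1).
#' @param seed integer seed.
#' @return A `sim_tree`: list with `parent` (integer vector; `parent[i]` is
#'   the parent of clade node `i`, 0 meaning the root) and `n_clades`.
#' @export
simulate_tree <- function(n_clades, seed) {
  n_clades <- as.integer(n_clades)
  if (is.na(n_clades) || n_clades < 1)
    stop("simulate_tree: n_clades must be >= 1")
  set.seed(stage_seed(seed, 1L))
  parent <- integer(n_clades)
  if (n_clades >= 1) parent[1] <- 0L
  if (n_clades >= 2) parent[2] <- 0L
  if (n_clades >= 3) parent[3] <- 1L
  if (n_clades >= 4) {
    for (i in 4:n_clades) {
      # attach below the root or any earlier clade, uniformly
      parent[i] <- sample.int(i, 1L) - 1L   # 0..(i-1)
    }
  }
  structure(list(parent = parent, n_clades = n_clades), class = "sim_tree")
}

# clade nodes (including `node` itself) in the subtree of `node`; node 0 is
# the root whose subtree is everything
subtree_nodes <- function(tree, node) {
  if (node == 0L) return(c(0L, seq_len(tree$n_clades)))
  out <- node
  repeat {
    more <- which(tree$parent %in% out & !(seq_len(tree$n_clades) %in% out))
    if (length(more) == 0) break
    out <- c(out, more)
  }
  sort(out)
}

# strict ancestors of a clade node, excluding the root
nonroot_ancestors <- function(tree, node) {
  out <- integer(0)
  p <- tree$parent[node]
  while (p != 0L) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

#' Simulate mutations and ground truth on a clade tree
#'
#' Places branch-private variants under an infinite-sites model, singleton
#' mutations on single case samples, and duplicated-region artefact variants
#' on two branches with disjoint subtrees (one of which has a non-root
#' parent, so the artefact is guaranteed to be four-gamete-incompatible with
#' that parent's variants). Also assigns case samples to tree nodes (two
#' private cases per clade node, the rest uniform) and draws population
#' labels.
#'
#' @param tree a `sim_tree` from [simulate_tree()].
#' @param config a [sim_config()].
#' @return list with `variants` (the variant table) and `truth`
#'   (a `sim_truth`: tree, branch/singleton/artefact variant maps,
#'   sample-to-node map, case/control ids, population labels, anchor id).
#' @export
simulate_mutations <- function(tree, config) {
  stopifnot(inherits(tree, "sim_tree"), inherits(config, "sim_config"))
  if (tree$n_clades != config$n_clades)
    stop("simulate_mutations: tree and config disagree on n_clades")
  set.seed(stage_seed(config$seed, 2L))
  nC <- tree$n_clades
  cases <- sprintf("S%03d", seq_len(config$n_case_samples))
  controls <- if (config$n_control_samples > 0)
    sprintf("C%03d", seq_len(config$n_control_samples)) else character(0)

  # sample -> node: two guaranteed private cases per clade, rest uniform
  tip <- integer(config$n_case_samples)
  names(tip) <- cases
  guaranteed <- rep(seq_len(nC), each = 2L)
  tip[seq_along(guaranteed)] <- guaranteed
  rest <- seq_along(tip)[-seq_along(guaranteed)]
  if (length(rest) > 0)
    tip[rest] <- sample(0:nC, length(rest), replace = TRUE)

  pops <- sample(names(config$populations),
                 config$n_case_samples + config$n_control_samples,
                 replace = TRUE, prob = config$populations)
  names(pops) <- c(cases, controls)

  n_branch <- nC * config$variants_per_branch
  n_total <- 1L + n_branch + config$singleton_count + config$recurrent_count
  if (n_total > 60e6) stop("simulate_mutations: position space exhausted")
  pos <- sample.int(60000000L, n_total)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n_total, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1L), character(1))

  ids <- paste0("chrY:", pos)
  name <- rep(NA_character_, n_total)
  name[1] <- config$anchor_name
  class_ <- c("anchor",
              rep("branch", n_branch),
              rep("singleton", config$singleton_count),
              rep("artefact", config$recurrent_count))

  branch_variants <- vector("list", nC)
  k <- 2L
  for (b in seq_len(nC)) {
    branch_variants[[b]] <- ids[k:(k + config$variants_per_branch - 1L)]
    k <- k + config$variants_per_branch
  }
  names(branch_variants) <- as.character(seq_len(nC))

  singleton_variants <- character(0)
  if (config$singleton_count > 0) {
    sidx <- k:(k + config$singleton_count - 1L)
    carriers <- sample(cases, config$singleton_count, replace = TRUE)
    singleton_variants <- stats::setNames(carriers, ids[sidx])
    k <- k + config$singleton_count
  }

  artefact_variants <- list()
  if (config$recurrent_count > 0) {
    # valid (A, B): A has a non-root parent; B's subtree is disjoint from
    # the subtree of A's parent (so the artefact conflicts with the
    # parent's variants and F4 can detect it)
    pairs <- list()
    for (a in seq_len(nC)) {
      pa <- tree$parent[a]
      if (pa == 0L) next
      pa_sub <- subtree_nodes(tree, pa)
      for (b in seq_len(nC)) {
        if (b %in% pa_sub) next
        if (pa %in% subtree_nodes(tree, b)) next
        pairs[[length(pairs) + 1L]] <- c(a, b)
      }
    }
    if (length(pairs) == 0)
      stop("simulate_mutations: no valid branch pair for recurrent artefacts")
    pick <- sample.int(length(pairs), config$recurrent_count, replace = TRUE)
    aidx <- k:(k + config$recurrent_count - 1L)
    artefact_variants <- stats::setNames(lapply(pick, function(i) pairs[[i]]),
                                         ids[aidx])
  }

  variants <- data.frame(id = ids, contig = "chrY", position = pos,
                         ancestral = anc, derived = der, name = name,
                         known = NA, rs_id = NA_character_,
                         stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(variants$position)
  variants <- variants[ord, , drop = FALSE]

  truth <- structure(list(tree = tree,
                          anchor_id = ids[1],
                          branch_variants = branch_variants,
                          singleton_variants = singleton_variants,
                          artefact_variants = artefact_variants,
                          sample_tip = tip,
                          case_samples = cases,
                          control_samples = controls,
                          populations = pops),
                     class = "sim_truth")
  list(variants = variants, truth = truth)
}

#' True derived-carrier samples of a simulated variant
#'
#' @param truth a `sim_truth`.
#' @param variant_id variant id (`"chrY:<pos>"`).
#' @return character vector of sample ids carrying the derived allele.
#' @export
truth_carriers <- function(truth, variant_id) {
  tip <- truth$sample_tip
  if (variant_id == truth$anchor_id) return(truth$case_samples)
  for (b in names(truth$branch_variants)) {
    if (variant_id %in% truth$branch_variants[[b]]) {
      nodes <- subtree_nodes(truth$tree, as.integer(b))
      return(names(tip)[tip %in% nodes])
    }
  }
  if (variant_id %in% names(truth$singleton_variants))
    return(unname(truth$singleton_variants[[variant_id]]))
  if (variant_id %in% names(truth$artefact_variants)) {
    ab <- truth$artefact_variants[[variant_id]]
    nodes <- c(subtree_nodes(truth$tree, ab[1]), subtree_nodes(truth$tree, ab[2]))
    return(names(tip)[tip %in% nodes])
  }
  stop("truth_carriers: unknown variant ", variant_id)
}

# samples x variants 0/1 truth matrix (1 = derived)
truth_state_matrix <- function(variants, truth) {
  samples <- c(truth$case_samples, truth$control_samples)
  M <- matrix(0L, nrow = length(samples), ncol = nrow(variants),
              dimnames = list(samples, variants$id))
  for (vid in variants$id) {
    M[truth_carriers(truth, vid), vid] <- 1L
  }
  M
}

#' Simulate low-coverage haploid calls
#'
#' Per sample x site: read depth ~ Poisson(`mean_coverage`); each read
#' reports the true allele with probability `1 - per_read_error`; the site
#' is dropped outright with probability `missing_rate`. The call is MISSING
#' at depth 0 or when dropped; AMBIGUOUS when both alleles have at least
#' `ambiguity_threshold_reads` supporting reads, or when read support is
#' tied; otherwise the majority allele. Per-allele read depths are kept (the
#' VCF AD channel) so ambiguity is recomputable by readers.
#'
#' @param variants variant table from [simulate_mutations()].
#' @param truth the matching `sim_truth`.
#' @param config the [sim_config()].
#' @return A [genotype_matrix()] with an `"ad"` attribute: list of two
#'   integer matrices `anc` and `der` of per-allele read depths.
#' @export
simulate_calls <- function(variants, truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 3L))
  M <- truth_state_matrix(variants, truth)
  n <- length(M)
  depth <- matrix(stats::rpois(n, config$mean_coverage), nrow = nrow(M))
  wrong <- matrix(stats::rbinom(n, as.vector(depth), config$per_read_error),
                  nrow = nrow(M))
  right <- depth - wrong
  n_der <- ifelse(M == 1L, right, wrong)
  n_anc <- depth - n_der
  dropped <- matrix(stats::runif(n) < config$missing_rate, nrow = nrow(M))
  n_der[dropped] <- 0L
  n_anc[dropped] <- 0L

  thr <- config$ambiguity_threshold_reads
  state <- matrix(CALL_STATES[["MISSING"]], nrow = nrow(M), ncol = ncol(M))
  obs <- (n_anc + n_der) > 0L
  both <- obs & ((n_anc >= thr & n_der >= thr) | (n_anc == n_der))
  state[obs & both] <- CALL_STATES[["AMBIGUOUS"]]
  maj_der <- obs & !both & (n_der > n_anc)
  maj_anc <- obs & !both & (n_anc > n_der)
  state[maj_der] <- CALL_STATES[["DERIVED"]]
  state[maj_anc] <- CALL_STATES[["ANCESTRAL"]]

  samples <- data.frame(
    sample_id = rownames(M),
    population = unname(truth$populations[rownames(M)]),
    stringsAsFactors = FALSE)
  mode(state) <- "integer"
  mode(n_anc) <- "integer"
  mode(n_der) <- "integer"
  gm <- genotype_matrix(state, variants, samples)
  dimnames(n_anc) <- dimnames(gm$calls)
  dimnames(n_der) <- dimnames(gm$calls)
  attr(gm, "ad") <- list(anc = n_anc, der = n_der)
  gm
}

#' Run the whole simulator
#'
#' Convenience wrapper: tree, mutations and calls in one step.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `variants`, `truth`, `gm`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_tree(config$n_clades, config$seed)
  mut <- simulate_mutations(tree, config)
  gm <- simulate_calls(mut$variants, mut$truth, config)
  list(tree = tree, variants = mut$variants, truth = mut$truth, gm = gm)
}

# newick for the true tree: clade nodes labelled "node<i>", attached samples
# as leaves
truth_newick <- function(truth) {
  tree <- truth$tree
  tip <- truth$sample_tip
  children <- lapply(0:tree$n_clades,
                     function(p) which(tree$parent == p))
  rec <- function(node) {
    kids <- children[[node + 1L]]
    samp <- sort(names(tip)[tip == node])
    label <- if (node == 0L) "root" else paste0("node", node)
    parts <- c(samp, vapply(kids, rec, character(1)))
    if (length(parts) == 0) return(label)
    paste0("(", paste(parts, collapse = ","), ")", label)
  }
  paste0(rec(0L), ";")
}

#' Write a complete fixture set
#'
#' Simulates a dataset and writes every file the downstream pipeline reads:
#' the VCF of calls, sample metadata, a known-variant list, a scaffold
#' marker table, three truth files (variant-to-branch map, true tree Newick,
#' sample-to-tip table) and a manifest listing all eight files. One named
#' marker per clade (the clade's first branch variant, named `K<node>`) is
#' seeded into both the scaffold and the known list, alongside the anchor.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) the manifest data.frame, with the simulated dataset
#'   attached as attribute `"dataset"`.
#' @export
write_fixture_set <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("write_fixture_set: cannot create output directory ", out_dir)
  ds <- simulate_dataset(config)
  truth <- ds$truth

  # named markers: clade b's first branch variant becomes K<b>
  marker_name <- stats::setNames(
    vapply(truth$branch_variants, `[`, character(1), 1L),
    sprintf("K%02d", as.integer(names(truth$branch_variants))))
  idx <- match(marker_name, ds$gm$variants$id)
  ds$gm$variants$name[idx] <- names(marker_name)
  ds$variants <- ds$gm$variants

  paths <- file.path(out_dir, c(
    vcf = "calls.vcf", samples = "samples.tsv", known = "known.tsv",
    scaffold = "scaffold.tsv", truth_branch = "truth_variant_branch.tsv",
    truth_tree = "truth_tree.nwk", truth_tip = "truth_sample_tip.tsv",
    manifest = "manifest.tsv"))
  names(paths) <- c("vcf", "samples", "known", "scaffold", "truth_branch",
                    "truth_tree", "truth_tip", "manifest")

  write_vcf(ds$gm, paths[["vcf"]])
  write_tsv(ds$gm$samples, paths[["samples"]])

  kn <- ds$gm$variants[!is.na(ds$gm$variants$name), ]
  write_tsv(data.frame(name = kn$name, contig = kn$contig,
                       position = kn$position, derived = kn$derived),
            paths[["known"]])

  par_marker <- function(b) {
    p <- truth$tree$parent[b]
    if (p == 0L) config$anchor_name else sprintf("K%02d", p)
  }
  scaffold <- data.frame(
    marker_name = c(config$anchor_name,
                    sprintf("K%02d", seq_len(truth$tree$n_clades))),
    parent_name = c("", vapply(seq_len(truth$tree$n_clades), par_marker,
                               character(1))),
    stringsAsFactors = FALSE)
  write_tsv(scaffold, paths[["scaffold"]])

  vb <- do.call(rbind, lapply(ds$variants$id, function(vid) {
    cls <- if (vid == truth$anchor_id) "anchor"
      else if (vid %in% unlist(truth$branch_variants)) "branch"
      else if (vid %in% names(truth$singleton_variants)) "singleton"
      else "artefact"
    branch <- switch(cls,
      anchor = "root",
      branch = names(truth$branch_variants)[vapply(truth$branch_variants,
                 function(v) vid %in% v, logical(1))],
      singleton = "",
      artefact = paste(truth$artefact_variants[[vid]], collapse = "+"))
    carrier <- if (cls == "singleton") truth$singleton_variants[[vid]] else ""
    data.frame(variant_id = vid, class = cls, branch = branch,
               carrier_sample = carrier, stringsAsFactors = FALSE)
  }))
  write_tsv(vb, paths[["truth_branch"]])

  writeLines(truth_newick(truth), paths[["truth_tree"]])
  write_tsv(data.frame(sample_id = names(truth$sample_tip),
                       node = unname(truth$sample_tip)),
            paths[["truth_tip"]])

  manifest <- data.frame(
    file = basename(paths),
    role = c("vcf_calls", "sample_metadata", "known_variants", "scaffold",
             "truth_variant_branch", "truth_tree", "truth_sample_tip",
             "manifest"),
    stringsAsFactors = FALSE)
  write_tsv(manifest, paths[["manifest"]])
  attr(manifest, "dataset") <- ds
  attr(manifest, "paths") <- paths
  invisible(manifest)
}
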