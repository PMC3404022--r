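#' Read a flat key-value config file
#'
#' DCF format (`key: value` lines), the R-native flat key-value format.
#' Recognised keys: `vcf`, `samples`, `known`, `scaffold`, `anchor`, `out`,
#' `max_ambiguous`, `ancestral_policy`, `orientation`,
#' `ambiguity_threshold_reads`, `seed`, plus every [sim_config()] field for
#' the simulator (`populations` as `LABEL=WEIGHT` pairs separated by
#' commas).
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  m <- read.dcf(path)
  stats::setNames(as.list(as.character(m[1, ])), colnames(m))
}

.cfg_sim <- function(cfg) {
  num <- function(k, d) if (is.null(cfg[[k]])) d else as.numeric(cfg[[k]])
  pops <- if (is.null(cfg$populations)) {
    formals(sim_config)$populations
    c(GBR = 0.35, CEU = 0.30, IBS = 0.20, TSI = 0.15)
  } else {
    kv <- strsplit(strsplit(cfg$populations, ",")[[1]], "=")
    stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                    vapply(kv, function(x) trimws(x[1]), character(1)))
  }
  sim_config(
    n_case_samples = num("n_case_samples", 30),
    n_control_samples = num("n_control_samples", 20),
    n_clades = num("n_clades", 8),
    variants_per_branch = num("variants_per_branch", 3),
    singleton_count = num("singleton_count", 5),
    recurrent_count = num("recurrent_count", 2),
    mean_coverage = num("mean_coverage", 3.0),
    per_read_error = num("per_read_error", 0.02),
    missing_rate = num("missing_rate", 0.05),
    ambiguity_threshold_reads = num("ambiguity_threshold_reads", 2),
    populations = pops,
    anchor_name = cfg$anchor_name %||% "L11",
    seed = num("seed", 1))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, " stage failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole discovery pipeline
#'
#' read -> screen -> filter cascade -> novelty -> equivalence blocks ->
#' tree -> scaffold reconciliation -> placement -> summary, writing every
#' artifact plus a run log. Idempotent for fixed inputs: two runs produce
#' byte-identical non-log outputs.
#'
#' @param config named list (or path to a [read_config()] file) with keys
#'   `vcf`, `samples`, `known`, `scaffold`, `anchor`, `out`, and optionally
#'   `max_ambiguous` (default 0), `ancestral_policy`, `orientation`,
#'   `ambiguity_threshold_reads`.
#' @return (invisibly) list with `status` (0), `manifest` and the in-memory
#'   stage results (`gm`, `screen`, `filter_report`, `blocks`, `tree`,
#'   `reconciliation`, `placements`, `summary`). Any stage error aborts
#'   with a stage-named message.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  need <- c("vcf", "samples", "known", "scaffold", "anchor", "out")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop("config stage failed: missing key(s): ", paste(miss, collapse = ", "))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  max_amb <- as.integer(config$max_ambiguous %||% 0L)
  policy <- config$ancestral_policy %||% "info-anc"
  orientation <- config$orientation %||% "as-read"
  thr <- as.integer(config$ambiguity_threshold_reads %||% 2L)

  gm <- .stage("read", {
    gm <- read_vcf(config$vcf, ancestral_policy = policy,
                   ambiguity_threshold_reads = thr)
    set_sample_metadata(gm, read_sample_metadata(config$samples))
  })
  known <- .stage("read", read_known_list(config$known))
  screen <- .stage("screen", screen_samples(gm, config$anchor))
  fr <- .stage("filter", run_filters(gm, screen, max_ambiguous = max_amb,
                                     known_list = known,
                                     orientation = orientation))
  blocks <- .stage("build", equivalence_blocks(fr$gm, fr$retained, screen))
  tree <- .stage("build", build_tree(blocks, screen$cases, gm = fr$gm))
  scaffold <- .stage("build", {
    if (!file.exists(config$scaffold %||% ""))
      stop("no such scaffold file: ", config$scaffold)
    read_scaffold(config$scaffold)
  })
  recon <- .stage("reconcile", reconcile_scaffold(tree, scaffold))
  placements <- .stage("place", place_samples(tree, fr$gm))
  summary <- .stage("report",
                    summarize_clades(tree, placements, fr$gm$samples,
                                     variants = fr$gm$variants))

  # annotate each retained variant with its block label
  for (n in tree$nodes$id) {
    for (b in tree$node_blocks[[n]]) {
      fr$table$block[match(b$variants, fr$table$id)] <- b$label
    }
  }

  paths <- file.path(out_dir, c(
    "screen.tsv", "variant_table.tsv", "conflict_edges.tsv", "tree.nwk",
    "reconciliation.tsv", "placements.tsv", "clade_summary.tsv",
    "manifest.tsv"))
  names(paths) <- c("screen", "variant_table", "conflict_edges", "tree",
                    "reconciliation", "placements", "clade_summary",
                    "manifest")
  .stage("write", {
    write_tsv(data.frame(
      sample_id = c(screen$cases, screen$controls, screen$excluded),
      group = rep(c("case", "control", "excluded"),
                  c(length(screen$cases), length(screen$controls),
                    length(screen$excluded)))), paths[["screen"]])
    write_variant_table(fr$gm$variants, fr, paths[["variant_table"]])
    write_tsv(fr$edges, paths[["conflict_edges"]])
    export_newick(tree, paths[["tree"]])
    write_tsv(as.data.frame(recon), paths[["reconciliation"]])
    write_tsv(placements, paths[["placements"]])
    write_clade_summary(summary, paths[["clade_summary"]])
    manifest <- data.frame(file = basename(paths),
                           role = names(paths), stringsAsFactors = FALSE)
    write_tsv(manifest, paths[["manifest"]])
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      paste0("ydiscover ", as.character(utils::packageVersion("ydiscover"))),
      paste0("time: ", format(Sys.time())),
      paste0("anchor: ", config$anchor),
      paste0("max_ambiguous: ", max_amb),
      paste0("ancestral_policy: ", policy),
      paste0("orientation: ", orientation),
      sprintf("cases=%d controls=%d excluded=%d variants=%d retained=%d",
              length(screen$cases), length(screen$controls),
              length(screen$excluded), nrow(fr$table),
              length(fr$retained))), log_path)
  })
  manifest <- read_tsv(paths[["manifest"]])
  invisible(list(status = 0L, manifest = manifest, paths = paths, gm = gm,
                 screen = screen, filter_report = fr, blocks = blocks,
                 tree = tree, reconciliation = recon,
                 placements = placements, summary = summary))
}
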