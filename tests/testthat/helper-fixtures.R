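# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# shorthand state codes
.A <- CALL_STATES[["ANCESTRAL"]]
.D <- CALL_STATES[["DERIVED"]]
.M <- CALL_STATES[["MISSING"]]
.H <- CALL_STATES[["AMBIGUOUS"]]

# build a genotype_matrix from a character matrix of "A","D","M","?"
# (rows = samples, cols = variants); positions default to 1000, 2000, ...
make_gm <- function(chr_mat, sample_ids = NULL, names = NULL,
                    positions = NULL) {
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(nrow(chr_mat)))
  nv <- ncol(chr_mat)
  if (is.null(positions)) positions <- 1000L * seq_len(nv)
  if (is.null(names)) names <- rep(NA_character_, nv)
  code <- c(A = .A, D = .D, M = .M, "?" = .H)
  calls <- matrix(code[chr_mat], nrow = nrow(chr_mat))
  mode(calls) <- "integer"
  variants <- data.frame(id = paste0("chrY:", positions), contig = "chrY",
                         position = positions, ancestral = "C",
                         derived = "T", name = names, known = NA,
                         rs_id = NA_character_, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_ids,
                        population = NA_character_,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples)
}

# a matrix whose first column is an anchor splitting samples into
# n_case derived + n_ctrl ancestral; extra columns appended from chr_mat
make_anchored_gm <- function(extra, n_case, n_ctrl, names = NULL, ...) {
  stopifnot(nrow(extra) == n_case + n_ctrl)
  anchor <- c(rep("D", n_case), rep("A", n_ctrl))
  m <- cbind(anchor, extra)
  nm <- c("ANCH", if (is.null(names)) rep(NA_character_, ncol(extra)) else names)
  make_gm(m, names = nm, ...)
}

# the noiseless regime of the exact-recovery acceptance runs: per-read
# error 0, no dropped sites, coverage deep enough that Poisson depth 0 is
# negligible
noiseless_config <- function(seed, ...) {
  sim_config(mean_coverage = 30, per_read_error = 0, missing_rate = 0,
             seed = seed, ...)
}

# independent oracle for rooted pairwise compatibility: scan every jointly
# observed sample, collect its gamete pattern, and reject only when all
# three derived-bearing patterns occur
oracle_compatible <- function(d1, d2, joint) {
  pats <- character(0)
  for (s in joint) {
    pats <- c(pats, paste0(as.integer(s %in% d1), as.integer(s %in% d2)))
  }
  !all(c("10", "01", "11") %in% pats)
}

# independent subtree walk over the simulator's parent vector (node 0 = root)
subtree_nodes_for_test <- function(tree, node) {
  if (node == 0L) return(c(0L, seq_len(tree$n_clades)))
  out <- node
  repeat {
    more <- setdiff(which(tree$parent %in% out), out)
    if (length(more) == 0) break
    out <- c(out, more)
  }
  sort(out)
}

read_tsv_for_test <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

run_core <- function(gm, anchor = "L11", ...) {
  scr <- screen_samples(gm, anchor)
  fr <- run_filters(gm, scr, ...)
  tree <- build_tree(equivalence_blocks(fr$gm, fr$retained, scr),
                     scr$cases, gm = fr$gm)
  list(screen = scr, fr = fr, tree = tree)
}
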