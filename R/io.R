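#' Write a genotype matrix as a haploid VCF 4.2
#'
#' One contig `chrY`; haploid GT values `"0"`, `"1"` or `"."`; AMBIGUOUS
#' cells written as `"0/1"`. REF is the ancestral allele, ALT the derived;
#' INFO `ANC` carries the ancestral allele explicitly. When the matrix has
#' per-allele read depths (the simulator's `"ad"` attribute) FORMAT includes
#' `AD`, so ambiguity is recomputable by readers. No date header is written,
#' so equal inputs produce byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  ord <- order(v$contig, v$position)
  v <- v[ord, , drop = FALSE]
  calls <- gm$calls[, ord, drop = FALSE]
  ad <- attr(gm, "ad")
  has_ad <- !is.null(ad)
  if (has_ad) {
    ad_anc <- ad$anc[, ord, drop = FALSE]
    ad_der <- ad$der[, ord, drop = FALSE]
  }

  gt_map <- c("0", "1", ".", "0/1")   # indexed by state code + 1
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrY,length=60000000>",
    "##INFO=<ID=ANC,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad)
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Per-allele read depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t"))

  gt <- matrix(gt_map[calls + 1L], nrow = nrow(calls))
  if (has_ad) {
    field <- matrix(paste0(gt, ":", ad_anc, ",", ad_der), nrow = nrow(calls))
  } else {
    field <- gt
  }
  sample_cols <- apply(field, 2, paste, collapse = "\t")
  rows <- paste(v$contig, v$position,
                ifelse(is.na(v$name), ".", v$name),
                v$ancestral, v$derived, ".", ".",
                paste0("ANC=", v$ancestral),
                if (has_ad) "GT:AD" else "GT",
                sample_cols, sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a haploid VCF into a genotype matrix
#'
#' Parsing is delegated to Bioconductor's VariantAnnotation. Haploid GT
#' `"0"` maps to the ancestral or derived state according to the ancestral
#' allele orientation, `"1"` likewise, `"."` to MISSING; diploid-coded
#' homozygous calls (`"0/0"`, `"1/1"`, phased or not) are accepted;
#' heterozygous calls (`"0/1"`) map to AMBIGUOUS. When the AD field is
#' present, any call with both alleles supported by at least
#' `ambiguity_threshold_reads` reads is AMBIGUOUS regardless of GT.
#' Multi-allelic and indel records are excluded with a single counted
#' warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param ancestral_policy `"info-anc"` (default): ancestral allele from the
#'   INFO `ANC` field, falling back to REF when absent;
#'   `"ref-is-ancestral"`: always REF. Orientation by control majority is a
#'   screening-stage concern, see [orient_by_controls()].
#' @param ambiguity_threshold_reads AD-based ambiguity threshold (default 2).
#' @return A [genotype_matrix()] (populations NA until
#'   [set_sample_metadata()] is applied).
#' @export
read_vcf <- function(path,
                     ancestral_policy = c("info-anc", "ref-is-ancestral"),
                     ambiguity_threshold_reads = 2L) {
  ancestral_policy <- match.arg(ancestral_policy)
  if (!file.exists(path)) stop("read_vcf: no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt >= 1] <- as.character(unlist(alt_list))[
    cumsum(n_alt)[n_alt >= 1] - n_alt[n_alt >= 1] + 1L]

  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning("read_vcf: excluded ", n_dropped,
            " multi-allelic or non-SNP record(s)")
  if (sum(keep) == 0) stop("read_vcf: no biallelic SNP records in ", path)

  contig <- as.character(GenomicRanges::seqnames(rr))[keep]
  position <- GenomicRanges::start(rr)[keep]
  ids <- names(rr)[keep]
  ref <- ref[keep]
  alt1 <- alt1[keep]

  info <- VariantAnnotation::info(vcf)
  anc <- rep(NA_character_, sum(keep))
  if (ancestral_policy == "info-anc" && "ANC" %in% colnames(info)) {
    a <- info$ANC
    if (is(a, "List") || is.list(a)) a <- as.character(unlist(lapply(a, `[`, 1L)))
    anc <- as.character(a)[keep]
  }
  anc[is.na(anc) | !(anc %in% c("A", "C", "G", "T"))] <- NA_character_
  flipped <- !is.na(anc) & anc == alt1
  bad_anc <- !is.na(anc) & anc != ref & anc != alt1
  if (any(bad_anc)) {
    warning("read_vcf: ANC matches neither REF nor ALT for ", sum(bad_anc),
            " record(s); treating REF as ancestral there")
  }
  use_ref <- is.na(anc) | bad_anc
  ancestral <- ifelse(flipped & !use_ref, alt1, ref)
  derived <- ifelse(flipped & !use_ref, ref, alt1)

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("read_vcf: no GT field in ", path)
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)

  ref_like <- c("0", "0/0", "0|0")
  alt_like <- c("1", "1/1", "1|1")
  mis_like <- c(".", "./.", ".|.", "")
  het_like <- c("0/1", "1/0", "0|1", "1|0")
  known_gt <- c(ref_like, alt_like, mis_like, het_like)
  bad <- !(gt %in% known_gt)
  dim(bad) <- dim(gt)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    stop("read_vcf: unrecognised GT '", gt[bad][1], "' at record ",
         contig[j[1]], ":", position[j[1]])
  }
  state <- matrix(CALL_STATES[["MISSING"]], nrow = nrow(gt), ncol = ncol(gt))
  state[gt %in% ref_like] <- CALL_STATES[["ANCESTRAL"]]
  state[gt %in% alt_like] <- CALL_STATES[["DERIVED"]]
  state[gt %in% het_like] <- CALL_STATES[["AMBIGUOUS"]]
  # flip orientation where the derived allele is REF
  if (any(flipped & !use_ref)) {
    fl <- which(flipped & !use_ref)
    a <- state[fl, , drop = FALSE]
    a[a == CALL_STATES[["ANCESTRAL"]]] <- 99L
    a[a == CALL_STATES[["DERIVED"]]] <- CALL_STATES[["ANCESTRAL"]]
    a[a == 99L] <- CALL_STATES[["DERIVED"]]
    state[fl, ] <- a
  }

  ad <- VariantAnnotation::geno(vcf)$AD
  ad_anc <- ad_der <- NULL
  if (!is.null(ad)) {
    thr <- as.integer(ambiguity_threshold_reads)
    if (length(dim(ad)) == 3) {
      a1 <- ad[keep, , 1, drop = FALSE]; dim(a1) <- dim(gt)
      a2 <- ad[keep, , 2, drop = FALSE]; dim(a2) <- dim(gt)
    } else {
      a1 <- apply(ad[keep, , drop = FALSE], c(1, 2),
                  function(x) as.integer(x[[1]][1]))
      a2 <- apply(ad[keep, , drop = FALSE], c(1, 2),
                  function(x) as.integer(x[[1]][2]))
    }
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    # a1/a2 are REF/ALT depths; convert to ancestral/derived orientation
    swap <- flipped & !use_ref
    ad_anc <- a1; ad_der <- a2
    if (any(swap)) {
      ad_anc[swap, ] <- a2[swap, , drop = FALSE]
      ad_der[swap, ] <- a1[swap, , drop = FALSE]
    }
    amb <- ad_anc >= thr & ad_der >= thr
    state[amb] <- CALL_STATES[["AMBIGUOUS"]]
  }

  name <- ids
  name[is.na(name) | name == "." | name == "" |
         grepl("^chrY:[0-9]+", name) | grepl(":[0-9]+_[ACGT]/[ACGT]$", name)] <-
    NA_character_
  variants <- data.frame(id = paste0(contig, ":", position),
                         contig = contig, position = position,
                         ancestral = ancestral, derived = derived,
                         name = name, known = NA, rs_id = NA_character_,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(variants$id))
    stop("read_vcf: duplicated (contig, position) in ", path)
  sample_df <- data.frame(sample_id = samples, population = NA_character_,
                          stringsAsFactors = FALSE)
  state <- t(state)   # VariantAnnotation is variant x sample
  mode(state) <- "integer"
  gm <- genotype_matrix(state, variants, sample_df)
  if (!is.null(ad_anc)) {
    ad_anc <- t(ad_anc); ad_der <- t(ad_der)
    mode(ad_anc) <- "integer"; mode(ad_der) <- "integer"
    dimnames(ad_anc) <- dimnames(gm$calls)
    dimnames(ad_der) <- dimnames(gm$calls)
    attr(gm, "ad") <- list(anc = ad_anc, der = ad_der)
  }
  gm
}

#' Read a known-variant list
#'
#' The local stand-in for a public Y-SNP browser: tab-separated columns
#' `name`, `contig`, `position`, `derived`. Duplicate
#' (contig, position, derived) keys are collapsed to the first entry with a
#' warning.
#'
#' @param path TSV path.
#' @return data.frame of class `known_variant_list`.
#' @export
read_known_list <- function(path) {
  df <- read_tsv(path)
  need <- c("name", "contig", "position", "derived")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("read_known_list: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(df$contig, df$position, df$derived, sep = ":")
  if (anyDuplicated(key)) {
    warning("read_known_list: ", sum(duplicated(key)),
            " duplicated key(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  class(df) <- c("known_variant_list", "data.frame")
  df
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `population`.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("read_sample_metadata: need columns sample_id, population")
  df
}

#' Read a scaffold marker table
#'
#' The prior hierarchy of named markers (the role a curated haplogroup tree
#' plays): columns `marker_name`, `parent_name`; the root row (the anchor)
#' has an empty parent.
#'
#' @param path TSV path.
#' @return data.frame of class `scaffold_tree`.
#' @export
read_scaffold <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("marker_name", "parent_name") %in% names(df)))
    stop("read_scaffold: need columns marker_name, parent_name")
  df$parent_name[is.na(df$parent_name)] <- ""
  if (anyDuplicated(df$marker_name))
    stop("read_scaffold: duplicated marker names")
  roots <- df$marker_name[df$parent_name == ""]
  if (length(roots) != 1)
    stop("read_scaffold: expected exactly one root marker, got ",
         length(roots))
  kids <- df$marker_name[df$parent_name != ""]
  if (!all(df$parent_name[df$parent_name != ""] %in% df$marker_name))
    stop("read_scaffold: parent names not all present as markers")
  # cycle check: walk each marker to the root
  for (m in kids) {
    seen <- character(0)
    cur <- m
    while (cur != roots) {
      if (cur %in% seen) stop("read_scaffold: cycle involving ", m)
      seen <- c(seen, cur)
      cur <- df$parent_name[df$marker_name == cur]
    }
  }
  class(df) <- c("scaffold_tree", "data.frame")
  df
}

#' Write the per-variant result table
#'
#' One row per variant: position, alleles, novelty, filter outcome,
#' supporting counts and (when retained) the assigned block label. Stable
#' column order; re-readable with [read_variant_table()].
#'
#' @param variants variant table of a [genotype_matrix()].
#' @param filter_report a `filter_report` from [run_filters()].
#' @param path output TSV.
#' @return (invisibly) `path`.
#' @export
write_variant_table <- function(variants, filter_report, path) {
  rep <- filter_report$table
  if (!all(variants$id %in% rep$id))
    stop("write_variant_table: report does not cover all variants")
  m <- match(variants$id, rep$id)
  out <- data.frame(
    id = variants$id,
    name = ifelse(is.na(variants$name), "", variants$name),
    contig = variants$contig,
    position = variants$position,
    ancestral = variants$ancestral,
    derived = variants$derived,
    status = ifelse(is.na(variants$known), "",
                    ifelse(variants$known, "known", "novel")),
    outcome = rep$outcome[m],
    n_derived_cases = rep$n_derived_cases[m],
    n_observed_controls = rep$n_observed_controls[m],
    n_ambiguous = rep$n_ambiguous[m],
    conflict_partners = rep$conflict_partners[m],
    block = rep$block[m],
    annotation = rep$annotation[m],
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read_tsv(path, colClasses = c(
    id = "character", name = "character", contig = "character",
    ancestral = "character", derived = "character", status = "character",
    outcome = "character", conflict_partners = "character",
    block = "character", annotation = "character"))
  for (col in c("name", "status", "conflict_partners", "block", "annotation"))
    df[[col]][is.na(df[[col]])] <- ""
  df
}
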