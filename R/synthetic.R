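#' Specification of a planted-block synthetic network
#'
#' The generator emulates a curated causal miRNA-disease network as a
#' bipartite stochastic block model: miRNAs and diseases are assigned to
#' co-association blocks and a causal edge is drawn with probability
#' `p_within` inside a block and `p_between` across blocks. A uniform
#' background of passive (non-causal) associations emulates the majority of
#' database records that carry no causality support.
#'
#' @param n_mirnas,n_diseases Entity counts.
#' @param n_blocks Number of planted co-association blocks.
#' @param p_within,p_between Causal edge probabilities inside / across
#'   blocks; `0 <= p_between < p_within <= 1`.
#' @param causal_fraction Probability that a drawn block-model edge is
#'   flagged causal. Default 1: the block model describes the causal
#'   network exactly.
#' @param p_noncausal Probability of a passive association on any pair not
#'   already carrying a causal edge. Default 0.35, leaving causal records a
#'   minority of the table as in real curated data.
#' @param seed Integer seed; the whole fixture is deterministic given it.
#' @return Validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mirnas = 60, n_diseases = 40, n_blocks = 4,
                           p_within = 0.3, p_between = 0.02,
                           causal_fraction = 1, p_noncausal = 0.35, seed = 1) {
  spec <- list(n_mirnas = n_mirnas, n_diseases = n_diseases,
               n_blocks = n_blocks, p_within = p_within,
               p_between = p_between, causal_fraction = causal_fraction,
               p_noncausal = p_noncausal, seed = seed)
  if (!is_count(n_mirnas) || !is_count(n_diseases) || !is_count(n_blocks)) {
    stop_usage("entity and block counts must be positive integers")
  }
  if (!(is_prob(p_within) && is_prob(p_between) && p_between < p_within)) {
    stop_usage("need 0 <= p_between < p_within <= 1")
  }
  if (!is_prob(causal_fraction) || !is_prob(p_noncausal)) {
    stop_usage("causal_fraction and p_noncausal must lie in [0, 1]")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic causal association network
#'
#' Entities are dealt to blocks round-robin, causal edges drawn per
#' [synthetic_spec()], evidence codes sampled from the causal-eligible
#' vocabulary (`Target`, `Genetics`) for causal records and from passive
#' codes (including `Genetics_GWAS`) otherwise. Entities left without any
#' causal edge are dropped from the network with a message — forcing an
#' edge would bias the edge probabilities.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `network` (`bipartite_network` of the causal edges),
#'   `records` (full `assoc_records` table, causal and passive),
#'   `mirna_blocks`, `disease_blocks` (named block assignment of retained
#'   entities), and the `spec`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)
  m <- spec$n_mirnas; d <- spec$n_diseases
  mirnas <- sprintf("hsa-mir-s%03d", seq_len(m))
  diseases <- sprintf("Synthetic disease %03d", seq_len(d))
  bm <- ((seq_len(m) - 1) %% spec$n_blocks) + 1
  bd <- ((seq_len(d) - 1) %% spec$n_blocks) + 1
  P <- matrix(spec$p_between, m, d)
  P[outer(bm, bd, `==`)] <- spec$p_within
  drawn <- matrix(stats::runif(m * d) < P, m, d)
  causal <- drawn & matrix(stats::runif(m * d) < spec$causal_fraction, m, d)
  passive <- !causal & matrix(stats::runif(m * d) < spec$p_noncausal, m, d)
  if (!any(causal)) stop_format("synthetic spec produced a network with no causal edge")
  rec_of <- function(mask, codes, is_causal) {
    ij <- which(mask, arr.ind = TRUE)
    data.frame(mirna_id = mirnas[ij[, 1]], disease_name = diseases[ij[, 2]],
               evidence_code = sample(codes, nrow(ij), replace = TRUE),
               pmid = sample.int(89999999L, nrow(ij)) + 10000000L,
               causal = rep(is_causal, nrow(ij)), stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec_of(causal, c("Target", "Genetics"), TRUE),
    rec_of(passive, c("Epigenetics", "Genetics_GWAS",
                      "Circulation_biomarker_diagnosis_down",
                      "Tissue_expression_up"), FALSE))
  records <- new_assoc_records(records[lex_order(records$mirna_id,
                                                 records$disease_name), ])
  rownames(records) <- NULL
  dropped_m <- rowSums(causal) == 0
  dropped_d <- colSums(causal) == 0
  if (any(dropped_m) || any(dropped_d)) {
    message(sum(dropped_m), " miRNA(s) and ", sum(dropped_d),
            " disease(s) drew no causal edge and are not in the network")
  }
  net <- build_network(records, causal_only = TRUE)
  list(network = net, records = records,
       mirna_blocks = stats::setNames(bm, mirnas)[net$mirnas],
       disease_blocks = stats::setNames(bd, diseases)[net$diseases],
       spec = spec)
}

#' Generate a toy disease ontology aligned with network blocks
#'
#' Builds a rooted tree of MeSH-style tree numbers with the given branching
#' and depth and attaches each disease to a leaf. When block assignments
#' are supplied, diseases of the same block are placed under the same
#' depth-1 subtree, so same-block pairs share deeper ancestors and semantic
#' similarity is informative about the planted structure. With more
#' diseases than available leaves, leaves are reused.
#'
#' @param diseases Character vector of disease names.
#' @param blocks Optional integer block assignment, same length (named or
#'   positional).
#' @param branching Children per internal node. Default 4.
#' @param depth Tree depth (root = depth 0; leaves at this depth). Default 3.
#' @param seed Integer seed controlling the leaf shuffling.
#' @return A `disease_ontology` mapping each disease to one leaf tree
#'   number, with the assignment in attribute `leaf_assignment`.
#' @export
generate_ontology <- function(diseases, blocks = NULL, branching = 4,
                              depth = 3, seed = 1) {
  if (!is_count(branching) || !is_count(depth)) {
    stop_usage("branching and depth must be positive integers")
  }
  withr::local_seed(seed)
  root <- "C01"
  leaves_under <- function(prefix, d) {
    if (d == 0) return(prefix)
    unlist(lapply(seq_len(branching), function(i) {
      leaves_under(paste0(prefix, ".", sprintf("%02d", i)), d - 1)
    }))
  }
  subtree_leaves <- lapply(seq_len(branching), function(i) {
    sample(leaves_under(paste0(root, ".", sprintf("%02d", i)), depth - 1))
  })
  n <- length(diseases)
  if (is.null(blocks)) blocks <- rep(seq_len(branching), length.out = n)
  assignment <- character(n)
  for (b in sort(unique(blocks))) {
    idx <- which(blocks == b)
    pool <- subtree_leaves[[((b - 1) %% branching) + 1]]
    assignment[idx] <- pool[((seq_along(idx) - 1) %% length(pool)) + 1]
  }
  treenums <- as.list(assignment)
  names(treenums) <- diseases
  onto <- new_disease_ontology(treenums, diseases)
  attr(onto, "leaf_assignment") <- stats::setNames(assignment, diseases)
  onto
}

#' Generate a conservation-analysis fixture with planted trends
#'
#' Draws per-miRNA causal (`cdn`) and total (`dsw`) disease counts, then
#' plants a positive family-size trend (`family_size = 1 + effect_family *
#' cdn + noise`) and a negative precursor-SNP trend (`snp = 1 + effect_snp *
#' (max(cdn) - cdn) + noise`), both rounded and clipped to valid counts.
#' With `noise_sd = 0` both maps are injective and monotone, so the rank
#' correlations are exactly +1 and -1.
#'
#' @param n_mirnas Number of miRNAs. Default 200.
#' @param effect_family Slope of family size in `cdn` (>= 0). Default 2.
#' @param effect_snp Magnitude of the negative SNP slope (>= 0). Default 1.
#' @param noise_sd Gaussian noise standard deviation. Default 1.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the association table, family
#'   table, precursor GFF3 and SNP VCF are written there in the exact
#'   dialects the parsers read.
#' @return List: `profiles` (the planted `conservation_profiles`),
#'   `records`, `family`, `intervals`, `snps` (in-memory fixtures),
#'   `expected_signs` (named: `family_size`, `snp_count`), and `paths` when
#'   `dir` was given.
#' @export
generate_conservation_fixture <- function(n_mirnas = 200, effect_family = 2,
                                          effect_snp = 1, noise_sd = 1,
                                          seed = 1, dir = NULL) {
  stopifnot(is_count(n_mirnas), effect_family >= 0, effect_snp >= 0,
            noise_sd >= 0)
  withr::local_seed(seed)
  n <- n_mirnas
  mirnas <- sprintf("hsa-mir-c%03d", seq_len(n))
  cdn <- stats::rpois(n, 6)
  dsw <- pmax(cdn + stats::rpois(n, 4), 1)   # every miRNA has >= 1 record
  family_size <- pmax(1, round(1 + effect_family * cdn + stats::rnorm(n, 0, noise_sd)))
  snp <- round(1 + effect_snp * (max(cdn) - cdn) + stats::rnorm(n, 0, noise_sd))
  snp <- pmin(pmax(snp, 0), 80)   # precursor is 100 bp; keep counts placeable
  pool <- sprintf("Synthetic disease %03d", seq_len(max(dsw) + 20))
  causal_flags <- unlist(lapply(seq_len(n), function(i) {
    c(rep(TRUE, cdn[i]), rep(FALSE, dsw[i] - cdn[i]))
  }))
  records <- new_assoc_records(data.frame(
    mirna_id = rep(mirnas, dsw),
    disease_name = unlist(lapply(dsw, sample, x = pool)),
    evidence_code = ifelse(causal_flags, "Target", "Epigenetics"),
    pmid = NA_integer_, causal = causal_flags, stringsAsFactors = FALSE))
  family <- data.frame(
    family_id = rep(sprintf("mirfam-%03d", seq_len(n)), family_size),
    mirna_id = unlist(lapply(seq_len(n), function(i) {
      c(mirnas[i], if (family_size[i] > 1)
        sprintf("%s-paralog-%02d", mirnas[i], seq_len(family_size[i] - 1)))
    })), stringsAsFactors = FALSE)
  start <- (seq_len(n) - 1) * 1000 + 1
  intervals <- data.frame(mirna_id = mirnas, chrom = "chr1",
                          start = start, end = start + 99,
                          strand = "+", stringsAsFactors = FALSE)
  class(intervals) <- c("precursor_intervals", "data.frame")
  pos <- unlist(lapply(seq_len(n), function(i) {
    if (snp[i] == 0) integer(0) else start[i] + sample.int(100, snp[i]) - 1
  }))
  snps <- data.frame(chrom = rep("chr1", length(pos)), pos = sort(pos),
                     stringsAsFactors = FALSE)
  snps$id <- sprintf("rs%06d", seq_len(nrow(snps)))
  profiles <- data.frame(mirna_id = mirnas, cdn = as.integer(cdn),
                         dsw = as.integer(dsw),
                         family_size = as.integer(family_size),
                         snp_count = as.integer(snp), stringsAsFactors = FALSE)
  class(profiles) <- c("conservation_profiles", "data.frame")
  out <- list(profiles = profiles, records = records, family = family,
              intervals = intervals, snps = snps,
              expected_signs = c(family_size = sign(effect_family),
                                 snp_count = -sign(effect_snp)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(associations = file.path(dir, "associations.tsv"),
                  family = file.path(dir, "families.tsv"),
                  gff3 = file.path(dir, "precursors.gff3"),
                  vcf = file.path(dir, "snps.vcf"))
    write_association_tsv(records, paths$associations)
    write_family_tsv(family, paths$family)
    write_precursor_gff3(intervals, paths$gff3)
    write_snp_vcf(snps, paths$vcf)
    out$paths <- paths
  }
  out
}

#' Write an association table in the parser's TSV dialect
#'
#' @param records An `assoc_records` data frame.
#' @param path Output path.
#' @export
write_association_tsv <- function(records, path) {
  df <- data.frame(mir = records$mirna_id, disease = records$disease_name,
                   category = records$evidence_code, pmid = records$pmid,
                   causality = ifelse(is.na(records$causal), "",
                                      ifelse(records$causal, "yes", "no")),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a disease ontology as two-column TSV
#'
#' @param ontology A `disease_ontology`.
#' @param path Output path; one `name<TAB>treenumber` line per tree number.
#' @export
write_mesh_tsv <- function(ontology, path) {
  lines <- unlist(lapply(seq_along(ontology$display), function(i) {
    paste(ontology$display[i], ontology$terms[[i]], sep = "\t")
  }))
  writeLines(c("disease\ttree_number", lines), path)
  invisible(path)
}

#' Write a disease ontology in the MeSH ASCII descriptor dialect
#'
#' @inheritParams write_mesh_tsv
#' @export
write_mesh_ascii <- function(ontology, path) {
  lines <- unlist(lapply(seq_along(ontology$display), function(i) {
    c("*NEWRECORD", paste("MH =", ontology$display[i]),
      paste("MN =", ontology$terms[[i]]))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a family membership table
#'
#' @param family Data frame with `family_id`, `mirna_id`.
#' @param path Output path.
#' @export
write_family_tsv <- function(family, path) {
  utils::write.table(family[, c("family_id", "mirna_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write precursor intervals as GFF3
#'
#' Features of type `miRNA_primary_transcript` with `ID`/`Name` attributes,
#' the layout [parse_precursor_gff()] reads.
#'
#' @param intervals `precursor_intervals` data frame.
#' @param path Output path.
#' @export
write_precursor_gff3 <- function(intervals, path) {
  body <- sprintf("%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                  intervals$chrom, intervals$start, intervals$end,
                  intervals$strand, intervals$mirna_id, intervals$mirna_id)
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}

#' Write SNP positions as a minimal VCF v4.2
#'
#' @param snps Data frame with `chrom`, `pos`, optional `id`.
#' @param path Output path.
#' @export
write_snp_vcf <- function(snps, path) {
  id <- if (!is.null(snps$id)) snps$id else sprintf("rs%06d", seq_len(nrow(snps)))
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) {
    sprintf("%s\t%d\t%s\tA\tG\t.\t.\t.", snps$chrom, snps$pos, id)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
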