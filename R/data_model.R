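#' Default column aliases for association tables
#'
#' HMDD-style downloads name their columns differently between versions; the
#' parser resolves each logical field through an alias list, matched
#' case-insensitively against the file header.
#'
#' @return Named list of character vectors: aliases for the `mirna`,
#'   `disease`, `evidence`, `pmid` and `causality` fields.
#' @export
association_aliases <- function() {
  list(
    mirna     = c("mir", "mirna", "mirna_id", "miRNA", "microrna"),
    disease   = c("disease", "disease_name"),
    evidence  = c("category", "evidence", "evidence_code", "description"),
    pmid      = c("pmid", "pubmed", "pubmed_id"),
    causality = c("causality", "causal")
  )
}

match_alias <- function(header, aliases) {
  hit <- which(tolower(header) %in% tolower(aliases))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Parse an HMDD-style miRNA-disease association table
#'
#' Reads a tab-separated table with a header row and returns one association
#' record per row. miRNA identifiers are lower-cased (precursor-level names
#' such as `hsa-mir-155`; arm suffixes are never stripped, since `-3p`/`-5p`
#' arms are distinct entities). Rows that are duplicated on
#' (miRNA, disease, evidence code, PMID) are collapsed to one record.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param aliases Column alias map, see [association_aliases()].
#' @return A data frame of class `assoc_records` with columns `mirna_id`,
#'   `disease_name`, `evidence_code`, `pmid` (integer, `NA` when absent) and
#'   `causal` (logical; `NA` when the table carries no causality column).
#' @export
parse_associations <- function(path, aliases = association_aliases()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  header <- names(raw)
  idx <- lapply(aliases, match_alias, header = header)
  for (field in c("mirna", "disease", "evidence")) {
    if (is.na(idx[[field]])) {
      stop_format("association table %s lacks a '%s' column (accepted names: %s)",
                  path, field, paste(aliases[[field]], collapse = ", "))
    }
  }
  if (nrow(raw) == 0) {
    warning("association table ", path, " has a header but no rows")
    return(new_assoc_records(data.frame(
      mirna_id = character(), disease_name = character(),
      evidence_code = character(), pmid = integer(), causal = logical(),
      stringsAsFactors = FALSE)))
  }
  pmid <- if (is.na(idx$pmid)) rep(NA_integer_, nrow(raw)) else
    suppressWarnings(as.integer(trimws(raw[[idx$pmid]])))
  causal <- if (is.na(idx$causality)) rep(NA, nrow(raw)) else
    tolower(trimws(raw[[idx$causality]])) %in% c("yes", "y", "true", "1", "causal")
  rec <- data.frame(
    mirna_id      = tolower(trimws(raw[[idx$mirna]])),
    disease_name  = trimws(raw[[idx$disease]]),
    evidence_code = trimws(raw[[idx$evidence]]),
    pmid          = pmid,
    causal        = causal,
    stringsAsFactors = FALSE
  )
  if (any(rec$mirna_id == "" | rec$disease_name == "")) {
    stop_format("association table %s contains empty miRNA or disease names", path)
  }
  key <- paste(rec$mirna_id, rec$disease_name, rec$evidence_code, rec$pmid, sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  rownames(rec) <- NULL
  new_assoc_records(rec)
}

new_assoc_records <- function(df) {
  class(df) <- c("assoc_records", "data.frame")
  df
}

#' Evidence-code candidate screen
#'
#' Keeps records whose evidence code contains the class `Target`, or a class
#' beginning with `Genetics` other than `Genetics_GWAS` (genome-wide
#' association hits relate loci to disease but carry no causality).
#' Compound codes (several classes separated by `,`, `;` or `|`) qualify if
#' any single class qualifies. Order is preserved and the operation is
#' idempotent. Unknown codes are simply not selected.
#'
#' @param records An `assoc_records` data frame.
#' @return The retained subset, same class and column layout.
#' @export
screen_candidates <- function(records) {
  if (nrow(records) == 0) return(records)
  keep <- vapply(strsplit(records$evidence_code, "[,;|]"), function(tokens) {
    tokens <- tolower(trimws(tokens))
    any(tokens == "target" |
          (startsWith(tokens, "genetics") & tokens != "genetics_gwas"))
  }, logical(1))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bipartite miRNA-disease network
#'
#' Materialises a binary adjacency matrix (rows = miRNAs, columns = diseases)
#' from association records. Entity orders are deterministic (locale-free
#' lexicographic), so the same record set always yields the same matrix
#' regardless of input row order.
#'
#' @param records An `assoc_records` data frame.
#' @param causal_only If `TRUE`, restrict to causal records: rows with
#'   `causal == TRUE` when the table carried a causality column, otherwise
#'   the evidence-code screen of [screen_candidates()] is used as the
#'   pre-filter fallback.
#' @return An object of class `bipartite_network`: list with `mirnas`,
#'   `diseases` and the binary `adjacency` matrix (dimnames set).
#' @export
build_network <- function(records, causal_only = FALSE) {
  if (causal_only) {
    records <- if (any(!is.na(records$causal))) {
      records[!is.na(records$causal) & records$causal, , drop = FALSE]
    } else {
      screen_candidates(records)
    }
  }
  if (nrow(records) == 0) {
    stop_format("no association records survive filtering; cannot build an empty network")
  }
  mirnas <- lex_sort(records$mirna_id)
  diseases <- lex_sort(records$disease_name)
  adjacency <- matrix(0L, length(mirnas), length(diseases),
                      dimnames = list(mirnas, diseases))
  adjacency[cbind(match(records$mirna_id, mirnas),
                  match(records$disease_name, diseases))] <- 1L
  new_bipartite_network(mirnas, diseases, adjacency)
}

new_bipartite_network <- function(mirnas, diseases, adjacency) {
  stopifnot(all(adjacency %in% c(0L, 1L)),
            nrow(adjacency) == length(mirnas),
            ncol(adjacency) == length(diseases))
  structure(list(mirnas = mirnas, diseases = diseases, adjacency = adjacency),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d miRNAs x %d diseases, %d edges\n",
              length(x$mirnas), length(x$diseases), sum(x$adjacency)))
  invisible(x)
}

#' Edge list of a bipartite network
#'
#' @param net A `bipartite_network`.
#' @return Data frame with columns `mirna_id`, `disease_name`, one row per edge.
#' @export
network_edges <- function(net) {
  ij <- which(net$adjacency == 1L, arr.ind = TRUE)
  ij <- ij[lex_order(net$mirnas[ij[, 1]], net$diseases[ij[, 2]]), , drop = FALSE]
  data.frame(mirna_id = net$mirnas[ij[, 1]],
             disease_name = net$diseases[ij[, 2]],
             stringsAsFactors = FALSE)
}

#' Rebuild a network from an explicit edge list
#'
#' @param edges Data frame with `mirna_id` and `disease_name` columns.
#' @return A `bipartite_network` over exactly the entities present in `edges`.
#' @export
network_from_edges <- function(edges) {
  if (nrow(edges) == 0) stop_format("cannot build a network from zero edges")
  rec <- new_assoc_records(data.frame(
    mirna_id = tolower(trimws(edges$mirna_id)),
    disease_name = trimws(edges$disease_name),
    evidence_code = "Target", pmid = NA_integer_, causal = TRUE,
    stringsAsFactors = FALSE))
  build_network(rec, causal_only = TRUE)
}

#' Parse a miRNA family membership table
#'
#' @param path TSV with a header; columns matched case-insensitively against
#'   `family`/`family_id` and `mir`/`mirna`/`mirna_id`.
#' @return Data frame with columns `family_id`, `mirna_id` (lower-cased).
#' @export
parse_family_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  fi <- match_alias(names(raw), c("family", "family_id", "mirfam"))
  mi <- match_alias(names(raw), c("mir", "mirna", "mirna_id", "member"))
  if (is.na(fi) || is.na(mi)) {
    stop_format("family table %s needs 'family' and 'mirna' columns", path)
  }
  data.frame(family_id = trimws(raw[[fi]]),
             mirna_id = tolower(trimws(raw[[mi]])),
             stringsAsFactors = FALSE)
}

#' Parse miRNA precursor intervals from GFF3
#'
#' Keeps features of type `miRNA_primary_transcript`; the `Name` attribute is
#' taken as the miRNA identifier. Coordinates are 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return Data frame of class `precursor_intervals` with columns `mirna_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
parse_precursor_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "miRNA_primary_transcript"]
  if (length(gr) == 0) {
    warning("no miRNA_primary_transcript features in ", path)
  }
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  out <- data.frame(
    mirna_id = tolower(nm),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("precursor_intervals", "data.frame")
  out
}

#' Parse SNP positions from a VCF
#'
#' Only CHROM, POS and ID are consumed; genotypes and INFO are ignored.
#'
#' @param path VCF v4.x file (plain text).
#' @return Data frame with columns `chrom`, `pos` (integer, 1-based), `id`.
#' @export
parse_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             id = as.character(fix[, "ID"]),
             stringsAsFactors = FALSE)
}
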