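#' Causal disease number and disease spectrum width per miRNA
#'
#' `dsw` (disease spectrum width) counts all distinct diseases associated
#' with a miRNA, causal or not; `cdn` (causal disease number) counts only
#' the distinct causally linked diseases, so `cdn <= dsw` always. Records
#' lacking a causality flag count towards `dsw` only.
#'
#' @param records An `assoc_records` data frame with causal flags.
#' @return Data frame with columns `mirna_id`, `cdn`, `dsw`, one row per
#'   miRNA, lexicographic order.
#' @export
compute_cdn_dsw <- function(records) {
  if (all(is.na(records$causal))) {
    warning("no causality flags present; cdn will be 0 for every miRNA")
  }
  mirnas <- lex_sort(records$mirna_id)
  pair_key <- !duplicated(paste(records$mirna_id, records$disease_name, sep = "\r"))
  dsw_tab <- table(factor(records$mirna_id[pair_key], levels = mirnas))
  causal <- records[!is.na(records$causal) & records$causal, , drop = FALSE]
  cpair <- !duplicated(paste(causal$mirna_id, causal$disease_name, sep = "\r"))
  cdn_tab <- table(factor(causal$mirna_id[cpair], levels = mirnas))
  data.frame(mirna_id = mirnas,
             cdn = as.integer(cdn_tab),
             dsw = as.integer(dsw_tab),
             stringsAsFactors = FALSE)
}

#' Group miRNAs by causal disease number
#'
#' Partitions miRNAs into bands of `cdn`. The default boundaries yield five
#' groups — `0`, `1-5`, `6-15`, `16-30`, `>30` — separating the roughly half
#' of miRNAs with no causal information from the few causal in more than 30
#' diseases.
#'
#' @param profiles Data frame with `mirna_id` and `cdn` columns (e.g. from
#'   [compute_cdn_dsw()]).
#' @param boundaries Strictly increasing integer cutoffs; group `g` holds
#'   miRNAs with `boundaries[g-1] < cdn <= boundaries[g]`, with an open top
#'   group above the last cutoff.
#' @return Named list mapping group label to the character vector of miRNA
#'   ids in it (a partition), with a `fractions` attribute summing to 1.
#' @export
group_by_cdn <- function(profiles, boundaries = c(0, 5, 15, 30)) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop_usage("cdn group boundaries must be strictly increasing")
  }
  breaks <- c(-Inf, boundaries, Inf)
  lo <- c(boundaries[1], boundaries[-length(boundaries)] + 1)
  hi <- boundaries
  labels <- c(ifelse(lo == hi, as.character(hi), paste0(lo, "-", hi)),
              paste0(">", boundaries[length(boundaries)]))
  band <- cut(profiles$cdn, breaks = breaks, labels = labels)
  groups <- split(profiles$mirna_id, band)
  fr <- lengths(groups) / nrow(profiles)
  attr(groups, "fractions") <- fr
  groups
}

#' Count SNPs inside miRNA precursor intervals
#'
#' Counts SNP positions falling within each precursor interval (1-based,
#' both ends inclusive; strand ignored) and collapses the counts by miRNA
#' name, so a miRNA with several genomic copies accumulates the SNPs of all
#' of them. Malformed intervals (`start > end`, empty chromosome) are
#' skipped with a warning.
#'
#' @param intervals `precursor_intervals` data frame (see
#'   [parse_precursor_gff()]).
#' @param snps Data frame of SNP positions (`chrom`, `pos`; see
#'   [parse_snp_vcf()]).
#' @return Named integer vector: miRNA id -> SNP count.
#' @export
snp_count <- function(intervals, snps) {
  bad <- intervals$start > intervals$end | !nzchar(intervals$chrom) |
    is.na(intervals$start) | is.na(intervals$end)
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed precursor interval(s)")
    intervals <- intervals[!bad, , drop = FALSE]
  }
  if (nrow(intervals) == 0) return(stats::setNames(integer(0), character(0)))
  chroms <- unique(c(intervals$chrom, snps$chrom))
  iv <- GenomicRanges::GRanges(
    factor(intervals$chrom, levels = chroms),
    IRanges::IRanges(intervals$start, intervals$end))
  sp <- GenomicRanges::GRanges(
    factor(snps$chrom, levels = chroms),
    IRanges::IRanges(snps$pos, width = 1))
  per_interval <- GenomicRanges::countOverlaps(iv, sp)
  counts <- tapply(per_interval, intervals$mirna_id, sum)
  mirnas <- lex_sort(intervals$mirna_id)
  stats::setNames(as.integer(counts[mirnas]), mirnas)
}

#' Assemble per-miRNA conservation profiles
#'
#' Joins cdn/dsw with family sizes (member count of the miRNA's family in
#' the membership table) and precursor SNP counts. miRNAs missing from the
#' family table or without precursor intervals get `NA` for the respective
#' feature.
#'
#' @param records An `assoc_records` data frame with causal flags.
#' @param family Optional family membership table (see
#'   [parse_family_table()]).
#' @param intervals,snps Optional precursor intervals and SNP positions.
#' @return Data frame of class `conservation_profiles` with columns
#'   `mirna_id`, `cdn`, `dsw`, `family_size`, `snp_count`.
#' @export
conservation_profiles <- function(records, family = NULL, intervals = NULL,
                                  snps = NULL) {
  prof <- compute_cdn_dsw(records)
  prof$family_size <- NA_integer_
  if (!is.null(family)) {
    sizes <- table(family$family_id)
    fam_of <- stats::setNames(family$family_id, family$mirna_id)
    prof$family_size <- as.integer(sizes[fam_of[prof$mirna_id]])
  }
  prof$snp_count <- NA_integer_
  if (!is.null(intervals) && !is.null(snps)) {
    cnt <- snp_count(intervals, snps)
    prof$snp_count <- as.integer(cnt[prof$mirna_id])
  }
  class(prof) <- c("conservation_profiles", "data.frame")
  prof
}

#' Correlate a disease-count metric with a conservation feature
#'
#' Reports both Pearson's r (the linear trend the smoothed scatter plots
#' display) and Spearman's rho (recommended for these count-valued
#' features). Optional min-max normalisation of the metric to `[0, 1]`
#' matches the normalised axis of the published plots; it is affine and so
#' changes neither coefficient.
#'
#' @param profiles A `conservation_profiles` data frame.
#' @param metric `"cdn"` or `"dsw"`.
#' @param feature `"family_size"` or `"snp_count"`.
#' @param normalize Min-max scale the metric before correlating.
#' @return List: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`, `metric`, `feature`.
#' @export
correlate_conservation <- function(profiles, metric = c("cdn", "dsw"),
                                   feature = c("family_size", "snp_count"),
                                   normalize = TRUE) {
  metric <- match.arg(metric)
  feature <- match.arg(feature)
  x <- profiles[[metric]]
  y <- profiles[[feature]]
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) < 3) stop_usage("need at least 3 complete profiles to correlate")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_numeric("correlation undefined: %s or %s has zero variance", metric, feature)
  }
  if (normalize) x <- (x - min(x)) / (max(x) - min(x))
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x), metric = metric, feature = feature)
}
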