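write_assoc_fixture <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                                                   .local_envir = parent.frame())) {
  writeLines(c("mir\tdisease\tcategory\tpmid\tcausality", rows), path)
  path
}

test_that("association parsing strips, lower-cases and deduplicates", {
  path <- write_assoc_fixture(c(
    "hsa-mir-155\tMyocardial infarction\tTarget\t31191799\tyes",
    "hsa-mir-155\tMyocardial infarction\tTarget\t31191799\tyes",   # byte-identical
    "HSA-miR-21\tNeoplasms\tGenetics\t123\tno",                    # alias-cased id
    "hsa-mir-1 \t Heart failure \tEpigenetics\t456\tno",           # stray spaces
    "hsa-mir-2\tGlioma\tTarget\t789\tyes",
    "hsa-mir-3\tGlioma\tCirculation_biomarker\t111\tno"))
  rec <- parse_associations(path)
  expect_s3_class(rec, "assoc_records")
  expect_equal(nrow(rec), 5)                       # 6 rows, 1 duplicate
  expect_true(all(rec$mirna_id == tolower(rec$mirna_id)))
  expect_true("hsa-mir-21" %in% rec$mirna_id)
  first <- rec[rec$mirna_id == "hsa-mir-155", ]
  expect_equal(first$disease_name, "Myocardial infarction")
  expect_equal(first$evidence_code, "Target")
  expect_equal(first$pmid, 31191799L)
  expect_true(first$causal)
  expect_equal(rec$disease_name[rec$mirna_id == "hsa-mir-1"], "Heart failure")
})

test_that("association parsing reports missing columns and empty tables", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mir\tcategory\tpmid", "hsa-mir-1\tTarget\t1"), bad)
  expect_error(parse_associations(bad), "disease", class = "mc_format_error")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mir\tdisease\tcategory\tpmid", empty)
  expect_warning(rec <- parse_associations(empty), "no rows")
  expect_equal(nrow(rec), 0)
})

test_that("evidence-code screen keeps Target and Genetics but not Genetics_GWAS", {
  rec <- new_records(data.frame(
    mirna_id = paste0("m", 1:4), disease_name = "d",
    evidence_code = c("Target", "Genetics", "Genetics_GWAS", "Epigenetics"),
    pmid = NA_integer_, causal = NA, stringsAsFactors = FALSE))
  kept <- screen_candidates(rec)
  expect_equal(kept$evidence_code, c("Target", "Genetics"))
  expect_equal(nrow(screen_candidates(rec[0, ])), 0)

  # 10-record fixture: 3 Target, 2 Genetics, 2 Genetics_GWAS, 3 other -> 5 kept
  rec10 <- new_records(data.frame(
    mirna_id = paste0("m", 1:10), disease_name = "d",
    evidence_code = c(rep("Target", 3), rep("Genetics_overexpression", 2),
                      rep("Genetics_GWAS", 2), "Epigenetics",
                      "Circulation_biomarker", "Tissue_expression"),
    pmid = NA_integer_, causal = NA, stringsAsFactors = FALSE))
  expect_equal(nrow(screen_candidates(rec10)), 5)
  # idempotent, order preserved
  expect_identical(screen_candidates(screen_candidates(rec10)),
                   screen_candidates(rec10))
})

test_that("network construction is deterministic, idempotent and order-independent", {
  one <- new_records(data.frame(mirna_id = "m1", disease_name = "d1",
                                evidence_code = "Target", pmid = NA_integer_,
                                causal = TRUE, stringsAsFactors = FALSE))
  net1 <- build_network(one, causal_only = TRUE)
  expect_equal(unname(net1$adjacency), matrix(1L, 1, 1))

  rec <- toy_records()
  net <- build_network(rec)
  expect_equal(dim(net$adjacency), c(2, 2))
  expect_equal(sum(net$adjacency), 3)
  expect_true(all(rowSums(net$adjacency) >= 1) && all(colSums(net$adjacency) >= 1))

  # duplicate rows change nothing
  expect_identical(build_network(rbind(rec, rec[1, ]))$adjacency, net$adjacency)
  # shuffled rows change nothing
  withr::with_seed(42, {
    shuffled <- rec[sample(nrow(rec)), ]
  })
  expect_identical(build_network(shuffled)$adjacency, net$adjacency)
})

test_that("causal_only uses the causality column and falls back to the screen", {
  rec <- new_records(data.frame(
    mirna_id = c("m1", "m1", "m2"), disease_name = c("d1", "d2", "d1"),
    evidence_code = c("Target", "Epigenetics", "Target"),
    pmid = NA_integer_, causal = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
  net <- build_network(rec, causal_only = TRUE)
  expect_equal(sum(net$adjacency), 1)   # only the flagged record
  rec$causal <- NA                      # no flags: evidence screen decides
  net2 <- build_network(rec, causal_only = TRUE)
  expect_equal(sum(net2$adjacency), 2)  # the two Target records
  rec$causal <- FALSE
  expect_error(build_network(rec, causal_only = TRUE), class = "mc_format_error")
})

test_that("MeSH parsing accepts both dialects and they agree", {
  ascii <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("*NEWRECORD",
               "MH = Myocardial Infarction",
               "MN = C14.280.647.500",
               "MN = C23.550.513.355.750",
               "*NEWRECORD",
               "MH = Ghost Term"), ascii)
  expect_warning(onto_a <- parse_mesh(ascii), "no tree numbers")
  expect_setequal(resolve_disease(onto_a, "myocardial  infarction"),
                  c("C14.280.647.500", "C23.550.513.355.750"))
  expect_null(resolve_disease(onto_a, "Ghost Term"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease\ttree_number",
               "Myocardial Infarction\tC14.280.647.500",
               "Myocardial Infarction\tC23.550.513.355.750"), tsv)
  onto_t <- parse_mesh(tsv)
  expect_setequal(resolve_disease(onto_t, "Myocardial Infarction"),
                  resolve_disease(onto_a, "Myocardial Infarction"))
})

test_that("GFF3 and VCF fixtures round-trip through the standard parsers", {
  iv <- data.frame(mirna_id = c("hsa-mir-1", "hsa-mir-2"), chrom = "chr1",
                   start = c(100L, 500L), end = c(179L, 599L), strand = "+",
                   stringsAsFactors = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_precursor_gff3(iv, gff)
  parsed <- parse_precursor_gff(gff)
  expect_equal(parsed$mirna_id, iv$mirna_id)
  expect_equal(parsed$start, iv$start)
  expect_equal(parsed$end, iv$end)

  sn <- data.frame(chrom = "chr1", pos = c(100L, 180L, 550L),
                   id = c("rs1", "rs2", "rs3"), stringsAsFactors = FALSE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(sn, vcf)
  parsed_snp <- parse_snp_vcf(vcf)
  expect_equal(parsed_snp$pos, sn$pos)
  expect_equal(parsed_snp$id, sn$id)
})
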