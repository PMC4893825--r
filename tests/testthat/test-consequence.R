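test_that("transcript coordinate projection matches hand traces", {
  b <- fixtureBundle()
  tx1 <- storeTranscript(b$store, "TX1")
  bb <- mapToTranscript(25L, 25L, tx1, b$store)
  expect_identical(bb$cdna_start, 15L)
  expect_identical(bb$cds_start, 5L)
  expect_identical(bb$protein_start, 2L)
  bb <- mapToTranscript(5L, 5L, tx1, b$store)
  expect_false(bb$within)
  expect_identical(bb$distance, 6L)
  expect_identical(bb$side, "upstream")
  # minus strand: last CDS-proximal genomic base is cds position 1
  tx3 <- storeTranscript(b$store, "TX3")
  bb <- mapToTranscript(1770L, 1770L, tx3, b$store)
  expect_identical(bb$cds_start, 1L)
  # wholly intronic span yields an intron index and no cDNA interval
  tx2 <- storeTranscript(b$store, "TX2")
  bb <- mapToTranscript(550L, 550L, tx2, b$store)
  expect_true(bb$whollyIntronic)
  expect_identical(bb$intron_idx, 1L)
  expect_true(is.na(bb$cdna_start))
})

test_that("codon-level annotation: missense with case convention, gating counter", {
  b <- fixtureBundle()
  tx1 <- storeTranscript(b$store, "TX1")
  row <- snvRow("chrT", 25L, "C", "T")
  stats <- newRunStatistics()
  ac <- assignConsequences(row, "T", tx1, b$store, b$registry, stats = stats)
  expect_true("missense_variant" %in% ac$terms)
  expect_identical(ac$context$codon$ref_codons_disp, "gCc")
  expect_identical(ac$context$codon$alt_codons_disp, "gTc")
  expect_identical(ac$context$codon$ref_aa, "A")
  expect_identical(ac$context$codon$alt_aa, "V")
  # donor+2 SNV: splice_donor only, coding predicates gated away
  tx2 <- storeTranscript(b$store, "TX2")
  row <- snvRow("chrT", 502L, baseAt(b, "chrT", 502L), "C")
  s2 <- newRunStatistics()
  ac <- assignConsequences(row, "C", tx2, b$store, b$registry, stats = s2)
  expect_identical(ac$terms, "splice_donor_variant")
  expect_gt(statsAsList(s2)$predicate_evaluations_skipped, 0L)
  # 200 bp past the transcript end, within flank
  row <- snvRow("chrT", 270L, baseAt(b, "chrT", 270L), "A")
  ac <- assignConsequences(row, "A", tx1, b$store, b$registry)
  expect_identical(ac$terms, "downstream_gene_variant")
  expect_identical(ac$context$bundle$distance, 200L)
})

test_that("pre-predicate gates change no results, only evaluation counts", {
  b <- fixtureBundle()
  vs <- readVcfVariants(b$vcf)
  s1 <- newRunStatistics(); s2 <- newRunStatistics()
  r1 <- annotateVariants(b$store, vs, b$registry, gates = TRUE, stats = s1, hgvs = FALSE)
  r2 <- annotateVariants(b$store, vs, b$registry, gates = FALSE, stats = s2, hgvs = FALSE)
  key <- function(r) paste(r$variant_index, r$allele, r$feature,
                           vapply(r$terms, termString, ""))
  expect_identical(key(r1), key(r2))
  l1 <- statsAsList(s1); l2 <- statsAsList(s2)
  expect_lt(l1$predicate_evaluations, l2$predicate_evaluations)
  expect_identical(l2$predicate_evaluations_skipped, 0L)
  # the n*f*p bound holds with the gate counters included
  expect_lte(l1$predicate_evaluations + l1$predicate_evaluations_skipped,
             l1$n * l1$f * l1$p)
})

test_that("engine reproduces the generated truth table exactly", {
  b <- fixtureBundle()
  vs <- readVcfVariants(b$vcf)
  res <- annotateVariants(b$store, vs, b$registry, hgvs = FALSE)
  truth <- b$fx$truth
  resKey <- paste(res$uploaded_variation, res$allele, sub("[.]1$", "", res$feature))
  resTerms <- vapply(res$terms, termString, "")
  truKey <- paste(truth$variant, truth$allele, truth$feature)
  expect_identical(sort(resKey), sort(truKey))
  m <- match(truKey, resKey)
  expect_identical(unname(resTerms[m]), truth$terms)
})

test_that("post-resolution term sets never contain an ancestor of a member", {
  b <- fixtureBundle()
  vs <- readVcfVariants(b$vcf)
  res <- annotateVariants(b$store, vs, b$registry, hgvs = FALSE)
  for (terms in res$terms) {
    anc <- unlist(lapply(terms, vcanno:::termAncestors, registry = b$registry))
    expect_length(intersect(terms, anc), 0L)
  }
})

test_that("coding SNVs with unchanged protein report synonymous or stop_retained", {
  b <- fixtureBundle()
  vs <- readVcfVariants(b$vcf)
  res <- annotateVariants(b$store, vs, b$registry, hgvs = FALSE)
  coding <- res[res$amino_acids != "-", , drop = FALSE]
  same <- !grepl("/", coding$amino_acids, fixed = TRUE)
  for (i in which(same)) {
    expect_true(any(c("synonymous_variant", "stop_retained_variant",
                      "incomplete_terminal_codon_variant") %in%
                      coding$terms[[i]]))
  }
})

test_that("structural variant rules: ablation, amplification, truncation, elongation", {
  b <- fixtureBundle()
  tx1 <- storeTranscript(b$store, "TX1")
  tx2 <- storeTranscript(b$store, "TX2")
  del <- variantTable(variantSet("chrT", 1L, 80L, "N", list("<DEL>"),
                                 is_structural = TRUE, sv_type = "DEL"))[1L, ]
  expect_identical(assignSvConsequences(del, tx1), "transcript_ablation")
  dup <- del; dup$sv_type <- "DUP"; dup$alt <- I(list("<DUP>"))
  expect_identical(assignSvConsequences(dup, tx1), "transcript_amplification")
  # partial overlaps
  delPart <- variantTable(variantSet("chrT", 950L, 1120L, "N", list("<DEL>"),
                                     is_structural = TRUE, sv_type = "DEL"))[1L, ]
  expect_setequal(assignSvConsequences(delPart, tx2),
                  c("feature_truncation", "coding_sequence_variant"))
  dupPart <- variantTable(variantSet("chrT", 590L, 910L, "N", list("<DUP>"),
                                     is_structural = TRUE, sv_type = "DUP"))[1L, ]
  expect_identical(assignSvConsequences(dupPart, tx2), "feature_elongation")
  # flank-only overlap gives the directional flank term
  delFlank <- variantTable(variantSet("chrT", 3000L, 3100L, "N", list("<DEL>"),
                                      is_structural = TRUE, sv_type = "DEL"))[1L, ]
  expect_identical(assignSvConsequences(delFlank, tx1), "downstream_gene_variant")
  # regulatory / motif analogues via the annotated fixture truth
  truth <- b$fx$truth
  expect_true("regulatory_region_ablation" %in%
                truth$terms[truth$variant == "sv05"])
  expect_true("TFBS_ablation" %in% truth$terms[truth$variant == "sv07"])
  expect_true("TFBS_amplification" %in% truth$terms[truth$variant == "sv08"])
})

test_that("engine agrees with the re-translation oracle on a sampled SNV set", {
  b <- fixtureBundle()
  set.seed(99)
  g <- b$genome$chrT
  cases <- list()
  for (txid in c("TX2", "TX3")) {
    tx <- b$tx[[txid]]
    sp <- range(c(IRanges::start(tx@exons), IRanges::end(tx@exons)))
    pos <- sample(sp[1L]:sp[2L], 40L)
    for (p in pos) {
      ref <- substr(g, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      cases[[length(cases) + 1L]] <- list(txid = txid, p = p, ref = ref, alt = alt)
    }
  }
  tb <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cc <- cases[[i]]
    r <- variantTable(variantSet("chrT", cc$p, cc$p, cc$ref, list(cc$alt)))
    r$input_index <- i; r
  }))
  vs <- new("VariantSet", tab = tb)
  res <- annotateVariants(b$store, vs, b$registry, hgvs = FALSE)
  for (i in seq_along(cases)) {
    cc <- cases[[i]]
    tx <- b$tx[[cc$txid]]
    o <- termString(naiveAnnotate(tb[i, , drop = FALSE], cc$alt, tx, b$genome))
    sel <- res[res$variant_index == i & res$feature == paste0(cc$txid, ".1"), ]
    e <- if (nrow(sel)) termString(sel$terms[[1L]]) else ""
    expect_identical(e, o,
      info = sprintf("%s pos %d %s>%s", cc$txid, cc$p, cc$ref, cc$alt))
  }
})
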