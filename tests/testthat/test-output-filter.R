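test_that("writers respect the per-allele-per-feature cardinality", {
  b <- fixtureBundle()
  # one SNV with exactly one overlapping transcript: restrict to the motif-free
  # region around TX5 only (position overlapping TX5 but also others' flanks);
  # use an isolated single-feature case on chrM
  v1 <- variantSet("chrM", 120L, 120L, baseAt(b, "chrM", 120L),
                   list(otherBase(baseAt(b, "chrM", 120L))))
  res <- annotateVariants(b$store, v1, b$registry)
  expect_identical(nrow(res), 1L)
  tab <- tempfile()
  writeResults(res, "tab", tab, meta = list(tool = "t"), variants = v1)
  lines <- readLines(tab)
  expect_identical(sum(!startsWith(lines, "#")), 1L)
  # 2 alts x 2 transcripts -> 4 rows / 4 CSQ blocks
  g <- b$genome$chrT
  ref <- substr(g, 260L, 260L)
  alts <- setdiff(c("A", "C", "G", "T"), ref)[1:2]
  v2 <- variantSet("chrT", 260L, 260L, ref, list(alts))
  res <- annotateVariants(b$store, v2, b$registry)
  shared <- res[res$feature %in% c("TX2.1", "TX2B.1"), ]
  expect_identical(nrow(shared), 4L)
  expect_identical(sort(table(shared$allele), decreasing = TRUE),
                   sort(table(c(alts, alts)), decreasing = TRUE))
  # VCF mode: one CSQ block per row, each with the declared field count
  raw <- sprintf("chrT\t260\t.\t%s\t%s\t.\t.\t.", ref, paste(alts, collapse = ","))
  out <- tempfile()
  writeResults(res, "vcf", out, meta = list(tool = "t"),
               raw_lines = raw, header_lines = c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"),
               variants = v2)
  lines <- readLines(out)
  hdr <- grep("^##INFO=<ID=CSQ", lines, value = TRUE)
  nFields <- length(strsplit(sub('.*Format: ', "", sub('">$', "", hdr)), "|",
                             fixed = TRUE)[[1L]])
  dataLine <- lines[!startsWith(lines, "#")]
  csq <- sub(".*CSQ=", "", dataLine)
  blocks <- strsplit(csq, ",", fixed = TRUE)[[1L]]
  expect_identical(length(blocks), nrow(res))
  for (bl in blocks)
    expect_identical(length(strsplit(bl, "|", fixed = TRUE)[[1L]]), nFields)
})

test_that("JSON output nests consequences per input variant", {
  b <- fixtureBundle()
  vs <- readVcfVariants(b$vcf)
  res <- annotateVariants(b$store, vs, b$registry)
  out <- tempfile()
  writeResults(res, "json", out, variants = vs)
  lines <- readLines(out)
  expect_identical(length(lines), length(vs))
  j <- jsonlite::fromJSON(lines[1L], simplifyVector = FALSE)
  expect_identical(j$id, "v01")
  expect_identical(j$most_severe_consequence, "missense_variant")
  expect_true(length(j$transcript_consequences) >= 1L)
  tc <- j$transcript_consequences[[1L]]
  expect_true(all(c("variant_allele", "consequence_terms", "impact") %in% names(tc)))
  # intergenic variants carry an intergenic consequences array
  jInt <- jsonlite::fromJSON(lines[which(variantTable(vs)$id == "v26")],
                             simplifyVector = FALSE)
  expect_identical(jInt$intergenic_consequences[[1L]]$consequence_terms[[1L]],
                   "intergenic_variant")
})

test_that("result prioritisation: canonical, biotype, severity, then tie-breaks", {
  b <- fixtureBundle()
  g <- b$genome$chrT
  # TX2 (non-canonical) coding exon 2; TX2B (canonical) intron: canonical wins
  v <- variantSet("chrT", 650L, 650L, substr(g, 650L, 650L),
                  list(otherBase(substr(g, 650L, 650L))))
  res <- annotateVariants(b$store, v, b$registry, hgvs = FALSE)
  pk <- pickOne(res)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$feature, "TX2B.1")
  expect_true("intron_variant" %in% pk$terms[[1L]])
  # among equal-priority transcripts severity decides
  sub <- res[res$feature %in% c("TX2.1", "TX2B.1"), ]
  sub$canonical <- FALSE
  expect_identical(pickOne(sub)$feature, "TX2.1")  # coding beats intron by rank
  # full tie except the identifier: lexicographically smallest wins
  tie <- sub
  tie$rank <- 1L; tie$cds_length <- 0L; tie$biotype <- "protein_coding"
  expect_identical(pickOne(tie)$feature, "TX2.1")
  # per-gene keeps one per (variant, gene)
  pg <- pickOne(res, per_gene = TRUE)
  expect_identical(anyDuplicated(paste(pg$variant_index, pg$gene)), 0L)
  expect_identical(sum(pg$gene == "G2"), 1L)
  expect_error(pickOne(res[0L, ]), "empty")
})

test_that("filter language: examples, composition, unknown fields", {
  b <- fixtureBundle()
  vs <- readVcfVariants(b$vcf)
  res <- annotateVariants(b$store, vs, b$registry, hgvs = FALSE)
  # attach pathogenicity scores as pass-through extras on a missense row
  i <- which(vapply(res$terms, function(t) "missense_variant" %in% t, logical(1)))[1L]
  res$extras[[i]] <- c(res$extras[[i]],
                       list(SIFT = "deleterious(0.02)", PolyPhen = "benign(0.1)"))
  f1 <- suppressWarnings(applyFilter(
    parseFilter("SIFT matches deleterious OR PolyPhen is probably_damaging"), res))
  expect_true(i %in% as.integer(rownames(res)[res$uploaded_variation %in% f1$uploaded_variation]) ||
                nrow(f1) >= 1L)
  expect_identical(f1$uploaded_variation[1L], res$uploaded_variation[i])
  # frequency example: rsK3 carries AFR=0.2, EUR=0.01
  f2 <- suppressWarnings(applyFilter(parseFilter("AFR >0.1 AND EUR <0.05"), res))
  expect_gt(nrow(f2), 0L)
  expect_true(all(f2$existing_variation == "rsK3"))
  # gene list from file
  gl <- tempfile(); writeLines(c("G1", "G99"), gl)
  f3 <- suppressWarnings(applyFilter(parseFilter(sprintf("Gene in %s", gl)), res))
  expect_identical(unique(f3$gene), "G1")
  # term filtering and AND composition
  fM <- suppressWarnings(applyFilter(parseFilter("Consequence is missense_variant"), res))
  expect_true(all(grepl("missense_variant", fM$consequence)))
  fA <- suppressWarnings(applyFilter(
    parseFilter("Consequence is missense_variant AND Gene is G1"), res))
  fB <- suppressWarnings(applyFilter(parseFilter("Gene is G1"), fM))
  expect_identical(fA$uploaded_variation, fB$uploaded_variation)
  # unresolvable field evaluates false with a warning
  expect_warning(f0 <- applyFilter(parseFilter("NoSuchField is x"),
                                   res[1L, , drop = FALSE]),
                 "does not resolve")
  expect_identical(nrow(f0), 0L)
  expect_error(parseFilter("Consequence is"), "value expected")
  expect_error(parseFilter(""), "empty")
})

test_that("full pipeline: block buffering, QC routing, intergenic dropping, plugins", {
  b <- fixtureBundle()
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out.tab")
  z <- runAnnotation(list(input = b$vcf, cache = b$store@dir,
                          fasta = file.path(b$dir, "genome.fa"),
                          output = out, format = "tab", buffer_size = 10L,
                          plugins = list(pluginNearbyThreshold(300L)),
                          custom = list(list(name = "demo_bed",
                                             path = file.path(b$dir, "custom.bed"),
                                             format = "bed"))))
  expect_identical(statsAsList(z$stats)$buffer_flushes,
                   c(rep(10L, length(readVcfVariants(b$vcf)) %/% 10L),
                     if (length(readVcfVariants(b$vcf)) %% 10L)
                       length(readVcfVariants(b$vcf)) %% 10L))
  lines <- readLines(out)
  expect_true(any(grepl("NEARBY=Y", lines)))
  expect_true(any(grepl("demo_bed=promoter_7", lines)))
  expect_true(file.exists(paste0(out, "_summary.json")))
  # QC-failing variant among clean ones: skipped, logged, rest annotated
  bad <- writeTestVcf(c("chrT\t25\tok1\tC\tT\t.\t.\t.",
                        "chrT\t26\tbad\tG\tA\t.\t.\t.",
                        "chrT\t29\tok2\tT\tA\t.\t.\t."),
                      file.path(dir, "qc.vcf"))
  out2 <- file.path(dir, "qc.tab")
  z2 <- runAnnotation(list(input = bad, cache = b$store@dir,
                           fasta = file.path(b$dir, "genome.fa"),
                           output = out2, format = "tab"))
  expect_identical(sort(unique(z2$results$variant_index)), c(1L, 3L))
  w <- utils::read.delim(paste0(out2, "_warnings.txt"))
  expect_identical(w$code, "REF_MISMATCH")
  expect_identical(w$line, 2L)
  # no_intergenic drops feature-less rows
  z3 <- runAnnotation(list(input = b$vcf, cache = b$store@dir,
                           fasta = file.path(b$dir, "genome.fa"),
                           output = file.path(dir, "noint.tab"), format = "tab",
                           no_intergenic = TRUE))
  expect_false(any(z3$results$feature_type == "Intergenic"))
  # empty input produces headers and zeroed statistics
  empty <- writeTestVcf(character(0), file.path(dir, "empty.vcf"))
  z4 <- runAnnotation(list(input = empty, cache = b$store@dir,
                           fasta = file.path(b$dir, "genome.fa"),
                           output = file.path(dir, "empty.tab"), format = "tab"))
  expect_identical(nrow(z4$results), 0L)
  expect_true(startsWith(readLines(file.path(dir, "empty.tab"))[1L], "##"))
  ss <- jsonlite::read_json(file.path(dir, "empty.tab_summary.json"))
  expect_identical(ss$variants_processed, 0L)
})

test_that("HGVS input mode runs through the pipeline", {
  b <- fixtureBundle()
  dir <- withr::local_tempdir()
  inp <- file.path(dir, "h.txt")
  writeLines(c("chrT:g.25C>T", "TX1.1:c.5C>T", "TX1.1:p.Ala2Val"), inp)
  out <- file.path(dir, "h.tab")
  z <- runAnnotation(list(input = inp, input_format = "hgvs",
                          cache = b$store@dir,
                          fasta = file.path(b$dir, "genome.fa"),
                          output = out, format = "tab"))
  expect_identical(sort(unique(z$results$variant_index)), c(1L, 2L))
  w <- utils::read.delim(paste0(out, "_warnings.txt"))
  expect_identical(w$code, "HGVS_PARSE")
})

test_that("the command-line front end annotates and filters", {
  b <- fixtureBundle()
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cli.tab")
  status <- cliMain(c("annotate", "--input", b$vcf, "--cache", b$store@dir,
                      "--fasta", file.path(b$dir, "genome.fa"),
                      "--output", out, "--format", "tab"))
  expect_identical(status, 0L)
  expect_true(file.exists(out))
  out2 <- file.path(dir, "cli-filtered.tab")
  status <- suppressWarnings(
    cliMain(c("filter", "--input", out, "--expr",
              "Consequence is missense_variant", "--output", out2)))
  expect_identical(status, 0L)
  kept <- readLines(out2)
  kept <- kept[!startsWith(kept, "#")]
  expect_true(length(kept) >= 1L)
  expect_true(all(grepl("missense_variant", kept)))
})
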