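# Shared fixture bundle: one generated genome/annotation/cache per test run,
# memoized across test files.

.fixtureCache <- new.env(parent = emptyenv())

fixtureBundle <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  dir <- file.path(tempdir(), paste0("vcanno-", key))
  unlink(dir, recursive = TRUE)
  fx <- makeFixture(fixtureSpec(seed = seed), dir)
  store <- buildFixtureCache(dir, file.path(dir, "cache"))
  b <- list(dir = dir, fx = fx, store = store, registry = loadRegistry(),
            genome = fx$genome, tx = fx$tx_models,
            vcf = file.path(dir, "variants.vcf"),
            bulk = file.path(dir, "bulk.vcf"))
  .fixtureCache[[key]] <- b
  b
}

snvRow <- function(chrom, p, ref, alt) {
  variantTable(variantSet(chrom, p, p, ref, list(alt)))[1L, , drop = FALSE]
}

baseAt <- function(b, chrom, p) substr(b$genome[[chrom]], p, p)

otherBase <- function(ref) if (ref == "A") "C" else "A"

termString <- function(terms) paste(sort(terms), collapse = ",")

engineTermsFor <- function(res, feature) {
  sel <- res[res$feature == feature, , drop = FALSE]
  if (nrow(sel) == 0L) return("")
  termString(sel$terms[[1L]])
}

# Re-anchor an internal variant back to VCF representation (for the
# internal -> VCF -> internal round trip).
internalToVcfLine <- function(row, genome) {
  ref <- row$ref; alts <- row$alt[[1L]]; pos <- row$start
  if (ref == "-" || any(alts == "-")) {
    anchor <- substr(genome[[row$chrom]], row$start - 1L, row$start - 1L)
    pos <- row$start - 1L
    ref <- paste0(anchor, if (ref == "-") "" else ref)
    alts <- vapply(alts, function(a)
      paste0(anchor, if (a == "-") "" else a), "")
  }
  sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", row$chrom, pos,
          if (is.na(row$id)) "." else row$id, ref, paste(alts, collapse = ","))
}

writeTestVcf <- function(lines, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), path)
  path
}
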