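test_that("parseVariantLabel handles the full label grammar", {
  v <- parseVariantLabel("p.Asn220Asp", "GJA8", "population")
  expect_equal(v$type, "missense")
  expect_equal(v$position, 220L)
  expect_equal(v$ref, "N")
  expect_equal(v$alt, "D")
  expect_equal(v$label, "N220D")

  cases <- list(
    list("N220D",        "missense",      220L, "N", "D"),
    list("p.(Asn220Asp)", "missense",     220L, "N", "D"),
    list("W4*",          "stop_gained",   4L,   "W", "*"),
    list("p.Trp4Ter",    "stop_gained",   4L,   "W", "*"),
    list("*360W",        "stop_lost",     360L, "*", "W"),
    list("p.Ter360Trp",  "stop_lost",     360L, "*", "W"),
    list("M1?",          "start_lost",    1L,   "M", NA_character_),
    list("p.Met1?",      "start_lost",    1L,   "M", NA_character_),
    list("p.Met1Leu",    "start_lost",    1L,   "M", "L"),
    list("S251fs",       "frameshift",    251L, "S", NA_character_),
    list("p.Ser251LeufsTer5", "frameshift", 251L, "S", NA_character_),
    list("K45del",       "inframe_indel", 45L,  "K", NA_character_),
    list("K45_G47del",   "inframe_indel", 45L,  "K", NA_character_),
    list("p.Lys45dup",   "inframe_indel", 45L,  "K", NA_character_),
    list("A30A",         "synonymous",    30L,  "A", "A"))
  for (cs in cases) {
    v <- parseVariantLabel(cs[[1]], "GJA1", "disease")
    expect_equal(v$type, cs[[2]], label = cs[[1]])
    expect_equal(v$position, cs[[3]], label = cs[[1]])
    expect_equal(v$ref, cs[[4]], label = cs[[1]])
    expect_equal(v$alt, cs[[5]], label = cs[[1]])
  }
})

test_that("parseVariantLabel rejects malformed and non-protein labels", {
  expect_error(parseVariantLabel("c.658A>G", "GJA1", "disease"),
               "nucleotide-level")
  expect_error(parseVariantLabel("g.100del", "GJA1", "disease"),
               "nucleotide-level")
  expect_error(parseVariantLabel("banana", "GJA1", "disease"),
               "unparseable")
  expect_error(parseVariantLabel("p.Xyz123Ala", "GJA1", "disease"),
               "non-standard amino-acid code")
  expect_error(parseVariantLabel("p.Ala0Gly", "GJA1", "disease"))
  expect_error(parseVariantLabel("K47_G45del", "GJA1", "disease"),
               "inverted")
  expect_error(parseVariantLabel("*10*", "GJA1", "disease"), "unparseable")
  expect_error(parseVariantLabel("N220D", "GJA1", "disease",
                                 allele_frequency = 2), "0, 1")
})

test_that("three-letter and one-letter forms normalise identically", {
  a <- parseVariantLabel("p.Asn220Asp", "GJA8", "disease")
  b <- parseVariantLabel("N220D", "GJA8", "disease")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("parseVariants deduplicates on (gene, cohort, label)", {
  v <- parseVariants(c("N220D", "p.Asn220Asp", "N220D", "W4*"),
                     "GJA8", "disease")
  expect_equal(nrow(v), 2L)
  ## same label, different cohort or gene, is a distinct record
  v2 <- parseVariants(c("N220D", "N220D"), "GJA8",
                      c("disease", "population"))
  expect_equal(nrow(v2), 2L)
  v3 <- parseVariants(c("N220D", "N220D"), c("GJA8", "GJA1"), "disease")
  expect_equal(nrow(v3), 2L)
  ## dedup is idempotent
  expect_equal(as.data.frame(dedupVariants(v)), as.data.frame(v))
})

test_that("tabulateVariantTypes reproduces direct ratios", {
  labs <- c(paste0("A", 1:87 + 1L, "G"),          # 87 missense
            paste0("A", 101:106, "*"),             # 6 stop gained
            paste0("A", 111:115, "fs"),            # 5 frameshift
            c("A121del", "A122dup"))               # 2 in-frame indels
  v <- parseVariants(labs, "GJA1", "disease")
  expect_equal(nrow(v), 100L)
  tab <- tabulateVariantTypes(v)
  pooled <- tab[tab$gene == "pooled", ]
  expect_equal(pooled$count[pooled$type == "missense"], 87L)
  expect_equal(pooled$percent[pooled$type == "missense"], 87)
  expect_equal(sum(pooled$percent), 100)
  expect_equal(sum(pooled$count), 100L)
})

test_that("dropSynonymous recomputes percentages over the reduced total", {
  labs <- c(paste0("A", 1:59 + 1L, "G"),           # 59 missense
            paste0("A", 71:105, "A"),              # 35 synonymous
            paste0("A", 111:116, "*"))             # 6 stop gained
  v <- parseVariants(labs, "GJA1", "population")
  tab <- tabulateVariantTypes(v, dropSynonymous = TRUE)
  pooled <- tab[tab$gene == "pooled", ]
  expect_equal(pooled$count[pooled$type == "synonymous"], 0L)
  expect_equal(sum(pooled$count), 65L)
  expect_equal(pooled$percent[pooled$type == "missense"], 100 * 59 / 65)
  expect_equal(sum(pooled$percent), 100)
})

test_that("selectMissense filters and is idempotent", {
  v <- parseVariants(c("N220D", "W4*", "A30A", "S251fs"), "GJA1", "disease")
  m <- selectMissense(v)
  expect_equal(nrow(m), 1L)
  expect_true(all(m$type == "missense"))
  expect_equal(as.data.frame(selectMissense(m)), as.data.frame(m))
})

test_that("computeOverlap counts shared positions, variants and identical substitutions", {
  d <- parseVariants(c("A10G", "A10V", "A20G", "A30G"), "GJA1", "disease")
  p <- parseVariants(c("A10G", "A20V", "A40G"), "GJA1", "population")
  ov <- computeOverlap(d, p)
  expect_equal(nrow(ov$sharedPositions), 2L)          # positions 10 and 20
  expect_equal(ov$sharedPositions$position, c(10L, 20L))
  expect_equal(ov$diseaseVariantsAtShared, 3L)        # A10G A10V A20G
  expect_equal(ov$populationVariantsAtShared, 2L)     # A10G A20V
  expect_equal(ov$identicalSubstitutions, 1L)         # A10G
})

test_that("computeOverlap keys on gene, is symmetric in shared positions, and validates input", {
  ## same positions in different genes must not collide
  d <- parseVariants("A10G", "GJA1", "disease")
  p <- parseVariants("A10G", "GJA8", "population")
  ov <- computeOverlap(d, p)
  expect_equal(nrow(ov$sharedPositions), 0L)
  expect_equal(ov$identicalSubstitutions, 0L)

  ## randomized oracle: recount by explicit loops
  set.seed(101)
  for (rep in 1:5) {
    mk <- function(n, cohort) {
      pos <- sample(1:30, n, replace = TRUE)
      alt <- sample(c("G", "V", "L"), n, replace = TRUE)
      dedupVariants(parseVariants(paste0("A", pos, alt), "GJA1", cohort))
    }
    d <- mk(25, "disease"); p <- mk(25, "population")
    ov <- computeOverlap(d, p)
    shared <- intersect(unique(d$position), unique(p$position))
    expect_equal(sort(ov$sharedPositions$position), sort(shared))
    expect_equal(ov$diseaseVariantsAtShared, sum(d$position %in% shared))
    expect_equal(ov$populationVariantsAtShared, sum(p$position %in% shared))
    ident <- length(intersect(paste(d$position, d$alt),
                              paste(p$position, p$alt)))
    expect_equal(ov$identicalSubstitutions, ident)
    ## shared positions are symmetric under swapping the cohorts
    ov2 <- computeOverlap(
      parseVariants(p$label, "GJA1", "disease"),
      parseVariants(d$label, "GJA1", "population"))
    expect_equal(ov2$sharedPositions$position, ov$sharedPositions$position)
  }
  expect_error(computeOverlap(parseVariants("W4*", "GJA1", "disease"),
                              parseVariants("A10G", "GJA1", "population")),
               "missense-only")
})

test_that("variant tables round-trip through TSV", {
  v <- parseVariants(c("N220D", "W4*", "K45del"), "GJA8", "disease",
                     allele_frequencies = c(0.1, NA, NA))
  f <- tempfile(fileext = ".tsv")
  writeVariantTable(v, f)
  d <- utils::read.delim(f)
  expect_equal(d$label, v$label)
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(gene = "GJA8", cohort = "disease",
               hgvs_p = c("p.Asn220Asp", "p.Trp4Ter")),
    f2, sep = "\t", quote = FALSE, row.names = FALSE)
  v2 <- readVariantTable(f2)
  expect_equal(v2$label, c("N220D", "W4*"))
  f3 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(foo = 1), f3, sep = "\t", row.names = FALSE)
  expect_error(readVariantTable(f3), "must have columns")
})

test_that("writeReport serialises tabulations and overlap reports", {
  v <- parseVariants(c("N220D", "W4*"), "GJA1", "disease")
  tab <- tabulateVariantTypes(v)
  fj <- tempfile(fileext = ".json")
  writeReport(tab, fj)
  back <- jsonlite::fromJSON(fj)
  expect_equal(nrow(back), nrow(tab))
  ov <- computeOverlap(selectMissense(v),
                       parseVariants("N220E", "GJA1", "population"))
  ft <- tempfile(fileext = ".tsv")
  writeReport(ov, ft)
  flat <- utils::read.delim(ft)
  expect_equal(flat$value[flat$key == "shared_positions"], 1L)
})
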