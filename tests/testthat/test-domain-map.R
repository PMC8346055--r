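test_that("DomainSegmentation validates contiguity and labels", {
  seg <- smallSeg()
  expect_equal(refLength(seg), 40L)
  expect_equal(length(residueLabels(seg)), 40L)
  expect_equal(residueLabels(seg)[5], "M1")
  expect_error(DomainSegmentation(c("NT", "CT"), c(1L, 12L), c(10L, 40L)),
               "contiguous")
  expect_error(DomainSegmentation(c("NT", "XX"), c(1L, 11L), c(10L, 40L)))
  L <- domainLengths(seg)
  expect_equal(unname(L$partitions["structured"]), 24)
  expect_equal(unname(L$partitions["unstructured"]), 16)
  expect_equal(sum(L$domains), 40)
  expect_equal(unname(L$partitions["pore"] + L$partitions["nonpore"]),
               unname(L$partitions["structured"]))
})

test_that("segmentation round-trips through TSV and JSON", {
  seg <- smallSeg()
  for (ext in c(".tsv", ".json")) {
    f <- tempfile(fileext = ext)
    writeSegmentation(seg, f)
    back <- readSegmentation(f)
    expect_equal(segmentTable(back), segmentTable(seg))
  }
})

test_that("the shipped default segmentation is well-formed", {
  seg <- defaultSegmentation()
  expect_equal(refLength(seg), 440L)
  expect_setequal(segmentTable(seg)$label, domainLabels())
  L <- domainLengths(seg)
  expect_equal(unname(sum(L$domains)), 440)
})

test_that("identical sequences give the identity map at 100% identity", {
  s <- "MGDWSFLGRLLENAQEHSTVIGKVWLTVLFIFRILLL"
  amap <- alignQueryToReference(s, s)
  expect_equal(alignmentMap(amap), seq_len(nchar(s)))
  expect_equal(percentIdentity(amap), 100L)
})

test_that("alignment scores match exhaustive enumeration for short sequences", {
  set.seed(7)
  aa <- aminoAcids()
  for (t in 1:10) {
    q <- paste(sample(aa, sample(2:6, 1), TRUE), collapse = "")
    r <- paste(sample(aa, sample(2:6, 1), TRUE), collapse = "")
    amap <- alignQueryToReference(q, r)
    expect_equal(amap@score, oracleAlignScore(q, r),
                 label = paste(q, "vs", r))
  }
})

test_that("an internal deletion is skipped in the residue map", {
  amap <- residueAlignmentMap("A-CE", "ADCE")
  expect_equal(alignmentMap(amap), c(1L, 3L, 4L))
  ## and an insertion maps to NA
  amap2 <- residueAlignmentMap("ADCE", "A-CE")
  expect_equal(alignmentMap(amap2), c(1L, NA, 2L, 3L))
  ## colinearity is enforced by validity
  expect_error(methods::new("ResidueAlignmentMap", queryId = "q",
                            refId = "r", map = c(3L, 1L), refLength = 3L,
                            score = 0, alignedQuery = "AC",
                            alignedRef = "ACA"))
})

test_that("percentIdentity rounds half-up and honours a reference mask", {
  ## 2 matches in 3 aligned columns -> 66.67 -> 67
  amap <- residueAlignmentMap("ACD", "ACE")
  expect_equal(percentIdentity(amap), 67L)
  ## 1 match in 2 masked columns (positions 2 and 3) -> 50
  expect_equal(percentIdentity(amap, refMask = 2:3), 50L)
  expect_error(percentIdentity(amap, refMask = integer(0)), "empty")
})

test_that("regionIdentity computes identity within structured domains only", {
  seg <- DomainSegmentation(c("M1", "CT"), c(1L, 6L), c(5L, 8L))
  ref <- "ACDEFGHI"
  ## mismatches only at unstructured (CT) positions 6 and 7
  qry <- "ACDEFAGI"
  amap <- residueAlignmentMap(qry, ref)
  expect_equal(regionIdentity(amap, seg), 100L)
  expect_lt(percentIdentity(amap), 100L)
})

test_that("buildDomainMap labels mapped, inserted and flanking residues", {
  seg <- smallSeg()
  L <- refLength(seg)
  ident <- paste(rep("A", L), collapse = "")
  dmap <- buildDomainMap(residueAlignmentMap(ident, ident), seg)
  expect_equal(residueLabels(dmap), residueLabels(seg))
  expect_equal(sum(isStructured(dmap)), 24)
  expect_true(all(is.na(isPore(dmap)[!isStructured(dmap)])))
  expect_equal(sum(isPore(dmap), na.rm = TRUE),
               unname(domainLengths(seg)$partitions["pore"]))

  ## insertion inside CL (after reference residue 15) stays CL
  aq <- paste0(substr(ident, 1, 15), "AA", substr(ident, 16, L))
  ar <- paste0(substr(ident, 1, 15), "--", substr(ident, 16, L))
  dmap2 <- buildDomainMap(residueAlignmentMap(aq, ar), seg)
  expect_equal(residueLabels(dmap2)[16:17], c("CL", "CL"))

  ## insertion at a boundary (between CL 17 and M3 18) takes the
  ## preceding label
  aq <- paste0(substr(ident, 1, 17), "A", substr(ident, 18, L))
  ar <- paste0(substr(ident, 1, 17), "-", substr(ident, 18, L))
  dmap3 <- buildDomainMap(residueAlignmentMap(aq, ar), seg)
  expect_equal(residueLabels(dmap3)[18], "CL")

  ## N-terminal extension -> NT; C-terminal extension -> CT
  aq <- paste0("AAA", ident, "AAAA")
  ar <- paste0("---", ident, "----")
  dmap4 <- buildDomainMap(residueAlignmentMap(aq, ar), seg)
  expect_equal(residueLabels(dmap4)[1:3], rep("NT", 3))
  expect_equal(residueLabels(dmap4)[(L + 4):(L + 7)], rep("CT", 4))
  expect_equal(length(residueLabels(dmap4)), L + 7L)

  ## a reference deletion shifts labels consistently
  aq <- paste0(substr(ident, 1, 4), substr(ident, 8, L))  # drop 5..7 (M1)
  amap <- residueAlignmentMap(
    paste0(substr(ident, 1, 4), "---", substr(ident, 8, L)),
    ident)
  dmap5 <- buildDomainMap(amap, seg)
  expect_equal(length(residueLabels(dmap5)), L - 3L)
  expect_equal(residueLabels(dmap5)[5], "E1")   # query 5 = reference 8

  expect_error(buildDomainMap(residueAlignmentMap("ACD", "ACD"), seg),
               "segmentation covers")
})

test_that("locateVariantDomains annotates and counts, rejecting bad input", {
  seg <- smallSeg()
  ann <- makeAnnotated(c(5, 6, 30), c(2, 15), seg)
  expect_equal(ann$domain, c("M1", "M1", "CT", "NT", "CL"))
  ## NT is structured (and pore-lining); CT and CL are not
  expect_equal(ann$structured, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(ann$pore, c(TRUE, TRUE, NA, TRUE, NA))

  ident <- paste(rep("A", 40), collapse = "")
  dmap <- buildDomainMap(residueAlignmentMap(ident, ident), seg)
  v <- parseVariants("A41G", "TESTG", "disease")
  expect_error(locateVariantDomains(v, dmap), "out of range")
  vb <- parseVariants("W4*", "TESTG", "disease")
  expect_error(locateVariantDomains(vb, dmap), "missense-only")
  cnt <- locateVariantDomains(selectMissense(parseVariants(
    c("A5G", "A6V"), "TESTG", "disease")), dmap)$counts
  expect_equal(unname(cnt$domains["M1"]), 2)
})

test_that("residue annotation is written per residue", {
  seg <- smallSeg()
  ident <- paste(rep("A", 40), collapse = "")
  dmap <- buildDomainMap(residueAlignmentMap(ident, ident), seg)
  f <- tempfile(fileext = ".tsv")
  writeResidueAnnotation(dmap, f, sequence = ident)
  d <- utils::read.delim(f)
  expect_equal(nrow(d), 40L)
  expect_equal(d$domain, residueLabels(dmap))
  expect_equal(unique(d$aa), "A")
})
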