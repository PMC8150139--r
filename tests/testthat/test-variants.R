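loadUtr <- function(bundleName) {
    p <- writeBundle(makeStaticFixtures()[[bundleName]])
    extractSplicedUTR(
        loadTranscripts(p["gtf"], p["fasta"], verbose = FALSE)[[1]],
        p["fasta"])
}

test_that("normalization trims prefix then suffix and advances pos", {
    v <- normalizeVariant("c", 7, "AA", "A")
    expect_identical(v@pos, 8L)
    expect_identical(v@ref, "A")
    expect_identical(v@alt, "")
    expect_identical(variantClass(v), "deletion")

    v <- normalizeVariant("c", 7, "C", "A")
    expect_identical(c(v@pos, 7L), c(7L, 7L))
    expect_identical(variantClass(v), "SNV")

    v <- normalizeVariant("c", 5, "TCG", "TAG")
    expect_identical(v@pos, 6L)
    expect_identical(v@ref, "C")
    expect_identical(v@alt, "A")

    v <- normalizeVariant("c", 7, "A", "AT")
    expect_identical(v@pos, 8L)
    expect_identical(v@ref, "")
    expect_identical(v@alt, "T")
    expect_identical(variantClass(v), "insertion")

    expect_error(normalizeVariant("c", 1, "A", "<DEL>"), "symbolic")
    expect_error(normalizeVariant("c", 1, "A", "A"), "identical")
})

test_that("the small-variant scope cap counts net change and length", {
    expect_true(withinScope(normalizeVariant("c", 1, "ACGTA", "TGCAT")))
    expect_false(withinScope(normalizeVariant("c", 1, "ACGTAC", "TGCATG")))
    expect_false(withinScope(normalizeVariant("c", 1, "ATTTTTT", "A")))
    expect_true(withinScope(normalizeVariant("c", 1, "A", "ATTTTT")))
})

test_that("applyVariant edits the spliced UTR in transcript orientation", {
    utr <- loadUtr("F1_plus_1exon")
    app <- applyVariant(utr, normalizeVariant("chr1", 7, "C", "A"))
    expect_identical(app$altSeq, "GGCACCATGGAAGTAAGGCGGCTTTCCGGC")
    expect_identical(app$editStart, 6L)
    expect_identical(nchar(app$altSeq), 30L)

    ## 1 bp deletion at UTR offset 7 of F2
    utr2 <- loadUtr("F2_plus_1exon")
    app <- applyVariant(utr2, normalizeVariant("chr1", 7, "AA", "A"))
    expect_identical(nchar(app$altSeq), 29L)
    expect_identical(substr(app$altSeq, 1, 13), "GCCATGAATAGCC")
})

test_that("minus-strand alleles are reverse complemented before editing", {
    utr <- loadUtr("F1_minus_1exon")
    ## transcript offset 6 sits at genomic pos 54 on the mirror; C>A in
    ## transcript space is G>T in genomic space
    app <- applyVariant(utr, normalizeVariant("chr1", 54, "G", "T"))
    expect_identical(app$editStart, 6L)
    expect_identical(app$altSeq, "GGCACCATGGAAGTAAGGCGGCTTTCCGGC")
})

test_that("variants outside UTR exons or spanning junctions are rejected", {
    utr <- loadUtr("F1_plus_1exon")
    ## CDS position
    res <- applyVariant(utr, normalizeVariant("chr1", 45, "C", "A"))
    expect_s3_class(res, "uorfNotApplicable")
    ## ref allele mismatch against the genome
    res <- applyVariant(utr, normalizeVariant("chr1", 7, "G", "A"))
    expect_s3_class(res, "uorfNotApplicable")

    utr2 <- loadUtr("F2_plus_2exon")
    ## deletion spanning the splice junction (exon1 ends at genomic 15)
    res <- applyVariant(utr2, normalizeVariant("chr1", 13, "CCGGT", "C"))
    expect_s3_class(res, "uorfNotApplicable")
})
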