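test_that("single-exon transcript loads with the expected spliced 5'UTR", {
    p <- writeBundle(makeStaticFixtures()[["F1_plus_1exon"]])
    txs <- loadTranscripts(p["gtf"], p["fasta"], verbose = FALSE)
    expect_length(txs, 1L)
    tx <- txs[[1]]
    expect_s4_class(tx, "TranscriptModel")
    expect_identical(tx@cdsStart, 31L)
    utr <- extractSplicedUTR(tx, p["fasta"])
    expect_identical(utrSequence(utr), F1_UTR_SEQ)
    expect_identical(utrLength(utr), 30L)
    ## UTR occupies genomic 1-30 (0-based 0-29), strictly increasing
    expect_identical(genomicPositions(utr), 0:29)
    ## CDS context starts at the annotated start codon
    expect_identical(substr(cdsContext(utr), 1, 3), "ATG")
})

test_that("a transcript with no 5'UTR is skipped with a warning", {
    d <- tempfile(); dir.create(d)
    fa <- file.path(d, "g.fa"); gtf <- file.path(d, "g.gtf")
    writeLines(c(">chr1", strrep("ACGT", 15)), fa)
    attrs <- 'gene_id "G"; transcript_id "T1"; gene_name "GN";'
    writeLines(c(
        paste("chr1\ttest\texon\t1\t60\t.\t+\t.", attrs, sep = "\t"),
        paste("chr1\ttest\tCDS\t1\t60\t.\t+\t0", attrs, sep = "\t")), gtf)
    expect_warning(txs <- loadTranscripts(gtf, fa, verbose = FALSE),
                   "length 0")
    expect_length(txs, 0L)
})

test_that("a transcript on a chromosome absent from the FASTA is skipped", {
    d <- tempfile(); dir.create(d)
    fa <- file.path(d, "g.fa"); gtf <- file.path(d, "g.gtf")
    writeLines(c(">chr1", strrep("ACGT", 15)), fa)
    attrs <- 'gene_id "G"; transcript_id "T1"; gene_name "GN";'
    writeLines(c(
        paste("chr9\ttest\texon\t1\t60\t.\t+\t.", attrs, sep = "\t"),
        paste("chr9\ttest\tCDS\t31\t60\t.\t+\t0", attrs, sep = "\t")), gtf)
    expect_warning(txs <- loadTranscripts(gtf, fa, verbose = FALSE),
                   "absent from FASTA")
    expect_length(txs, 0L)
})

test_that("missing input files are fatal", {
    expect_error(loadTranscripts(tempfile(), tempfile()), "not found")
})

test_that("splicing concatenates exonic UTR bases and skips introns", {
    p <- writeBundle(makeStaticFixtures()[["F2_plus_2exon"]])
    txs <- loadTranscripts(p["gtf"], p["fasta"], verbose = FALSE)
    utr <- extractSplicedUTR(txs[[1]], p["fasta"])
    expect_identical(utrSequence(utr), F2_UTR_SEQ)
    ## the intron (genomic 16-25) never contributes positions
    expect_false(any(genomicPositions(utr) %in% 15:24))
    ## intronic position maps to nothing
    expect_identical(genomicToUtrOffset(utr, 17L), NA_integer_)
})

test_that("minus-strand mirrors yield byte-identical spliced UTRs", {
    for (fx in c("F1", "F2")) {
        pp <- writeBundle(makeStaticFixtures()[[paste0(fx, "_plus_1exon")]])
        pm <- writeBundle(makeStaticFixtures()[[paste0(fx, "_minus_1exon")]])
        up <- extractSplicedUTR(
            loadTranscripts(pp["gtf"], pp["fasta"], verbose = FALSE)[[1]],
            pp["fasta"])
        um <- extractSplicedUTR(
            loadTranscripts(pm["gtf"], pm["fasta"], verbose = FALSE)[[1]],
            pm["fasta"])
        expect_identical(utrSequence(um), utrSequence(up))
        expect_identical(substr(cdsContext(um), 1, 12),
                         substr(cdsContext(up), 1, 12))
        ## minus-strand positions are strictly decreasing
        expect_true(all(diff(genomicPositions(um)) < 0))
    }
})

test_that("genomic<->offset mapping round-trips for every UTR base", {
    for (nm in c("F1_plus_1exon", "F2_minus_2exon")) {
        p <- writeBundle(makeStaticFixtures()[[nm]])
        utr <- extractSplicedUTR(
            loadTranscripts(p["gtf"], p["fasta"], verbose = FALSE)[[1]],
            p["fasta"])
        gp <- genomicPositions(utr)
        expect_identical(genomicToUtrOffset(utr, gp),
                         seq_along(gp) - 1L)
    }
    ## position in the CDS is outside the UTR
    p <- writeBundle(makeStaticFixtures()[["F1_plus_1exon"]])
    utr <- extractSplicedUTR(
        loadTranscripts(p["gtf"], p["fasta"], verbose = FALSE)[[1]],
        p["fasta"])
    expect_identical(genomicToUtrOffset(utr, 35L), NA_integer_)
    expect_identical(genomicToUtrOffset(utr, 6L), 6L)
})
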