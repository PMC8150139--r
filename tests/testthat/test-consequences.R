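## Detector-level checks on the hand-verified fixture strings. Edits are
## expressed directly in transcript space via annotateUTREdit.

test_that("uAUG_gained: SNV creating a Strong in-frame oORF", {
    rows <- annotateUTREdit(F1_UTR_SEQ, "ATGGCTGCA", 6L, "C", "A")
    expect_identical(nrow(rows), 1L)
    expect_identical(rows$consequence, "uAUG_gained")
    expect_identical(rows$KozakContext, "ACCATGG")
    expect_identical(rows$KozakStrength, "Strong")
    expect_identical(rows$CapDistanceToStart, 6L)
    expect_identical(rows$StartDistanceToCDS, 24L)
    expect_identical(rows$Type, "inframe_oORF")
    expect_true(is.na(rows$StartDistanceToStop))
    expect_true(is.na(rows$Evidence))   # a new uORF has no prior evidence
    expect_identical(rows$existing_uORFs, 0L)
})

test_that("uAUG_gained: AUG inside inserted bases; no call without new AUG", {
    ## insertion of ATG into an AUG-free UTR
    rows <- annotateUTREdit(F1_UTR_SEQ, "ATGGCT", 10L, "", "ATG")
    expect_identical(rows$consequence, "uAUG_gained")
    expect_identical(rows$CapDistanceToStart, 10L)
    ## SNV that creates no AUG
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 20L, "C", "G")
    expect_identical(nrow(rows), 0L)
})

test_that("an AUG merely shifted by an upstream indel is not gained", {
    ## F2's AUG at offset 3 shifts right under an upstream insertion
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 1L, "", "C")
    expect_false("uAUG_gained" %in% rows$consequence)
})

test_that("uAUG_lost: SNV destroying the uORF start", {
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 4L, "T", "C")
    expect_identical(nrow(rows), 1L)
    expect_identical(rows$consequence, "uAUG_lost")
    expect_identical(rows$KozakContext, "GCCATGA")
    expect_identical(rows$KozakStrength, "Moderate")
    expect_identical(rows$StartDistanceToCDS, 27L)
    expect_identical(rows$StartDistanceToStop, 6L)
    expect_identical(rows$Type, "uORF")
    expect_false(rows$Evidence)
    ## an edit away from the AUG does not lose it
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 20L, "C", "A")
    expect_false("uAUG_lost" %in% rows$consequence)
    ## deletion removing the whole AUG
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 3L, "ATG", "")
    expect_true("uAUG_lost" %in% rows$consequence)
})

test_that("uSTOP_lost: stop destroyed, no alternative stop, frame reported", {
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 10L, "A", "G")
    sl <- rows[rows$consequence == "uSTOP_lost", ]
    expect_identical(nrow(sl), 1L)
    expect_identical(sl$KozakStrength, "Moderate")
    expect_false(sl$AltStop)
    expect_identical(sl$FrameWithCDS, "inFrame")   # (30-3) %% 3 == 0
    expect_false(sl$Evidence)
    expect_true(is.na(sl$Type))
    ## the same SNV also creates an out-of-frame AUG: two consequences
    expect_identical(rows$consequence, c("uAUG_gained", "uSTOP_lost"))
    expect_identical(rows$KozakContext[1], "GAAATGG")
    expect_identical(rows$Type[1], "OutOfFrame_oORF")
})

test_that("uSTOP_lost: alternative downstream in-frame stop is found", {
    ## uORF ATG AAA TAG with a second in-frame TGA downstream in the UTR
    utr <- "CCCATGAAATAGCCCTGACCCCCCC"
    rows <- annotateUTREdit(utr, "ATGGCT", 9L, "T", "C")
    sl <- rows[rows$consequence == "uSTOP_lost", ]
    expect_identical(nrow(sl), 1L)
    expect_true(sl$AltStop)
    ## TGA first base at offset 15; distance = 25 - 15
    expect_identical(sl$AltStopDistanceToCDS, 10L)
    expect_true(is.na(sl$FrameWithCDS))
})

test_that("uSTOP_lost requires the edit to hit the stop codon", {
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 13L, "C", "A")
    expect_false("uSTOP_lost" %in% rows$consequence)
})

test_that("uSTOP_gained: in-frame early stop shortens the uORF", {
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 6L, "A", "T")
    expect_identical(rows$consequence, "uSTOP_gained")
    expect_identical(rows$NewStopDistanceToCDS, 24L)
    expect_identical(rows$StartDistanceToCDS, 27L)
    expect_identical(rows$Type, "uORF")
    expect_identical(rows$KozakStrength, "Moderate")
})

test_that("an out-of-frame stop-like edit is not uSTOP_gained", {
    ## TAA written at offsets 7-9 is out of frame with the AUG at 3
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 7L, "AAT", "TAA")
    expect_false("uSTOP_gained" %in% rows$consequence)
    ## and no call at all on an AUG-free UTR
    rows <- annotateUTREdit(F1_UTR_SEQ, "ATGGCT", 12L, "G", "T")
    expect_identical(nrow(rows), 0L)
})

test_that("uFrameshift: 1 bp deletion turns the uORF out of frame", {
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 7L, "A", "")
    expect_identical(rows$consequence, "uFrameshift")
    expect_identical(rows$Type, "uORF")
    expect_identical(rows$AltType, "OutOfFrame_oORF")
    expect_identical(rows$StartDistanceToCDS, 26L)
    expect_identical(rows$KozakStrength, "Moderate")
})

test_that("in-frame indels and edits outside ORF bodies do not frameshift", {
    ## 3 bp deletion inside the uORF body: multiple of three
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 6L, "AAA", "")
    expect_false("uFrameshift" %in% rows$consequence)
    ## 1 bp insertion upstream of every AUG
    rows <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 1L, "", "C")
    expect_false("uFrameshift" %in% rows$consequence)
})

test_that("one deletion frameshifting two overlapping uORFs gives 2 rows", {
    ## AUGs at 0 and 3 share the TAA at 9; the deletion at offset 7 sits in
    ## both ORF bodies
    utr <- "ATGATGAAATAACCCCCCCCC"
    rows <- annotateUTREdit(utr, "ATGGCT", 7L, "A", "")
    fs <- rows[rows$consequence == "uFrameshift", ]
    expect_identical(nrow(fs), 2L)
    expect_identical(sort(fs$StartDistanceToCDS), c(17L, 20L))
})

test_that("high-impact prioritization keeps oORF-forming and evidenced rows", {
    ## build real rows, then filter
    gained <- annotateUTREdit(F1_UTR_SEQ, "ATGGCT", 6L, "C", "A")
    gained$gene_id <- "G1"
    expect_identical(gained$Type, "inframe_oORF")   # condition A, Strong
    expect_identical(nrow(prioritizeHighImpact(gained, c("G1"))), 1L)
    expect_identical(nrow(prioritizeHighImpact(gained, c("OTHER"))), 0L)
    expect_identical(nrow(prioritizeHighImpact(gained)), 1L)

    ## uAUG_gained forming a plain uORF is dropped under condition A
    u <- "CCCCCCATAAAATAGCCCCCC"
    uorfGain <- annotateUTREdit(u, "ATGGCT", 8L, "A", "G")
    expect_identical(uorfGain$consequence, "uAUG_gained")
    expect_identical(uorfGain$Type, "uORF")
    uorfGain$gene_id <- "G1"
    expect_identical(nrow(prioritizeHighImpact(uorfGain, c("G1"))), 0L)

    ## disrupting row with evidence: kept under condition B
    lost <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 4L, "T", "C",
                            evidenceFn = function(s) s == 3L)
    lost$gene_id <- "G2"
    expect_true(lost$Evidence)
    expect_identical(nrow(prioritizeHighImpact(lost, c("G2"))), 1L)
    ## same row without evidence is dropped (uAUG_lost is not an oORF-former)
    lost2 <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 4L, "T", "C")
    lost2$gene_id <- "G2"
    expect_identical(nrow(prioritizeHighImpact(lost2, c("G2"))), 0L)

    ## uSTOP_lost with no alternative stop forms an oORF: condition A
    sl <- annotateUTREdit(F2_UTR_SEQ, F2_CDS_SEQ, 10L, "A", "G")
    sl$gene_id <- "G3"
    kept <- prioritizeHighImpact(sl, c("G3"))
    expect_true(all(c("uAUG_gained", "uSTOP_lost") %in% kept$consequence))
})

test_that("applying a variant and its exact reversal restores the UTR", {
    set.seed(77)
    bases <- c("A", "C", "G", "T")
    for (i in 1:50) {
        e <- randomUtrEdit()
        alt <- paste0(substr(e$utr, 1, e$offset), e$alt,
                      substr(e$utr, e$offset + nchar(e$ref) + 1,
                             nchar(e$utr)))
        back <- paste0(substr(alt, 1, e$offset), e$ref,
                       substr(alt, e$offset + nchar(e$alt) + 1, nchar(alt)))
        expect_identical(back, e$utr)
    }
})
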