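test_that("findUaugs reports every AUG, ascending", {
    expect_identical(findUaugs("ATGATG"), c(0L, 3L))
    expect_identical(findUaugs("ATGTGATG"), c(0L, 5L))
    expect_identical(findUaugs(F1_UTR_SEQ), integer(0))
    expect_identical(findUaugs("AT"), integer(0))
    ## N can never form an AUG
    expect_identical(findUaugs("ANGATG"), 3L)
})

test_that("scanOrf walks codons and classifies subtypes", {
    ## F2 uORF: ATG AAA TAG
    orf <- scanOrf(3L, F2_UTR_SEQ, F2_CDS_SEQ)
    expect_identical(orf$stopOffset, 9L)
    expect_true(orf$stopInUtr)
    expect_identical(orf$subtype, "uORF")
    ## F1 after C>A at offset 6: no UTR stop, (30-6) %% 3 == 0
    alt <- F1_UTR_SEQ; substr(alt, 7, 7) <- "A"
    orf <- scanOrf(6L, alt, "ATGGCT")
    expect_false(orf$stopInUtr)
    expect_identical(orf$subtype, "inframe_oORF")
    ## forced out-of-frame by the mod-3 rule
    orf <- scanOrf(1L, "CATGAA", "GGGGGG")
    expect_identical(orf$subtype, "OutOfFrame_oORF")
    ## a stop straddling the UTR/CDS junction is not in the UTR
    orf <- scanOrf(0L, "ATGCCCT", "AACCC")
    expect_false(orf$stopInUtr)
    expect_identical(orf$subtype, "OutOfFrame_oORF")
    expect_identical(orf$stopOffset, 6L)  # TAA straddles offset 6-8
    expect_error(scanOrf(1L, "ATGAAA", ""), "no ATG")
})

test_that("kozakAssess applies the -3 purine / +4 G rule with N padding", {
    alt <- F1_UTR_SEQ; substr(alt, 7, 7) <- "A"
    k <- kozakAssess(alt, "ATGGCT", 6L)
    expect_identical(k$context, "ACCATGG")
    expect_identical(k$strength, "Strong")
    k <- kozakAssess(F2_UTR_SEQ, F2_CDS_SEQ, 3L)
    expect_identical(k$context, "GCCATGA")
    expect_identical(k$strength, "Moderate")
    ## cap-proximal AUG: positions before the cap pad with N, which fails
    k <- kozakAssess("ATGCAAAAA", "", 0L)
    expect_identical(k$context, "NNNATGC")
    expect_identical(k$strength, "Weak")
    ## +4 read across the UTR/CDS junction
    k <- kozakAssess("AAAATG", "GCC", 3L)
    expect_identical(k$context, "AAAATGG")
    expect_identical(k$strength, "Strong")
})

test_that("census counts partition AUGs by subtype", {
    cen <- uorfCensus(F2_UTR_SEQ, F2_CDS_SEQ)
    expect_identical(cen@nUorf, 1L)
    expect_identical(cen@nInframeOorf, 0L)
    expect_identical(cen@nOutofframeOorf, 0L)
    cen <- uorfCensus(F1_UTR_SEQ, "ATG")
    expect_identical(cen@nUorf + cen@nInframeOorf + cen@nOutofframeOorf, 0L)
    ## two AUGs sharing one stop still count as two uORFs
    cen <- uorfCensus("ATGATGTAA", "GGG")
    expect_identical(cen@nUorf, 2L)
})

test_that("census matches a brute-force enumeration on random sequences", {
    set.seed(101)
    bases <- c("A", "C", "G", "T")
    stops <- c("TAA", "TAG", "TGA")
    for (i in 1:200) {
        L <- sample(10:300, 1)
        utr <- paste(sample(bases, L, TRUE), collapse = "")
        cds <- paste(sample(bases, 60, TRUE), collapse = "")
        cen <- uorfCensus(utr, cds)
        ## independent count: test every offset for ATG, walk triplets
        nA <- 0L; cnt <- c(uORF = 0L, inf = 0L, oof = 0L)
        for (o in 0:(L - 3)) {
            if (substr(utr, o + 1, o + 3) != "ATG") next
            nA <- nA + 1L
            j <- o; inUtr <- FALSE
            full <- paste0(utr, cds)
            while (j + 3 <= nchar(full)) {
                if (substr(full, j + 1, j + 3) %in% stops) {
                    inUtr <- (j + 3) <= L
                    break
                }
                j <- j + 3
            }
            if (inUtr) cnt["uORF"] <- cnt["uORF"] + 1L
            else if ((L - o) %% 3 == 0) cnt["inf"] <- cnt["inf"] + 1L
            else cnt["oof"] <- cnt["oof"] + 1L
        }
        expect_identical(cen@nUorf, cnt[["uORF"]])
        expect_identical(cen@nInframeOorf, cnt[["inf"]])
        expect_identical(cen@nOutofframeOorf, cnt[["oof"]])
        ## partition and strength trichotomy
        expect_identical(cen@nUorf + cen@nInframeOorf + cen@nOutofframeOorf,
                         nA)
        expect_true(all(cen@records$kozakStrength %in%
                        c("Strong", "Moderate", "Weak")))
    }
})
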