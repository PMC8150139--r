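## Shared fixture plumbing for the suite. Everything is generated in code;
## nothing is read from disk outside tempdir().

F1_UTR_SEQ <- "GGCACCCTGGAAGTAAGGCGGCTTTCCGGC"
F2_UTR_SEQ <- "GCCATGAAATAGCCGGCTTTCCGGCAAGGC"
F2_CDS_SEQ <- "ATGGCTGCATAAGCTGCTGCAGCTGCTTGA"

## write a bundle to a fresh temp dir, return file paths
writeBundle <- function(bundle) {
    d <- tempfile("bundle")
    dir.create(d)
    writeFixtureBundle(bundle, d)
}

## canonical row key for set comparison of annotation tables
rowKeys <- function(df) {
    cols <- names(emptyAnnotations())
    sort(do.call(paste, c(lapply(df[, cols, drop = FALSE], as.character),
                          sep = "~")))
}

## random trimmed UTR edit for engine/oracle equivalence checks;
## returns list(utr, cds, offset, ref, alt)
randomUtrEdit <- function(bases = c("A", "C", "G", "T")) {
    L <- sample(10:300, 1L)
    utr <- paste(sample(bases, L, TRUE), collapse = "")
    cds <- paste(c("ATG", sample(bases, 3L * sample(5:30, 1L), TRUE)),
                 collapse = "")
    type <- sample(c("snv", "mnv", "ins", "del"), 1L,
                   prob = c(.4, .2, .2, .2))
    if (type == "snv") {
        o <- sample(L, 1L) - 1L
        r <- substr(utr, o + 1L, o + 1L)
        a <- sample(setdiff(bases, r), 1L)
    } else if (type == "mnv") {
        n <- sample(2:5, 1L)
        o <- sample(max(L - n, 1L), 1L) - 1L
        r <- substr(utr, o + 1L, o + n)
        repeat {
            a <- paste(sample(bases, nchar(r), TRUE), collapse = "")
            if (a != r &&
                substr(a, 1L, 1L) != substr(r, 1L, 1L) &&
                substr(a, nchar(a), nchar(a)) !=
                    substr(r, nchar(r), nchar(r))) break
        }
    } else if (type == "ins") {
        o <- sample(L - 1L, 1L)
        r <- ""
        a <- paste(sample(bases, sample(1:5, 1L), TRUE), collapse = "")
    } else {
        n <- sample(1:min(5L, L - 1L), 1L)
        o <- sample(L - n, 1L) - 1L
        r <- substr(utr, o + 1L, o + n)
        a <- ""
    }
    list(utr = utr, cds = cds, offset = o, ref = r, alt = a)
}
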