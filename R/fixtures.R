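## Fixture generation: self-consistent mini FASTA + GTF + VCF trios with
## known expected annotations, so the whole tool is testable offline.

## generator-side allele trimmer (prefix first, then suffix), independent of
## the engine's normalizeVariant
.gTrim <- function(pos, ref, alt) {
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
    }
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    list(pos = as.integer(pos), ref = ref, alt = alt)
}

## Build one locus: a transcript (UTR + CDS) laid out on a mini chromosome,
## optionally split by introns, on either strand. `cuts` are transcript
## coordinates (1-based) after which an intron is inserted; intronSeqs must
## have one entry per cut. Returns the genome string, GTF lines and the
## UTR-offset -> 1-based genomic position map.
.buildLocus <- function(chrom, txId, geneId, geneName, utrSeq, cdsSeq,
                        strand = "+", cuts = integer(0),
                        intronSeqs = character(0), flank5 = "",
                        flank3 = "") {
    txSeq <- paste0(utrSeq, cdsSeq)
    Lt <- nchar(txSeq); utrLen <- nchar(utrSeq)
    stopifnot(length(cuts) == length(intronSeqs),
              all(cuts >= 1L & cuts < Lt))
    bounds <- c(0L, sort(cuts), Lt)
    nseg <- length(bounds) - 1L
    gPlus <- nchar(flank5)
    pieces <- flank5
    segStartG <- integer(nseg); segA <- integer(nseg); segB <- integer(nseg)
    for (k in seq_len(nseg)) {
        a <- bounds[k] + 1L; b <- bounds[k + 1L]
        segA[k] <- a; segB[k] <- b
        segStartG[k] <- gPlus + 1L
        pieces <- paste0(pieces, substr(txSeq, a, b))
        gPlus <- gPlus + (b - a + 1L)
        if (k < nseg) {
            pieces <- paste0(pieces, intronSeqs[k])
            gPlus <- gPlus + nchar(intronSeqs[k])
        }
    }
    plusGenome <- paste0(pieces, flank3)
    L <- nchar(plusGenome)
    tx2plus <- function(t) {
        k <- findInterval(t, segA)
        segStartG[k] + (t - segA[k])
    }
    g <- function(t) {          # transcript coord -> genomic 1-based
        gp <- tx2plus(t)
        if (strand == "+") gp else L - gp + 1L
    }
    genomeSeq <- if (strand == "+") plusGenome else .revcomp(plusGenome)

    iv <- function(t1, t2) {    # transcript range -> genomic (start<=end)
        a <- g(t1); b <- g(t2); c(min(a, b), max(a, b))
    }
    attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
        geneId, txId, geneName)
    gtf <- character(0)
    feat <- function(type, t1, t2, frame = ".") {
        x <- iv(t1, t2)
        sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                chrom, type, x[1L], x[2L], strand, frame, attrs)
    }
    for (k in seq_len(nseg))
        gtf <- c(gtf, feat("exon", segA[k], segB[k]))
    ## CDS and start_codon, clipped per exon
    for (k in seq_len(nseg)) {
        a <- max(segA[k], utrLen + 1L); b <- segB[k]
        if (a <= b) gtf <- c(gtf, feat("CDS", a, b, frame = "0"))
    }
    gtf <- c(gtf, feat("start_codon", utrLen + 1L, utrLen + 3L, frame = "0"))
    map <- vapply(seq_len(utrLen), g, integer(1))
    list(chrom = chrom, genomeSeq = genomeSeq, gtf = gtf, map = map,
         strand = strand, utrSeq = utrSeq, cdsSeq = cdsSeq,
         txId = txId, geneId = geneId)
}

## Convert a transcript-space edit (0-based offset, alleles in transcript
## orientation) into a VCF record on the locus genome; indels get the
## conventional left anchor base.
.edit2vcf <- function(locus, offset, refU, altU) {
    nref <- nchar(refU); map <- locus$map
    minus <- locus$strand == "-"
    if (nref > 0L) {
        gpos <- map[offset + seq_len(nref)]
        a <- min(gpos); b <- max(gpos)
        gref <- substr(locus$genomeSeq, a, b)
        galt <- if (minus) .revcomp(altU) else altU
        if (nchar(altU) == 0L) {            # pure deletion: anchor at a-1
            anchor <- substr(locus$genomeSeq, a - 1L, a - 1L)
            list(pos = a - 1L, ref = paste0(anchor, gref), alt = anchor)
        } else {
            list(pos = a, ref = gref, alt = galt)
        }
    } else {                                # pure insertion before `offset`
        gL <- map[offset]; gR <- map[offset + 1L]   # transcript neighbours
        p <- min(gL, gR)
        anchor <- substr(locus$genomeSeq, p, p)
        ins <- if (minus) .revcomp(altU) else altU
        list(pos = p, ref = anchor, alt = paste0(anchor, ins))
    }
}

.vcfText <- function(contigs, lengths, records) {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contigs, lengths),
             paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                 "QUAL", "FILTER", "INFO"),
                               collapse = "\t")))
    paste(c(hdr, records), collapse = "\n")
}

.fastaText <- function(names, seqs) {
    paste(vapply(seq_along(names), function(i)
        paste0(">", names[i], "\n", seqs[i]), character(1)),
        collapse = "\n")
}

## normalized identity + oracle rows for one edit on one locus
.truthFor <- function(locus, vcfrec) {
    tr <- .gTrim(vcfrec$pos, vcfrec$ref, vcfrec$alt)
    minus <- locus$strand == "-"
    nref <- nchar(tr$ref)
    if (nref > 0L) {
        offs <- match(tr$pos + seq_len(nref) - 1L, locus$map) - 1L
        o <- min(offs)
        refU <- if (minus) .revcomp(tr$ref) else tr$ref
        altU <- if (minus) .revcomp(tr$alt) else tr$alt
    } else {
        offL <- match(tr$pos - 1L, locus$map) - 1L
        offR <- match(tr$pos, locus$map) - 1L
        o <- max(offL, offR)
        refU <- ""
        altU <- if (minus) .revcomp(tr$alt) else tr$alt
    }
    stopifnot(!anyNA(o))
    if (nref > 0L) {
        expect <- if (minus) .revcomp(tr$ref) else tr$ref
        stopifnot(substr(locus$utrSeq, o + 1L, o + nref) == expect)
    }
    rows <- oracleAnnotateEdit(locus$utrSeq, locus$cdsSeq, o, refU, altU)
    if (nrow(rows) == 0L) return(emptyAnnotations())
    id <- data.frame(chrom = locus$chrom, pos = tr$pos, ref = tr$ref,
                     alt = tr$alt, transcript_id = locus$txId,
                     gene_id = locus$geneId, stringsAsFactors = FALSE)
    out <- cbind(id[rep(1L, nrow(rows)), , drop = FALSE], rows)
    out$sortStart <- NULL
    rownames(out) <- NULL
    out
}

F1_UTR <- "GGCACCCTGGAAGTAAGGCGGCTTTCCGGC"
F1_CDS <- "ATGGCTGCAGCTGCTGCAGCTGCTGCATAA"
F2_UTR <- "GCCATGAAATAGCCGGCTTTCCGGCAAGGC"
F2_CDS <- "ATGGCTGCATAAGCTGCTGCAGCTGCTTGA"

#' Hand-verified static fixture bundles
#'
#' Builds the two reference fixtures as complete FASTA+GTF+VCF bundles, in
#' plus/minus strand and single/two-exon versions (8 bundles): F1 carries an
#' AUG-free 30 nt 5'UTR with variant V1 (an SNV creating a Strong-Kozak
#' in-frame oORF), F2 carries a 5'UTR with one uORF (ATG-AAA-TAG) and
#' variants V2 (uAUG_lost), V3 (uSTOP_lost, which also creates an
#' out-of-frame uAUG — a two-consequence variant), V4 (uSTOP_gained) and V5
#' (a 1 bp frameshift deletion). Truth rows are hand-derived and frozen;
#' transcript-space fields are identical across the strand and exon-layout
#' versions of each fixture.
#'
#' @return named list of \linkS4class{FixtureBundle} objects.
#' @export
makeStaticFixtures <- function() {
    layouts <- list(
        plus_1exon = list(strand = "+", cuts = integer(0)),
        minus_1exon = list(strand = "-", cuts = integer(0)),
        plus_2exon = list(strand = "+", cuts = 15L),
        minus_2exon = list(strand = "-", cuts = 15L))
    intron <- "GTAAGTCTAG"
    bundles <- list()
    for (fx in c("F1", "F2")) {
        utr <- if (fx == "F1") F1_UTR else F2_UTR
        cds <- if (fx == "F1") F1_CDS else F2_CDS
        vars <- if (fx == "F1") {
            list(V1 = list(offset = 6L, refU = "C", altU = "A"))
        } else {
            list(V2 = list(offset = 4L, refU = "T", altU = "C"),
                 V3 = list(offset = 10L, refU = "A", altU = "G"),
                 V4 = list(offset = 6L, refU = "A", altU = "T"),
                 V5 = list(offset = 7L, refU = "A", altU = ""))
        }
        for (ln in names(layouts)) {
            lay <- layouts[[ln]]
            name <- paste(fx, ln, sep = "_")
            locus <- .buildLocus(
                chrom = "chr1", txId = paste0("TX_", fx),
                geneId = paste0("G_", fx), geneName = paste0("GENE", fx),
                utrSeq = utr, cdsSeq = cds, strand = lay$strand,
                cuts = lay$cuts,
                intronSeqs = rep(intron, length(lay$cuts)))
            recs <- character(0)
            truth <- cbind(variant_label = character(0), emptyAnnotations())
            for (vn in names(vars)) {
                vv <- vars[[vn]]
                vr <- .edit2vcf(locus, vv$offset, vv$refU, vv$altU)
                recs <- c(recs, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                    locus$chrom, vr$pos, vn, vr$ref, vr$alt))
                tr <- .truthFor(locus, vr)
                if (nrow(tr))
                    truth <- rbind(truth, cbind(variant_label = vn, tr))
            }
            ## VCF records must be position-sorted for indexing tools
            ord <- order(as.integer(vapply(strsplit(recs, "\t"),
                                           `[[`, "", 2L)))
            bundles[[name]] <- new("FixtureBundle", name = name,
                fastaText = .fastaText(locus$chrom, locus$genomeSeq),
                gtfText = paste(locus$gtf, collapse = "\n"),
                vcfText = .vcfText(locus$chrom, nchar(locus$genomeSeq),
                                   recs[ord]),
                truthRows = truth, seed = 0L)
        }
    }
    bundles
}

#' Seeded random fixture bundles with oracle-computed truth
#'
#' Generates \code{nTranscripts} random transcripts (5'UTR length 10-300 nt
#' at ~50\% GC, 1-3 exons, random strand, CDS of 10-40 codons) on separate
#' mini chromosomes, then places \code{nVariants} random 1-5 bp variants in
#' their 5'UTRs. Variant construction is class-balanced by rejection
#' sampling — purely uniform drawing under-samples stop-codon edits — so
#' all five consequence classes appear in large bundles. Truth rows are
#' computed by the independent brute-force oracle
#' (\code{\link{oracleAnnotateEdit}}), not by the annotation engine.
#'
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @param nTranscripts,nVariants positive counts.
#' @return a \linkS4class{FixtureBundle}.
#' @export
makeRandomFixture <- function(seed, nTranscripts = 5L, nVariants = 20L) {
    stopifnot(nTranscripts >= 1L, nVariants >= 1L)
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    nonStop <- setdiff(apply(expand.grid(bases, bases, bases), 1L,
                             paste, collapse = ""), STOP_CODONS)
    rseq <- function(n) paste(sample(bases, n, replace = TRUE),
                              collapse = "")
    loci <- vector("list", nTranscripts)
    for (i in seq_len(nTranscripts)) {
        utrLen <- sample(10:300, 1L)
        utr <- rseq(utrLen)
        cds <- paste0("ATG",
            paste(sample(nonStop, sample(8:38, 1L), replace = TRUE),
                  collapse = ""),
            sample(STOP_CODONS, 1L))
        Lt <- utrLen + nchar(cds)
        nex <- sample(1:3, 1L)
        cuts <- integer(0)
        if (nex > 1L) {
            ## avoid splitting the start codon so it stays one GTF feature
            ok <- setdiff(seq_len(Lt - 1L), utrLen + 0:3)
            cuts <- sort(sample(ok, nex - 1L))
        }
        loci[[i]] <- .buildLocus(
            chrom = paste0("chr", i), txId = sprintf("TX%03d", i),
            geneId = sprintf("G%03d", i), geneName = sprintf("GENE%03d", i),
            utrSeq = utr, cdsSeq = cds,
            strand = sample(c("+", "-"), 1L),
            cuts = cuts, intronSeqs = vapply(cuts, function(x)
                rseq(sample(20:80, 1L)), character(1)),
            flank5 = rseq(10L), flank3 = rseq(10L))
    }

    ## exon-block id of each UTR offset (variants must not cross junctions)
    blockOf <- function(locus) {
        d <- c(1L, abs(diff(locus$map)))
        cumsum(d != 1L)
    }
    recs <- character(0)
    truth <- cbind(variant_label = character(0), emptyAnnotations())
    classes <- c("gained", "lost", "stop_lost", "stop_gained", "frameshift",
                 "random")
    for (j in seq_len(nVariants)) {
        target <- classes[(j - 1L) %% length(classes) + 1L]
        ed <- NULL; locus <- NULL
        for (try in 1:40) {
            cand <- loci[[sample(nTranscripts, 1L)]]
            e <- .proposeEdit(cand, target, bases)
            if (is.null(e)) next
            L <- nchar(cand$utrSeq)
            blk <- blockOf(cand)
            if (nchar(e$refU) > 0L) {
                span <- e$offset + seq_len(nchar(e$refU)) - 1L
                if (max(span) > L - 1L) next
                if (length(unique(blk[span + 1L])) > 1L) next
            } else {
                ## insertion: both transcript flanks must share a block
                if (e$offset < 1L || e$offset > L - 1L) next
                if (blk[e$offset] != blk[e$offset + 1L]) next
            }
            ed <- e; locus <- cand
            break
        }
        if (is.null(ed)) next
        vr <- .edit2vcf(locus, ed$offset, ed$refU, ed$altU)
        lab <- sprintf("RV%03d", j)
        recs <- c(recs, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            locus$chrom, vr$pos, lab, vr$ref, vr$alt))
        tr <- .truthFor(locus, vr)
        if (nrow(tr))
            truth <- rbind(truth, cbind(variant_label = lab, tr))
    }
    chroms <- vapply(loci, `[[`, "", "chrom")
    seqs <- vapply(loci, `[[`, "", "genomeSeq")
    ord <- order(match(vapply(strsplit(recs, "\t"), `[[`, "", 1L), chroms),
                 as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 2L)))
    new("FixtureBundle", name = sprintf("random_seed%d", seed),
        fastaText = .fastaText(chroms, seqs),
        gtfText = paste(unlist(lapply(loci, `[[`, "gtf")), collapse = "\n"),
        vcfText = .vcfText(chroms, nchar(seqs), recs[ord]),
        truthRows = truth, seed = as.integer(seed))
}

## propose one transcript-space edit aiming at a consequence class;
## NULL when the locus offers no suitable site
.proposeEdit <- function(locus, target, bases) {
    utr <- locus$utrSeq
    L <- nchar(utr)
    augs <- .oAugs(.oChars(utr)) - 1L            # 0-based
    pick <- function(x) if (length(x)) x[sample.int(length(x), 1L)] else NULL
    subst <- function(o, len, newSeq) {
        refU <- substr(utr, o + 1L, o + len)
        if (refU == newSeq) return(NULL)
        list(offset = o, refU = refU, altU = newSeq)
    }
    if (target == "gained") {
        if (L < 3L) return(NULL)
        subst(sample.int(L - 2L, 1L) - 1L, 3L, "ATG")
    } else if (target == "lost") {
        s <- pick(augs); if (is.null(s)) return(NULL)
        b <- sample(0:2, 1L)
        old <- substr(utr, s + b + 1L, s + b + 1L)
        subst(s + b, 1L, sample(setdiff(bases, old), 1L))
    } else if (target == "stop_lost") {
        orfs <- lapply(augs + 1L, function(i1)
            .oOrf(.oChars(utr), .oChars(locus$cdsSeq), i1))
        us <- which(vapply(orfs, `[[`, "", "subtype") == "uORF")
        k <- pick(us); if (is.null(k)) return(NULL)
        t0 <- orfs[[k]]$stop1 - 1L
        b <- sample(0:2, 1L)
        old <- substr(utr, t0 + b + 1L, t0 + b + 1L)
        cand <- setdiff(bases, old)
        for (nb in sample(cand)) {
            cd <- paste0(substr(utr, t0 + 1L, t0 + 3L))
            substr(cd, b + 1L, b + 1L) <- nb
            if (!cd %in% STOP_CODONS) return(subst(t0 + b, 1L, nb))
        }
        NULL
    } else if (target == "stop_gained") {
        orfs <- lapply(augs + 1L, function(i1)
            .oOrf(.oChars(utr), .oChars(locus$cdsSeq), i1))
        if (!length(orfs)) return(NULL)
        k <- sample.int(length(orfs), 1L)
        s <- augs[k]
        lim <- if (orfs[[k]]$subtype == "uORF") orfs[[k]]$stop1 - 1L
               else L
        if (lim - 3L < s + 3L) return(NULL)
        ks <- seq.int(s + 3L, lim - 3L, by = 3L)
        ks <- ks[ks + 3L <= L]
        p <- pick(ks); if (is.null(p)) return(NULL)
        subst(p, 3L, sample(STOP_CODONS, 1L))
    } else if (target == "frameshift") {
        orfs <- lapply(augs + 1L, function(i1)
            .oOrf(.oChars(utr), .oChars(locus$cdsSeq), i1))
        if (!length(orfs)) return(NULL)
        k <- sample.int(length(orfs), 1L)
        s <- augs[k]
        bodyEnd <- if (orfs[[k]]$inUtr) orfs[[k]]$stop1 + 1L else L - 1L
        if (bodyEnd < s + 3L) return(NULL)
        o <- sample(seq.int(s + 3L, bodyEnd), 1L)
        n <- sample(c(1L, 2L, 4L, 5L), 1L)
        if (stats::runif(1) < 0.5 && o + n - 1L <= min(bodyEnd, L - 1L)) {
            list(offset = o, refU = substr(utr, o + 1L, o + n), altU = "")
        } else {
            list(offset = o, refU = "",
                 altU = paste(sample(bases, n, TRUE), collapse = ""))
        }
    } else {
        o <- sample.int(L, 1L) - 1L
        n <- sample(1:3, 1L)
        if (o + n > L) n <- 1L
        subst(o, n, paste(sample(bases, n, TRUE), collapse = ""))
    }
}

#' Write a fixture bundle's files to a directory
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @param dir output directory (created if needed).
#' @return named character vector with elements \code{fasta}, \code{gtf},
#'   \code{vcf}.
#' @export
writeFixtureBundle <- function(bundle, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(fasta = file.path(dir, paste0(bundle@name, ".fa")),
               gtf = file.path(dir, paste0(bundle@name, ".gtf")),
               vcf = file.path(dir, paste0(bundle@name, ".vcf")))
    writeLines(bundle@fastaText, paths["fasta"])
    writeLines(bundle@gtfText, paths["gtf"])
    writeLines(bundle@vcfText, paths["vcf"])
    paths
}
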