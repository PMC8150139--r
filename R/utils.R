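STOP_CODONS <- c("TAA", "TAG", "TGA")

CONSEQUENCE_LEVELS <- c("uAUG_gained", "uAUG_lost", "uSTOP_lost",
                        "uSTOP_gained", "uFrameshift")

OORF_SUBTYPES <- c("inframe_oORF", "OutOfFrame_oORF")

## reverse complement of a plain character string (N-safe)
.revcomp <- function(x) {
    if (nchar(x) == 0L) return(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Accept a genome as a DNAStringSet, an Rsamtools::FaFile, or a FASTA path.
.asGenome <- function(genome) {
    if (is(genome, "DNAStringSet") || is(genome, "FaFile")) return(genome)
    if (isSingleString(genome)) {
        if (!file.exists(genome))
            stop("genome FASTA not found: ", genome)
        fai <- paste0(genome, ".fai")
        if (file.exists(fai))
            return(Rsamtools::FaFile(genome))
        gx <- Biostrings::readDNAStringSet(genome)
        ## FASTA headers may carry descriptions; keep the first token
        names(gx) <- sub("\\s.*$", "", names(gx))
        return(gx)
    }
    stop("genome must be a DNAStringSet, FaFile or FASTA file path")
}

.genomeSeqnames <- function(genome) {
    if (is(genome, "FaFile")) {
        as.character(GenomicRanges::seqnames(Rsamtools::seqinfo(genome)))
    } else {
        names(genome)
    }
}

## Fetch genome sequence for 1-based [start, end]; uppercased, plus strand.
.fetchSeq <- function(genome, chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    seq <- if (is(genome, "FaFile")) {
        Rsamtools::scanFa(genome, gr)
    } else {
        if (!chrom %in% names(genome))
            stop("chromosome absent from FASTA: ", chrom)
        Biostrings::DNAStringSet(Biostrings::subseq(
            genome[[chrom]], start, end))
    }
    toupper(as.character(seq[[1L]]))
}

.isStop <- function(codon) codon %in% STOP_CODONS

## 0-based substring helpers: sequence offsets follow the package-wide
## convention that offset 0 is the cap-proximal base.
.sub0 <- function(x, from0, len) substr(x, from0 + 1L, from0 + len)

.msg <- function(verbose, ...) if (verbose) message(...)
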