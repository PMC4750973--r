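#' @importClassesFrom S4Vectors DFrame
#' @importFrom BiocGenerics start end width strand
#' @importFrom GenomeInfoDb seqnames seqlevels
NULL

#' @describeIn GeneModels-class gene identifiers.
#' @param x a GeneModels object.
#' @export
geneIds <- function(x) names(x@exons)

#' @describeIn GeneModels-class exon blocks as a named GRangesList.
#' @export
exonBlocks <- function(x) x@exons

#' @describeIn GeneModels-class genomic CDS spans as a named GRanges.
#' @export
cdsSpan <- function(x) x@cds

#' @describeIn GeneModels-class logical vector; TRUE for known genes.
#' @export
isKnown <- function(x) x@known

#' @describeIn GeneModels-class one genomic span per gene (first exon start
#'   to last exon end).
#' @export
geneSpans <- function(x) {
    unlist(range(x@exons), use.names = TRUE)
}

#' @describeIn GeneModels-class introns: the gaps between consecutive exon
#'   blocks, as a named GRangesList (empty element for single-exon genes).
#' @export
intronBlocks <- function(x) {
    GRangesList(lapply(x@exons, function(gr) {
        if (length(gr) < 2L)
            return(GRanges(seqnames = character(),
                           ranges = IRanges(), strand = character()))
        GRanges(seqnames = seqnames(gr)[-1],
                ranges = IRanges(start = end(gr)[-length(gr)] + 1L,
                                 end = start(gr)[-1] - 1L),
                strand = strand(gr)[-1])
    }))
}

setMethod("show", "GeneModels", function(object) {
    n <- length(object@exons)
    cat("GeneModels with ", n, " genes (",
        sum(object@known), " known, ", sum(!object@known), " unknown); ",
        sum(lengths(object@exons)), " exon blocks\n", sep = "")
})

#' @describeIn GeneModels-class number of genes.
#' @export
setMethod("length", "GeneModels", function(x) length(x@exons))

#' @describeIn GeneModels-class subset by gene index or id.
#' @param i index or gene id.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GeneModels", function(x, i, j, ..., drop = FALSE) {
    geneModels(x@exons[i], x@cds[i], x@known[i])
})

#' Per-gene feature blocks (5'UTR, CDS, 3'UTR, intron)
#'
#' Decomposes one gene into strand-aware feature intervals: exonic bases
#' upstream of the CDS in transcription direction are the 5'UTR, exonic
#' bases inside the CDS span are coding, exonic bases downstream are the
#' 3'UTR, and inter-exon gaps are introns.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param gene_id a single gene id.
#' @return A named list of GRanges: \code{utr5}, \code{cds}, \code{utr3},
#'   \code{intron}.
#' @export
featureBlocks <- function(models, gene_id) {
    fc <- featureCoords(models, gene_id)
    chrom <- fc$chrom
    asGR <- function(m) {
        GRanges(seqnames = rep(chrom, nrow(m)),
                ranges = IRanges(start = m[, 1], end = m[, 2]))
    }
    list(utr5 = asGR(fc$utr5), cds = asGR(fc$cds), utr3 = asGR(fc$utr3),
         intron = asGR(fc$intron))
}

## plain-integer feature decomposition of one gene; [start, end] matrices.
## Avoids GRanges arithmetic so per-tag classification stays cheap.
featureCoords <- function(models, gene_id) {
    exn <- models@exons[[gene_id]]
    i <- match(gene_id, names(models@cds))
    cs <- start(models@cds)[i]; ce <- end(models@cds)[i]
    es <- start(exn); ee <- end(exn)
    minus <- as.character(strand(exn))[1] == "-"
    clip <- function(s, e) {
        keep <- s <= e
        cbind(s[keep], e[keep], deparse.level = 0)
    }
    cds <- clip(pmax(es, cs), pmin(ee, ce))
    left <- clip(es, pmin(ee, cs - 1L))
    right <- clip(pmax(es, ce + 1L), ee)
    n <- length(es)
    intron <- if (n > 1L) clip(ee[-n] + 1L, es[-1] - 1L)
              else cbind(integer(0), integer(0))
    list(chrom = as.character(seqnames(exn))[1], minus = minus,
         utr5 = if (minus) right else left,
         cds = cds,
         utr3 = if (minus) left else right,
         intron = intron)
}

## total overlap (nt) of the single interval [qs, qe] with interval rows m
coordOverlap <- function(qs, qe, m) {
    if (nrow(m) == 0L) return(0L)
    sum(pmax(0L, pmin(qe, m[, 2]) - pmax(qs, m[, 1]) + 1L))
}

#' Write and read gene models as BED12
#'
#' BED12 blocks carry the exon structure, thickStart/thickEnd the CDS span,
#' and the score column the known/unknown flag (1 = known, 0 = unknown;
#' BED has no dedicated field for annotation status). Coordinates on disk
#' are 0-based half-open per the BED convention; in memory everything is a
#' 1-based GRanges.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param path output file.
#' @return \code{writeGeneModelsBED} returns \code{path} invisibly;
#'   \code{readGeneModelsBED} returns a \linkS4class{GeneModels}.
#' @export
writeGeneModelsBED <- function(models, path) {
    exn <- models@exons
    spans <- geneSpans(models)
    lines <- vapply(seq_along(exn), function(i) {
        gr <- exn[[i]]
        chromStart <- start(spans)[i] - 1L
        paste(as.character(seqnames(gr))[1],
              chromStart,
              end(spans)[i],
              names(exn)[i],
              as.integer(models@known[i]),
              as.character(strand(gr))[1],
              start(models@cds)[i] - 1L,
              end(models@cds)[i],
              "0",
              length(gr),
              paste0(paste(width(gr), collapse = ","), ","),
              paste0(paste(start(gr) - 1L - chromStart, collapse = ","), ","),
              sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGeneModelsBED
#' @export
readGeneModelsBED <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
    blocks <- gr$blocks
    exons <- GRangesList(lapply(seq_along(gr), function(i) {
        b <- IRanges::shift(blocks[[i]], start(gr)[i] - 1L)
        GRanges(seqnames = rep(seqnames(gr)[i], length(b)), ranges = b,
                strand = rep(strand(gr)[i], length(b)))
    }))
    names(exons) <- ids
    cds <- GRanges(seqnames = seqnames(gr),
                   ranges = IRanges(start = start(gr$thick),
                                    end = end(gr$thick)),
                   strand = strand(gr))
    names(cds) <- ids
    geneModels(exons, cds, stats::setNames(gr$score == 1, ids))
}

#' Write gene models as GTF
#'
#' Emits one \code{exon} feature per exon block and one \code{CDS} feature
#' per exonic piece of the CDS span, with \code{gene_id}, \code{transcript_id}
#' and a \code{gene_status} attribute ("known"/"unknown"). GTF coordinates
#' are 1-based inclusive.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelsGTF <- function(models, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(models@exons)) {
        id <- names(models@exons)[i]
        status <- if (models@known[i]) "known" else "unknown"
        attrs <- sprintf(
            'gene_id "%s"; transcript_id "%s.t1"; gene_status "%s";',
            id, id, status)
        exn <- models@exons[[i]]
        for (j in seq_along(exn)) {
            writeLines(paste(as.character(seqnames(exn))[j], "clipscape",
                             "exon", start(exn)[j], end(exn)[j], ".",
                             as.character(strand(exn))[j], ".", attrs,
                             sep = "\t"), con)
        }
        fb <- featureBlocks(models, id)
        cdsp <- fb$cds
        for (j in seq_along(cdsp)) {
            writeLines(paste(as.character(seqnames(exn))[1], "clipscape",
                             "CDS", start(cdsp)[j], end(cdsp)[j], ".",
                             as.character(strand(exn))[1], "0", attrs,
                             sep = "\t"), con)
        }
    }
    invisible(path)
}
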