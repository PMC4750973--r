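#' @importFrom GenomicRanges findOverlaps pintersect granges
#' @importFrom S4Vectors queryHits subjectHits
NULL

overlapWidth <- function(gr, features) {
    if (length(features) == 0L) return(0L)
    coordOverlap(start(gr), end(gr),
                 cbind(start(features), end(features)))
}

#' Assign a uniquely mapped tag to its gene context
#'
#' Overlap with any gene span assigns the tag to that gene; known genes
#' beat unknown ones, remaining ties go to the larger overlap and then the
#' lexicographically smaller gene id. Tags overlapping no gene are
#' intergenic. Within-gene tags are subclassified by
#' \code{\link{classifyWithinGene}}.
#'
#' @param alignments GRanges of unique tag placements (with \code{tag_id}
#'   metadata), or the \code{DataFrame} from \code{\link{mapTagsExact}}.
#' @param models a \linkS4class{GeneModels}.
#' @return data.frame with one row per tag: \code{tag_id}, \code{category}
#'   (intergenic, unknown_gene, intron, utr5, cds, utr3), \code{gene_id}
#'   (NA for intergenic), \code{overlap_fraction}.
#' @export
assignGeneContext <- function(alignments, models) {
    if (!is(alignments, "GRanges"))
        alignments <- alignmentsAsGRanges(alignments)
    spans <- geneSpans(models)
    if (!all(as.character(seqnames(alignments)) %in%
             seqlevels(GRanges(seqnames(spans), IRanges(1, 1)))) &&
        length(alignments) > 0L) {
        miss <- setdiff(as.character(seqnames(alignments)),
                        as.character(seqnames(spans)))
        if (length(miss))
            stop("chromosome absent from annotation: ",
                 paste(miss, collapse = ", "))
    }
    ov <- findOverlaps(alignments, spans, ignore.strand = TRUE)
    res <- data.frame(
        tag_id = if (!is.null(mcols(alignments)$tag_id))
                     mcols(alignments)$tag_id
                 else sprintf("tag%04d", seq_along(alignments)),
        category = rep("intergenic", length(alignments)),
        gene_id = rep(NA_character_, length(alignments)),
        overlap_fraction = rep(NA_real_, length(alignments)),
        stringsAsFactors = FALSE)
    qs <- start(alignments); qe <- end(alignments)
    ss <- start(spans); se <- end(spans)
    known_all <- isKnown(models)
    fc_cache <- new.env(parent = emptyenv())
    hitsq <- queryHits(ov); hitss <- subjectHits(ov)
    for (i in unique(hitsq)) {
        genes <- hitss[hitsq == i]
        ids <- names(spans)[genes]
        known <- known_all[ids]
        ovw <- pmin(qe[i], se[genes]) - pmax(qs[i], ss[genes]) + 1L
        ord <- order(!known, -ovw, ids)
        pick <- ids[ord[1]]
        res$gene_id[i] <- pick
        res$overlap_fraction[i] <- ovw[ord[1]] / (qe[i] - qs[i] + 1L)
        if (!known_all[pick]) {
            res$category[i] <- "unknown_gene"
        } else {
            fc <- get0(pick, envir = fc_cache)
            if (is.null(fc)) {
                fc <- featureCoords(models, pick)
                assign(pick, fc, envir = fc_cache)
            }
            res$category[i] <- majorityFeature(qs[i], qe[i], fc)
        }
    }
    res
}

majorityFeature <- function(qs, qe, fc) {
    w <- c(cds = coordOverlap(qs, qe, fc$cds),
           intron = coordOverlap(qs, qe, fc$intron),
           utr5 = coordOverlap(qs, qe, fc$utr5),
           utr3 = coordOverlap(qs, qe, fc$utr3))
    if (sum(w) == 0L) stop("tag does not overlap the gene body")
    names(w)[which.max(w)]     # ties: first of cds > intron > utr5 > utr3
}

#' Subclassify a tag within one gene
#'
#' Labels every overlapped base as 5'UTR, CDS, 3'UTR or intron
#' (strand-aware: the 5'UTR is 5' in transcription direction) and applies a
#' majority-overlap rule; ties are broken toward \code{cds}, then
#' \code{intron}, then the UTRs — so a tag straddling an exon/intron
#' boundary goes to whichever feature holds more of its bases.
#'
#' @param alignment a single-range GRanges (or 1-row alignment DataFrame).
#' @param models a \linkS4class{GeneModels}.
#' @param gene_id the gene to classify against.
#' @return one of \code{"utr5"}, \code{"cds"}, \code{"utr3"},
#'   \code{"intron"}.
#' @export
classifyWithinGene <- function(alignment, models, gene_id) {
    if (!is(alignment, "GRanges"))
        alignment <- alignmentsAsGRanges(alignment)
    stopifnot(length(alignment) == 1L)
    majorityFeature(start(alignment), end(alignment),
                    featureCoords(models, gene_id))
}

#' Category fractions over within-gene tags
#'
#' @param assignments data.frame from \code{\link{assignGeneContext}}.
#' @param categories which categories define the denominator (default: the
#'   within-known-gene features).
#' @return named numeric vector of fractions summing to 1.
#' @examples
#' df <- data.frame(category = c("intron", "intron", "intron", "cds"))
#' categoryFractions(df)
#' @export
categoryFractions <- function(assignments,
                              categories = c("intron", "utr5", "cds",
                                             "utr3")) {
    x <- assignments$category[assignments$category %in% categories]
    if (length(x) == 0L)
        return(setNames(rep(NA_real_, length(categories)), categories))
    tab <- table(factor(x, levels = categories))
    setNames(as.numeric(tab) / length(x), categories)
}

GENETIC_STOPS <- c("UAA", "UAG", "UGA")

codonStops <- function(rna, cds_offset) {
    ## 1-based codon indices (from the CDS start) of stop codons
    n_codons <- (nchar(rna) - cds_offset + 1L) %/% 3L
    if (n_codons < 1L) return(integer(0))
    starts <- cds_offset + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(rna, starts, starts + 2L)
    which(codons %in% GENETIC_STOPS)
}

#' Detect a premature stop codon introduced by an alternative exon
#'
#' Translates the inclusion and skip isoforms in the reading frame given by
#' the CDS start offset and reports the first in-frame stop codon present
#' in the inclusion isoform at a codon position where the skip isoform has
#' none — the signature by which an alternative exon introduces a premature
#' termination codon (PTC) and can route a transcript to nonsense-mediated
#' decay. Frame preservation holds exactly when the exon length is a
#' multiple of 3. No 50-nt junction rule is applied; the codon index is
#' reported so callers can apply any NMD rule they favour.
#'
#' @param skip_seq transcript sequence without the alternative exon
#'   (RNA or DNA alphabet).
#' @param exon_seq the alternative exon sequence.
#' @param exon_insert_pos 1-based position in \code{skip_seq} before which
#'   the exon is inserted.
#' @param cds_offset 1-based position of the first CDS base in
#'   \code{skip_seq}.
#' @return list with \code{stop_found}, \code{stop_codon_index} (1-based
#'   codon number from the CDS start, NA when none), and
#'   \code{frame_preserved} (TRUE iff exon length \%\% 3 == 0).
#' @examples
#' detectPrematureStop(paste(rep("GCU", 40), collapse = ""),
#'                     exon_seq = "UAA", exon_insert_pos = 31,
#'                     cds_offset = 1)
#' @export
detectPrematureStop <- function(skip_seq, exon_seq, exon_insert_pos,
                                cds_offset) {
    skip <- dnaToRna(skip_seq)
    exon <- dnaToRna(exon_seq)
    if (cds_offset < 1L || cds_offset > nchar(skip))
        stop("cds_offset must fall within the transcript")
    if (nchar(exon) < 1L) stop("alternative exon must be non-empty")
    if (exon_insert_pos < 1L || exon_insert_pos > nchar(skip) + 1L)
        stop("exon_insert_pos outside the transcript")
    incl <- paste0(substr(skip, 1L, exon_insert_pos - 1L), exon,
                   substr(skip, exon_insert_pos, nchar(skip)))
    stops_incl <- codonStops(incl, cds_offset)
    stops_skip <- codonStops(skip, cds_offset)
    new_stops <- setdiff(stops_incl, stops_skip)
    first_new <- if (length(stops_incl) == 0L) NA_integer_
                 else min(stops_incl)
    ## a stop counts as introduced when the inclusion isoform terminates at
    ## a codon where the skip isoform reads through
    premature <- length(new_stops) > 0L &&
        (length(stops_skip) == 0L || min(new_stops) < min(stops_skip))
    list(stop_found = premature,
         stop_codon_index = if (premature) min(new_stops) else NA_integer_,
         frame_preserved = nchar(exon) %% 3L == 0L)
}

#' Virtual RT-PCR product sizes across isoforms
#'
#' Computes the amplicon length each isoform would yield for a primer pair
#' in flanking exons: the count of exonic nucleotides between the two
#' primers' 5' ends, inclusive. For an alternative-exon event the inclusion
#' product exceeds the skip product by exactly the exon length.
#'
#' @param isoforms named list of GRangesList elements or GRanges, each the
#'   exon blocks of one isoform (same chromosome, plus-strand genomic
#'   coordinates).
#' @param fwd_5p,rev_5p genomic positions (1-based) of the forward and
#'   reverse primer 5' ends; the forward 5' end must lie upstream. Both
#'   must fall in exons of every isoform.
#' @return named integer vector of product sizes (bp), one per isoform.
#' @export
rtpcrProductSizes <- function(isoforms, fwd_5p, rev_5p) {
    if (fwd_5p >= rev_5p)
        stop("forward primer 5' end must lie upstream of the reverse")
    amplicon <- GRanges(seqnames = "amp",
                        ranges = IRanges(fwd_5p, rev_5p))
    vapply(isoforms, function(exn) {
        if (!is(exn, "GRanges")) exn <- unlist(exn)
        exr <- GRanges(seqnames = "amp",
                       ranges = IRanges(start(exn), end(exn)))
        inside <- function(p) any(p >= start(exn) & p <= end(exn))
        if (!inside(fwd_5p) || !inside(rev_5p))
            stop("primer position not contained in any exon of an isoform")
        ov <- GenomicRanges::intersect(amplicon, exr)
        as.integer(sum(width(ov)))
    }, integer(1))
}
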