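## Shared fixtures: small, fast simulation configs and hand-built gene
## models, plus independent brute-force oracles used against the package's
## interval logic.

smallConfig <- function(seed = 1L, ...) {
    args <- list(seed = seed, chrom_length = 200000L, n_genes = 12L,
                 intron_median = 800, intron_large_cutoff = 4000,
                 intron_large_frac = 0.12, n_sites = 15L, n_clones = 120L)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

## one hand-built gene as a GeneModels object
mkModels <- function(genes) {
    exons <- GenomicRanges::GRangesList(lapply(genes, function(g) {
        GenomicRanges::GRanges(
            seqnames = g$chrom %||% "chr1",
            ranges = IRanges::IRanges(start = g$exon_starts,
                                      end = g$exon_ends),
            strand = g$strand %||% "+")
    }))
    names(exons) <- vapply(genes, `[[`, character(1), "id")
    cds <- GenomicRanges::GRanges(
        seqnames = vapply(genes, function(g) g$chrom %||% "chr1",
                          character(1)),
        ranges = IRanges::IRanges(
            start = vapply(genes, `[[`, numeric(1), "cds_start"),
            end = vapply(genes, `[[`, numeric(1), "cds_end")),
        strand = vapply(genes, function(g) g$strand %||% "+",
                        character(1)))
    names(cds) <- names(exons)
    known <- vapply(genes, function(g) isTRUE(g$known %||% TRUE),
                    logical(1))
    geneModels(exons, cds, stats::setNames(known, names(exons)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent per-base label: feature of a single genomic position within
## one gene (exon membership + CDS span + strand give the UTR side)
oracleBaseLabel <- function(pos, models, id) {
    exn <- exonBlocks(models)[[id]]
    cds <- cdsSpan(models)[id]
    minus <- as.character(BiocGenerics::strand(exn))[1] == "-"
    es <- BiocGenerics::start(exn); ee <- BiocGenerics::end(exn)
    if (pos < min(es) || pos > max(ee)) return(NA_character_)
    if (!any(pos >= es & pos <= ee)) return("intron")
    if (pos >= BiocGenerics::start(cds) && pos <= BiocGenerics::end(cds))
        return("cds")
    if (pos < BiocGenerics::start(cds)) {
        if (minus) "utr3" else "utr5"
    } else {
        if (minus) "utr5" else "utr3"
    }
}

## brute-force tag assignment: every overlapping gene, known-beats-unknown,
## then larger overlap, then gene id; majority per-base label with ties
## toward cds then intron
oracleAssign <- function(tag_start, tag_end, models) {
    ids <- geneIds(models)
    spans <- geneSpans(models)
    ov <- pmin(tag_end, BiocGenerics::end(spans)) -
        pmax(tag_start, BiocGenerics::start(spans)) + 1
    cand <- which(ov > 0)
    if (length(cand) == 0L)
        return(list(category = "intergenic", gene_id = NA_character_))
    kn <- isKnown(models)[ids[cand]]
    ord <- order(!kn, -ov[cand], ids[cand])
    pick <- ids[cand][ord[1]]
    if (!isKnown(models)[pick])
        return(list(category = "unknown_gene", gene_id = pick))
    exn <- exonBlocks(models)[[pick]]
    cds <- cdsSpan(models)[pick]
    es <- BiocGenerics::start(exn); ee <- BiocGenerics::end(exn)
    cs <- BiocGenerics::start(cds); ce <- BiocGenerics::end(cds)
    minus <- as.character(BiocGenerics::strand(exn))[1] == "-"
    pos <- max(tag_start, min(es)):min(tag_end, max(ee))
    inExon <- vapply(pos, function(p) any(p >= es & p <= ee), logical(1))
    labs <- ifelse(!inExon, "intron",
            ifelse(pos >= cs & pos <= ce, "cds",
            ifelse(pos < cs, if (minus) "utr3" else "utr5",
                   if (minus) "utr5" else "utr3")))
    cnt <- c(cds = sum(labs == "cds"),
             intron = sum(labs == "intron"),
             utr5 = sum(labs == "utr5"),
             utr3 = sum(labs == "utr3"))
    list(category = names(cnt)[which.max(cnt)], gene_id = pick)
}

## naive all-positions substring scan of both strands
oracleScan <- function(tag, genome) {
    hits <- 0L
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tag)))
    for (ch in names(genome)) {
        s <- as.character(genome[[ch]])
        n <- nchar(s); m <- nchar(tag)
        for (pos in seq_len(n - m + 1L)) {
            sub <- substr(s, pos, pos + m - 1L)
            if (sub == tag) hits <- hits + 1L
            if (sub == rc) hits <- hits + 1L
        }
    }
    hits
}

## flip every gene's strand, keeping coordinates
flipStrands <- function(models) {
    exn <- exonBlocks(models)
    flipped <- GenomicRanges::GRangesList(lapply(exn, function(gr) {
        BiocGenerics::strand(gr) <-
            ifelse(as.character(BiocGenerics::strand(gr)) == "+", "-", "+")
        gr
    }))
    names(flipped) <- names(exn)
    cds <- cdsSpan(models)
    BiocGenerics::strand(cds) <-
        ifelse(as.character(BiocGenerics::strand(cds)) == "+", "-", "+")
    geneModels(flipped, cds, isKnown(models))
}

## random tag placements wholly inside gene spans or introns
randomTagsInRanges <- function(gr, n, tag_len = 30L) {
    gr <- gr[BiocGenerics::width(gr) > tag_len + 2L]
    idx <- sample(seq_along(gr), n, replace = TRUE)
    starts <- vapply(idx, function(j) {
        lo <- BiocGenerics::start(gr)[j]
        hi <- BiocGenerics::end(gr)[j] - tag_len + 1L
        sample(seq(lo, hi), 1L)
    }, numeric(1))
    out <- GenomicRanges::GRanges(
        seqnames = as.character(GenomeInfoDb::seqnames(gr))[idx],
        ranges = IRanges::IRanges(start = starts, width = tag_len),
        strand = "+")
    S4Vectors::mcols(out)$tag_id <- sprintf("rt%04d", seq_len(n))
    out
}
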