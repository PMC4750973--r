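## a compact two-gene annotation used across blocks: plus-strand g1 with
## three exons, minus-strand g2 with two, one unknown gene g3
twoGeneModels <- function() {
    mkModels(list(
        list(id = "g1", exon_starts = c(1001, 2001, 3001),
             exon_ends = c(1200, 2200, 3400),
             cds_start = 1101, cds_end = 3200, strand = "+"),
        list(id = "g2", exon_starts = c(6001, 8001),
             exon_ends = c(6300, 8400),
             cds_start = 6101, cds_end = 8300, strand = "-"),
        list(id = "g3", exon_starts = c(10001, 10501),
             exon_ends = c(10100, 10700),
             cds_start = 10001, cds_end = 10700, known = FALSE)))
}

tagAt <- function(start, end, id = "t1") {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                 strand = "+")
    S4Vectors::mcols(gr)$tag_id <- id
    gr
}

test_that("gene context assignment follows containment and known/unknown rules", {
    m <- twoGeneModels()
    ## wholly inside g1's first intron
    a <- assignGeneContext(tagAt(1500, 1530), m)
    expect_equal(a$category, "intron")
    expect_equal(a$gene_id, "g1")
    ## outside every gene
    expect_equal(assignGeneContext(tagAt(5000, 5030), m)$category,
                 "intergenic")
    ## inside the unknown gene
    u <- assignGeneContext(tagAt(10050, 10080), m)
    expect_equal(u$category, "unknown_gene")
    expect_equal(u$gene_id, "g3")
})

test_that("within-gene classification is strand-aware and majority-based", {
    m <- twoGeneModels()
    ## exonic bases upstream of the CDS on + strand: 5'UTR
    expect_equal(assignGeneContext(tagAt(1010, 1080), m)$category, "utr5")
    ## the same genomic layout on the - strand gene is a 3'UTR
    expect_equal(assignGeneContext(tagAt(6010, 6080), m)$category, "utr3")
    ## inside CDS
    expect_equal(assignGeneContext(tagAt(1110, 1150), m)$category, "cds")
    ## straddling exon/intron with 60% intronic bases -> intron
    ## exon g1 ends at 1200; tag 1181..1230 has 20 exonic, 30 intronic
    expect_equal(assignGeneContext(tagAt(1181, 1230), m)$category,
                 "intron")
    ## and with the majority exonic (CDS) -> cds
    expect_equal(assignGeneContext(tagAt(1161, 1210), m)$category, "cds")
})

test_that("strand flip swaps the UTRs and preserves intron/cds", {
    m <- twoGeneModels()
    mf <- flipStrands(m)
    tags <- list(tagAt(1010, 1080), tagAt(1110, 1150), tagAt(1500, 1530),
                 tagAt(3250, 3350))
    for (tg in tags) {
        c1 <- assignGeneContext(tg, m)$category
        c2 <- assignGeneContext(tg, mf)$category
        swap <- c(utr5 = "utr3", utr3 = "utr5", cds = "cds",
                  intron = "intron")
        expect_equal(c2, unname(swap[c1]))
    }
})

test_that("assignments agree with the per-base oracle on simulated tags", {
    cfg <- smallConfig(seed = 41, n_genes = 10L)
    g <- generateGenome(cfg)
    m <- generateGeneModels(g, cfg)
    set.seed(41)
    ## tags across gene bodies and random positions
    spans <- geneSpans(m)
    genic <- randomTagsInRanges(spans, 120, tag_len = 30L)
    rnd_start <- sample(cfg@chrom_length - 40L, 60)
    rnd <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(rnd_start, width = 30),
                                  strand = "+")
    S4Vectors::mcols(rnd)$tag_id <- sprintf("rnd%03d", seq_along(rnd))
    tags <- c(genic, rnd)
    got <- assignGeneContext(tags, m)
    for (i in seq_along(tags)) {
        oracle <- oracleAssign(BiocGenerics::start(tags)[i],
                               BiocGenerics::end(tags)[i], m)
        expect_equal(got$category[i], oracle$category)
        if (!is.na(oracle$gene_id))
            expect_equal(got$gene_id[i], oracle$gene_id)
    }
})

test_that("category fractions mirror tag composition", {
    df <- data.frame(category = c("intron", "intron", "intron", "cds"))
    fr <- categoryFractions(df)
    expect_equal(unname(fr["intron"]), 0.75)
    expect_equal(sum(fr), 1)
    one <- categoryFractions(data.frame(category = "utr3"))
    expect_equal(unname(one["utr3"]), 1)
})

test_that("premature stop detection translates the inclusion isoform", {
    ## a clean CDS of 40 alanine codons, stop-free
    skip <- paste(rep("GCU", 40), collapse = "")
    ## an in-frame UAA inserted at a codon boundary is found at its codon
    res <- detectPrematureStop(skip, "UAA", exon_insert_pos = 31,
                               cds_offset = 1)
    expect_true(res$stop_found)
    expect_equal(res$stop_codon_index, 11)
    expect_true(res$frame_preserved)  # 3 nt
    ## an 84-nt exon preserves frame
    set.seed(51)
    exon84 <- paste(rep("GCA", 28), collapse = "")  # 84 nt, no stops
    res84 <- detectPrematureStop(skip, exon84, exon_insert_pos = 31,
                                 cds_offset = 1)
    expect_true(res84$frame_preserved)
    expect_false(res84$stop_found)
    ## a stop-bearing 84-nt exon triggers detection
    exon84s <- paste0(paste(rep("GCA", 13), collapse = ""), "UGA",
                      paste(rep("GCA", 14), collapse = ""))
    expect_equal(nchar(exon84s), 84)
    ress <- detectPrematureStop(skip, exon84s, exon_insert_pos = 31,
                                cds_offset = 1)
    expect_true(ress$stop_found)
    expect_false(detectPrematureStop(skip, "GCAA", 31, 1)$frame_preserved)
    expect_error(detectPrematureStop(skip, "UAA", 31, cds_offset = 500),
                 "cds_offset")
})

test_that("virtual RT-PCR product sizes track exon content", {
    ## two isoforms differing by an 84-nt cassette exon
    skip_ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(101, 1001), end = c(400, 1400)))
    incl_ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(101, 601, 1001), end = c(400, 684, 1400)))
    sizes <- rtpcrProductSizes(list(skip = skip_ex, inclusion = incl_ex),
                               fwd_5p = 201, rev_5p = 1291)
    expect_equal(unname(sizes["inclusion"] - sizes["skip"]), 84)
    expect_equal(unname(sizes["skip"]), 200 + 291)
    ## identical isoforms give identical products
    s2 <- rtpcrProductSizes(list(a = skip_ex, b = skip_ex), 201, 1291)
    expect_equal(unname(s2["a"]), unname(s2["b"]))
    ## string-level virtual PCR oracle: splice the exon sequences and
    ## measure the amplicon on the transcript directly
    set.seed(52)
    chrseq <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                    collapse = "")
    spliced <- function(ex) paste(substring(
        chrseq, BiocGenerics::start(ex), BiocGenerics::end(ex)),
        collapse = "")
    txpos <- function(ex, gpos) {
        ## genomic -> transcript coordinate
        off <- 0L
        for (j in seq_along(ex)) {
            s <- BiocGenerics::start(ex)[j]; e <- BiocGenerics::end(ex)[j]
            if (gpos >= s && gpos <= e) return(off + gpos - s + 1L)
            off <- off + e - s + 1L
        }
        NA_integer_
    }
    for (iso in list(skip_ex, incl_ex)) {
        tx <- spliced(iso)
        f <- txpos(iso, 201); r <- txpos(iso, 1291)
        expect_equal(unname(rtpcrProductSizes(list(x = iso), 201, 1291)),
                     r - f + 1L)
        expect_lte(r - f + 1L, nchar(tx))
    }
    expect_error(rtpcrProductSizes(list(a = skip_ex), 500, 1291),
                 "not contained")
    expect_error(rtpcrProductSizes(list(a = skip_ex), 1291, 201),
                 "upstream")
})
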