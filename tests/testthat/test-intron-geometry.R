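geomModels <- function() {
    ## one + and one - strand gene, each with a [1000, 2000]-style intron
    mkModels(list(
        list(id = "gp", exon_starts = c(500, 2001),
             exon_ends = c(999, 2400),
             cds_start = 600, cds_end = 2300, strand = "+"),
        list(id = "gm", exon_starts = c(10500, 12001),
             exon_ends = c(10999, 12400),
             cds_start = 10600, cds_end = 12300, strand = "-")))
}

tagGR <- function(start, end, id) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end))
    S4Vectors::mcols(gr)$tag_id <- id
    gr
}

test_that("splice-site distances follow the exclusive-gap convention", {
    m <- geomModels()
    ## + strand: intron [1000, 2000], tag [1300, 1329] (width 30)
    cx <- locateContainingIntron(tagGR(1300, 1329, "t1"), m)
    expect_equal(cx$intron_length, 1001)
    expect_equal(cx$dist_upstream, 300)
    expect_equal(cx$dist_downstream, 671)
    expect_equal(cx$dist_upstream + cx$tag_length + cx$dist_downstream,
                 cx$intron_length)
    ## same offsets within the - strand intron [11000, 12000] swap sides
    cm <- locateContainingIntron(tagGR(11300, 11329, "t2"), m)
    expect_equal(cm$dist_upstream, 671)
    expect_equal(cm$dist_downstream, 300)
    ## a tag abutting the donor has distance zero
    c0 <- locateContainingIntron(tagGR(1000, 1029, "t3"), m)
    expect_equal(c0$dist_upstream, 0)
})

test_that("conservation and strand involution hold over simulated contexts", {
    cfg <- smallConfig(seed = 61, n_genes = 10L, unknown_frac = 0)
    g <- generateGenome(cfg)
    m <- generateGeneModels(g, cfg)
    set.seed(61)
    introns <- unlist(intronBlocks(m))
    tags <- randomTagsInRanges(introns, 1000, tag_len = 28L)
    cx <- locateContainingIntron(tags, m)
    expect_equal(nrow(cx), 1000)
    expect_true(all(cx$dist_upstream >= 0))
    expect_true(all(cx$dist_downstream >= 0))
    expect_true(all(cx$dist_upstream + cx$tag_length +
                        cx$dist_downstream == cx$intron_length))
    ## flipping every gene's strand swaps the two distances exactly
    cxf <- locateContainingIntron(tags, flipStrands(m))
    ord <- order(cx$tag_id); ordf <- order(cxf$tag_id)
    expect_equal(cx$dist_upstream[ord], cxf$dist_downstream[ordf])
    expect_equal(cx$dist_downstream[ord], cxf$dist_upstream[ordf])
    ## brute-force recomputation of a sample of contexts
    for (i in sample(nrow(cx), 50)) {
        row <- cx[i, ]
        intr <- intronBlocks(m)[[row$gene_id]]
        hit <- which(BiocGenerics::start(intr) <= row$intron_start &
                         BiocGenerics::end(intr) >= row$intron_end)
        expect_length(hit, 1)
        expect_equal(row$intron_length,
                     BiocGenerics::width(intr)[hit])
    }
})

test_that("geometry summaries report mean, SEM, median and range", {
    cx <- data.frame(intron_length = c(370, 247578),
                     dist_upstream = c(100, 200),
                     dist_downstream = c(240, 247348))
    s <- summarizeGeometry(cx)
    il <- s[s$metric == "intron_length", ]
    expect_equal(il$min, 370)
    expect_equal(il$max, 247578)
    expect_equal(il$mean, mean(c(370, 247578)))
    expect_equal(il$sem, stats::sd(c(370, 247578)) / sqrt(2))
    expect_equal(il$median, mean(c(370, 247578)))
    ## degenerate single context
    s1 <- summarizeGeometry(data.frame(intron_length = 500,
                                       dist_upstream = 100,
                                       dist_downstream = 370))
    expect_equal(s1$sem, rep(0, 3))
    expect_false(any(s1$sem_defined))
    expect_equal(s1$median[1], 500)
    ## direct formula evaluation on simulated contexts
    set.seed(62)
    cx2 <- data.frame(intron_length = sample(300:5000, 46),
                      dist_upstream = sample(0:400, 46),
                      dist_downstream = sample(0:400, 46))
    s2 <- summarizeGeometry(cx2)
    du <- s2[s2$metric == "dist_upstream", ]
    expect_equal(du$mean, mean(cx2$dist_upstream))
    expect_equal(du$sem, stats::sd(cx2$dist_upstream) / sqrt(46))
    expect_equal(du$median, stats::median(cx2$dist_upstream))
    ## permutation stability
    s3 <- summarizeGeometry(cx2[sample(46), ])
    expect_equal(s3, s2)
    expect_error(summarizeGeometry(cx2[0, ]), "no intron contexts")
})

test_that("proximity fractions count tags within the threshold per side", {
    ## 46 contexts with 7 within 500 nt of the upstream splice site
    cx <- data.frame(
        dist_upstream = c(rep(100, 7), rep(5000, 39)),
        dist_downstream = c(rep(5000, 42), rep(200, 4)),
        intron_length = rep(20000, 46))
    fr <- proximityFractions(cx, 500)
    expect_equal(round(unname(fr["within_upstream"]), 3), 0.152)
    expect_equal(round(unname(fr["within_downstream"]), 3), 0.087)
    expect_equal(unname(fr["within_either"]), (7 + 4) / 46)
    ## saturation: threshold at least the longest intron
    fr2 <- proximityFractions(cx, 5000)
    expect_equal(unname(fr2), c(1, 1, 1))
    ## brute-force agreement on random contexts
    set.seed(63)
    cx3 <- data.frame(dist_upstream = sample(0:2000, 200, TRUE),
                      dist_downstream = sample(0:2000, 200, TRUE))
    fr3 <- proximityFractions(cx3, 500)
    expect_equal(unname(fr3["within_upstream"]),
                 sum(cx3$dist_upstream <= 500) / 200)
    expect_equal(unname(fr3["within_either"]),
                 sum(cx3$dist_upstream <= 500 |
                         cx3$dist_downstream <= 500) / 200)
})

test_that("intron length bins are half-open and sum to one", {
    fr <- lengthBins(c(5000, 50000, 150000), c(10000, 100000))
    expect_equal(unname(fr), c(1, 1, 1) / 3)
    fr2 <- lengthBins(c(100, 200, 300), c(10000, 100000))
    expect_equal(unname(fr2[1]), 1)
    ## boundary values land in the right (upper) bin
    fr3 <- lengthBins(c(10000), c(10000, 100000))
    expect_equal(unname(fr3), c(0, 1, 0))
    ## simulated heavy tail recovers the generating mass
    set.seed(64)
    len <- sampleIntronLengths(500, median = 3000, cutoff = 10000,
                               frac = 0.15)
    fr4 <- lengthBins(len, c(10000))
    expect_true(abs(unname(fr4[2]) - 0.15) <= 0.05)
    expect_equal(sum(fr4), 1)
})

test_that("dataset comparison stacks one summary block per dataset", {
    set.seed(65)
    a <- data.frame(intron_length = sample(500:3000, 30),
                    dist_upstream = sample(0:500, 30),
                    dist_downstream = sample(0:500, 30))
    b <- data.frame(intron_length = sample(5000:30000, 30),
                    dist_upstream = sample(0:5000, 30),
                    dist_downstream = sample(0:5000, 30))
    cmp <- runComparison(short = a, long = b)
    expect_equal(nrow(cmp), 6)   # 2 datasets x 3 metrics
    expect_equal(unique(cmp$dataset), c("short", "long"))
    med <- function(d, m) cmp$median[cmp$dataset == d & cmp$metric == m]
    expect_lt(med("short", "intron_length"), med("long", "intron_length"))
    ## same dataset twice gives identical blocks
    cmp2 <- runComparison(x = a, y = a)
    expect_equal(cmp2$mean[cmp2$dataset == "x"],
                 cmp2$mean[cmp2$dataset == "y"])
})
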