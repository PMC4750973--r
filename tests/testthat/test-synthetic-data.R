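test_that("generated genomes follow the configured base composition and seed", {
    cfg <- simConfig(seed = 1, n_chroms = 1L, chrom_length = 10000L)
    g <- generateGenome(cfg)
    freq <- Biostrings::alphabetFrequency(g[[1]])[c("A", "C", "G", "T")]
    expect_true(all(abs(freq / 10000 - 0.25) <= 0.02))

    ## degenerate composition
    cfgA <- simConfig(seed = 2, chrom_length = 500L,
                      base_composition = c(1, 0, 0, 0))
    gA <- generateGenome(cfgA)
    expect_equal(as.character(gA[[1]]), strrep("A", 500))

    ## byte-identical FASTA for the same config
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
    generateGenome(cfg, path = f1)
    generateGenome(cfg, path = f2)
    expect_identical(readLines(f1), readLines(f2))

    ## invalid composition is rejected
    expect_error(simConfig(base_composition = c(0.5, 0.5, 0.5, 0.5)),
                 "composition")
})

test_that("intron length law delivers the configured median and tail mass", {
    set.seed(42)
    len <- sampleIntronLengths(500, median = 3000, cutoff = 10000,
                               frac = 0.15)
    expect_true(abs(mean(len > 10000) - 0.15) <= 0.05)
    expect_true(abs(stats::median(len) - 3000) / 3000 < 0.25)
})

test_that("gene models are well-formed and introns are exact exon gaps", {
    cfg <- smallConfig(seed = 3)
    g <- generateGenome(cfg)
    m <- generateGeneModels(g, cfg)
    expect_s4_class(m, "GeneModels")
    expect_length(m, cfg@n_genes)
    ## no overlap between gene spans
    spans <- geneSpans(m)
    expect_equal(sum(IRanges::overlapsAny(
        spans, drop.self = TRUE, drop.redundant = TRUE)), 0)
    ## introns are the gaps between consecutive blocks
    intr <- intronBlocks(m)
    for (id in geneIds(m)[1:3]) {
        ex <- exonBlocks(m)[[id]]
        gaps <- intr[[id]]
        expect_equal(BiocGenerics::start(gaps),
                     BiocGenerics::end(ex)[-length(ex)] + 1L)
        expect_equal(BiocGenerics::end(gaps),
                     BiocGenerics::start(ex)[-1] - 1L)
    }
    ## two-exon arithmetic: exons [100,200) and [500,600) in 0-based
    ## half-open coordinates give one intron [200,500) of length 300
    m2 <- mkModels(list(list(id = "g1", exon_starts = c(101, 501),
                             exon_ends = c(200, 600),
                             cds_start = 150, cds_end = 550)))
    i2 <- intronBlocks(m2)[["g1"]]
    expect_equal(BiocGenerics::start(i2), 201)
    expect_equal(BiocGenerics::end(i2), 500)
    expect_equal(BiocGenerics::width(i2), 300)
    ## sizing error when the genome cannot hold the genes
    tiny <- simConfig(seed = 1, chrom_length = 5000L, n_genes = 50L)
    expect_error(generateGeneModels(generateGenome(tiny), tiny),
                 "too small|not fit")
})

test_that("gene models round-trip through BED12", {
    cfg <- smallConfig(seed = 4, n_genes = 6L)
    m <- generateGeneModels(generateGenome(cfg), cfg)
    path <- tempfile(fileext = ".bed")
    writeGeneModelsBED(m, path)
    m2 <- readGeneModelsBED(path)
    expect_equal(geneIds(m2), geneIds(m))
    expect_equal(isKnown(m2), isKnown(m))
    for (id in geneIds(m)) {
        expect_equal(BiocGenerics::start(exonBlocks(m2)[[id]]),
                     BiocGenerics::start(exonBlocks(m)[[id]]))
        expect_equal(BiocGenerics::end(exonBlocks(m2)[[id]]),
                     BiocGenerics::end(exonBlocks(m)[[id]]))
    }
    expect_equal(BiocGenerics::start(cdsSpan(m2)),
                 BiocGenerics::start(cdsSpan(m)),
                 ignore_attr = TRUE)
})

test_that("planted sites are intronic, recorded, and length-preserving", {
    cfg <- smallConfig(seed = 5, n_sites = 20L)
    g <- generateGenome(cfg)
    m <- generateGeneModels(g, cfg)
    p <- plantBindingSites(g, m, cfg)
    expect_length(p$sites, 20)
    expect_equal(BiocGenerics::width(g), BiocGenerics::width(p$genome))
    ## genome substring at each site equals the DNA view of the motif
    motif_dna <- chartr("U", "T", cfg@motif)
    for (i in seq_along(p$sites)) {
        ch <- as.character(GenomeInfoDb::seqnames(p$sites)[i])
        s <- as.character(Biostrings::subseq(
            p$genome[[ch]], BiocGenerics::start(p$sites)[i],
            BiocGenerics::end(p$sites)[i]))
        expect_equal(s, motif_dna)
    }
    ## every site interval is intronic per the per-base oracle
    for (i in seq_along(p$sites)) {
        gid <- S4Vectors::mcols(p$sites)$gene_id[i]
        labs <- vapply(
            BiocGenerics::start(p$sites)[i]:BiocGenerics::end(p$sites)[i],
            oracleBaseLabel, character(1), models = m, id = gid)
        expect_true(all(labs == "intron"))
    }
    ## zero sites leaves the genome unchanged
    cfg0 <- smallConfig(seed = 5, n_sites = 0L)
    p0 <- plantBindingSites(g, m, cfg0)
    expect_identical(as.character(p0$genome), as.character(g))
})

test_that("clone libraries have the configured structure and exact truth", {
    cfg <- smallConfig(seed = 6, n_clones = 200L, contaminant_rate = 0.25,
                       rc_clones = FALSE)
    g <- generateGenome(cfg)
    m <- generateGeneModels(g, cfg)
    p <- plantBindingSites(g, m, cfg)
    sim <- simulateClipClones(p$genome, p$sites, cfg)
    expect_length(sim$clones, 200)
    expect_equal(nrow(sim$truth), 200)
    ## conservation: origins partition the library
    expect_equal(sum(table(sim$truth$origin)), 200)
    ## contaminant count within 3 sd of Binomial(200, 0.25)
    n_cont <- sum(sim$truth$origin == "contaminant")
    expect_true(abs(n_cont - 50) <= 3 * sqrt(200 * 0.25 * 0.75))
    ## well-formed clones are adapter5 + insert + adapter3
    wf <- sim$truth$origin != "malformed"
    expect_true(all(as.character(sim$clones)[wf] ==
                        paste0(cfg@adapter5, sim$truth$insert[wf],
                               cfg@adapter3)))
    ## determinism
    sim2 <- simulateClipClones(p$genome, p$sites, cfg)
    expect_identical(as.character(sim$clones), as.character(sim2$clones))
})

test_that("simulated DE tables encode their truth exactly", {
    sim <- simulateDeTable(n_genes = 1000L, frac_only_kd = 0.1, seed = 7)
    ## ~100 genes with control expression exactly 0
    expect_equal(sum(sim$table$expr_control == 0),
                 sum(sim$truth$category == "only_kd"))
    expect_equal(sum(sim$truth$category == "only_kd"), 100)
    expect_equal(sum(sim$table$expr_kd == 0),
                 sum(sim$truth$category == "only_control"))
    ## regulated genes meet the fold threshold
    reg <- sim$truth$category %in% c("shared_down", "shared_up")
    expect_true(all(sim$truth$true_fold[reg] >= 1.5))
    ## no categories requested -> all-zero summary
    none <- simulateDeTable(n_genes = 50, frac_down = 0, frac_up = 0,
                            frac_only_control = 0, frac_only_kd = 0,
                            seed = 8)
    s <- categorizeDe(none$table)$summary
    expect_true(all(s == 0))
})
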