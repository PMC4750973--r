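#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges GRangesList
NULL

#' Simulation configuration for the synthetic CLIP study
#'
#' Holds every knob of the synthetic-data generator: genome size and base
#' composition, gene-model geometry (UTR lengths, exon counts, the
#' heavy-tailed intron-length law), the planted binding-site motif, clone
#' library composition (site-derived, background, contaminant and malformed
#' fractions), tag-length bounds and the cloning adapter sequences.
#'
#' The intron-length law is a log-normal parameterised by its median and the
#' fraction of mass above a "large intron" cutoff, mirroring the heavy tail
#' of intron lengths in vertebrate genomes where binding-site-containing
#' introns are often tens to hundreds of kilobases long.
#'
#' @slot seed integer master seed; all generator randomness derives from it.
#' @slot n_chroms,chrom_length integer; number and length (nt) of chromosomes.
#' @slot base_composition numeric(4), probabilities for A,C,G,T summing to 1.
#' @slot n_genes integer number of non-overlapping genes to place.
#' @slot intron_median,intron_large_cutoff,intron_large_frac numeric;
#'   log-normal intron law with the stated median and the stated fraction of
#'   introns longer than the cutoff.
#' @slot min_exons integer minimum number of exons per gene (>= 3 so that a
#'   5'UTR-bearing first exon, internal CDS exons and a 3'UTR-bearing last
#'   exon all exist).
#' @slot utr5_len,utr3_len integer UTR lengths (nt).
#' @slot cds_exon_len integer length of each coding exon block (nt).
#' @slot unknown_frac numeric fraction of genes flagged "unknown"
#'   (EST-supported but unannotated loci).
#' @slot motif character binding-site motif over A/C/G/U (RNA alphabet).
#' @slot n_sites integer number of motif copies planted into introns.
#' @slot site_tag_rate,contaminant_rate,malformed_rate numeric clone-origin
#'   fractions; the remainder of clones are genomic background.
#' @slot tag_min_len,tag_max_len integer insert length bounds (nt).
#' @slot adapter5,adapter3 character cloning adapter sequences (DNA).
#' @slot n_clones integer library size.
#' @slot rc_clones logical; if TRUE each emitted clone is
#'   reverse-complemented with probability 0.5 (Sanger clones are read from
#'   either end).
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    n_chroms = "integer",
    chrom_length = "integer",
    base_composition = "numeric",
    n_genes = "integer",
    intron_median = "numeric",
    intron_large_cutoff = "numeric",
    intron_large_frac = "numeric",
    min_exons = "integer",
    utr5_len = "integer",
    utr3_len = "integer",
    cds_exon_len = "integer",
    unknown_frac = "numeric",
    motif = "character",
    n_sites = "integer",
    site_tag_rate = "numeric",
    contaminant_rate = "numeric",
    malformed_rate = "numeric",
    tag_min_len = "integer",
    tag_max_len = "integer",
    adapter5 = "character",
    adapter3 = "character",
    n_clones = "integer",
    rc_clones = "logical"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    p <- object@base_composition
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "base_composition must be 4 probabilities summing to 1")
    rates <- c(object@site_tag_rate, object@contaminant_rate,
               object@malformed_rate, object@unknown_frac,
               object@intron_large_frac)
    if (any(rates < 0) || any(rates > 1))
        msg <- c(msg, "all rates/fractions must lie in [0, 1]")
    if (object@site_tag_rate + object@contaminant_rate +
        object@malformed_rate > 1 + 1e-9)
        msg <- c(msg, "clone origin fractions must sum to <= 1")
    if (object@tag_min_len < 6L)
        msg <- c(msg, "tag_min_len must be >= 6 (the largest counted k-mer)")
    if (object@tag_max_len < object@tag_min_len)
        msg <- c(msg, "tag_max_len must be >= tag_min_len")
    if (object@chrom_length < 1L)
        msg <- c(msg, "chrom_length must be >= 1")
    if (!grepl("^[ACGU]+$", object@motif))
        msg <- c(msg, "motif must be a non-empty string over A/C/G/U")
    if (!nzchar(object@adapter5) || !nzchar(object@adapter3))
        msg <- c(msg, "adapters must be non-empty")
    if (grepl(object@adapter5, object@adapter3, fixed = TRUE) ||
        grepl(object@adapter3, object@adapter5, fixed = TRUE))
        msg <- c(msg, "adapters must not be substrings of each other")
    if (object@min_exons < 3L)
        msg <- c(msg, "min_exons must be >= 3")
    if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' All arguments have defaults describing the package's reference synthetic
#' study: one 2 Mb chromosome, 60 genes with log-normal intron lengths
#' (median 3,000 nt, 15\% above 10,000 nt), a planted (UG)3 motif, and a
#' 500-clone library with half the clones drawn from planted sites, a quarter
#' bacterial-rRNA-like contaminants and 5\% malformed clones.
#'
#' @param seed integer master seed.
#' @param n_chroms,chrom_length genome shape.
#' @param base_composition probabilities for A,C,G,T.
#' @param n_genes number of genes.
#' @param intron_median,intron_large_cutoff,intron_large_frac intron-length
#'   law (log-normal; median, and fraction above the cutoff).
#' @param min_exons,utr5_len,utr3_len,cds_exon_len gene geometry (nt).
#' @param unknown_frac fraction of genes flagged unknown.
#' @param motif RNA-alphabet motif to plant.
#' @param n_sites number of planted sites.
#' @param site_tag_rate,contaminant_rate,malformed_rate clone origin mix.
#' @param tag_min_len,tag_max_len insert length bounds.
#' @param adapter5,adapter3 adapter sequences (DNA).
#' @param n_clones library size.
#' @param rc_clones reverse-complement clones with probability 0.5?
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, n_clones = 100)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      n_chroms = 1L,
                      chrom_length = 2000000L,
                      base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      n_genes = 60L,
                      intron_median = 3000,
                      intron_large_cutoff = 10000,
                      intron_large_frac = 0.15,
                      min_exons = 4L,
                      utr5_len = 150L,
                      utr3_len = 300L,
                      cds_exon_len = 120L,
                      unknown_frac = 0.1,
                      motif = "UGUGUG",
                      n_sites = 40L,
                      site_tag_rate = 0.5,
                      contaminant_rate = 0.25,
                      malformed_rate = 0.05,
                      tag_min_len = 30L,
                      tag_max_len = 80L,
                      adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                      adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                      n_clones = 500L,
                      rc_clones = TRUE) {
    new("SimConfig",
        seed = as.integer(seed), n_chroms = as.integer(n_chroms),
        chrom_length = as.integer(chrom_length),
        base_composition = stats::setNames(as.numeric(base_composition),
                                           c("A", "C", "G", "T")),
        n_genes = as.integer(n_genes),
        intron_median = as.numeric(intron_median),
        intron_large_cutoff = as.numeric(intron_large_cutoff),
        intron_large_frac = as.numeric(intron_large_frac),
        min_exons = as.integer(min_exons),
        utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
        cds_exon_len = as.integer(cds_exon_len),
        unknown_frac = as.numeric(unknown_frac),
        motif = as.character(motif), n_sites = as.integer(n_sites),
        site_tag_rate = as.numeric(site_tag_rate),
        contaminant_rate = as.numeric(contaminant_rate),
        malformed_rate = as.numeric(malformed_rate),
        tag_min_len = as.integer(tag_min_len),
        tag_max_len = as.integer(tag_max_len),
        adapter5 = toupper(adapter5), adapter3 = toupper(adapter3),
        n_clones = as.integer(n_clones), rc_clones = as.logical(rc_clones))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (seed ", object@seed, ")\n",
        "  genome: ", object@n_chroms, " x ", object@chrom_length, " nt\n",
        "  genes: ", object@n_genes, " (", object@unknown_frac * 100,
        "% unknown); intron law: log-normal median ", object@intron_median,
        ", P(>", object@intron_large_cutoff, ") = ",
        object@intron_large_frac, "\n",
        "  motif ", object@motif, " x ", object@n_sites, " sites\n",
        "  clones: ", object@n_clones, " (site ", object@site_tag_rate,
        ", contaminant ", object@contaminant_rate, ", malformed ",
        object@malformed_rate, ")\n", sep = "")
})

#' Strand-aware transcript models
#'
#' A compact container for one-transcript-per-gene models: exon blocks as a
#' named \linkS4class{GRangesList} (sorted, disjoint, strand set), the
#' genomic CDS span per gene, and a known/unknown flag ("unknown" marks
#' EST/cDNA-supported but unannotated loci). Introns are derived as the gaps
#' between consecutive exon blocks.
#'
#' @slot exons named GRangesList of exon blocks, one element per gene.
#' @slot cds named GRanges, one genomic CDS span per gene.
#' @slot known named logical; TRUE for annotated ("known") genes.
#' @export
setClass("GeneModels", representation(
    exons = "GRangesList",
    cds = "GRanges",
    known = "logical"
))

setValidity("GeneModels", function(object) {
    msg <- character()
    ids <- names(object@exons)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "exons must be named by unique gene ids")
    if (!identical(ids, names(object@cds)) ||
        !identical(ids, names(object@known)))
        msg <- c(msg, "exons, cds and known must share identical names")
    ok_sorted <- all(vapply(object@exons, function(gr) {
        s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
        length(gr) >= 1L && !is.unsorted(s, strictly = TRUE) &&
            all(s[-1] > e[-length(e)] + 0L)
    }, logical(1)))
    if (!ok_sorted)
        msg <- c(msg, "exon blocks must be sorted and disjoint within genes")
    for (i in seq_along(object@cds)) {
        cds <- object@cds[i]
        exn <- object@exons[[i]]
        cov <- GenomicRanges::intersect(
            GenomicRanges::granges(cds), GenomicRanges::granges(exn),
            ignore.strand = TRUE)
        if (BiocGenerics::start(cds) < min(BiocGenerics::start(exn)) ||
            BiocGenerics::end(cds) > max(BiocGenerics::end(exn)))
            msg <- c(msg, "CDS span must lie within the exon span")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneModels-class constructor.
#' @param exons named GRangesList of exon blocks.
#' @param cds named GRanges of genomic CDS spans.
#' @param known named logical vector.
#' @export
geneModels <- function(exons, cds, known) {
    new("GeneModels", exons = exons, cds = cds,
        known = stats::setNames(as.logical(known), names(exons)))
}

#' A set of distinct CLIP tags
#'
#' Distinct insert sequences recovered from a clone library, with per-tag
#' occurrence counts and the ids of the source clones, plus the extraction
#' report (totals per rejection reason). "Different tags" means distinct
#' sequences; the occurrence count records how many accepted clones carried
#' each one.
#'
#' @slot tags DFrame with columns \code{sequence} (DNA character),
#'   \code{count} (integer) and \code{clone_ids} (CharacterList); row names
#'   are tag ids.
#' @slot report named integer vector: accepted clones and totals per
#'   rejection reason.
#' @export
setClass("ClipTagSet", representation(
    tags = "DFrame",
    report = "integer"
))

setValidity("ClipTagSet", function(object) {
    msg <- character()
    df <- object@tags
    need <- c("sequence", "count", "clone_ids")
    if (!all(need %in% colnames(df)))
        msg <- c(msg, "tags must have columns sequence, count, clone_ids")
    else {
        if (anyDuplicated(df$sequence))
            msg <- c(msg, "tag sequences must be distinct")
        if (!all(df$count == lengths(df$clone_ids)))
            msg <- c(msg, "count must equal the number of clone_ids")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClipTagSet", function(object) {
    cat(class(object), "with", nrow(object@tags), "distinct tags from",
        sum(object@tags$count), "accepted clones\n")
    rep <- object@report
    rej <- rep[setdiff(names(rep), "accepted")]
    rej <- rej[rej > 0]
    if (length(rej))
        cat("rejections:", paste(names(rej), rej, sep = "=", collapse = ", "),
            "\n")
})

#' @describeIn ClipTagSet-class number of distinct tags.
#' @param x a ClipTagSet.
#' @export
setMethod("length", "ClipTagSet", function(x) nrow(x@tags))
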